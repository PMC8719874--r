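#' Generate a toy coding genome
#'
#' Builds a small synthetic gene catalogue used by the cohort simulator and
#' the mutation-rate model: each gene gets a sense-strand coding sequence
#' (ATG start, sense codons, terminal stop), a fake genomic anchor
#' (chromosome and start coordinate) and a per-gene LOEUF-like constraint
#' value. Coding lengths are drawn log-uniformly so the catalogue spans
#' short ion-channel-exon-sized genes up to titin-scale ones.
#'
#' @param n_genes Number of genes (default 200).
#' @param min_length,max_length Coding-length bounds in bases; lengths are
#'   rounded to whole codons (defaults 300 and 15000, i.e. 0.3-15 kb).
#' @param seed RNG seed; the catalogue is a pure function of its arguments.
#' @return A `data.frame` of class `toy_genome` with columns `symbol`,
#'   `chrom`, `start`, `cds`, `length`, `loeuf`.
#' @export
#' @examples
#' g <- toy_genome(n_genes = 5, max_length = 600)
#' g$length
toy_genome <- function(n_genes = 200, min_length = 300, max_length = 15000,
                       seed = 202) {
  stopifnot(n_genes >= 1, min_length >= 9, max_length >= min_length)
  key <- paste("toy_genome", n_genes, min_length, max_length, seed, sep = "_")
  cache_get_or(key, function() {
    with_seed(seed, {
      codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                      collapse = "")
      stops <- c("TAA", "TAG", "TGA")
      sense <- setdiff(codons, stops)

      n_codons <- pmax(
        round(exp(stats::runif(n_genes, log(min_length), log(max_length))) / 3),
        ceiling(min_length / 3)
      )
      cds <- vapply(n_codons, function(k) {
        paste0("ATG",
               paste(sample(sense, k - 2, replace = TRUE), collapse = ""),
               sample(stops, 1))
      }, character(1))

      symbol <- sprintf("GENE%03d", seq_len(n_genes))
      chrom <- as.character(rep_len(1:22, n_genes))
      # lay genes along each chromosome with generous spacing
      start <- integer(n_genes)
      for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        start[idx] <- cumsum(c(10000L, nchar(cds[idx])[-length(idx)] + 10000L))
      }
      loeuf <- round(stats::runif(n_genes, 0.01, 2), 3)

      structure(
        data.frame(symbol = symbol, chrom = chrom, start = start,
                   cds = cds, length = nchar(cds), loeuf = loeuf,
                   stringsAsFactors = FALSE),
        class = c("toy_genome", "data.frame"),
        seed = seed
      )
    })
  })
}
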