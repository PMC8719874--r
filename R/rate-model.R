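## Trinucleotide-context mutation-rate model.
##
## The null for every Poisson burden test: per-gene, per-effect-class
## probabilities of a de novo SNV per chromosome per generation, obtained by
## summing trimer-context substitution rates over every coding position and
## classifying each substitution under the standard genetic code.

EFFECT_CLASSES <- c("synonymous", "missense", "inframe-indel", "LoF")

# raw substitution categories -> requested effect class indicator
match_effect_class <- function(raw, effect_class) {
  switch(effect_class,
    synonymous    = raw == "synonymous",
    missense      = raw == "missense",
    LoF           = raw == "stop_gain",
    nonsynonymous = raw %in% c("missense", "stop_gain", "stop_loss"),
    any           = rep(TRUE, length(raw)),
    stop_tb("unknown effect class: ", effect_class)
  )
}

# enumerate and classify all 3L single-base substitutions of a CDS
classify_substitutions <- function(cds) {
  L <- nchar(cds)
  if (L < 3) stop_tb("coding sequence shorter than one codon")
  if (L %% 3 != 0) stop_tb("coding sequence length not a multiple of 3")
  bases <- strsplit(cds, "", fixed = TRUE)[[1]]
  if (!all(bases %in% DNA_BASES)) stop_tb("coding sequence has non-ACGT bases")

  alt_lookup <- t(vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b),
                         character(3)))
  pos <- rep(seq_len(L), each = 3)
  ref <- bases[pos]
  alt <- as.vector(t(alt_lookup[bases, , drop = FALSE]))

  codon_idx <- (pos - 1L) %/% 3L + 1L
  within <- (pos - 1L) %% 3L + 1L
  cm <- matrix(bases, nrow = 3)
  c1 <- cm[1, codon_idx]; c2 <- cm[2, codon_idx]; c3 <- cm[3, codon_idx]
  c1[within == 1L] <- alt[within == 1L]
  c2[within == 2L] <- alt[within == 2L]
  c3[within == 3L] <- alt[within == 3L]

  gc_tab <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc_tab[paste0(cm[1, codon_idx], cm[2, codon_idx],
                                 cm[3, codon_idx])])
  aa_alt <- unname(gc_tab[paste0(c1, c2, c3)])

  raw <- ifelse(aa_ref == aa_alt, "synonymous",
         ifelse(aa_alt == "*", "stop_gain",
         ifelse(aa_ref == "*", "stop_loss", "missense")))

  data.frame(pos = pos, ref = ref, alt = alt, class = raw,
             stringsAsFactors = FALSE)
}

# named rate vector keyed "TRIMER>ALT", with N-flank keys imputed as the
# mean over the four compatible trimers (CDS-edge rule)
rate_lookup <- function(rate_table) {
  validate_rate_table(rate_table)
  key <- paste0(rate_table$trimer, ">", rate_table$alt)
  rates <- stats::setNames(rate_table$rate, key)

  centre <- substr(rate_table$trimer, 2, 2)
  right <- substr(rate_table$trimer, 3, 3)
  left <- substr(rate_table$trimer, 1, 1)
  n_left <- tapply(rate_table$rate,
                   paste0("N", centre, right, ">", rate_table$alt), mean)
  n_right <- tapply(rate_table$rate,
                    paste0(left, centre, "N", ">", rate_table$alt), mean)
  c(rates, n_left, n_right)
}

# per-substitution table with trimer context and rate attached
substitution_table <- function(cds, rate_table, flank5 = "N", flank3 = "N") {
  subs <- classify_substitutions(cds)
  bases <- strsplit(cds, "", fixed = TRUE)[[1]]
  L <- length(bases)
  prev <- c(flank5, bases[-L])
  nxt <- c(bases[-1], flank3)
  trimer <- paste0(prev[subs$pos], subs$ref, nxt[subs$pos])
  lk <- rate_lookup(rate_table)
  subs$trimer <- trimer
  subs$rate <- unname(lk[paste0(trimer, ">", subs$alt)])
  if (anyNA(subs$rate)) stop_tb("trimer missing from rate table")
  subs
}

#' Expected de novo SNV count for one gene
#'
#' Sums, over every coding position and alternate base, the trimer-context
#' mutation rate times an indicator that the substitution produces the
#' requested effect class under the standard genetic code (reading frame
#' from the CDS start), then scales to a cohort: expectation = probability
#' x 2 chromosomes x `n_trios`.
#'
#' @param cds Coding sequence (sense strand, concatenated CDS, length a
#'   multiple of 3) as a single string.
#' @param rate_table Trimer rate table (see [read_rate_table()] or
#'   [default_rate_table()]).
#' @param effect_class One of `"synonymous"`, `"missense"`, `"LoF"`
#'   (stop-gain), `"nonsynonymous"` (missense + stop-gain + stop-loss) or
#'   `"any"`.
#' @param n_trios Number of trios the expectation is scaled to.
#' @param flank5,flank3 Single bases flanking the CDS, used for the trimer
#'   context of the first and last base. The default `"N"` imputes the mean
#'   rate over the four compatible trimers.
#' @return A single non-negative expectation.
#' @export
#' @examples
#' rt <- uniform_rate_table(1e-8)
#' expected_count("ATGAAATGA", rt, "any", n_trios = 1)
expected_count <- function(cds, rate_table,
                           effect_class = c("nonsynonymous", "synonymous",
                                            "missense", "LoF", "any"),
                           n_trios = 1, flank5 = "N", flank3 = "N") {
  effect_class <- match.arg(effect_class)
  stopifnot(n_trios >= 1)
  subs <- substitution_table(cds, rate_table, flank5, flank3)
  p <- sum(subs$rate[match_effect_class(subs$class, effect_class)])
  p * 2 * n_trios
}

#' Per-gene effect-class mutation probabilities for a genome
#'
#' Computes, for every gene in a catalogue, the per-chromosome
#' per-generation probability of a synonymous, missense, LoF (stop-gain),
#' stop-loss and nonsynonymous de novo SNV. This is the workhorse behind
#' [geneset_expected()] and the cohort simulator's placement weights.
#'
#' @param genome A [toy_genome()]-style data frame with `symbol` and `cds`.
#' @param rate_table Trimer rate table.
#' @return Data frame with one row per gene and columns `symbol`, `length`,
#'   `p_synonymous`, `p_missense`, `p_lof`, `p_stop_loss`, `p_nonsynonymous`,
#'   `p_any`.
#' @export
gene_class_probabilities <- function(genome, rate_table) {
  seed <- attr(genome, "seed")
  key <- if (!is.null(seed)) {
    paste("gcp", seed, nrow(genome), sum(genome$length),
          signif(sum(rate_table$rate), 10), sep = "_")
  }
  compute <- function() {
    lk <- rate_lookup(rate_table)
    rows <- lapply(seq_len(nrow(genome)), function(i) {
      subs <- substitution_table(genome$cds[i], rate_table)
      agg <- tapply(subs$rate, subs$class, sum)
      get0c <- function(nm) if (nm %in% names(agg)) unname(agg[[nm]]) else 0
      data.frame(
        symbol = genome$symbol[i],
        length = nchar(genome$cds[i]),
        p_synonymous = get0c("synonymous"),
        p_missense = get0c("missense"),
        p_lof = get0c("stop_gain"),
        p_stop_loss = get0c("stop_loss"),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out$p_nonsynonymous <- out$p_missense + out$p_lof + out$p_stop_loss
    out$p_any <- out$p_synonymous + out$p_nonsynonymous
    out
  }
  if (is.null(key)) compute() else cache_get_or(key, compute)
}

#' Expected de novo SNV count for a gene set
#'
#' Sum of per-gene expectations over a set of gene symbols (expectations
#' are additive over disjoint genes and linear in the number of trios).
#' Symbols absent from the gene catalogue are reported with a warning, not
#' silently dropped.
#'
#' @inheritParams gene_class_probabilities
#' @param symbols Character vector of gene symbols.
#' @inheritParams expected_count
#' @return A single expectation.
#' @export
geneset_expected <- function(genome, symbols, rate_table,
                             effect_class = c("nonsynonymous", "synonymous",
                                              "missense", "LoF", "any"),
                             n_trios = 1) {
  effect_class <- match.arg(effect_class)
  symbols <- unique(symbols)
  known <- symbols %in% genome$symbol
  if (!any(known)) stop_tb("no gene symbol in the set is present in the genome")
  if (!all(known)) {
    warning(sum(!known), " gene symbol(s) not in genome, skipped: ",
            paste(utils::head(symbols[!known], 5), collapse = ", "))
  }
  gcp <- gene_class_probabilities(genome[genome$symbol %in% symbols, ,
                                         drop = FALSE], rate_table)
  col <- switch(effect_class,
                synonymous = "p_synonymous", missense = "p_missense",
                LoF = "p_lof", nonsynonymous = "p_nonsynonymous",
                any = "p_any")
  sum(gcp[[col]]) * 2 * n_trios
}

#' Expected de novo indel count for a gene set
#'
#' The trimer framework covers SNVs only; coding indels are modelled as a
#' single genome-wide per-trio rate apportioned across genes by coding
#' length.
#'
#' @inheritParams geneset_expected
#' @param rate_per_trio Genome-wide coding indel rate per trio (default
#'   0.1).
#' @return A single expectation.
#' @export
indel_expected <- function(genome, symbols, rate_per_trio = 0.1,
                           n_trios = 1) {
  symbols <- unique(symbols)
  known <- symbols %in% genome$symbol
  if (!any(known)) stop_tb("no gene symbol in the set is present in the genome")
  share <- sum(genome$length[genome$symbol %in% symbols]) /
           sum(genome$length)
  rate_per_trio * share * n_trios
}

## ---- rate tables -----------------------------------------------------------

all_trimers <- function() {
  g <- expand.grid(a = DNA_BASES, b = DNA_BASES, c = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$a, g$b, g$c)
}

validate_rate_table <- function(rate_table) {
  need <- c("trimer", "alt", "rate")
  if (!all(need %in% names(rate_table))) {
    stop_tb("rate table must have columns ", paste(need, collapse = ", "))
  }
  key <- paste0(rate_table$trimer, ">", rate_table$alt)
  dup <- duplicated(key)
  if (any(dup)) stop_tb("duplicate rate-table row(s): ", key[which(dup)[1]])
  bad_alt <- rate_table$alt == substr(rate_table$trimer, 2, 2)
  if (any(bad_alt)) stop_tb("alt equals central base at row ", which(bad_alt)[1])
  expected_keys <- as.vector(vapply(all_trimers(), function(tri) {
    paste0(tri, ">", setdiff(DNA_BASES, substr(tri, 2, 2)))
  }, character(3)))
  missing <- setdiff(expected_keys, key)
  if (length(missing)) {
    stop_tb("rate table incomplete: ", length(missing),
            " contexts missing (e.g. ", missing[1], ")")
  }
  if (any(rate_table$rate <= 0 | rate_table$rate >= 1)) {
    stop_tb("rates must lie strictly in (0, 1)")
  }
  invisible(rate_table)
}

#' Read or write a trimer mutation-rate table
#'
#' The table is a tab-delimited file with header columns `trimer`,
#' `alt` (alternate central base) and `rate` (per-chromosome per-generation
#' substitution probability). It must cover all 64 trimers x 3 alternate
#' central bases (192 rows), with no duplicates and every rate in (0, 1).
#'
#' @param path File path.
#' @return `read_rate_table` returns the validated data frame.
#' @export
read_rate_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_rate_table(tab)
  tab
}

#' @rdname read_rate_table
#' @param rate_table Rate table data frame.
#' @export
write_rate_table <- function(rate_table, path) {
  validate_rate_table(rate_table)
  utils::write.table(rate_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Constant-rate table (every substitution at the same rate)
#'
#' Useful for closed-form checks: a single-codon gene then has expectation
#' `9 * rate * 2 * n_trios`.
#'
#' @param rate Per-substitution rate.
#' @return A 192-row rate table.
#' @export
uniform_rate_table <- function(rate = 1e-8) {
  tri <- all_trimers()
  out <- do.call(rbind, lapply(tri, function(t3) {
    data.frame(trimer = t3, alt = setdiff(DNA_BASES, substr(t3, 2, 2)),
               rate = rate, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# synthetic but realistically shaped rates: transition/transversion ratio
# near 2, CpG transitions boosted ~8x, log-normal context noise
random_rate_table <- function(seed = 7, base_rate = 1.2e-8) {
  with_seed(seed, {
    out <- uniform_rate_table(base_rate)
    centre <- substr(out$trimer, 2, 2)
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    is_ts <- out$alt == transition[centre]
    cpg_ts <- (centre == "C" & substr(out$trimer, 3, 3) == "G" & out$alt == "T") |
              (centre == "G" & substr(out$trimer, 1, 1) == "C" & out$alt == "A")
    mult <- ifelse(cpg_ts, 8, ifelse(is_ts, 4, 1))
    out$rate <- base_rate * mult * stats::rlnorm(nrow(out), 0, 0.4)
    out
  })
}

#' Default calibrated trimer rate table for a toy genome
#'
#' Generates a synthetic rate table with realistic shape (transitions over
#' transversions, boosted CpG transitions, context noise) and rescales it
#' once so that the genome-wide nonsynonymous expectation at a reference
#' cohort size matches a target count. With the defaults, a 124-trio cohort
#' has an exome-wide expected nonsynonymous de novo SNV count of 85.5,
#' which puts the whole simulator on the scale of a real trio exome study.
#'
#' @param genome Toy genome the calibration is computed against.
#' @param exome_nonsyn_expectation Target genome-wide nonsynonymous
#'   expectation at `n_trios` trios.
#' @param n_trios Reference cohort size for the calibration.
#' @param seed Seed for the pre-calibration rate shape.
#' @return A 192-row calibrated rate table.
#' @export
default_rate_table <- function(genome = toy_genome(),
                               exome_nonsyn_expectation = 85.5,
                               n_trios = 124, seed = 7) {
  key <- paste("drt", attr(genome, "seed") %||% "x", nrow(genome),
               exome_nonsyn_expectation, n_trios, seed, sep = "_")
  cache_get_or(key, function() {
    raw <- random_rate_table(seed = seed)
    gcp <- gene_class_probabilities(genome, raw)
    current <- sum(gcp$p_nonsynonymous) * 2 * n_trios
    raw$rate <- raw$rate * exome_nonsyn_expectation / current
    raw
  })
}
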