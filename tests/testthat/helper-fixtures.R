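# shared fixtures: all built in code, no files

small_genome <- function(n_genes = 12, max_length = 900, seed = 404) {
  toy_genome(n_genes = n_genes, min_length = 300, max_length = max_length,
             seed = seed)
}

# one trio variant record with explicit read evidence
trio_record <- function(child_gt = "0/1", child_alt = 13, child_dp = 28,
                        mother_gt = "0/0", mother_alt = 0, mother_dp = 50,
                        father_gt = "0/0", father_alt = 0, father_dp = 50,
                        trio_id = "T1", chrom = "1", pos = 100,
                        ref = "A", alt = "G") {
  data.frame(trio_id = trio_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt,
             key = variant_key(chrom, pos, ref, alt),
             child_gt = child_gt, child_ref_reads = child_dp - child_alt,
             child_alt_reads = child_alt, child_dp = child_dp,
             mother_gt = mother_gt, mother_ref_reads = mother_dp - mother_alt,
             mother_alt_reads = mother_alt, mother_dp = mother_dp,
             father_gt = father_gt, father_ref_reads = father_dp - father_alt,
             father_alt_reads = father_alt, father_dp = father_dp,
             stringsAsFactors = FALSE)
}

# annotation rows matching trio_record() keys
annotation_row <- function(key, gene = "GENE001", effect = "missense",
                           score = 25, clinvar = "none", loeuf = 1.0) {
  data.frame(key = key, gene = gene, effect = effect, score = score,
             clinvar = clinvar, loeuf = loeuf, stringsAsFactors = FALSE)
}

# independent two-sided Fisher p: full enumeration over tables with the
# observed margins, minimum-likelihood inclusion rule
fisher_p_enumeration <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent per-class expectation: brute-force enumeration of all 9L
# substitutions, translated codon-by-codon with Biostrings
expected_count_bruteforce <- function(cds, rate_table, effect_class,
                                      n_trios = 1) {
  bases <- strsplit(cds, "")[[1]]
  L <- length(bases)
  rate_of <- function(trimer, alt) {
    if (substr(trimer, 1, 1) == "N" || substr(trimer, 3, 3) == "N") {
      pat <- strsplit(trimer, "")[[1]]
      hits <- rate_table[substr(rate_table$trimer, 2, 2) == pat[2] &
                           rate_table$alt == alt &
                           (pat[1] == "N" |
                              substr(rate_table$trimer, 1, 1) == pat[1]) &
                           (pat[3] == "N" |
                              substr(rate_table$trimer, 3, 3) == pat[3]), ]
      return(mean(hits$rate))
    }
    rate_table$rate[rate_table$trimer == trimer & rate_table$alt == alt]
  }
  translate1 <- function(codon) {
    as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                       no.init.codon = TRUE))
  }
  total <- 0
  for (i in seq_len(L)) {
    ci <- (i - 1) %/% 3
    codon <- substr(cds, ci * 3 + 1, ci * 3 + 3)
    aa_ref <- translate1(codon)
    prev <- if (i == 1) "N" else bases[i - 1]
    nxt <- if (i == L) "N" else bases[i + 1]
    for (alt in setdiff(c("A", "C", "G", "T"), bases[i])) {
      mut <- codon
      substr(mut, (i - 1) %% 3 + 1, (i - 1) %% 3 + 1) <- alt
      aa_alt <- translate1(mut)
      raw <- if (aa_ref == aa_alt) "synonymous"
             else if (aa_alt == "*") "stop_gain"
             else if (aa_ref == "*") "stop_loss"
             else "missense"
      keep <- switch(effect_class,
                     synonymous = raw == "synonymous",
                     missense = raw == "missense",
                     LoF = raw == "stop_gain",
                     nonsynonymous = raw %in% c("missense", "stop_gain",
                                                "stop_loss"),
                     any = TRUE)
      if (keep) total <- total + rate_of(paste0(prev, bases[i], nxt), alt)
    }
  }
  total * 2 * n_trios
}
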