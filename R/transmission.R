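## Overtransmission analysis: enumerate deleterious heterozygous parental
## variants, test transmission against the Mendelian null of one half, and
## test recessive biallelic genotype formation.

#' Enumerate qualifying deleterious parental heterozygous variants
#'
#' A parental heterozygous variant qualifies if it is 1) LoF in a gene with
#' LOEUF below the constraint cutoff, or 2) missense with a ClinVar
#' pathogenic or likely-pathogenic label. One entry is produced per
#' (variant, carrier parent); a variant carried heterozygously by both
#' parents yields two entries. The transmitted flag is true iff the child
#' carries the alternate allele; entries with a missing child genotype are
#' marked indeterminate and excluded from the test denominator. De novo
#' sites (child carries, neither parent does) are not parental variants
#' and do not qualify.
#'
#' @param records Trio variant records (see [read_trio_vcf()]).
#' @param annotations Annotation table with `key`, `gene`, `effect`,
#'   `clinvar`, `loeuf`.
#' @param loeuf_cutoff LoF-intolerance cutoff (default 0.35, strict).
#' @param autosomes_only Drop X/Y/MT records (the 0.5 transmission null
#'   assumes autosomal biparental inheritance); default `TRUE`.
#' @return Data frame with one row per qualifying (variant, parent):
#'   `trio_id`, `key`, `gene`, `carrier_parent`, `rule`, `transmitted`,
#'   `indeterminate`.
#' @export
enumerate_qualifying <- function(records, annotations, loeuf_cutoff = 0.35,
                                 autosomes_only = TRUE) {
  check_trio_columns(records)
  if (autosomes_only) {
    records <- records[!toupper(records$chrom) %in%
                         c("X", "Y", "MT", "M", "CHRX", "CHRY", "CHRM"), ,
                       drop = FALSE]
  }
  idx <- match(records$key, annotations$key)
  eff <- annotations$effect[idx]
  loeuf <- annotations$loeuf[idx]
  clinvar <- annotations$clinvar[idx]
  rule <- ifelse(!is.na(eff) & eff == "LoF" & !is.na(loeuf) &
                   loeuf < loeuf_cutoff, "LoF-in-constrained",
          ifelse(!is.na(eff) & eff == "missense" & !is.na(clinvar) &
                   clinvar %in% c("pathogenic", "likely_pathogenic"),
                 "ClinVar-pathogenic-missense", NA_character_))

  out <- NULL
  for (parent in c("mother", "father")) {
    het <- !is.na(records[[paste0(parent, "_gt")]]) &
      records[[paste0(parent, "_gt")]] == "0/1" & !is.na(rule)
    if (!any(het)) next
    child_gt <- records$child_gt[het]
    out <- rbind(out, data.frame(
      trio_id = records$trio_id[het],
      key = records$key[het],
      gene = annotations$gene[idx][het],
      carrier_parent = parent,
      rule = rule[het],
      transmitted = !is.na(child_gt) & child_gt %in% c("0/1", "1/1"),
      indeterminate = is.na(child_gt),
      stringsAsFactors = FALSE))
  }
  out %||% data.frame(trio_id = character(), key = character(),
                      gene = character(), carrier_parent = character(),
                      rule = character(), transmitted = logical(),
                      indeterminate = logical(), stringsAsFactors = FALSE)
}

#' One-sided binomial overtransmission test
#'
#' Under the Mendelian null a qualifying heterozygous parental variant is
#' transmitted with probability one half; the test reports the exact upper
#' tail `P(X >= n_transmitted)` for `X ~ Binomial(n_qualifying, 0.5)`.
#'
#' @param n_transmitted Number of transmitted qualifying variants.
#' @param n_qualifying Total qualifying variants (determinate entries).
#' @return Data frame with `n_qualifying`, `n_transmitted`, `fraction`
#'   (2-decimal) and one-sided `p_value`.
#' @export
#' @examples
#' overtransmission_test(11, 14)  # fraction 0.79, p ~ 0.03
overtransmission_test <- function(n_transmitted, n_qualifying) {
  if (n_qualifying < 1) stop_tb("need at least one qualifying variant")
  if (n_transmitted > n_qualifying) {
    stop_tb("transmitted count exceeds qualifying count")
  }
  p <- stats::binom.test(n_transmitted, n_qualifying, p = 0.5,
                         alternative = "greater")$p.value
  data.frame(n_qualifying = n_qualifying, n_transmitted = n_transmitted,
             fraction = round(n_transmitted / n_qualifying, 2), p_value = p)
}

#' One-sided binomial recessive-formation test
#'
#' An "opportunity" is a trio in which both parents are heterozygous
#' carriers at biallelic-compatible sites of the same gene; under the null
#' each opportunity forms the biallelic genotype with probability 0.25.
#' Reports the exact upper tail `P(X >= n_formed)`.
#'
#' @param n_formed Number of opportunities where the biallelic genotype
#'   formed.
#' @param n_opportunities Total opportunities.
#' @param per_opportunity_p Null formation probability (default 0.25).
#' @return Data frame with counts, `fraction` and one-sided `p_value`.
#' @export
#' @examples
#' recessive_formation_test(1, 2)  # p = 0.4375 exactly
recessive_formation_test <- function(n_formed, n_opportunities,
                                     per_opportunity_p = 0.25) {
  if (n_opportunities < 1) stop_tb("need at least one opportunity")
  if (per_opportunity_p <= 0 || per_opportunity_p >= 1) {
    stop_tb("per_opportunity_p must lie in (0, 1)")
  }
  if (n_formed > n_opportunities) {
    stop_tb("formed count exceeds opportunity count")
  }
  p <- stats::binom.test(n_formed, n_opportunities, p = per_opportunity_p,
                         alternative = "greater")$p.value
  data.frame(n_opportunities = n_opportunities, n_formed = n_formed,
             fraction = round(n_formed / n_opportunities, 2), p_value = p)
}

#' Summarize transmission of enumerated qualifying variants
#'
#' Applies [overtransmission_test()] to an [enumerate_qualifying()] table,
#' excluding indeterminate entries from the denominator.
#'
#' @param qualifying Output of [enumerate_qualifying()].
#' @return As [overtransmission_test()], with an extra column
#'   `n_indeterminate`.
#' @export
transmission_summary <- function(qualifying) {
  det <- qualifying[!qualifying$indeterminate, , drop = FALSE]
  if (!nrow(det)) stop_tb("no determinate qualifying variants")
  out <- overtransmission_test(sum(det$transmitted), nrow(det))
  out$n_indeterminate <- sum(qualifying$indeterminate)
  out
}
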