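## Burden hypothesis tests: one-sided exact Poisson observed-vs-expected,
## observed-minus-expected with an exact (Garwood) lower confidence bound,
## two-sided Fisher carrier tests with conditional-MLE odds ratios, and the
## deterministic screen-style call filters.

#' One-sided Poisson burden test
#'
#' Tests whether an observed de novo count exceeds the mutation-model
#' expectation: `p = P(X >= observed)` for `X ~ Poisson(expected)`, the
#' exact upper tail. Vectorized over `observed`/`expected`.
#'
#' @param observed Observed count(s).
#' @param expected Expected count(s) under the rate model (> 0).
#' @param geneset,effect_class Optional labels carried into the result.
#' @return Data frame with columns `geneset`, `effect_class`, `observed`,
#'   `expected`, `enrichment`, `obs_minus_exp`, `obs_minus_exp_lower95`
#'   (exact Poisson lower limit on the observed count minus the
#'   expectation) and `p_value`.
#' @export
#' @examples
#' poisson_burden_test(5, 3.12)   # enrichment 1.60, p ~ 0.21
poisson_burden_test <- function(observed, expected, geneset = NA_character_,
                                effect_class = NA_character_) {
  if (any(expected <= 0)) stop_tb("expected count must be > 0")
  if (any(observed < 0 | observed != floor(observed))) {
    stop_tb("observed must be a non-negative integer count")
  }
  ci <- obs_minus_exp_ci(observed, expected)
  data.frame(geneset = geneset, effect_class = effect_class,
             observed = observed, expected = expected,
             enrichment = observed / expected,
             obs_minus_exp = ci$estimate,
             obs_minus_exp_lower95 = ci$lower,
             p_value = stats::ppois(observed - 1, expected,
                                    lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Observed-minus-expected estimate with exact lower confidence bound
#'
#' Estimate is `observed - expected`; the lower bound shifts the exact
#' (Garwood, chi-square inversion) lower confidence limit for a Poisson
#' count by the expectation. With the default two-sided 95% construction
#' the lower limit for a count `x > 0` is `qchisq(0.025, 2x) / 2`.
#'
#' @inheritParams poisson_burden_test
#' @param level Confidence level of the two-sided interval whose lower
#'   limit is reported (default 0.95).
#' @return List with vectors `estimate` and `lower`.
#' @export
obs_minus_exp_ci <- function(observed, expected, level = 0.95) {
  if (any(expected <= 0)) stop_tb("expected count must be > 0")
  alpha <- (1 - level) / 2
  lower_limit <- ifelse(observed > 0,
                        stats::qchisq(alpha, 2 * observed) / 2, 0)
  list(estimate = observed - expected, lower = lower_limit - expected)
}

#' Two-sided Fisher exact carrier test
#'
#' Case/control association between carrying at least one qualifying
#' variant and case status, conditioned on the 2x2 margins. The p-value
#' uses the minimum-likelihood two-sided rule, the odds ratio is the
#' conditional maximum-likelihood estimate under the noncentral
#' hypergeometric model, and the confidence interval inverts the exact
#' test -- the conventions of [stats::fisher.test()].
#'
#' @param cases_with,cases_without,controls_with,controls_without 2x2 cell
#'   counts (carriers and non-carriers among cases and controls).
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`
#'   and the four counts.
#' @export
#' @examples
#' fisher_carrier_test(5, 119, 2, 571)  # OR ~ 11.9, p ~ 2.57e-3
fisher_carrier_test <- function(cases_with, cases_without, controls_with,
                                controls_without, conf_level = 0.95) {
  counts <- c(cases_with, cases_without, controls_with, controls_without)
  if (any(counts < 0)) stop_tb("cell counts must be non-negative")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(data.frame(odds_ratio = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_, p_value = 1,
                      cases_with = cases_with, cases_without = cases_without,
                      controls_with = controls_with,
                      controls_without = controls_without,
                      degenerate = TRUE))
  }
  ft <- stats::fisher.test(tab, conf.level = conf_level)
  data.frame(odds_ratio = unname(ft$estimate), ci_lower = ft$conf.int[1],
             ci_upper = ft$conf.int[2], p_value = ft$p.value,
             cases_with = cases_with, cases_without = cases_without,
             controls_with = controls_with,
             controls_without = controls_without, degenerate = FALSE)
}

#' Build a carrier 2x2 table from calls and a cohort roster
#'
#' A subject is a carrier iff it has at least one qualifying call (effect
#' class within the gene set); mosaic-origin calls are counted only when
#' `include_mosaics = TRUE` (they are comparable only against controls
#' called with the same trio-based pipeline). Excluded trios are removed
#' from both margins.
#'
#' @param calls Combined call table (see [combine_callsets()]); must carry
#'   `gene` and `effect` columns.
#' @param roster Data frame with `trio_id` and `status`
#'   (`case`/`control`), e.g. from [ped_trios()].
#' @param geneset Gene symbols defining the qualifying set, or `NULL` for
#'   all genes.
#' @param effect_classes Character vector of qualifying effect classes
#'   (default nonsynonymous: missense, inframe-indel, LoF).
#' @param include_mosaics Count mosaic-origin calls as qualifying.
#' @param excluded_trios Trio ids dropped from both margins (the >= 6-DNM
#'   rule).
#' @return One-row data frame as accepted by [fisher_carrier_test()].
#' @export
carrier_counts <- function(calls, roster, geneset = NULL,
                           effect_classes = c("missense", "inframe-indel",
                                              "LoF"),
                           include_mosaics = FALSE,
                           excluded_trios = character()) {
  stopifnot(all(c("trio_id", "status") %in% names(roster)))
  unknown <- setdiff(calls$trio_id, roster$trio_id)
  if (length(unknown)) {
    stop_tb("call(s) from subject absent in roster: ",
            paste(utils::head(unknown, 3), collapse = ", "))
  }
  roster <- roster[!roster$trio_id %in% excluded_trios, , drop = FALSE]
  calls <- calls[!calls$trio_id %in% excluded_trios, , drop = FALSE]
  qualifying <- calls$effect %in% effect_classes
  if (!is.null(geneset)) {
    qualifying <- qualifying & calls$gene %in% as.character(geneset)
  }
  if (!include_mosaics && "origin" %in% names(calls)) {
    qualifying <- qualifying & calls$origin != "mosaic"
  }
  carriers <- unique(calls$trio_id[qualifying])
  is_case <- roster$status == "case"
  data.frame(cases_with = sum(is_case & roster$trio_id %in% carriers),
             cases_without = sum(is_case & !roster$trio_id %in% carriers),
             controls_with = sum(!is_case & roster$trio_id %in% carriers),
             controls_without = sum(!is_case & !roster$trio_id %in% carriers))
}

#' Screen-style deterministic call filters
#'
#' Subsets an annotated call table by one of the clinical screening
#' criteria: membership in an actionable-gene panel (`"geneset"`), ClinVar
#' pathogenic/likely-pathogenic missense (`"pathogenic-missense"`),
#' LoF-intolerant genes (`"loeuf"`, strict `loeuf < cutoff`) or
#' LoF-intolerant genes that additionally carry at least one LoF de novo
#' in an external catalogue (`"loeuf-denovodb"`).
#'
#' @param calls Annotated call table (`gene`, `effect`, `clinvar`, `loeuf`
#'   columns as required by the criterion).
#' @param criterion One of `"geneset"`, `"pathogenic-missense"`, `"loeuf"`,
#'   `"loeuf-denovodb"`.
#' @param geneset Gene symbols (for `"geneset"` and `"loeuf-denovodb"`,
#'   where it is the catalogue hit list).
#' @param loeuf_cutoff Constraint cutoff (default 0.35, strict less-than).
#' @return The filtered call table.
#' @export
screen_subset <- function(calls,
                          criterion = c("geneset", "pathogenic-missense",
                                        "loeuf", "loeuf-denovodb"),
                          geneset = NULL, loeuf_cutoff = 0.35) {
  criterion <- match.arg(criterion)
  need <- switch(criterion,
                 geneset = "gene",
                 `pathogenic-missense` = c("effect", "clinvar"),
                 loeuf = "loeuf",
                 `loeuf-denovodb` = c("loeuf", "gene"))
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    stop_tb("criterion '", criterion, "' needs call column(s): ",
            paste(miss, collapse = ", "))
  }
  keep <- switch(criterion,
    geneset = calls$gene %in% as.character(geneset),
    `pathogenic-missense` = calls$effect == "missense" &
      calls$clinvar %in% c("pathogenic", "likely_pathogenic"),
    loeuf = !is.na(calls$loeuf) & calls$loeuf < loeuf_cutoff,
    `loeuf-denovodb` = !is.na(calls$loeuf) & calls$loeuf < loeuf_cutoff &
      calls$gene %in% as.character(geneset))
  calls[keep, , drop = FALSE]
}

#' Diagnostic yield
#'
#' Percentage of trios with a classified (likely contributory) genotype,
#' rounded to one decimal: `100 * count / n_trios`.
#'
#' @param count Number of trios with a qualifying finding.
#' @param n_trios Cohort size.
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' diagnostic_yield(11, 124)  # 8.9
diagnostic_yield <- function(count, n_trios) {
  if (n_trios <= 0) stop_tb("n_trios must be positive")
  if (any(count > n_trios)) stop_tb("count exceeds n_trios")
  round1(100 * count / n_trios)
}
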