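# Generative model of the synthetic trio cohort.

quiet_cfg <- function(...) {
  # event-only configs keep convergence tests fast
  cohort_config(noise_sites_per_trio = 0, artifact_sites_per_trio = 0, ...)
}

test_that("configuration is validated", {
  expect_error(cohort_config(n_case_trios = 0, n_control_trios = 0), "zero")
  expect_error(cohort_config(mosaic_fraction = 1.5), "mosaic_fraction")
  expect_error(cohort_config(transmission_bias = -0.1), "transmission_bias")
  expect_error(cohort_config(mean_coding_snv_dnms_per_trio = -1), ">= 0")
  expect_error(cohort_config(nonsyn_enrichment_factor = 0.5), ">= 1")
  g <- small_genome()
  expect_error(simulate_cohort(cohort_config(enriched_geneset = "NOPE"), g,
                               uniform_rate_table(1e-8)),
               "unknown gene")
})

test_that("identical seeds give identical cohorts; different seeds differ", {
  g <- small_genome()
  rt <- uniform_rate_table(1e-7)
  a <- simulate_cohort(cohort_config(n_case_trios = 10, n_control_trios = 10,
                                     seed = 5), g, rt)
  b <- simulate_cohort(cohort_config(n_case_trios = 10, n_control_trios = 10,
                                     seed = 5), g, rt)
  c <- simulate_cohort(cohort_config(n_case_trios = 10, n_control_trios = 10,
                                     seed = 6), g, rt)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$records, c$records))
})

test_that("zero event rates give an empty truth table", {
  g <- small_genome()
  co <- simulate_cohort(
    quiet_cfg(n_case_trios = 5, n_control_trios = 5,
              mean_coding_snv_dnms_per_trio = 0,
              mean_coding_indel_dnms_per_trio = 0, mosaic_fraction = 0,
              mean_qualifying_het_per_trio = 0,
              mean_recessive_opportunities_per_trio = 0, seed = 2),
    g, uniform_rate_table(1e-8))
  expect_equal(nrow(co$truth), 0)
  expect_equal(nrow(co$records), 0)
})

test_that("per-trio event counts converge to the configured Poisson means", {
  g <- toy_genome()
  co <- simulate_cohort(quiet_cfg(n_case_trios = 2000, n_control_trios = 0,
                                  mean_qualifying_het_per_trio = 0,
                                  mean_recessive_opportunities_per_trio = 0,
                                  seed = 303), g)
  events <- co$truth[co$truth$kind %in% c("dnm-snv", "dnm-indel",
                                          "parental-mosaic"), ]
  mean_per_trio <- nrow(events) / 2000
  se <- sqrt(1.1 / 2000)
  expect_lt(abs(mean_per_trio - 1.1), 3 * se)

  # mosaic share of de novo-appearing events
  frac <- mean(events$kind == "parental-mosaic")
  se_frac <- sqrt(0.038 * 0.962 / nrow(events))
  expect_lt(abs(frac - 0.038), 3 * se_frac)

  # SNV vs indel split (simulated indels are anchored deletions)
  indels <- mean(grepl("-[ACGT]{2,}-[ACGT]+$", events$key))
  expect_lt(abs(indels - 0.1 / 1.1), 3 * sqrt(0.09 / nrow(events)))
})

test_that("read evidence follows the configured depth and allele-fraction models", {
  g <- small_genome()
  co <- simulate_cohort(cohort_config(n_case_trios = 150, n_control_trios = 0,
                                      noise_sites_per_trio = 5, seed = 9),
                        g, uniform_rate_table(1e-7))
  rec <- co$records
  # negative-binomial depth, mean 89
  expect_lt(abs(mean(rec$child_dp) - 89),
            3 * stats::sd(rec$child_dp) / sqrt(nrow(rec)))
  # binomial(depth, 1/2) allele fraction at true heterozygous child sites
  in_truth <- paste(rec$trio_id, rec$key) %in%
    paste(co$truth$trio_id, co$truth$key)
  het <- rec[rec$child_gt == "0/1" & in_truth, ]
  frac <- het$child_alt_reads / het$child_dp
  expect_lt(abs(mean(frac) - 0.5), 3 * stats::sd(frac) / sqrt(nrow(het)))
  # hom-ref parents at noise sites carry only error-level alternate reads
  noise <- rec[!in_truth & rec$child_gt == "0/0", ]
  expect_gt(nrow(noise), 100)
  expect_lt(mean(noise$mother_alt_reads / noise$mother_dp), 0.01)
})

test_that("mosaic parental allele fractions sit below the heterozygous threshold", {
  g <- small_genome()
  co <- simulate_cohort(quiet_cfg(n_case_trios = 300, n_control_trios = 0,
                                  mosaic_fraction = 0.5, seed = 21),
                        g, uniform_rate_table(1e-7))
  expect_gt(sum(co$truth$kind == "parental-mosaic"), 20)
  vaf <- co$truth$parent_vaf[co$truth$kind == "parental-mosaic"]
  expect_true(all(vaf >= 0.03 & vaf <= 0.20))
  expect_true(all(vaf < 0.30))
})

test_that("every truth event maps to exactly one emitted record", {
  g <- small_genome()
  co <- simulate_cohort(cohort_config(n_case_trios = 60, n_control_trios = 60,
                                      seed = 13), g, uniform_rate_table(1e-7))
  truth_ids <- paste(co$truth$trio_id, co$truth$key)
  rec_ids <- paste(co$records$trio_id, co$records$key)
  expect_true(all(truth_ids %in% rec_ids))
  expect_false(any(duplicated(truth_ids)))
  expect_false(any(duplicated(rec_ids)))
})

test_that("transmission of qualifying variants is binomial at the configured bias", {
  g <- small_genome()
  transmitted <- 0; total <- 0
  for (s in 1:6) {
    co <- simulate_cohort(quiet_cfg(n_case_trios = 120, n_control_trios = 0,
                                    mean_coding_snv_dnms_per_trio = 0,
                                    mean_coding_indel_dnms_per_trio = 0,
                                    mean_qualifying_het_per_trio = 0.5,
                                    seed = 1000 + s),
                          g, uniform_rate_table(1e-7))
    q <- co$truth[co$truth$kind == "inherited-het", ]
    transmitted <- transmitted + sum(q$transmitted)
    total <- total + nrow(q)
  }
  expect_gt(total, 200)
  # two-sided exact test against the null 0.5 should not reject strongly
  expect_gt(stats::binom.test(transmitted, total, 0.5)$p.value, 0.001)
})

test_that("case-only nonsynonymous enrichment recovers the configured factor", {
  g <- toy_genome()
  rt <- default_rate_table(g)
  set_genes <- g$symbol[seq(1, 200, by = 4)]   # 50-gene designated set
  f <- 10
  co <- simulate_cohort(quiet_cfg(n_case_trios = 500, n_control_trios = 0,
                                  enriched_geneset = set_genes,
                                  nonsyn_enrichment_factor = f,
                                  mean_qualifying_het_per_trio = 0,
                                  mean_recessive_opportunities_per_trio = 0,
                                  seed = 505), g, rt)
  ns <- co$truth[co$truth$kind %in% c("dnm-snv", "parental-mosaic") &
                   co$truth$effect %in% c("missense", "LoF"), ]
  n_in <- sum(ns$gene %in% set_genes)
  n_out <- sum(!ns$gene %in% set_genes)
  e_in <- geneset_expected(g, set_genes, rt, "nonsynonymous", 500)
  e_out <- geneset_expected(g, setdiff(g$symbol, set_genes), rt,
                            "nonsynonymous", 500)
  est <- (n_in / e_in) / (n_out / e_out)
  # analytic Poisson means at the configured rates give the Monte-Carlo SE
  mc_se <- f * sqrt(1 / (e_in * f / 1.02) + 1 / (e_out / 1.02))
  expect_lt(abs(est - f), 3 * mc_se)
})
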