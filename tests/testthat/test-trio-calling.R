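# De novo and parental-mosaic calling rules.

test_that("a clean Mendelian-violation site passes every de novo filter", {
  rec <- trio_record(child_alt = 13, child_dp = 28)   # fraction 0.464
  calls <- call_dnms(rec)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$vtype, "snv")
  expect_equal(calls$child_alt_fraction, 13 / 28, tolerance = 1e-12)
})

test_that("child allele fraction below the 30% threshold is filtered", {
  # a real frameshift supported by ~28% of reads must be rejected at 0.30
  rec <- trio_record(child_alt = 28, child_dp = 100, ref = "AT", alt = "A")
  expect_equal(nrow(call_dnms(rec)), 0)
  rec30 <- trio_record(child_alt = 30, child_dp = 100)
  expect_equal(nrow(call_dnms(rec30)), 1)
})

test_that("a genotyped parental alternate allele vetoes the de novo call", {
  rec <- trio_record(mother_gt = "0/1", mother_alt = 22)
  expect_equal(nrow(call_dnms(rec)), 0)
  rec2 <- trio_record(father_gt = "1/1", father_alt = 49)
  expect_equal(nrow(call_dnms(rec2)), 0)
})

test_that("depth, parental read evidence and control carriers are enforced", {
  expect_equal(nrow(call_dnms(trio_record(child_dp = 9, child_alt = 5))), 0)
  expect_equal(nrow(call_dnms(trio_record(mother_dp = 8, mother_alt = 0))),
               0)
  # parent hom-ref with alternate evidence above tolerance
  expect_equal(nrow(call_dnms(trio_record(mother_alt = 5, mother_dp = 50))),
               0)
  # within tolerance (2 reads at 50x)
  expect_equal(nrow(call_dnms(trio_record(mother_alt = 2, mother_dp = 50))),
               1)
  rec <- trio_record()
  idx <- stats::setNames(1L, rec$key)
  expect_equal(nrow(call_dnms(rec, control_index = idx)), 0)
  expect_equal(nrow(call_dnms(rec, control_index = c(`9-9-A-G` = 3L))), 1)
})

test_that("missing genotypes are skipped with a logged reason, not an error", {
  rec <- rbind(trio_record(pos = 1),
               trio_record(pos = 2, father_gt = NA))
  calls <- call_dnms(rec)
  expect_equal(nrow(calls), 1)
  skipped <- attr(calls, "skipped")
  expect_equal(nrow(skipped), 1)
  expect_match(skipped$reason, "missing genotype")
})

test_that("trios at or above the DNM-count bound are excluded entirely", {
  mk <- function(trio, n) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      trio_record(trio_id = trio, pos = i * 10)
    }))
  }
  calls <- call_dnms(rbind(mk("six", 6), mk("five", 5), mk("one", 1)))
  kept <- exclude_outlier_trios(calls)
  expect_equal(kept$excluded_trios, "six")
  expect_setequal(unique(kept$calls$trio_id), c("five", "one"))
  empty <- exclude_outlier_trios(calls[0, ])
  expect_equal(length(empty$excluded_trios), 0)
})

test_that("parental mosaic calls require band-level evidence in exactly one parent", {
  # mother 45 ref / 5 alt (fraction 0.10), father ref-only
  rec <- trio_record(child_alt = 25, child_dp = 50,
                     mother_gt = "0/0", mother_alt = 5, mother_dp = 50,
                     father_alt = 0, father_dp = 50)
  m <- call_transmitted_mosaics(rec)
  expect_equal(nrow(m), 1)
  expect_equal(m$mosaic_parent, "mother")
  expect_equal(m$parent_alt_fraction, 0.10)

  # heterozygous-band fraction in the parent: ordinary inherited variant
  het <- trio_record(mother_gt = "0/1", mother_alt = 22, mother_dp = 49)
  expect_equal(nrow(call_transmitted_mosaics(het)), 0)

  # 1 of 80 reads: noise floor
  noise <- trio_record(mother_alt = 1, mother_dp = 80)
  expect_equal(nrow(call_transmitted_mosaics(noise)), 0)

  # both parents in the band: skipped with reason
  both <- trio_record(mother_alt = 6, mother_dp = 50,
                      father_alt = 7, father_dp = 50)
  mb <- call_transmitted_mosaics(both)
  expect_equal(nrow(mb), 0)
  expect_match(attr(mb, "skipped")$reason, "both parents")
})

test_that("combining call sets reports the mosaic percentage", {
  mk_calls <- function(n, prefix) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      trio_record(trio_id = paste0(prefix, i), pos = i * 100)
    }))
  }
  dnms <- call_dnms(mk_calls(125, "d"))
  mosaics <- call_transmitted_mosaics(
    do.call(rbind, lapply(1:5, function(i) {
      trio_record(trio_id = paste0("m", i), pos = i * 7 + 1,
                  child_alt = 25, child_dp = 50,
                  mother_alt = 5, mother_dp = 50)
    })))
  comb <- combine_callsets(dnms, mosaics)
  expect_equal(nrow(comb$calls), 130)
  expect_equal(comb$mosaic_fraction_pct, 3.8)

  expect_equal(combine_callsets(dnms, mosaics[0, ])$mosaic_fraction_pct, 0)
  expect_equal(combine_callsets(dnms[0, ], mosaics)$mosaic_fraction_pct, 100)

  dup <- dnms[1, ]
  dup$trio_id <- mosaics$trio_id[1]
  dup$key <- mosaics$key[1]
  expect_error(combine_callsets(rbind(dnms, dup), mosaics), "both call sets")
})

test_that("calling is order-independent and monotone in the child threshold", {
  g <- small_genome()
  rt <- uniform_rate_table(1e-7)
  co <- simulate_cohort(cohort_config(n_case_trios = 25, n_control_trios = 25,
                                      seed = 77), g, rt)
  base <- call_dnms(co$records)
  shuffled <- co$records[sample(nrow(co$records)), ]
  expect_equal(as.data.frame(call_dnms(shuffled)), as.data.frame(base))

  stricter <- call_dnms(co$records,
                        qc_thresholds(min_child_alt_allele_fraction = 0.4))
  expect_true(all(paste(stricter$trio_id, stricter$key) %in%
                    paste(base$trio_id, base$key)))

  # no call ever at a site where a parent carries a genotyped alt allele
  rec_idx <- match(paste(base$trio_id, base$key),
                   paste(co$records$trio_id, co$records$key))
  expect_true(all(co$records$mother_gt[rec_idx] == "0/0" &
                    co$records$father_gt[rec_idx] == "0/0"))
})

test_that("caller recovers injected de novo events on a small synthetic cohort", {
  g <- toy_genome()
  co <- simulate_cohort(cohort_config(n_case_trios = 40, n_control_trios = 40,
                                      seed = 11), g)
  calls <- call_dnms(co$records)
  truth <- co$truth[co$truth$kind %in% c("dnm-snv", "dnm-indel"), ]
  truth_keys <- paste(truth$trio_id, truth$key)
  call_keys <- paste(calls$trio_id, calls$key)
  expect_gte(mean(truth_keys %in% call_keys), 0.9)
  expect_lte(mean(!call_keys %in% truth_keys), 0.06)
})
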