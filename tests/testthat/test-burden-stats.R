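# Poisson burden tests, Fisher carrier tests, screens and yields.

test_that("one-sided Poisson burden test reproduces published-style rows", {
  # LoF burden in LoF-intolerant genes: observed 5, expected 3.12
  r1 <- poisson_burden_test(5, 3.12)
  expect_equal(round(r1$enrichment, 2), 1.60)
  expect_equal(round(r1$p_value, 2), 0.21)
  # narrowed to catalogue-hit constrained genes: observed 3, expected 0.70
  r2 <- poisson_burden_test(3, 0.70)
  expect_equal(round(r2$p_value, 2), 0.03)
  # empty upper tail complement
  expect_equal(poisson_burden_test(0, 2.5)$p_value, 1)
  expect_error(poisson_burden_test(3, 0), "> 0")
  expect_error(poisson_burden_test(-1, 1), "count")
})

test_that("Poisson p is monotone in observed and expected", {
  for (lambda in c(0.5, 2, 10)) {
    p <- poisson_burden_test(0:20, rep(lambda, 21))$p_value
    expect_true(all(diff(p) < 0))
  }
  lambdas <- seq(0.5, 8, by = 0.5)
  p <- poisson_burden_test(rep(4, length(lambdas)), lambdas)$p_value
  expect_true(all(diff(p) > 0))
})

test_that("observed-minus-expected and its exact lower bound are correct", {
  ci <- obs_minus_exp_ci(7, 1.25)
  expect_equal(ci$estimate, 5.75)
  expect_equal(obs_minus_exp_ci(3, 3)$estimate, 0)

  # grid inversion of the exact Poisson test at 2.5% for observed = 10
  target <- 0.025
  grid <- seq(0.001, 10, by = 1e-4)
  lower_oracle <- grid[which(stats::ppois(10 - 1, grid,
                                          lower.tail = FALSE) >= target)[1]]
  expect_equal(obs_minus_exp_ci(10, 2)$lower + 2, lower_oracle,
               tolerance = 1e-3)
  # and against the exact CI reported by stats::poisson.test
  expect_equal(obs_minus_exp_ci(10, 2)$lower + 2,
               stats::poisson.test(10)$conf.int[1], tolerance = 1e-9)
})

test_that("Fisher carrier test reproduces the printed pathogenic-missense comparison", {
  res <- fisher_carrier_test(5, 119, 2, 571)
  expect_equal(round(res$odds_ratio, 1), 11.9)
  expect_equal(res$p_value, 2.57e-3, tolerance = 0.005)
  expect_true(res$ci_lower <= res$odds_ratio &
                res$odds_ratio <= res$ci_upper)

  null <- fisher_carrier_test(3, 7, 3, 7)
  expect_equal(null$p_value, 1)
  expect_equal(round(null$odds_ratio), 1)

  degen <- fisher_carrier_test(0, 0, 5, 5)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$odds_ratio))
})

test_that("Fisher p equals exhaustive margin-conditioned enumeration on small tables", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    a <- sample(0:n, 1); b <- n - a
    m <- sample(4:12, 1)
    c <- sample(0:m, 1); d <- m - c
    if ((a + c) == 0 || (b + d) == 0) next
    expect_equal(fisher_carrier_test(a, b, c, d)$p_value,
                 fisher_p_enumeration(a, b, c, d), tolerance = 1e-9,
                 label = paste(a, b, c, d))
  }
})

test_that("carrier counting respects gene set, mosaic flag and trio exclusion", {
  calls <- data.frame(
    trio_id = c("c1", "c1", "c2", "c3", "k1"),
    key = paste0("1-", 1:5, "-A-G"),
    gene = c("G1", "G2", "G1", "G3", "G1"),
    effect = c("missense", "synonymous", "LoF", "missense", "missense"),
    origin = c("dnm", "dnm", "dnm", "mosaic", "dnm"),
    stringsAsFactors = FALSE)
  roster <- data.frame(trio_id = c("c1", "c2", "c3", "c4", "k1", "k2"),
                       status = c(rep("case", 4), rep("control", 2)),
                       stringsAsFactors = FALSE)

  cc <- carrier_counts(calls, roster, geneset = c("G1", "G3"))
  expect_equal(cc$cases_with, 2)      # c1 (G1 missense), c2; c3 mosaic excluded
  expect_equal(cc$controls_with, 1)
  cc_m <- carrier_counts(calls, roster, geneset = c("G1", "G3"),
                         include_mosaics = TRUE)
  expect_equal(cc_m$cases_with, 3)

  cc_x <- carrier_counts(calls, roster, geneset = c("G1", "G3"),
                         excluded_trios = "c1")
  expect_equal(cc_x$cases_with + cc_x$cases_without, 3)

  empty <- carrier_counts(calls, roster, geneset = character())
  expect_equal(empty$cases_with + empty$controls_with, 0)

  expect_error(carrier_counts(rbind(calls,
                                    data.frame(trio_id = "zz",
                                               key = "1-9-A-G", gene = "G1",
                                               effect = "missense",
                                               origin = "dnm")),
                              roster), "absent in roster")
})

test_that("screen subsets apply the clinical criteria deterministically", {
  # annotated calls shaped like a published pathogenic-variant table
  calls <- data.frame(
    trio_id = sprintf("t%d", 1:8),
    key = c("12-2613692-G-A", "12-2613674-G-C", "14-90870730-A-G",
            "16-56370693-G-A", "1-237608788-C-T", "1-237798237-C-T",
            "2-166929950-A-G", "19-55663261-G-A"),
    gene = c("CACNA1C", "CACNA1C", "CALM1", "GNAO1", "RYR2", "RYR2",
             "SCN1A", "TNNI3"),
    effect = "missense",
    clinvar = c("pathogenic", "none", "pathogenic", "none", "pathogenic",
                "pathogenic", "none", "likely_pathogenic"),
    loeuf = c(0.30, 0.30, 0.60, 0.20, 0.35, 0.35, 0.05, 0.90),
    stringsAsFactors = FALSE)
  acmg <- c("RYR2", "TNNI3", "MYH7", "KCNQ1", "SCN5A")

  hit <- screen_subset(calls, "geneset", geneset = acmg)
  expect_equal(sort(hit$gene), c("RYR2", "RYR2", "TNNI3"))

  path_mis <- screen_subset(calls, "pathogenic-missense")
  expect_equal(nrow(path_mis), 5)

  constrained <- screen_subset(calls, "loeuf")
  expect_false(any(constrained$loeuf >= 0.35))   # 0.35 excluded, strict <
  expect_equal(sort(unique(constrained$gene)),
               c("CACNA1C", "GNAO1", "SCN1A"))

  expect_equal(nrow(screen_subset(calls[0, ], "geneset", geneset = acmg)), 0)
  expect_error(screen_subset(calls[, c("trio_id", "gene")], "loeuf"),
               "loeuf")
})

test_that("diagnostic yield matches the published arithmetic", {
  expect_equal(diagnostic_yield(7, 124), 5.6)
  expect_equal(diagnostic_yield(1, 124), 0.8)
  expect_equal(diagnostic_yield(8, 124), 6.5)
  expect_equal(diagnostic_yield(3, 124), 2.4)
  expect_equal(diagnostic_yield(11, 124), 8.9)
  expect_equal(diagnostic_yield(0, 50), 0)
  expect_error(diagnostic_yield(5, 0), "positive")
  expect_error(diagnostic_yield(10, 5), "exceeds")
})
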