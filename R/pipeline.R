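## End-to-end orchestration: simulate -> call -> burden -> transmission ->
## network -> yield, with a reproducibility manifest. Each stage is a pure
## function of its declared inputs; the pipeline only wires them together.

#' Toy protein-interaction graph over a gene catalogue
#'
#' Scale-free-ish random graph (preferential attachment) over the genome's
#' symbols, used to exercise the network-enrichment stage in demos and
#' tests when no curated interaction database is supplied.
#'
#' @param genome Gene catalogue.
#' @param edges_per_node Attachment parameter (default 2).
#' @param seed RNG seed.
#' @return An [igraph::graph] with one node per gene symbol.
#' @export
random_ppi_graph <- function(genome, edges_per_node = 2, seed = 11) {
  with_seed(seed, {
    g <- igraph::sample_pa(nrow(genome), m = edges_per_node,
                           directed = FALSE)
    igraph::V(g)$name <- genome$symbol
    igraph::simplify(g)
  })
}

#' Per-category diagnostic yield table
#'
#' Counts trios per finding category and overall; a trio with several
#' findings counts once in the total. Percentages are over `n_trios`,
#' rounded to one decimal.
#'
#' @param classified Data frame with columns `trio_id` and `category`;
#'   categories must be among `pathogenic-DNM`, `pathogenic-mosaic`,
#'   `inherited-dominant`, `biallelic-recessive`.
#' @param n_trios Cohort size the percentages refer to.
#' @return Data frame with one row per category plus a `total` row
#'   (distinct trios), columns `category`, `n_trios_with_finding`,
#'   `yield_pct`.
#' @export
#' @examples
#' cls <- data.frame(trio_id = c("a", "b", "c"),
#'                   category = c("pathogenic-DNM", "pathogenic-DNM",
#'                                "inherited-dominant"))
#' summarize_yield(cls, 124)
summarize_yield <- function(classified, n_trios) {
  categories <- c("pathogenic-DNM", "pathogenic-mosaic",
                  "inherited-dominant", "biallelic-recessive")
  bad <- setdiff(unique(classified$category), categories)
  if (length(bad)) stop_tb("unknown yield category: ", bad[1])
  per_cat <- vapply(categories, function(cat) {
    length(unique(classified$trio_id[classified$category == cat]))
  }, integer(1))
  total <- length(unique(classified$trio_id))
  data.frame(category = c(categories, "total"),
             n_trios_with_finding = c(per_cat, total),
             yield_pct = diagnostic_yield(c(per_cat, total), n_trios),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Orchestrates every stage: cohort simulation, de novo and mosaic
#' calling with outlier-trio exclusion, observed-vs-expected Poisson
#' burden (exome-wide and within a designated gene set, synonymous and
#' nonsynonymous), case/control Fisher carrier tests, the parental
#' overtransmission test, deleteriousness-stratified network enrichment,
#' and the diagnostic-yield table. Fails fast with the stage name in the
#' message.
#'
#' @param config A [cohort_config()].
#' @param genome,rate_table Gene catalogue and trimer rate table.
#' @param geneset Gene set for the focused burden comparison (defaults to
#'   the configured `enriched_geneset`, if any).
#' @param network Optional [igraph::graph]; default builds a
#'   [random_ppi_graph()] over the genome.
#' @param thresholds A [qc_thresholds()].
#' @param n_permutations Network-null resamples (default 999 for speed;
#'   increase for fine p-value resolution).
#' @param cadd_threshold Score cutoff partitioning network hit sets
#'   (default 15).
#' @return List of class `trioburden_report` with elements `cohort`,
#'   `calls`, `excluded_trios`, `mosaic_fraction_pct`, `burden`,
#'   `carrier_tests`, `transmission`, `network`, `yield`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(),
                         genome = toy_genome(),
                         rate_table = default_rate_table(genome),
                         geneset = NULL,
                         network = random_ppi_graph(genome),
                         thresholds = qc_thresholds(),
                         n_permutations = 999,
                         cadd_threshold = 15) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_tb("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  cohort <- stage("simulate", simulate_cohort(config, genome, rate_table))
  roster <- stage("roster", ped_trios(cohort$pedigree))

  dnms <- stage("call-dnm",
                call_dnms(cohort$records, thresholds,
                          annotations = cohort$annotations))
  kept <- stage("exclude-outliers", exclude_outlier_trios(dnms, thresholds))
  mosaics <- stage("call-mosaic",
                   call_transmitted_mosaics(cohort$records, thresholds,
                                            annotations = cohort$annotations))
  mosaics <- mosaics[!mosaics$trio_id %in% kept$excluded_trios, ,
                     drop = FALSE]
  combined <- stage("combine", combine_callsets(kept$calls, mosaics))
  calls <- combined$calls
  roster_kept <- roster[!roster$trio_id %in% kept$excluded_trios, ,
                        drop = FALSE]
  n_case <- sum(roster_kept$status == "case")

  geneset <- geneset %||%
    (if (length(config$enriched_geneset)) config$enriched_geneset)

  case_calls <- calls[calls$trio_id %in%
                        roster_kept$trio_id[roster_kept$status == "case"], ,
                      drop = FALSE]
  burden <- stage("burden", {
    one <- function(set_name, symbols, class) {
      snv <- case_calls$origin == "dnm" & case_calls$vtype == "snv"
      in_set <- if (is.null(symbols)) TRUE else case_calls$gene %in% symbols
      qualifies <- if (class == "synonymous") {
        case_calls$effect == "synonymous"
      } else {
        case_calls$effect %in% c("missense", "inframe-indel", "LoF")
      }
      obs <- sum(snv & in_set & qualifies)
      expd <- geneset_expected(genome, symbols %||% genome$symbol,
                               rate_table, class, n_case)
      poisson_burden_test(obs, expd, geneset = set_name,
                          effect_class = class)
    }
    rbind(one("exome", NULL, "synonymous"),
          one("exome", NULL, "nonsynonymous"),
          if (!is.null(geneset)) one("focused", geneset, "synonymous"),
          if (!is.null(geneset)) one("focused", geneset, "nonsynonymous"))
  })

  carrier_tests <- stage("carrier", {
    one <- function(set_name, symbols, include_mosaics) {
      cc <- carrier_counts(calls, roster_kept, geneset = symbols,
                           include_mosaics = include_mosaics,
                           excluded_trios = kept$excluded_trios)
      cbind(geneset = set_name, include_mosaics = include_mosaics,
            fisher_carrier_test(cc$cases_with, cc$cases_without,
                                cc$controls_with, cc$controls_without))
    }
    rbind(one("exome", NULL, TRUE),
          if (!is.null(geneset)) one("focused", geneset, TRUE))
  })

  transmission <- stage("transmit", {
    case_records <- cohort$records[cohort$records$trio_id %in%
                                     roster$trio_id[roster$status == "case"], ,
                                   drop = FALSE]
    qual <- enumerate_qualifying(case_records, cohort$annotations)
    if (nrow(qual[!qual$indeterminate, ])) {
      list(qualifying = qual, test = transmission_summary(qual))
    } else {
      list(qualifying = qual, test = NULL)
    }
  })

  network_res <- stage("network", {
    nonsyn_case <- case_calls[case_calls$effect %in%
                                c("missense", "inframe-indel", "LoF"), ,
                              drop = FALSE]
    if (!nrow(nonsyn_case) || is.null(network)) {
      NULL
    } else {
      part <- partition_by_deleteriousness(
        nonsyn_case[, c("gene", "score")], threshold = cadd_threshold)
      high <- suppressMessages(
        edge_enrichment(network, part$high$gene, n_permutations,
                        seed = config$seed))
      low <- if (nrow(part$low)) suppressMessages(
        edge_enrichment(network, part$low$gene, n_permutations,
                        seed = config$seed))
      clusters <- extract_clusters(network, part$high$gene)
      list(partition = part, high = high, low = low, clusters = clusters,
           cluster_mean_length_kb = cluster_length_check(clusters, genome))
    }
  })

  yield <- stage("yield", {
    pathogenic <- !is.na(calls$clinvar) &
      calls$clinvar %in% c("pathogenic", "likely_pathogenic")
    case_ids <- roster_kept$trio_id[roster_kept$status == "case"]
    block <- function(ids, category) {
      data.frame(trio_id = ids, category = rep(category, length(ids)),
                 stringsAsFactors = FALSE)
    }
    cls <- rbind(
      block(calls$trio_id[pathogenic & calls$origin == "dnm" &
                            calls$trio_id %in% case_ids], "pathogenic-DNM"),
      block(calls$trio_id[pathogenic & calls$origin == "mosaic" &
                            calls$trio_id %in% case_ids],
            "pathogenic-mosaic"),
      if (!is.null(transmission$qualifying) &&
          nrow(transmission$qualifying)) {
        tq <- transmission$qualifying
        block(tq$trio_id[tq$transmitted & tq$trio_id %in% case_ids],
              "inherited-dominant")
      })
    if (is.null(cls) || !nrow(cls)) NULL
    else summarize_yield(cls, max(length(case_ids), 1))
  })

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    stage_rows = c(records = nrow(cohort$records),
                   dnm_calls = nrow(dnms),
                   retained_dnm_calls = nrow(kept$calls),
                   mosaic_calls = nrow(mosaics),
                   excluded_trios = length(kept$excluded_trios),
                   qualifying_variants =
                     nrow(transmission$qualifying %||% data.frame())))

  structure(list(cohort = cohort, calls = calls,
                 excluded_trios = kept$excluded_trios,
                 mosaic_fraction_pct = combined$mosaic_fraction_pct,
                 burden = burden, carrier_tests = carrier_tests,
                 transmission = transmission, network = network_res,
                 yield = yield, manifest = manifest),
            class = "trioburden_report")
}

#' @export
print.trioburden_report <- function(x, ...) {
  cat("trioburden report\n")
  cat("  calls:", nrow(x$calls), "(mosaic", x$mosaic_fraction_pct, "%)",
      "excluded trios:", length(x$excluded_trios), "\n")
  cat("  burden tests:\n")
  print(x$burden, row.names = FALSE)
  if (!is.null(x$transmission$test)) {
    cat("  overtransmission:\n")
    print(x$transmission$test, row.names = FALSE)
  }
  if (!is.null(x$network)) {
    cat("  network (high-deleteriousness set):\n")
    print(x$network$high, row.names = FALSE)
  }
  if (!is.null(x$yield)) {
    cat("  yield:\n")
    print(x$yield, row.names = FALSE)
  }
  invisible(x)
}
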