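## Synthetic trio-cohort generator.
##
## Emulates the statistical structure a trio-exome "genetic autopsy" rests
## on: Poisson-distributed coding de novo SNVs and indels per trio, a small
## fraction of events that are parental-mosaic in origin, binomial
## read-level allele fractions at heterozygous sites, negative-binomial
## site depths, per-read sequencing error at hom-ref sites, deleterious
## heterozygous parental variants with a configurable transmission bias,
## and rare biallelic-formation opportunities. Every injected event is
## recorded in a truth table so callers and tests can be validated.

#' Cohort simulation configuration
#'
#' Defaults reproduce the study conditions the generator emulates: 124 case
#' and 573 control trios; about 1 coding de novo SNV and 0.1 coding de novo
#' indel per trio; 3.8% of de novo + mosaic events mosaic in origin; site
#' depth negative-binomial with mean 89x; a null (0.5) transmission
#' probability for qualifying parental heterozygous variants; and no
#' case-specific gene-set enrichment (factor 1).
#'
#' @param n_case_trios,n_control_trios Trio counts (cases carry the
#'   enrichment, controls never do).
#' @param mean_coding_snv_dnms_per_trio,mean_coding_indel_dnms_per_trio
#'   Poisson means of coding de novo SNVs / indels per trio.
#' @param mosaic_fraction Probability that a de novo-appearing event is
#'   parental-mosaic in origin (parental blood allele fraction drawn
#'   Uniform(0.03, 0.20), below the heterozygous detection band).
#' @param enriched_geneset Gene symbols receiving extra nonsynonymous case
#'   DNMs.
#' @param nonsyn_enrichment_factor Multiplier (>= 1) on nonsynonymous DNM
#'   rates inside `enriched_geneset`, applied to case trios only.
#' @param transmission_bias Probability a qualifying parental heterozygous
#'   variant is transmitted to the child (0.5 = Mendelian null).
#' @param mean_qualifying_het_per_trio Poisson mean of qualifying
#'   deleterious parental heterozygous variants per trio (default 14/124,
#'   the rate scale of a real 124-trio cohort).
#' @param mean_recessive_opportunities_per_trio Poisson mean of trios in
#'   which both parents carry heterozygous variants in the same gene
#'   (default 2/124).
#' @param depth_mean,depth_dispersion Negative-binomial read-depth model
#'   (mu / size), default mean 89x.
#' @param error_rate Per-read sequencing error rate at hom-ref sites
#'   (default 0.5%), exercising false-positive filtering.
#' @param artifact_sites_per_trio Poisson mean of allele-balance-artifact
#'   sites (child genotyped het but supported by <30% of reads).
#' @param noise_sites_per_trio Poisson mean of invariant sites carrying
#'   error reads only.
#' @param seed RNG seed; identical configuration and seed give identical
#'   cohorts.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_case_trios = 124,
                          n_control_trios = 573,
                          mean_coding_snv_dnms_per_trio = 1.0,
                          mean_coding_indel_dnms_per_trio = 0.1,
                          mosaic_fraction = 0.038,
                          enriched_geneset = character(),
                          nonsyn_enrichment_factor = 1,
                          transmission_bias = 0.5,
                          mean_qualifying_het_per_trio = 14 / 124,
                          mean_recessive_opportunities_per_trio = 2 / 124,
                          depth_mean = 89, depth_dispersion = 8,
                          error_rate = 0.005,
                          artifact_sites_per_trio = 0.3,
                          noise_sites_per_trio = 20,
                          seed = 1) {
  cfg <- list(n_case_trios = n_case_trios, n_control_trios = n_control_trios,
              mean_coding_snv_dnms_per_trio = mean_coding_snv_dnms_per_trio,
              mean_coding_indel_dnms_per_trio = mean_coding_indel_dnms_per_trio,
              mosaic_fraction = mosaic_fraction,
              enriched_geneset = as.character(enriched_geneset),
              nonsyn_enrichment_factor = nonsyn_enrichment_factor,
              transmission_bias = transmission_bias,
              mean_qualifying_het_per_trio = mean_qualifying_het_per_trio,
              mean_recessive_opportunities_per_trio =
                mean_recessive_opportunities_per_trio,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              error_rate = error_rate,
              artifact_sites_per_trio = artifact_sites_per_trio,
              noise_sites_per_trio = noise_sites_per_trio,
              seed = seed)
  if (n_case_trios + n_control_trios < 1) stop_tb("zero trios requested")
  rates <- c(mean_coding_snv_dnms_per_trio, mean_coding_indel_dnms_per_trio,
             mean_qualifying_het_per_trio,
             mean_recessive_opportunities_per_trio,
             artifact_sites_per_trio, noise_sites_per_trio)
  if (any(rates < 0)) stop_tb("all rates must be >= 0")
  if (mosaic_fraction < 0 || mosaic_fraction > 1) {
    stop_tb("mosaic_fraction must lie in [0, 1]")
  }
  if (transmission_bias < 0 || transmission_bias > 1) {
    stop_tb("transmission_bias must lie in [0, 1]")
  }
  if (nonsyn_enrichment_factor < 1) {
    stop_tb("nonsyn_enrichment_factor must be >= 1")
  }
  structure(cfg, class = "cohort_config")
}

# classify arbitrary (gene, pos, alt) substitutions, vectorized over sites
classify_sites <- function(genome, gene_idx, pos, alt) {
  cds <- genome$cds[gene_idx]
  ref <- substring(cds, pos, pos)
  codon_start <- pos - (pos - 1L) %% 3L
  within <- (pos - 1L) %% 3L + 1L
  codon <- substring(cds, codon_start, codon_start + 2L)
  mut <- codon
  substr(mut, within, within) <- alt
  gc_tab <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc_tab[codon])
  aa_alt <- unname(gc_tab[mut])
  raw <- ifelse(aa_ref == aa_alt, "synonymous",
         ifelse(aa_alt == "*", "stop_gain",
         ifelse(aa_ref == "*", "stop_loss", "missense")))
  data.frame(ref = ref, alt = alt, class = raw, stringsAsFactors = FALSE)
}

# raw substitution class -> annotation effect class
raw_to_effect <- function(raw) {
  ifelse(raw == "synonymous", "synonymous",
  ifelse(raw == "stop_gain", "LoF", "missense"))
}

# deleteriousness: rank-uniform within effect-stratified bands, then CADD
# scaled as -10*log10(rank)
simulate_scores <- function(effect) {
  n <- length(effect)
  lo <- c(synonymous = 0.1, missense = 0.001, `inframe-indel` = 0.01,
          LoF = 1e-4)
  hi <- c(synonymous = 1, missense = 0.3, `inframe-indel` = 0.3, LoF = 0.01)
  rank <- stats::runif(n, lo[effect], hi[effect])
  round(cadd_scaled_score(rank), 2)
}

# weighted per-class site draw within one gene, using the cached full
# substitution table
sample_class_site <- function(gene_row, n, classes, sub_cache) {
  sym <- gene_row$symbol
  if (is.null(sub_cache[[sym]])) {
    sub_cache[[sym]] <- substitution_table(gene_row$cds,
                                           sub_cache$.rate_table)
  }
  subs <- sub_cache[[sym]]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- if (classes[i] == "synonymous") subs$class == "synonymous"
            else subs$class != "synonymous"
    pool <- subs[keep, , drop = FALSE]
    j <- sample.int(nrow(pool), 1, prob = pool$rate)
    out[[i]] <- pool[j, c("pos", "ref", "alt", "class")]
  }
  do.call(rbind, out)
}

#' Simulate a trio cohort
#'
#' Generates per-trio variant records (genotype, allele depths and total
#' depth for child, mother and father), a pedigree, an annotation table and
#' a truth table of every injected event. See [cohort_config()] for the
#' generative model. De novo events are placed across genes proportionally
#' to their trimer-model mutation probabilities, so observed/expected
#' comparisons against [geneset_expected()] are internally consistent.
#'
#' @param config A [cohort_config()].
#' @param genome Gene catalogue, default [toy_genome()].
#' @param rate_table Trimer rate table, default [default_rate_table()].
#' @return A list of class `trio_cohort` with elements `config`, `genome`,
#'   `records`, `pedigree`, `annotations`, `truth`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            genome = toy_genome(),
                            rate_table = default_rate_table(genome)) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(config$enriched_geneset)) {
    unknown <- setdiff(config$enriched_geneset, genome$symbol)
    if (length(unknown)) {
      stop_tb("enriched_geneset references unknown gene(s): ",
              paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  gcp <- gene_class_probabilities(genome, rate_table)

  with_seed(config$seed, {
    n_case <- config$n_case_trios
    n_ctrl <- config$n_control_trios
    trio_ids <- c(sprintf("CASE%04d", seq_len(n_case)),
                  sprintf("CTRL%04d", seq_len(n_ctrl)))
    status <- rep(c("case", "control"), c(n_case, n_ctrl))

    pedigree <- do.call(rbind, lapply(seq_along(trio_ids), function(i) {
      t <- trio_ids[i]
      data.frame(
        family_id = t,
        individual_id = paste0(t, c("-C", "-F", "-M")),
        father_id = c(paste0(t, "-F"), "0", "0"),
        mother_id = c(paste0(t, "-M"), "0", "0"),
        sex = c(0L, 1L, 2L),
        phenotype = c(if (status[i] == "case") 2L else 1L, 1L, 1L),
        stringsAsFactors = FALSE)
    }))

    sub_cache <- new.env(parent = emptyenv())
    sub_cache$.rate_table <- rate_table

    ## --- de novo (and mosaic-origin) SNV events ---------------------------
    in_set <- gcp$symbol %in% config$enriched_geneset
    w <- c(gcp$p_synonymous, gcp$p_nonsynonymous)
    w_class <- rep(c("synonymous", "nonsynonymous"), each = nrow(gcp))
    w_gene <- rep(seq_len(nrow(gcp)), 2)
    w_total <- sum(w)
    mean_snv <- config$mean_coding_snv_dnms_per_trio
    boost <- ifelse(w_class == "nonsynonymous" & in_set[w_gene],
                    config$nonsyn_enrichment_factor, 1)

    draw_events <- function(ids, boosted) {
      lam <- mean_snv * w / w_total * (if (boosted) boost else 1)
      k <- stats::rpois(length(lam), length(ids) * lam)
      tot <- sum(k)
      if (!tot) return(NULL)
      data.frame(trio_id = sample(ids, tot, replace = TRUE),
                 gene_idx = rep(w_gene, k),
                 class = rep(w_class, k),
                 stringsAsFactors = FALSE)
    }
    snv_events <- rbind(
      if (n_case) draw_events(trio_ids[status == "case"], TRUE),
      if (n_ctrl) draw_events(trio_ids[status == "control"], FALSE))

    events <- NULL
    if (!is.null(snv_events) && nrow(snv_events)) {
      placed <- do.call(rbind, lapply(
        split(seq_len(nrow(snv_events)), snv_events$gene_idx),
        function(idx) {
          gi <- snv_events$gene_idx[idx[1]]
          site <- sample_class_site(genome[gi, ], length(idx),
                                    snv_events$class[idx], sub_cache)
          data.frame(row = idx, site, stringsAsFactors = FALSE)
        }))
      placed <- placed[order(placed$row), , drop = FALSE]
      ev <- snv_events
      ev$pos_in_gene <- placed$pos
      ev$ref <- placed$ref
      ev$alt <- placed$alt
      ev$effect <- raw_to_effect(placed$class)
      ev$vtype <- "snv"
      ev$kind <- ifelse(stats::runif(nrow(ev)) < config$mosaic_fraction,
                        "parental-mosaic", "dnm-snv")
      events <- ev
    }

    ## --- de novo indel events --------------------------------------------
    len_w <- genome$length / sum(genome$length)
    mean_indel <- config$mean_coding_indel_dnms_per_trio
    draw_indels <- function(ids, boosted) {
      lam <- mean_indel * len_w *
        (if (boosted) ifelse(in_set, config$nonsyn_enrichment_factor, 1) else 1)
      k <- stats::rpois(length(lam), length(ids) * lam)
      tot <- sum(k)
      if (!tot) return(NULL)
      data.frame(trio_id = sample(ids, tot, replace = TRUE),
                 gene_idx = rep(seq_len(nrow(genome)), k),
                 stringsAsFactors = FALSE)
    }
    indel_events <- rbind(
      if (n_case) draw_indels(trio_ids[status == "case"], TRUE),
      if (n_ctrl) draw_indels(trio_ids[status == "control"], FALSE))
    if (!is.null(indel_events) && nrow(indel_events)) {
      n_i <- nrow(indel_events)
      inframe <- stats::runif(n_i) < 0.1
      del_len <- ifelse(inframe, 3L, 1L)
      gl <- genome$length[indel_events$gene_idx]
      anchor <- floor(stats::runif(n_i, 1, gl - del_len))
      cds <- genome$cds[indel_events$gene_idx]
      ev <- indel_events
      ev$class <- NA_character_
      ev$pos_in_gene <- anchor
      ev$ref <- substring(cds, anchor, anchor + del_len)
      ev$alt <- substring(cds, anchor, anchor)
      ev$effect <- ifelse(inframe, "inframe-indel", "LoF")
      ev$vtype <- "indel"
      ev$kind <- ifelse(stats::runif(n_i) < config$mosaic_fraction,
                        "parental-mosaic", "dnm-indel")
      events <- rbind(events, ev[, names(events) %||% names(ev)])
    }

    ## --- qualifying inherited heterozygous parental variants --------------
    qual <- NULL
    n_qual <- stats::rpois(1, config$mean_qualifying_het_per_trio *
                                length(trio_ids))
    if (n_qual) {
      constrained <- which(genome$loeuf < 0.35)
      rule <- sample(c("lof", "missense"), n_qual, replace = TRUE)
      rule[rule == "lof" & !length(constrained)] <- "missense"
      gi <- integer(n_qual)
      gi[rule == "lof"] <- constrained[sample.int(length(constrained),
                                                  sum(rule == "lof"),
                                                  replace = TRUE,
                                                  prob = gcp$p_lof[constrained])]
      gi[rule == "missense"] <- sample(seq_len(nrow(genome)),
                                       sum(rule == "missense"),
                                       replace = TRUE, prob = gcp$p_missense)
      qual <- data.frame(trio_id = sample(trio_ids, n_qual, replace = TRUE),
                         gene_idx = gi, rule = rule,
                         stringsAsFactors = FALSE)
      placed <- do.call(rbind, lapply(seq_len(n_qual), function(i) {
        gene_row <- genome[qual$gene_idx[i], ]
        sym <- gene_row$symbol
        if (is.null(sub_cache[[sym]])) {
          sub_cache[[sym]] <- substitution_table(gene_row$cds, rate_table)
        }
        subs <- sub_cache[[sym]]
        want <- if (qual$rule[i] == "lof") "stop_gain" else "missense"
        pool <- subs[subs$class == want, , drop = FALSE]
        pool[sample.int(nrow(pool), 1, prob = pool$rate),
             c("pos", "ref", "alt")]
      }))
      qual$pos_in_gene <- placed$pos
      qual$ref <- placed$ref
      qual$alt <- placed$alt
      qual$effect <- ifelse(qual$rule == "lof", "LoF", "missense")
      qual$carrier <- sample(c("mother", "father"), n_qual, replace = TRUE)
      qual$transmitted <- stats::runif(n_qual) < config$transmission_bias
    }

    ## --- recessive biallelic opportunities (case trios) -------------------
    rec <- NULL
    n_rec <- if (n_case) {
      stats::rpois(1, config$mean_recessive_opportunities_per_trio * n_case)
    } else 0L
    if (n_rec) {
      gi <- sample(seq_len(nrow(genome)), n_rec, replace = TRUE,
                   prob = gcp$p_missense)
      rec <- do.call(rbind, lapply(seq_len(n_rec), function(i) {
        gene_row <- genome[gi[i], ]
        sym <- gene_row$symbol
        if (is.null(sub_cache[[sym]])) {
          sub_cache[[sym]] <- substitution_table(gene_row$cds, rate_table)
        }
        pool <- sub_cache[[sym]]
        pool <- pool[pool$class == "missense", , drop = FALSE]
        j <- sample.int(nrow(pool), 2, prob = pool$rate)
        out <- pool[j, c("pos", "ref", "alt")]
        names(out)[1] <- "pos_in_gene"
        out$effect <- "missense"
        out$trio_id <- sample(trio_ids[status == "case"], 1)
        out$gene_idx <- gi[i]
        out$carrier <- c("mother", "father")
        out$transmitted <- stats::runif(2) < config$transmission_bias
        out
      }))
    }

    ## --- artifact and noise sites ----------------------------------------
    random_sites <- function(n) {
      gi <- sample(seq_len(nrow(genome)), n, replace = TRUE, prob = len_w)
      pos <- floor(stats::runif(n, 1, genome$length[gi] + 1))
      ref <- substring(genome$cds[gi], pos, pos)
      alt_lookup <- t(vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b),
                             character(3)))
      alt <- alt_lookup[cbind(match(ref, DNA_BASES),
                              sample.int(3, n, replace = TRUE))]
      cls <- classify_sites(genome, gi, pos, alt)
      data.frame(gene_idx = gi, pos_in_gene = pos, ref = ref, alt = alt,
                 effect = raw_to_effect(cls$class), stringsAsFactors = FALSE)
    }
    n_art <- stats::rpois(length(trio_ids), config$artifact_sites_per_trio)
    art <- if (sum(n_art)) {
      cbind(trio_id = rep(trio_ids, n_art), random_sites(sum(n_art)),
            stringsAsFactors = FALSE)
    }
    n_noise <- stats::rpois(length(trio_ids), config$noise_sites_per_trio)
    noise <- if (sum(n_noise)) {
      cbind(trio_id = rep(trio_ids, n_noise), random_sites(sum(n_noise)),
            stringsAsFactors = FALSE)
    }

    ## --- assemble site rows with genotypes --------------------------------
    mk_rows <- function(df, child_gt, mother_gt, father_gt, site_kind) {
      if (is.null(df) || !nrow(df)) return(NULL)
      data.frame(trio_id = df$trio_id,
                 chrom = genome$chrom[df$gene_idx],
                 pos = genome$start[df$gene_idx] + df$pos_in_gene - 1L,
                 ref = df$ref, alt = df$alt,
                 gene = genome$symbol[df$gene_idx],
                 effect = df$effect,
                 child_gt = child_gt, mother_gt = mother_gt,
                 father_gt = father_gt,
                 site_kind = site_kind,
                 mosaic_parent = NA_character_,
                 mosaic_vaf = NA_real_,
                 artifact_vaf = NA_real_,
                 stringsAsFactors = FALSE)
    }

    site_rows <- NULL
    truth <- NULL
    if (!is.null(events) && nrow(events)) {
      is_mosaic <- events$kind == "parental-mosaic"
      rows <- mk_rows(events, "0/1", "0/0", "0/0", "event")
      rows$mosaic_parent[is_mosaic] <- sample(c("mother", "father"),
                                              sum(is_mosaic), replace = TRUE)
      rows$mosaic_vaf[is_mosaic] <- stats::runif(sum(is_mosaic), 0.03, 0.20)
      site_rows <- rows
      truth <- data.frame(trio_id = events$trio_id, kind = events$kind,
                          chrom = rows$chrom, pos = rows$pos,
                          gene = rows$gene, effect = events$effect,
                          parent = rows$mosaic_parent,
                          parent_vaf = rows$mosaic_vaf,
                          transmitted = NA,
                          key = variant_key(rows$chrom, rows$pos, rows$ref,
                                            rows$alt),
                          stringsAsFactors = FALSE)
    }
    if (!is.null(qual)) {
      rows <- mk_rows(qual, ifelse(qual$transmitted, "0/1", "0/0"),
                      ifelse(qual$carrier == "mother", "0/1", "0/0"),
                      ifelse(qual$carrier == "father", "0/1", "0/0"),
                      "inherited")
      site_rows <- rbind(site_rows, rows)
      truth <- rbind(truth, data.frame(
        trio_id = qual$trio_id, kind = "inherited-het",
        chrom = rows$chrom, pos = rows$pos, gene = rows$gene,
        effect = qual$effect, parent = qual$carrier, parent_vaf = NA_real_,
        transmitted = qual$transmitted,
        key = variant_key(rows$chrom, rows$pos, rows$ref, rows$alt),
        stringsAsFactors = FALSE))
    }
    if (!is.null(rec)) {
      rows <- mk_rows(rec, ifelse(rec$transmitted, "0/1", "0/0"),
                      ifelse(rec$carrier == "mother", "0/1", "0/0"),
                      ifelse(rec$carrier == "father", "0/1", "0/0"),
                      "inherited")
      site_rows <- rbind(site_rows, rows)
      truth <- rbind(truth, data.frame(
        trio_id = rec$trio_id, kind = "inherited-biallelic",
        chrom = rows$chrom, pos = rows$pos, gene = rows$gene,
        effect = "missense", parent = rec$carrier, parent_vaf = NA_real_,
        transmitted = rec$transmitted,
        key = variant_key(rows$chrom, rows$pos, rows$ref, rows$alt),
        stringsAsFactors = FALSE))
    }
    if (!is.null(art)) {
      rows <- mk_rows(art, "0/1", "0/0", "0/0", "artifact")
      rows$artifact_vaf <- stats::runif(nrow(rows), 0.10, 0.28)
      site_rows <- rbind(site_rows, rows)
    }
    if (!is.null(noise)) {
      site_rows <- rbind(site_rows, mk_rows(noise, "0/0", "0/0", "0/0",
                                            "noise"))
    }

    if (is.null(site_rows)) {
      site_rows <- data.frame(trio_id = character(), chrom = character(),
                              pos = integer(), ref = character(),
                              alt = character(), gene = character(),
                              effect = character(), child_gt = character(),
                              mother_gt = character(),
                              father_gt = character(),
                              site_kind = character(),
                              mosaic_parent = character(),
                              mosaic_vaf = numeric(),
                              artifact_vaf = numeric(),
                              stringsAsFactors = FALSE)
    }
    site_rows$key <- variant_key(site_rows$chrom, site_rows$pos,
                                 site_rows$ref, site_rows$alt)
    if (is.null(truth)) {
      truth <- data.frame(trio_id = character(), kind = character(),
                          chrom = character(), pos = integer(),
                          gene = character(), effect = character(),
                          parent = character(), parent_vaf = numeric(),
                          transmitted = logical(), key = character(),
                          stringsAsFactors = FALSE)
    }

    # drop rare within-trio site collisions (keep first occurrence) so each
    # truth event maps to exactly one emitted record
    dup <- duplicated(paste(site_rows$trio_id, site_rows$key))
    if (any(dup)) site_rows <- site_rows[!dup, , drop = FALSE]
    truth <- truth[paste(truth$trio_id, truth$key) %in%
                   paste(site_rows$trio_id, site_rows$key), , drop = FALSE]
    truth <- truth[!duplicated(paste(truth$trio_id, truth$key)), ,
                   drop = FALSE]

    ## --- read-level evidence ----------------------------------------------
    n_sites <- nrow(site_rows)
    draw_depth <- function(n) {
      pmax(stats::rnbinom(n, mu = config$depth_mean,
                          size = config$depth_dispersion), 1L)
    }
    alt_reads_for <- function(gt, dp, vaf_override = NULL) {
      p <- ifelse(gt == "0/1", 0.5,
           ifelse(gt == "1/1", 1 - config$error_rate, config$error_rate))
      if (!is.null(vaf_override)) p <- ifelse(is.na(vaf_override), p,
                                              vaf_override)
      stats::rbinom(length(dp), dp, p)
    }
    for (role in c("child", "mother", "father")) {
      dp <- draw_depth(n_sites)
      gt <- site_rows[[paste0(role, "_gt")]]
      vaf <- rep(NA_real_, n_sites)
      if (role == "child") vaf <- site_rows$artifact_vaf
      if (role %in% c("mother", "father")) {
        vaf <- ifelse(!is.na(site_rows$mosaic_parent) &
                        site_rows$mosaic_parent == role,
                      site_rows$mosaic_vaf, NA_real_)
      }
      alt <- alt_reads_for(gt, dp, vaf)
      site_rows[[paste0(role, "_gt")]] <- gt
      site_rows[[paste0(role, "_ref_reads")]] <- dp - alt
      site_rows[[paste0(role, "_alt_reads")]] <- alt
      site_rows[[paste0(role, "_dp")]] <- dp
    }

    ## --- annotations -------------------------------------------------------
    uniq <- !duplicated(site_rows$key)
    ann <- data.frame(key = site_rows$key[uniq],
                      gene = site_rows$gene[uniq],
                      effect = site_rows$effect[uniq],
                      stringsAsFactors = FALSE)
    ann$score <- simulate_scores(ann$effect)
    ann$clinvar <- rep("none", nrow(ann))
    # pathogenic labels: qualifying missense rule-2 variants by design,
    # plus a sprinkle of other high-scoring missense
    if (!is.null(qual)) {
      mis_keys <- site_rows$key[site_rows$site_kind == "inherited" &
                                site_rows$effect == "missense"]
      lab <- ann$key %in% mis_keys
      ann$clinvar[lab] <- sample(c("pathogenic", "likely_pathogenic"),
                                 sum(lab), replace = TRUE)
    }
    extra <- ann$effect == "missense" & ann$clinvar == "none" &
             ann$score > 25 & stats::runif(nrow(ann)) < 0.05
    ann$clinvar[extra] <- "likely_pathogenic"
    ann$loeuf <- genome$loeuf[match(ann$gene, genome$symbol)]

    truth$score <- ann$score[match(truth$key, ann$key)]
    truth <- truth[order(truth$trio_id, as.integer(truth$chrom), truth$pos), ,
                   drop = FALSE]
    rownames(truth) <- NULL

    records <- site_rows[order(site_rows$trio_id,
                               as.integer(site_rows$chrom),
                               site_rows$pos, site_rows$alt),
                         c("trio_id", "chrom", "pos", "ref", "alt", "key",
                           "child_gt", "child_ref_reads", "child_alt_reads",
                           "child_dp",
                           "mother_gt", "mother_ref_reads",
                           "mother_alt_reads", "mother_dp",
                           "father_gt", "father_ref_reads",
                           "father_alt_reads", "father_dp")]
    rownames(records) <- NULL

    structure(list(config = config, genome = genome, records = records,
                   pedigree = pedigree, annotations = ann, truth = truth),
              class = "trio_cohort")
  })
}

#' @export
print.trio_cohort <- function(x, ...) {
  tr <- ped_trios(x$pedigree)
  cat("trio_cohort:", sum(tr$status == "case"), "case /",
      sum(tr$status == "control"), "control trios,",
      nrow(x$records), "variant records,",
      nrow(x$truth), "truth events\n")
  invisible(x)
}

#' Write and re-read a simulated cohort
#'
#' `write_cohort` emits one multi-sample VCF per trio (FORMAT `GT:AD:DP`)
#' under `dir/trios/`, a 6-column PED, an annotation TSV and a truth TSV.
#' `read_cohort` reconstructs the in-memory records from those files.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   list with `records`, `pedigree`, `annotations`, `truth`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "trio_cohort"))
  dir.create(file.path(dir, "trios"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_tb("cannot create output directory: ", dir)
  write_ped(cohort$pedigree, file.path(dir, "cohort.ped"))
  write_annotations(cohort$annotations, file.path(dir, "annotations.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  trios <- ped_trios(cohort$pedigree)
  for (i in seq_len(nrow(trios))) {
    recs <- cohort$records[cohort$records$trio_id == trios$trio_id[i], ,
                           drop = FALSE]
    if (!nrow(recs)) next
    write_trio_vcf(recs, file.path(dir, "trios",
                                   paste0(trios$trio_id[i], ".vcf")),
                   child = trios$child[i], mother = trios$mother[i],
                   father = trios$father[i])
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pedigree <- read_ped(file.path(dir, "cohort.ped"))
  trios <- ped_trios(pedigree)
  recs <- lapply(seq_len(nrow(trios)), function(i) {
    path <- file.path(dir, "trios", paste0(trios$trio_id[i], ".vcf"))
    if (!file.exists(path)) return(NULL)
    out <- read_trio_vcf(path, child = trios$child[i],
                         mother = trios$mother[i], father = trios$father[i],
                         trio_id = trios$trio_id[i])
    names(out) <- sub("^(child|mother|father)_ref_reads$", "\\1_ref_reads",
                      names(out))
    out
  })
  records <- do.call(rbind, recs)
  if (!is.null(records)) {
    records <- records[order(records$trio_id, as.integer(records$chrom),
                             records$pos, records$alt), , drop = FALSE]
    rownames(records) <- NULL
    records <- records[, c("trio_id", "chrom", "pos", "ref", "alt", "key",
                           "child_gt", "child_ref_reads", "child_alt_reads",
                           "child_dp", "mother_gt", "mother_ref_reads",
                           "mother_alt_reads", "mother_dp", "father_gt",
                           "father_ref_reads", "father_alt_reads",
                           "father_dp")]
  }
  list(records = records, pedigree = pedigree,
       annotations = read_annotations(file.path(dir, "annotations.tsv")),
       truth = utils::read.delim(file.path(dir, "truth.tsv"),
                                 stringsAsFactors = FALSE))
}
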