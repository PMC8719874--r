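## De novo and transmitted parental-mosaic variant calling from trio
## genotype records, with hard allele-balance/depth quality control and
## per-trio outlier exclusion.

#' Quality-control thresholds for trio calling
#'
#' @param min_child_alt_allele_fraction Minimum fraction of child reads
#'   supporting the alternate allele (default 0.30).
#' @param min_depth_child,min_depth_parent Minimum site depths (default 10).
#' @param parent_alt_fraction_tolerance Maximum fraction of a hom-ref
#'   parent's reads allowed to show the alternate allele for a de novo call
#'   (default 0.02; the absolute bound is
#'   `max(min_parent_alt_read_floor, tolerance * depth)` reads).
#' @param min_parent_alt_read_floor Absolute read floor for the parental
#'   tolerance (default 2; at 0.5% per-read error and ~90x depth a 1-read
#'   floor would reject a substantial share of true de novo events).
#' @param mosaic_band Allele-fraction interval in a hom-ref parent read as
#'   evidence of parental mosaicism (default 0.03-0.20, below the 0.30
#'   heterozygous detection threshold).
#' @param min_mosaic_alt_reads Minimum alternate reads for mosaic-band
#'   evidence (default 4; at typical depths 2-3 alternate reads are too
#'   easily produced by per-read error).
#' @param max_control_carriers Maximum carrier count among reference
#'   controls for a call to survive (default 0: absent from all controls).
#' @param max_dnms_per_trio Trios with at least this many DNM calls are
#'   excluded outright (default 6).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_child_alt_allele_fraction = 0.30,
                          min_depth_child = 10, min_depth_parent = 10,
                          parent_alt_fraction_tolerance = 0.02,
                          min_parent_alt_read_floor = 2,
                          mosaic_band = c(0.03, 0.20),
                          min_mosaic_alt_reads = 4,
                          max_control_carriers = 0,
                          max_dnms_per_trio = 6) {
  stopifnot(min_child_alt_allele_fraction > 0,
            min_child_alt_allele_fraction <= 0.5,
            min_depth_child >= 0, min_depth_parent >= 0,
            parent_alt_fraction_tolerance >= 0,
            length(mosaic_band) == 2, mosaic_band[1] < mosaic_band[2],
            mosaic_band[2] < min_child_alt_allele_fraction,
            max_control_carriers >= 0, max_dnms_per_trio >= 1)
  structure(list(min_child_alt_allele_fraction = min_child_alt_allele_fraction,
                 min_depth_child = min_depth_child,
                 min_depth_parent = min_depth_parent,
                 parent_alt_fraction_tolerance = parent_alt_fraction_tolerance,
                 min_parent_alt_read_floor = min_parent_alt_read_floor,
                 mosaic_band = mosaic_band,
                 min_mosaic_alt_reads = min_mosaic_alt_reads,
                 max_control_carriers = max_control_carriers,
                 max_dnms_per_trio = max_dnms_per_trio),
            class = "qc_thresholds")
}

check_trio_columns <- function(records) {
  need <- c("trio_id", "chrom", "pos", "ref", "alt", "key",
            as.vector(outer(c("child", "mother", "father"),
                            c("_gt", "_alt_reads", "_dp"), paste0)))
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_tb("trio records missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(records)
}

alt_fraction <- function(alt_reads, dp) {
  ifelse(dp > 0, alt_reads / dp, NA_real_)
}

parent_alt_tolerance <- function(dp, thresholds) {
  pmax(thresholds$min_parent_alt_read_floor,
       thresholds$parent_alt_fraction_tolerance * dp)
}

#' Count control-cohort carriers per variant key
#'
#' Builds the lookup used by the "absent in unrelated controls" filter: for
#' each variant key, the number of control trios in which any member
#' carries at least one genotyped alternate allele.
#'
#' @param records Trio variant records from the control cohort.
#' @return Named integer vector (variant key -> carrier count).
#' @export
control_carrier_index <- function(records) {
  check_trio_columns(records)
  carries <- function(gt) !is.na(gt) & gt %in% c("0/1", "1/1")
  any_carrier <- carries(records$child_gt) | carries(records$mother_gt) |
                 carries(records$father_gt)
  hits <- records[any_carrier, c("trio_id", "key")]
  hits <- hits[!duplicated(hits), , drop = FALSE]
  tab <- table(hits$key)
  stats::setNames(as.integer(tab), names(tab))
}

#' Call de novo mutations in trio records
#'
#' A site is called de novo iff the child is genotyped heterozygous with
#' alternate allele fraction at or above the child threshold and adequate
#' depth; both parents are genotyped hom-ref with adequate depth and
#' alternate-read evidence within the parental tolerance; and the variant
#' key is carried by no more than `max_control_carriers` control subjects.
#' Sites with missing genotypes are skipped (recorded in the `skipped`
#' attribute with a reason), never raised as errors.
#'
#' @param records Trio variant records (see [read_trio_vcf()]).
#' @param thresholds A [qc_thresholds()].
#' @param control_index Optional named vector from
#'   [control_carrier_index()].
#' @param annotations Optional annotation table; matching columns (`gene`,
#'   `effect`, `score`, `clinvar`, `loeuf`) are joined onto the calls.
#' @return Data frame of DNM calls sorted by coordinate, with columns
#'   `trio_id`, `key`, `chrom`, `pos`, `ref`, `alt`, `vtype`
#'   (`snv`/`indel`), `child_alt_fraction` and any joined annotation;
#'   attribute `skipped` holds the site-skip log.
#' @export
call_dnms <- function(records, thresholds = qc_thresholds(),
                      control_index = NULL, annotations = NULL) {
  check_trio_columns(records)
  gts <- cbind(records$child_gt, records$mother_gt, records$father_gt)
  missing_gt <- rowSums(is.na(gts)) > 0
  skipped <- if (any(missing_gt)) {
    data.frame(trio_id = records$trio_id[missing_gt],
               key = records$key[missing_gt],
               reason = "missing genotype", stringsAsFactors = FALSE)
  } else {
    data.frame(trio_id = character(), key = character(),
               reason = character(), stringsAsFactors = FALSE)
  }

  child_frac <- alt_fraction(records$child_alt_reads, records$child_dp)
  ok <- !missing_gt &
    records$child_gt == "0/1" &
    records$mother_gt == "0/0" &
    records$father_gt == "0/0" &
    records$child_dp >= thresholds$min_depth_child &
    records$mother_dp >= thresholds$min_depth_parent &
    records$father_dp >= thresholds$min_depth_parent &
    !is.na(child_frac) &
    child_frac >= thresholds$min_child_alt_allele_fraction &
    records$mother_alt_reads <= parent_alt_tolerance(records$mother_dp,
                                                     thresholds) &
    records$father_alt_reads <= parent_alt_tolerance(records$father_dp,
                                                     thresholds)
  if (!is.null(control_index)) {
    carriers <- control_index[records$key]
    carriers[is.na(carriers)] <- 0L
    ok <- ok & carriers <= thresholds$max_control_carriers
  }

  calls <- records[which(ok),
                   c("trio_id", "key", "chrom", "pos", "ref", "alt"),
                   drop = FALSE]
  calls$vtype <- ifelse(nchar(calls$ref) == 1 & nchar(calls$alt) == 1,
                        "snv", "indel")
  calls$child_alt_fraction <- child_frac[which(ok)]
  calls <- calls[order(calls$trio_id, suppressWarnings(as.numeric(calls$chrom)),
                       calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  if (!is.null(annotations)) calls <- join_annotations(calls, annotations)
  structure(calls, skipped = skipped, class = c("dnm_calls", "data.frame"))
}

join_annotations <- function(calls, annotations) {
  idx <- match(calls$key, annotations$key)
  for (col in intersect(c("gene", "effect", "score", "clinvar", "loeuf"),
                        names(annotations))) {
    calls[[col]] <- annotations[[col]][idx]
  }
  calls
}

#' Exclude trios with excess DNM calls
#'
#' Trios with `max_dnms_per_trio` (default 6) or more calls are dropped
#' entirely -- an excess of Mendelian-violation calls marks a sample-quality
#' problem, not biology.
#'
#' @param calls DNM call table from [call_dnms()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `calls` (retained rows) and `excluded_trios`.
#' @export
exclude_outlier_trios <- function(calls, thresholds = qc_thresholds()) {
  if (!nrow(calls)) return(list(calls = calls, excluded_trios = character()))
  per_trio <- table(calls$trio_id)
  bad <- names(per_trio)[per_trio >= thresholds$max_dnms_per_trio]
  list(calls = calls[!calls$trio_id %in% bad, , drop = FALSE],
       excluded_trios = bad)
}

#' Call transmitted parental-mosaic variants
#'
#' A site is called mosaic iff the child passes the same het/fraction/depth
#' QC as for de novo calls; exactly one parent is genotyped hom-ref yet
#' shows an alternate allele fraction inside the mosaic band (default
#' 0.03-0.20); and the other parent shows no alternate evidence beyond the
#' hom-ref tolerance. Sites where both parents show mosaic-band evidence
#' are skipped with a logged reason.
#'
#' @inheritParams call_dnms
#' @return Data frame of mosaic calls with `mosaic_parent` and
#'   `parent_alt_fraction` columns; attribute `skipped` as in [call_dnms()].
#' @export
call_transmitted_mosaics <- function(records, thresholds = qc_thresholds(),
                                     annotations = NULL) {
  check_trio_columns(records)
  gts <- cbind(records$child_gt, records$mother_gt, records$father_gt)
  missing_gt <- rowSums(is.na(gts)) > 0

  child_frac <- alt_fraction(records$child_alt_reads, records$child_dp)
  child_ok <- !missing_gt &
    records$child_gt == "0/1" &
    records$child_dp >= thresholds$min_depth_child &
    !is.na(child_frac) &
    child_frac >= thresholds$min_child_alt_allele_fraction

  band <- thresholds$mosaic_band
  # a parent is mosaic-evidenced only when its alternate support exceeds the
  # hom-ref tolerance: weaker evidence is indistinguishable from sequencing
  # error and such sites remain de novo candidates (keeps call sets disjoint)
  in_band <- function(role) {
    alt <- records[[paste0(role, "_alt_reads")]]
    dp <- records[[paste0(role, "_dp")]]
    frac <- alt_fraction(alt, dp)
    !missing_gt &
      records[[paste0(role, "_gt")]] == "0/0" &
      dp >= thresholds$min_depth_parent &
      alt > parent_alt_tolerance(dp, thresholds) &
      alt >= thresholds$min_mosaic_alt_reads &
      !is.na(frac) & frac >= band[1] & frac <= band[2]
  }
  clean <- function(role) {
    records[[paste0(role, "_gt")]] == "0/0" &
      records[[paste0(role, "_dp")]] >= thresholds$min_depth_parent &
      records[[paste0(role, "_alt_reads")]] <=
        parent_alt_tolerance(records[[paste0(role, "_dp")]], thresholds) &
      alt_fraction(records[[paste0(role, "_alt_reads")]],
                   records[[paste0(role, "_dp")]]) < band[1]
  }
  mother_band <- in_band("mother")
  father_band <- in_band("father")
  both <- child_ok & mother_band & father_band
  mosaic_mother <- child_ok & mother_band & !father_band & clean("father")
  mosaic_father <- child_ok & father_band & !mother_band & clean("mother")

  skipped <- rbind(
    if (any(missing_gt)) data.frame(trio_id = records$trio_id[missing_gt],
                                    key = records$key[missing_gt],
                                    reason = "missing genotype",
                                    stringsAsFactors = FALSE),
    if (any(both)) data.frame(trio_id = records$trio_id[both],
                              key = records$key[both],
                              reason = "mosaic-band evidence in both parents",
                              stringsAsFactors = FALSE))
  skipped <- skipped %||% data.frame(trio_id = character(), key = character(),
                                     reason = character(),
                                     stringsAsFactors = FALSE)

  pick <- mosaic_mother | mosaic_father
  calls <- records[which(pick),
                   c("trio_id", "key", "chrom", "pos", "ref", "alt"),
                   drop = FALSE]
  calls$vtype <- ifelse(nchar(calls$ref) == 1 & nchar(calls$alt) == 1,
                        "snv", "indel")
  calls$child_alt_fraction <- child_frac[which(pick)]
  calls$mosaic_parent <- ifelse(mosaic_mother[which(pick)], "mother",
                                "father")
  pf <- ifelse(mosaic_mother[pick],
               alt_fraction(records$mother_alt_reads,
                            records$mother_dp)[which(pick)],
               alt_fraction(records$father_alt_reads,
                            records$father_dp)[which(pick)])
  calls$parent_alt_fraction <- pf
  calls <- calls[order(calls$trio_id, suppressWarnings(as.numeric(calls$chrom)),
                       calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  if (!is.null(annotations)) calls <- join_annotations(calls, annotations)
  structure(calls, skipped = skipped,
            class = c("mosaic_calls", "data.frame"))
}

#' Combine de novo and mosaic call sets
#'
#' Concatenates the two call sets (which must not share a trio/variant key)
#' and reports the mosaic share of all de novo-appearing events, as a
#' percentage rounded to one decimal.
#'
#' @param dnms,mosaics Call tables from [call_dnms()] and
#'   [call_transmitted_mosaics()].
#' @return List with `calls` (column `origin` distinguishes `dnm` from
#'   `mosaic`) and `mosaic_fraction_pct`.
#' @export
combine_callsets <- function(dnms, mosaics) {
  shared <- intersect(paste(dnms$trio_id, dnms$key),
                      paste(mosaics$trio_id, mosaics$key))
  if (length(shared)) {
    stop_tb("variant present in both call sets: ", shared[1])
  }
  common <- c("trio_id", "key", "chrom", "pos", "ref", "alt", "vtype",
              "child_alt_fraction",
              intersect(c("gene", "effect", "score", "clinvar", "loeuf"),
                        intersect(names(dnms), names(mosaics))))
  d <- as.data.frame(dnms)[, common, drop = FALSE]
  m <- as.data.frame(mosaics)[, common, drop = FALSE]
  if (nrow(d)) d$origin <- "dnm"
  else d$origin <- character()
  if (nrow(m)) {
    m$origin <- "mosaic"
    m$mosaic_parent <- mosaics$mosaic_parent
  } else {
    m$origin <- character()
    m$mosaic_parent <- character()
  }
  d$mosaic_parent <- rep(NA_character_, nrow(d))
  combined <- rbind(d, m)
  total <- nrow(combined)
  frac <- if (total) round1(100 * nrow(m) / total) else 0
  list(calls = combined, mosaic_fraction_pct = frac)
}
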