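## Readers and writers for the standard inputs: trio VCFs (via vcfR), PED
## pedigrees, gene sets, annotation tables and interaction networks. All
## tables are tab-delimited with a header row; coordinates are 1-based.

GT_LEVELS <- c("0/0", "0/1", "1/1")

check_required_columns <- function(tab, need, what) {
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_tb(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in need) {
    bad <- which(is.na(tab[[col]]))
    if (length(bad)) {
      stop_tb(what, ": missing value in column '", col, "' at data line ",
              bad[1])
    }
  }
  invisible(tab)
}

#' Read and write PED pedigree files
#'
#' Standard 6-column PED (family, individual, father, mother, sex,
#' phenotype; phenotype 2 = case, 1 = control). [ped_trios()] extracts one
#' row per complete trio (child with both parents present in the file).
#'
#' @param path File path.
#' @return `read_ped` returns a data frame with columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id`, `sex`, `phenotype`.
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("family_id", "individual_id",
                                         "father_id", "mother_id", "sex",
                                         "phenotype"))
  check_required_columns(tab, c("family_id", "individual_id"), "PED file")
  tab
}

#' @rdname read_ped
#' @param pedigree Pedigree data frame as returned by [read_ped()].
#' @export
write_ped <- function(pedigree, path) {
  utils::write.table(pedigree[, c("family_id", "individual_id", "father_id",
                                  "mother_id", "sex", "phenotype")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname read_ped
#' @export
ped_trios <- function(pedigree) {
  kids <- pedigree[pedigree$father_id != "0" & pedigree$mother_id != "0", ,
                   drop = FALSE]
  ok <- kids$father_id %in% pedigree$individual_id &
        kids$mother_id %in% pedigree$individual_id
  if (!all(ok)) {
    stop_tb("pedigree references missing parent(s) for: ",
            paste(kids$individual_id[!ok], collapse = ", "))
  }
  data.frame(trio_id = kids$family_id, child = kids$individual_id,
             mother = kids$mother_id, father = kids$father_id,
             status = ifelse(kids$phenotype == 2, "case", "control"),
             stringsAsFactors = FALSE)
}

## ---- trio VCF --------------------------------------------------------------

# map a raw GT string to the biallelic genotype for alt allele j
recode_gt <- function(gt, allele) {
  out <- rep(NA_character_, length(gt))
  known <- !is.na(gt) & !grepl("\\.", gt)
  n_alt <- vapply(strsplit(gt[known], "[/|]"), function(a) {
    sum(a == as.character(allele))
  }, integer(1))
  out[known] <- GT_LEVELS[n_alt + 1L]
  out
}

#' Read one trio's variants from a multi-sample VCF
#'
#' Extracts GT, AD and DP for the three trio members and returns one
#' biallelic record per site; multi-allelic sites are decomposed into one
#' record per alternate allele (shared chromosome/position, per-allele
#' depths recomputed from the AD vector). Missing genotypes are preserved
#' as `NA`.
#'
#' @param path VCF file (4.2; FORMAT must carry GT, AD and DP).
#' @param child,mother,father Sample names of the trio members.
#' @param trio_id Optional trio label attached to every record.
#' @return A data frame of trio variant records with columns `trio_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `key` and, per member (`child_`,
#'   `mother_`, `father_` prefixes), `gt`, `ref_reads`, `alt_reads`, `dp`.
#' @export
read_trio_vcf <- function(path, child, mother, father, trio_id = child) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  need <- c(child, mother, father)
  if (!all(need %in% samples)) {
    stop_tb("sample(s) missing from VCF: ",
            paste(setdiff(need, samples), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, "GT")
  ad <- vcfR::extract.gt(v, "AD")
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    do.call(rbind, lapply(seq_along(alts), function(j) {
      rec <- data.frame(chrom = fix[i, "CHROM"],
                        pos = as.integer(fix[i, "POS"]),
                        ref = fix[i, "REF"], alt = alts[j],
                        stringsAsFactors = FALSE)
      for (role in c("child", "mother", "father")) {
        s <- switch(role, child = child, mother = mother, father = father)
        ad_vec <- suppressWarnings(
          as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1]]))
        rec[[paste0(role, "_gt")]] <- recode_gt(gt[i, s], j)
        rec[[paste0(role, "_ref_reads")]] <- ad_vec[1]
        rec[[paste0(role, "_alt_reads")]] <- ad_vec[j + 1L]
        rec[[paste0(role, "_dp")]] <- as.integer(dp[i, s])
      }
      rec
    }))
  })
  out <- do.call(rbind, rows)
  out <- cbind(trio_id = trio_id, out, stringsAsFactors = FALSE)
  out$key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  rownames(out) <- NULL
  out
}

#' Write one trio's records as a multi-sample VCF
#'
#' Emits a minimal VCF 4.2 with FORMAT `GT:AD:DP` and the three trio
#' members as samples, suitable for re-reading with [read_trio_vcf()].
#'
#' @param records Trio variant records for a single trio (see
#'   [read_trio_vcf()] for the column layout).
#' @inheritParams read_trio_vcf
#' @export
write_trio_vcf <- function(records, path, child, mother, father) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", child, mother, father, sep = "\t")
  )
  fmt <- function(role) {
    gt <- records[[paste0(role, "_gt")]]
    gt[is.na(gt)] <- "./."
    paste0(gt, ":",
           records[[paste0(role, "_ref_reads")]], ",",
           records[[paste0(role, "_alt_reads")]], ":",
           records[[paste0(role, "_dp")]])
  }
  ord <- order(records$chrom, records$pos, records$alt)
  records <- records[ord, , drop = FALSE]
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", "PASS", ".", "GT:AD:DP",
                fmt("child"), fmt("mother"), fmt("father"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

## ---- gene sets -------------------------------------------------------------

#' Gene sets
#'
#' A gene set is a named collection of unique gene symbols (for example a
#' curated cardiac/epilepsy panel, or the ACMG actionable-gene list).
#' Duplicate symbols -- which arise when overlapping source panels are
#' merged -- are removed with a message.
#'
#' @param name Set label.
#' @param members Character vector of gene symbols.
#' @return `gene_set` returns a character vector of unique symbols with a
#'   `name` attribute and class `gene_set`.
#' @export
gene_set <- function(name, members) {
  members <- as.character(members)
  members <- members[!is.na(members) & nzchar(members)]
  if (!length(members)) stop_tb("gene set '", name, "' is empty")
  if (anyDuplicated(members)) {
    message("gene set '", name, "': removed ",
            sum(duplicated(members)), " duplicate symbol(s)")
    members <- unique(members)
  }
  structure(members, name = name, class = c("gene_set", "character"))
}

#' @rdname gene_set
#' @param path One-column tab-delimited file of gene symbols (header `gene`
#'   optional).
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && tolower(lines[1]) %in% c("gene", "symbol")) {
    lines <- lines[-1]
  }
  gene_set(name %||% sub("\\.[^.]*$", "", basename(path)), lines)
}

#' @rdname gene_set
#' @param x Gene set.
#' @export
write_gene_set <- function(x, path) {
  writeLines(c("gene", as.character(x)), path)
  invisible(path)
}

## ---- annotations -----------------------------------------------------------

#' Read and write variant annotation tables
#'
#' Tab-delimited table keyed by the canonical `chrom-pos-ref-alt` variant
#' key, carrying the consumed (not computed) functional annotation: gene
#' symbol, effect class (`synonymous`, `missense`, `inframe-indel`, `LoF`),
#' a scaled CADD-style deleteriousness score, a ClinVar-style pathogenicity
#' label (`none`, `pathogenic`, `likely_pathogenic`) and the gene's LOEUF
#' constraint value.
#'
#' @param path File path.
#' @return `read_annotations` returns the validated data frame.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_required_columns(tab, c("key", "gene", "effect"), "annotation table")
  bad <- which(!tab$effect %in% EFFECT_CLASSES)
  if (length(bad)) {
    stop_tb("annotation table: unknown effect class '", tab$effect[bad[1]],
            "' at data line ", bad[1])
  }
  if (!is.null(tab$clinvar)) {
    badc <- which(!tab$clinvar %in% c("none", "pathogenic",
                                      "likely_pathogenic"))
    if (length(badc)) {
      stop_tb("annotation table: unknown clinvar label '",
              tab$clinvar[badc[1]], "' at data line ", badc[1])
    }
  }
  if (!is.null(tab$loeuf) && any(tab$loeuf < 0, na.rm = TRUE)) {
    stop_tb("annotation table: negative LOEUF value")
  }
  tab
}

#' @rdname read_annotations
#' @param annotations Annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- interaction network ---------------------------------------------------

#' Read a protein-interaction network from an edge list
#'
#' Tab-delimited edge list with columns `gene_a`, `gene_b` and an optional
#' evidence `channel`. The result is a simple undirected graph: self-loops
#' are dropped and duplicate edges collapsed. An optional one-column node
#' file adds isolated nodes (genes with no listed interaction).
#'
#' @param path Edge-list file.
#' @param nodes_path Optional one-column file of node names to retain even
#'   if they have no edges.
#' @return An [igraph::graph] object.
#' @export
read_network <- function(path, nodes_path = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(tab)) stop_tb("network edge list is empty")
  check_required_columns(tab, c("gene_a", "gene_b"), "network edge list")
  g <- igraph::graph_from_data_frame(tab, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  if (!is.null(nodes_path)) {
    extra <- readLines(nodes_path)
    extra <- trimws(extra)
    extra <- extra[nzchar(extra)]
    if (length(extra) && tolower(extra[1]) %in% c("gene", "node")) {
      extra <- extra[-1]
    }
    new <- setdiff(extra, igraph::V(g)$name)
    if (length(new)) g <- igraph::add_vertices(g, length(new), name = new)
  }
  g
}
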