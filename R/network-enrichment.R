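## Deleteriousness scaling and protein-interaction network enrichment: CADD
## rank scaling, threshold partition of mutated genes, edge-count
## enrichment of a hit set under resampling nulls (uniform or
## degree-matched), connected-component cluster extraction and the
## coding-length confound check.

#' Scaled deleteriousness score from a rank fraction
#'
#' CADD-style scaling: `score = -10 * log10(rank_fraction)`, so the top 1%
#' of substitutions scores 20 and the top 0.1% scores 30.
#'
#' @param rank_fraction Deleteriousness rank as a fraction in (0, 1].
#' @return Scaled score(s).
#' @export
#' @examples
#' cadd_scaled_score(c(0.1, 0.01, 0.001))  # 10, 20, 30
cadd_scaled_score <- function(rank_fraction) {
  if (any(rank_fraction <= 0 | rank_fraction > 1)) {
    stop_tb("rank_fraction must lie in (0, 1]")
  }
  -10 * log10(rank_fraction)
}

#' Partition mutated genes by deleteriousness threshold
#'
#' Each gene is represented once with the maximum score among its
#' mutations and a multiplicity count (genes hit by two mutations are the
#' "double circles" of a network figure). Genes with score strictly above
#' the threshold go to the high set; ties at the threshold go low.
#'
#' @param hits Data frame with columns `gene` and `score` (one row per
#'   mutation).
#' @param threshold Score cutoff (default 15, the conventional CADD
#'   cutoff).
#' @return List with data frames `high` and `low`, each with `gene`,
#'   `score` (max) and `multiplicity`.
#' @export
partition_by_deleteriousness <- function(hits, threshold = 15) {
  if (!nrow(hits)) {
    empty <- data.frame(gene = character(), score = numeric(),
                        multiplicity = integer(), stringsAsFactors = FALSE)
    return(list(high = empty, low = empty))
  }
  agg <- do.call(rbind, lapply(split(hits, hits$gene), function(d) {
    data.frame(gene = d$gene[1], score = max(d$score),
               multiplicity = nrow(d), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  list(high = agg[agg$score > threshold, , drop = FALSE],
       low = agg[agg$score <= threshold, , drop = FALSE])
}

count_internal_edges <- function(graph, nodes) {
  sub <- igraph::induced_subgraph(graph, vids = nodes)
  igraph::ecount(sub)
}

#' Edge-count enrichment of a hit set on an interaction graph
#'
#' Observed statistic: number of edges with both endpoints in the hit set.
#' The null resamples node sets of equal size, either uniformly or
#' degree-matched (sampling within degree-quintile bins, approximating a
#' background that allows for the proclivity of well-connected genes to
#' interact). The p-value is the standard permutation upper tail
#' `(1 + #{null >= observed}) / (n_permutations + 1)`, so it is never zero
#' and has resolution `1/(n_permutations + 1)`.
#'
#' @param graph An [igraph::graph] (see [read_network()]).
#' @param hits Character vector of hit gene symbols; symbols absent from
#'   the graph are dropped with a message.
#' @param n_permutations Number of null resamples (default 9999).
#' @param null `"degree-matched"` (default) or `"uniform"`.
#' @param seed RNG seed for the resampling.
#' @return Data frame with `n_hits`, `observed_edges`, `expected_edges`
#'   (null mean), `p_value`, `n_permutations`, `null`, `seed`.
#' @export
edge_enrichment <- function(graph, hits, n_permutations = 9999,
                            null = c("degree-matched", "uniform"),
                            seed = 1) {
  null <- match.arg(null)
  stopifnot(n_permutations >= 1)
  nodes <- igraph::V(graph)$name
  hits <- unique(as.character(hits))
  absent <- setdiff(hits, nodes)
  if (length(absent)) {
    message(length(absent), " hit gene(s) absent from graph, dropped")
    hits <- setdiff(hits, absent)
  }
  k <- length(hits)
  if (k > length(nodes)) stop_tb("hit set larger than the node set")
  if (k < 2) {
    return(data.frame(n_hits = k, observed_edges = 0, expected_edges = 0,
                      null_sd = 0, p_value = 1,
                      n_permutations = n_permutations, null = null,
                      seed = seed))
  }
  observed <- count_internal_edges(graph, hits)

  deg <- igraph::degree(graph)
  with_seed(seed, {
    if (null == "uniform") {
      draw <- function() sample(nodes, k)
    } else {
      # degree-quintile bins; hit-set bin composition is preserved
      qs <- unique(stats::quantile(deg, probs = seq(0, 1, 0.2)))
      breaks <- unique(c(-Inf, qs[-1]))
      bin <- if (length(breaks) < 2) rep(1L, length(deg))
             else cut(deg, breaks = breaks, labels = FALSE)
      names(bin) <- nodes
      by_bin <- split(nodes, bin)
      hit_bins <- table(bin[hits])
      draw <- function() {
        unlist(lapply(names(hit_bins), function(b) {
          sample(by_bin[[b]], hit_bins[[b]])
        }), use.names = FALSE)
      }
    }
    null_edges <- vapply(seq_len(n_permutations),
                         function(i) count_internal_edges(graph, draw()),
                         numeric(1))
  })
  data.frame(n_hits = k, observed_edges = observed,
             expected_edges = mean(null_edges),
             null_sd = stats::sd(null_edges),
             p_value = (1 + sum(null_edges >= observed)) /
                       (n_permutations + 1),
             n_permutations = n_permutations, null = null, seed = seed)
}

#' Extract interaction clusters from a hit set
#'
#' Connected components of the graph induced on the hit set, keeping
#' components of at least `min_size` genes ("clusters with more than two
#' proteins"), ordered by decreasing size with ties broken
#' lexicographically by smallest member symbol.
#'
#' @inheritParams edge_enrichment
#' @param min_size Minimum component size retained (default 3).
#' @return List of character vectors (sorted gene symbols per cluster).
#' @export
extract_clusters <- function(graph, hits, min_size = 3) {
  hits <- intersect(unique(as.character(hits)), igraph::V(graph)$name)
  if (!length(hits)) return(list())
  sub <- igraph::induced_subgraph(graph, vids = hits)
  comp <- igraph::components(sub)
  clusters <- split(igraph::V(sub)$name, comp$membership)
  clusters <- lapply(clusters, sort)
  clusters <- clusters[lengths(clusters) >= min_size]
  if (!length(clusters)) return(list())
  first <- vapply(clusters, `[`, character(1), 1)
  ord <- order(-lengths(clusters), first)
  unname(clusters[ord])
}

#' Mean coding length per cluster
#'
#' Arithmetic mean of member coding lengths, in kilobases -- the confound
#' check that a cluster is not driven simply by large, mutation-prone
#' genes. Members without a gene model are excluded with a warning.
#'
#' @param clusters List of gene-symbol vectors (see [extract_clusters()]).
#' @param genome Gene catalogue with `symbol` and `length` columns.
#' @return Numeric vector of per-cluster mean coding lengths (kb).
#' @export
cluster_length_check <- function(clusters, genome) {
  vapply(clusters, function(members) {
    known <- members %in% genome$symbol
    if (!all(known)) {
      warning("no gene model for: ",
              paste(members[!known], collapse = ", "), call. = FALSE)
    }
    if (!any(known)) return(NA_real_)
    mean(genome$length[match(members[known], genome$symbol)]) / 1000
  }, numeric(1))
}
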