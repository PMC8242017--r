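#' Network descriptors
#'
#' Topology statistics used to characterize each disease network: density,
#' global transitivity, degree assortativity, the degree CCDF, and a one-row
#' summary combining them with the modularity of the best Louvain partition.
#' All statistics except modularity are computed on the unweighted skeleton;
#' modularity uses the edge weights, matching common Louvain practice. Both
#' choices are recorded in the summary.
#'
#' @name network_descriptors
NULL

#' Density from node and edge counts
#'
#' `2m / (n (n - 1))`: the number of existing edges relative to the possible
#' number in a simple undirected graph.
#'
#' @param n_nodes node count (>= 2).
#' @param n_edges edge count.
#' @return density in \[0, 1\].
#' @examples
#' density_from_counts(1725, 8208)  # ~0.0055
#' @export
density_from_counts <- function(n_nodes, n_edges) {
  if (!is_scalar_number(n_nodes) || n_nodes < 2) {
    bv_stop("density needs at least 2 nodes", "domain")
  }
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' @rdname network_descriptors
#' @param net a [disease_network()].
#' @return `network_density()`: density in \[0, 1\].
#' @export
network_density <- function(net) {
  density_from_counts(n_nodes(net), n_edges(net))
}

#' @rdname network_descriptors
#' @return `network_transitivity()`: 3 x triangles / connected triads, the
#'   global clustering coefficient; 0 when the graph has no connected triads.
#' @export
network_transitivity <- function(net) {
  t <- igraph::transitivity(net$graph, type = "global")
  if (is.nan(t)) 0 else t
}

#' @rdname network_descriptors
#' @return `degree_assortativity()`: Pearson correlation of endpoint degrees
#'   over edges, in \[-1, 1\]; `NA` when undefined (zero degree variance over
#'   endpoints, e.g. a regular graph).
#' @export
degree_assortativity <- function(net) {
  if (n_edges(net) < 1) return(NA_real_)
  r <- suppressWarnings(igraph::assortativity_degree(net$graph))
  if (is.nan(r)) NA_real_ else r
}

#' Degree complementary cumulative distribution function
#'
#' For each observed degree k, the fraction of nodes with degree >= k (the
#' tail distribution). On a log-log plot a slower fall-off indicates a heavier
#' tail, i.e. stronger hubs.
#'
#' @param net a [disease_network()] with at least one node.
#' @return data frame with ascending `degree` and non-increasing `ccdf`; the
#'   first row always has `ccdf = 1`.
#' @export
degree_ccdf <- function(net) {
  if (n_nodes(net) < 1) bv_stop("network has no nodes", "domain")
  deg <- igraph::degree(net$graph)
  ks <- sort(unique(deg))
  data.frame(degree = ks,
             ccdf = vapply(ks, function(k) mean(deg >= k), numeric(1)))
}

#' Summarize a disease network
#'
#' One row of descriptors: node and edge counts, density, modularity of the
#' best Louvain partition at the given seed, transitivity and assortativity.
#'
#' @param net a [disease_network()] with >= 2 nodes and >= 1 edge.
#' @param seed integer seed for the Louvain pass.
#' @return an object of class `network_summary` (a named list).
#' @export
summarize_network <- function(net, seed = 1L) {
  if (n_nodes(net) < 2) bv_stop("network has fewer than 2 nodes", "domain")
  part <- louvain_best_partition(net, seed = seed)
  structure(list(
    source_id = net$meta$source_id %||% NA_character_,
    n_nodes = n_nodes(net),
    n_edges = n_edges(net),
    density = network_density(net),
    modularity = part$modularity_q,
    transitivity = network_transitivity(net),
    assortativity = degree_assortativity(net),
    seed = seed,
    weighting = "modularity weighted; other statistics unweighted"
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    "<network_summary '%s': n=%d m=%d density=%.4f Q=%.3f T=%.3f r=%s>\n",
    x$source_id, x$n_nodes, x$n_edges, x$density, x$modularity,
    x$transitivity,
    if (is.na(x$assortativity)) "NA" else sprintf("%.3f", x$assortativity)))
  invisible(x)
}

#' Disease-dataset coverage of a network
#'
#' What fraction of the diseases in a text dataset a network's node set
#' covers; used to contrast the broad coverage of phenotypic networks with the
#' concentration of omics reference networks on fewer diseases.
#'
#' @param net a [disease_network()], or directly a character vector of node
#'   ids.
#' @param dataset_ids character vector of all disease ids in the dataset.
#' @return list with `count` (covered diseases) and `pct` (percent of the
#'   dataset).
#' @export
dataset_coverage <- function(net, dataset_ids) {
  nodes <- if (inherits(net, "disease_network")) {
    network_nodes(net)
  } else {
    unique(as.character(net))
  }
  dataset_ids <- unique(as.character(dataset_ids))
  if (length(dataset_ids) == 0L) bv_stop("empty disease dataset", "domain")
  count <- length(intersect(nodes, dataset_ids))
  list(count = count, pct = 100 * count / length(dataset_ids))
}

#' Cross-network normalized transitivity z-scores
#'
#' For a set of networks, each with a null distribution of transitivity from
#' its own G(n, m) randomizations, computes the transitivity z-scores and
#' min-max normalizes them across the set so the most (least) significantly
#' transitive network maps to 1 (0).
#'
#' @param summaries list of [summarize_network()] results (>= 2).
#' @param nulls list of [build_null()] results of the same length, each the
#'   transitivity null of the matching network.
#' @return list with `z` (raw z-scores) and `normalized` (min-max scaled to
#'   \[0, 1\]); names are taken from `summaries`.
#' @export
normalized_transitivity_scores <- function(summaries, nulls) {
  if (length(summaries) < 2L) {
    bv_stop("need at least 2 networks to normalize across", "domain")
  }
  if (length(summaries) != length(nulls)) {
    bv_stop("summaries and nulls must have the same length")
  }
  z <- mapply(function(s, nd) zscore(s$transitivity, nd)$z, summaries, nulls)
  nms <- names(summaries) %||% vapply(summaries, function(s) s$source_id,
                                      character(1))
  names(z) <- nms
  list(z = z, normalized = stats::setNames(minmax_normalize(z), nms))
}
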