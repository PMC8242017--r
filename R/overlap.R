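#' Node and edge overlap between disease networks
#'
#' The first evaluation criterion: how much of the structure of a reference
#' omics network (disease-gene, disease-protein, disease-drug) is recovered by
#' the phenotypic network a bio-NER tool induces. Counts are symmetric;
#' percentages are reported relative to the reference network (the quantity of
#' interest is the fraction of reference structure recovered), with
#' phenotypic-relative percentages also attached for completeness.
#'
#' @param a,ref,phen [disease_network()] objects; `ref` is the reference.
#' @return `node_overlap()` / `edge_overlap()`: list with `count`, `pct`
#'   (percent of reference nodes/edges) and `pct_phen` (percent of `a`'s own
#'   nodes/edges). Weights are ignored; an edge overlaps if the unordered pair
#'   is present in both.
#' @export
node_overlap <- function(a, ref) {
  na <- network_nodes(a)
  nr <- network_nodes(ref)
  shared <- length(intersect(na, nr))
  list(count = shared,
       pct = pct_of(shared, length(nr)),
       pct_phen = pct_of(shared, length(na)))
}

#' @rdname node_overlap
#' @export
edge_overlap <- function(a, ref) {
  ea <- network_edges(a)
  er <- network_edges(ref)
  ka <- pair_keys(ea$disease_a, ea$disease_b)
  kr <- pair_keys(er$disease_a, er$disease_b)
  shared <- length(intersect(ka, kr))
  list(count = shared,
       pct = pct_of(shared, length(kr)),
       pct_phen = pct_of(shared, length(ka)))
}

pct_of <- function(count, total) {
  if (total > 0) 100 * count / total else NA_real_
}

# reference edges expressed as pair indices over a sorted node universe;
# edges with an endpoint outside the universe can never overlap and are
# dropped.
edge_indices_in_universe <- function(net, universe) {
  ed <- network_edges(net)
  i <- match(ed$disease_a, universe)
  j <- match(ed$disease_b, universe)
  keep <- !is.na(i) & !is.na(j)
  i <- i[keep]
  j <- j[keep]
  pair_index(pmin(i, j), pmax(i, j), length(universe))
}

#' Significance of the edge overlap with a reference network
#'
#' Compares the observed shared-edge count with the count expected if the
#' phenotypic network were random: the null redraws the phenotypic network as
#' G(n, m) on its own node set (same node set, same edge count) while the
#' reference is held fixed — the statistic evaluates the NER tool, not the
#' omics data. The null shared-edge counts give a z-score and a Shapiro-Wilk
#' normality p-value.
#'
#' The G(n, m) null is sampled directly in pair-index space, which draws
#' exactly the edge sets [random_gnm()] would produce for the per-replicate
#' seeds, without materializing each graph.
#'
#' @param phen phenotypic [disease_network()] under evaluation.
#' @param ref reference [disease_network()].
#' @param n_reps number of randomizations (>= 2; pipeline default 1000).
#' @param seed master integer seed.
#' @param null_model `"gnm"` (default) or `"degree_preserving"`.
#' @return an object of class `overlap_result`: `phenotypic_id`,
#'   `reference_id`, `shared_nodes`, `pct_nodes`, `shared_edges`, `pct_edges`,
#'   reference-relative, plus `pct_nodes_phen`/`pct_edges_phen`, `z` (a
#'   [zscore()] result on the shared-edge count) and `shapiro_p`.
#' @export
overlap_significance <- function(phen, ref, n_reps = 1000L, seed = 1L,
                                 null_model = c("gnm", "degree_preserving")) {
  null_model <- match.arg(null_model)
  no <- node_overlap(phen, ref)
  eo <- edge_overlap(phen, ref)
  nd <- shared_edge_null(phen, list(ref), n_reps, seed, null_model)
  z <- zscore(eo$count, nd)
  structure(list(
    phenotypic_id = phen$meta$source_id %||% NA_character_,
    reference_id = ref$meta$source_id %||% NA_character_,
    shared_nodes = no$count, pct_nodes = no$pct,
    pct_nodes_phen = no$pct_phen,
    shared_edges = eo$count, pct_edges = eo$pct,
    pct_edges_phen = eo$pct_phen,
    z = z, shapiro_p = nd$shapiro_p,
    n_reps = nd$n_reps, seed = seed, null_model = null_model
  ), class = "overlap_result")
}

shared_edge_null <- function(phen, refs, n_reps, seed, null_model) {
  if (!is_scalar_number(n_reps) || n_reps < 2) {
    bv_stop("n_reps must be at least 2", "domain")
  }
  if (null_model == "degree_preserving") {
    stat <- function(g) {
      keys <- Reduce(intersect, lapply(refs, function(r) {
        er <- network_edges(r)
        pair_keys(er$disease_a, er$disease_b)
      }))
      eg <- network_edges(g)
      length(intersect(pair_keys(eg$disease_a, eg$disease_b), keys))
    }
    return(build_null(stat, phen, n_reps, seed, "shared_edges",
                      "degree_preserving"))
  }
  universe <- network_nodes(phen)
  n <- length(universe)
  m <- n_edges(phen)
  ref_idx <- Reduce(intersect,
                    lapply(refs, edge_indices_in_universe, universe = universe))
  samples <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    idx <- sample_pair_indices(n, m, derive_seed(seed, i))
    samples[i] <- sum(idx %in% ref_idx)
  }
  new_null_distribution("shared_edges", samples, seed, as.integer(n_reps))
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result %s vs %s: nodes %d (%.2f%%), edges %d (%.2f%%), z=%.2f>\n",
    x$phenotypic_id, x$reference_id, x$shared_nodes, x$pct_nodes,
    x$shared_edges, x$pct_edges, x$z$z))
  invisible(x)
}

#' Overlap with all reference networks simultaneously
#'
#' Shared nodes/edges are those present in the phenotypic network and in
#' every reference. Percentages are relative to the intersection of the
#' references (nodes present in all references; edges present in all
#' references). The null randomizes the phenotypic network only, as in
#' [overlap_significance()]. An empty reference intersection yields zero
#' counts, not an error.
#'
#' @param refs list of at least two reference [disease_network()] objects.
#' @inheritParams overlap_significance
#' @return an `overlap_result` with `reference_id` naming all references.
#' @export
simultaneous_overlap <- function(phen, refs, n_reps = 1000L, seed = 1L,
                                 null_model = c("gnm", "degree_preserving")) {
  null_model <- match.arg(null_model)
  if (length(refs) < 2L) bv_stop("need at least 2 reference networks", "domain")
  inter_nodes <- Reduce(intersect, lapply(refs, network_nodes))
  inter_keys <- Reduce(intersect, lapply(refs, function(r) {
    er <- network_edges(r)
    pair_keys(er$disease_a, er$disease_b)
  }))
  phen_nodes <- network_nodes(phen)
  ep <- network_edges(phen)
  phen_keys <- pair_keys(ep$disease_a, ep$disease_b)
  shared_nodes <- length(intersect(phen_nodes, inter_nodes))
  shared_edges <- length(intersect(phen_keys, inter_keys))
  nd <- shared_edge_null(phen, refs, n_reps, seed, null_model)
  z <- zscore(shared_edges, nd)
  structure(list(
    phenotypic_id = phen$meta$source_id %||% NA_character_,
    reference_id = paste(vapply(refs, function(r) {
      as.character(r$meta$source_id %||% "?")
    }, character(1)), collapse = "+"),
    shared_nodes = shared_nodes, pct_nodes = pct_of(shared_nodes, length(inter_nodes)),
    pct_nodes_phen = pct_of(shared_nodes, length(phen_nodes)),
    shared_edges = shared_edges, pct_edges = pct_of(shared_edges, length(inter_keys)),
    pct_edges_phen = pct_of(shared_edges, length(phen_keys)),
    z = z, shapiro_p = nd$shapiro_p,
    n_reps = nd$n_reps, seed = seed, null_model = null_model
  ), class = "overlap_result")
}
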