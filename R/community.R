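#' Louvain partition of a disease network
#'
#' Finds the best modularity partition with the Louvain multilevel algorithm,
#' using edge weights. Louvain's result depends on the order in which nodes
#' are visited; to make "best partition" reproducible, the node order is
#' shuffled by the seed before the pass and the same seed always returns the
#' same partition.
#'
#' @param net a [disease_network()] with at least one edge.
#' @param seed integer seed.
#' @param resolution resolution parameter of the modularity objective
#'   (default 1, the classic Newman-Girvan modularity).
#' @return an object of class `louvain_partition`: `assignment` (named integer
#'   vector, disease -> community id), `modularity_q` (weighted modularity of
#'   the assignment, recomputed from the partition), `seed`, `resolution`.
#' @export
louvain_best_partition <- function(net, seed = 1L, resolution = 1) {
  stopifnot(inherits(net, "disease_network"))
  if (n_edges(net) < 1) bv_stop("cannot partition an edgeless network", "domain")
  g <- net$graph
  cl <- with_seed(seed, {
    perm <- sample(igraph::vcount(g))
    g2 <- igraph::permute(g, perm)
    igraph::cluster_louvain(g2, resolution = resolution)
  })
  memb <- igraph::membership(cl)
  memb <- memb[igraph::V(g)$name]
  q <- partition_modularity(net, memb)
  structure(list(assignment = memb, modularity_q = q, seed = seed,
                 resolution = resolution),
            class = "louvain_partition")
}

#' Modularity of a given partition
#'
#' Weighted modularity Q of an explicit community assignment: the fraction of
#' edge weight inside communities minus the expectation under random placement
#' with the same strengths.
#'
#' @param net a [disease_network()].
#' @param assignment named vector (disease -> community) covering all nodes.
#' @return Q.
#' @export
partition_modularity <- function(net, assignment) {
  nodes <- igraph::V(net$graph)$name
  if (!all(nodes %in% names(assignment))) {
    bv_stop("assignment must cover every network node")
  }
  memb <- as.integer(factor(assignment[nodes]))
  igraph::modularity(net$graph, memb, weights = igraph::E(net$graph)$weight)
}

#' @export
print.louvain_partition <- function(x, ...) {
  cat(sprintf("<louvain_partition: %d nodes, %d communities, Q=%.4f, seed=%d>\n",
              length(x$assignment), length(unique(x$assignment)),
              x$modularity_q, x$seed))
  invisible(x)
}

#' Write a partition as a two-column TSV
#'
#' @param partition a [louvain_best_partition()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(disease_id = names(partition$assignment),
                   community_id = unname(partition$assignment))
  df <- df[order_c(df$disease_id), ]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# modularity_q=%.17g", partition$modularity_q), con)
  writeLines(sprintf("# seed=%d", partition$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Coincidence of network communities with disease categories
#'
#' For each community, the majority category among its members that are mapped
#' in the classification system, and the proportion of mapped members
#' belonging to it. The aggregate ratio is the mapped-size-weighted mean of
#' the per-community proportions (so tiny communities do not dominate;
#' `weighted = FALSE` gives the plain mean). Diseases absent from the category
#' map are excluded from numerator and denominator; communities with no mapped
#' member are excluded and counted in `n_unmapped_communities`. Majority ties
#' are broken lexicographically and flagged.
#'
#' @param partition a [louvain_best_partition()] result.
#' @param cmap a [category_map()].
#' @param weighted aggregate by mapped community size (default) or plain mean.
#' @return an object of class `coincidence_result` (without significance
#'   fields): `system_id`, `n_communities`, `per_community` data frame
#'   (`community_id`, `size`, `n_mapped`, `majority_category`, `proportion`,
#'   `tie`), `ratio`, `n_unmapped_communities`.
#' @export
community_coincidence <- function(partition, cmap, weighted = TRUE) {
  stopifnot(inherits(partition, "louvain_partition"),
            inherits(cmap, "category_map"))
  asg <- partition$assignment
  comm <- as.integer(asg)
  cats <- cmap$assignments[names(asg)]
  comm_ids <- sort(unique(comm))
  fc <- factor(comm, levels = comm_ids)
  size <- as.integer(tabulate(fc, nbins = length(comm_ids)))
  mapped_mask <- !is.na(cats)
  if (!any(mapped_mask)) {
    bv_stop(sprintf("no network disease is mapped in system %s",
                    cmap$system_id), "domain")
  }
  cat_levels <- sort_c(unique(cats[mapped_mask]))
  counts <- table(fc[mapped_mask],
                  factor(cats[mapped_mask], levels = cat_levels))
  n_mapped <- as.integer(rowSums(counts))
  top <- apply(counts, 1, max)
  # cat_levels are sorted, so which.max picks the lexicographically smallest
  # winner on ties
  major_idx <- apply(counts, 1, which.max)
  tie <- apply(counts, 1, function(r) sum(r == max(r)) > 1L) & n_mapped > 0L
  per <- data.frame(
    community_id = comm_ids,
    size = size,
    n_mapped = n_mapped,
    majority_category = ifelse(n_mapped > 0L, cat_levels[major_idx],
                               NA_character_),
    proportion = ifelse(n_mapped > 0L, as.numeric(top) / n_mapped, NA_real_),
    tie = unname(tie)
  )
  mapped <- per[per$n_mapped > 0L, , drop = FALSE]
  if (nrow(mapped) == 0L) {
    bv_stop(sprintf("no network disease is mapped in system %s",
                    cmap$system_id), "domain")
  }
  ratio <- if (weighted) {
    sum(mapped$n_mapped * mapped$proportion) / sum(mapped$n_mapped)
  } else {
    mean(mapped$proportion)
  }
  structure(list(system_id = cmap$system_id,
                 n_communities = length(comm_ids),
                 per_community = per,
                 ratio = ratio,
                 weighted = weighted,
                 n_unmapped_communities = sum(per$n_mapped == 0L)),
            class = "coincidence_result")
}

#' @export
print.coincidence_result <- function(x, ...) {
  cat(sprintf("<coincidence_result system %s: %d communities, ratio=%.3f%s>\n",
              x$system_id, x$n_communities, x$ratio,
              if (!is.null(x$z)) sprintf(", z=%.2f", x$z$z) else ""))
  invisible(x)
}

#' Significance of the community-category coincidence
#'
#' Computes the coincidence ratio of the network's Louvain communities with
#' the given classification system, then compares it with the ratio obtained
#' on randomized G(n, m) versions of the network (Louvain + coincidence run on
#' each replicate). Random networks still attain a nonzero baseline ratio —
#' at least the largest category's frequency — which is exactly what the
#' z-score corrects for.
#'
#' @param net phenotypic [disease_network()].
#' @param cmap a [category_map()].
#' @param n_reps randomizations (>= 2; pipeline default 1000).
#' @param seed master integer seed (also drives the observed Louvain pass).
#' @param resolution Louvain resolution.
#' @param weighted see [community_coincidence()].
#' @param null_model `"gnm"` (default) or `"degree_preserving"`.
#' @return a `coincidence_result` with additional fields `z` (a [zscore()]
#'   result on the ratio), `shapiro_p`, `n_reps`, `seed`, and the observed
#'   `partition`.
#' @export
coincidence_significance <- function(net, cmap, n_reps = 1000L, seed = 1L,
                                     resolution = 1, weighted = TRUE,
                                     null_model = c("gnm", "degree_preserving")) {
  null_model <- match.arg(null_model)
  part <- louvain_best_partition(net, seed = derive_seed(seed, 0), resolution)
  obs <- community_coincidence(part, cmap, weighted)
  stat <- function(g) {
    p <- louvain_best_partition(g, seed = g$meta$build_seed %||% 1L, resolution)
    community_coincidence(p, cmap, weighted)$ratio
  }
  nd <- build_null(stat, net, n_reps, seed, "coincidence_ratio", null_model)
  obs$z <- zscore(obs$ratio, nd)
  obs$shapiro_p <- nd$shapiro_p
  obs$n_reps <- nd$n_reps
  obs$seed <- seed
  obs$null_model <- null_model
  obs$phenotypic_id <- net$meta$source_id %||% NA_character_
  obs$partition <- part
  obs
}

#' Category profile of a partitioned network
#'
#' For the `top_k` largest top-level categories of a classification system:
#' the reference bar (percentage of all mapped diseases in the system that
#' carry the category) and the percentage of mapped network diseases whose
#' community's majority category is that category — the view used to compare
#' a tool's community structure against the classification itself.
#'
#' @param partition a [louvain_best_partition()] result.
#' @param cmap a [category_map()].
#' @param top_k how many of the largest categories to report (default 10).
#' @return data frame `category_id`, `n_reference`, `pct_reference`,
#'   `pct_majority`, ordered by descending reference size.
#' @export
category_profile <- function(partition, cmap, top_k = 10L) {
  cc <- community_coincidence(partition, cmap)
  ref <- category_reference_profile(cmap, top_k)
  top <- ref$category_id
  # mapped network diseases, each credited to its community's majority category
  asg <- partition$assignment
  mapped <- names(asg)[names(asg) %in% names(cmap$assignments)]
  comm_major <- stats::setNames(cc$per_community$majority_category,
                                cc$per_community$community_id)
  major_of_disease <- comm_major[as.character(asg[mapped])]
  n_mapped <- length(mapped)
  data.frame(
    category_id = top,
    n_reference = ref$n,
    pct_reference = ref$pct,
    pct_majority = vapply(top, function(cat) {
      100 * sum(major_of_disease == cat, na.rm = TRUE) / n_mapped
    }, numeric(1)),
    row.names = NULL
  )
}

#' Category sizes of a classification system
#'
#' The reference bars of the category-profile view: how many (and what
#' percentage of) mapped diseases carry each top-level category, largest
#' first.
#'
#' @param cmap a [category_map()].
#' @param top_k how many of the largest categories to report (default all).
#' @return data frame `category_id`, `n`, `pct`, ordered by descending size.
#' @export
category_reference_profile <- function(cmap, top_k = Inf) {
  stopifnot(inherits(cmap, "category_map"))
  tab <- sort(table(cmap$assignments), decreasing = TRUE)
  top <- names(tab)[seq_len(min(top_k, length(tab)))]
  data.frame(category_id = top,
             n = as.integer(tab[top]),
             pct = 100 * as.numeric(tab[top]) / sum(tab),
             row.names = NULL)
}
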