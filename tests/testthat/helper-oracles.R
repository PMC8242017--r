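# Independent brute-force oracles used to cross-check the graph statistics.
# These deliberately avoid igraph: everything is computed from edge lists by
# direct enumeration.

# transitivity = 3 * triangles / connected triads, by enumerating node triples
oracle_transitivity <- function(net) {
  ed <- network_edges(net)
  nodes <- network_nodes(net)
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(ed))) {
    adj[ed$disease_a[r], ed$disease_b[r]] <- TRUE
    adj[ed$disease_b[r], ed$disease_a[r]] <- TRUE
  }
  n <- length(nodes)
  triangles <- 0L
  triads <- 0L
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      e <- adj[i, j] + adj[i, k] + adj[j, k]
      if (e == 3L) triangles <- triangles + 1L
    }
  }
  deg <- rowSums(adj)
  triads <- sum(choose(deg, 2))
  if (triads == 0) 0 else 3 * triangles / triads
}

# shared unordered edges by a double loop over edge lists
oracle_edge_overlap <- function(a, ref) {
  ea <- network_edges(a)
  er <- network_edges(ref)
  count <- 0L
  for (i in seq_len(nrow(ea))) {
    for (j in seq_len(nrow(er))) {
      same <- (ea$disease_a[i] == er$disease_a[j] &&
                 ea$disease_b[i] == er$disease_b[j]) ||
        (ea$disease_a[i] == er$disease_b[j] &&
           ea$disease_b[i] == er$disease_a[j])
      if (same) {
        count <- count + 1L
        break
      }
    }
  }
  count
}

# weighted modularity straight from the definition:
# Q = (1/2W) sum_ij [A_ij - s_i s_j / (2W)] delta(c_i, c_j)
oracle_modularity <- function(net, assignment) {
  ed <- network_edges(net)
  nodes <- network_nodes(net)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(ed))) {
    A[ed$disease_a[r], ed$disease_b[r]] <- ed$weight[r]
    A[ed$disease_b[r], ed$disease_a[r]] <- ed$weight[r]
  }
  s <- rowSums(A)
  W2 <- sum(A)  # = 2W
  comm <- assignment[nodes]
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (comm[i] == comm[j]) q <- q + A[i, j] - s[i] * s[j] / W2
  }
  unname(q / W2)
}

# all set partitions of 1..n as integer assignment vectors (canonical labels)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    k <- max(p)
    for (c in seq_len(k + 1)) out[[length(out) + 1L]] <- c(p, c)
  }
  out
}

# exhaustive best-modularity partition for tiny graphs
oracle_best_partition <- function(net) {
  nodes <- network_nodes(net)
  best_q <- -Inf
  best <- NULL
  for (p in all_partitions(length(nodes))) {
    q <- oracle_modularity(net, stats::setNames(p, nodes))
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- stats::setNames(p, nodes)
    }
  }
  list(assignment = best, q = best_q)
}

# random small disease_network for oracle-equivalence sweeps; guarantees at
# least one edge
random_small_network <- function(n, p = 0.35, seed = 1L, ids = NULL) {
  set.seed(seed)
  ids <- ids %||% sprintf("n%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample(length(keep), 1)] <- TRUE
  disease_network(data.frame(disease_a = pairs[keep, 1],
                             disease_b = pairs[keep, 2],
                             weight = stats::runif(sum(keep), 0.2, 1)),
                  nodes = ids, meta = list(source_id = "toy"))
}

# partition of community assignments into sets of node names, for comparing
# partitions up to relabeling
partition_sets <- function(assignment) {
  unname(lapply(split(names(assignment), assignment), sort))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
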