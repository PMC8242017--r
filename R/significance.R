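#' Randomized null models and z-scores
#'
#' Every evaluation statistic in the pipeline (transitivity, shared-edge
#' overlap, community-category coincidence) is judged against an empirical
#' null: the same statistic computed on randomized networks that keep the
#' original node set and edge count. The default null is the Erdos-Renyi
#' G(n, m) model — m edges placed uniformly at random over all node pairs —
#' with a degree-preserving rewiring alternative available. Null samples are
#' checked for normality with the Shapiro-Wilk test, and observed values are
#' expressed as z-scores against the null.
#'
#' @name null_models
NULL

new_null_distribution <- function(statistic_label, samples, seed, n_reps,
                                  n_failed = 0L) {
  samples <- as.numeric(samples)
  mu <- mean(samples)
  s <- if (length(samples) >= 2) stats::sd(samples) else 0
  sp <- if (length(samples) >= 3 && length(samples) <= 5000 && s > 0) {
    shapiro_wilk_p(samples)
  } else {
    NA_real_
  }
  structure(list(statistic_label = statistic_label, samples = samples,
                 mean = mu, sd = s, shapiro_p = sp, n_reps = n_reps,
                 n_failed = n_failed, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution '%s': %d samples, mean=%.4g sd=%.4g shapiro_p=%s>\n",
    x$statistic_label, length(x$samples), x$mean, x$sd,
    if (is.na(x$shapiro_p)) "NA" else sprintf("%.3g", x$shapiro_p)))
  invisible(x)
}

# uniform sample of m pair indices out of C(n,2); the primitive behind
# random_gnm and the fast overlap-null path, so both draw identical samples
# for the same seed.
sample_pair_indices <- function(n, m, seed) {
  total <- pair_count(n)
  if (m > total) {
    bv_stop(sprintf("m = %d exceeds the %d possible pairs", m, total), "domain")
  }
  with_seed(seed, sample.int(total, m))
}

#' Random G(n, m) network
#'
#' A simple undirected graph on the given node set with exactly `m` edges
#' drawn uniformly without replacement over all node pairs; all edge weights
#' are 1. Deterministic given the seed.
#'
#' @param nodes character vector of node ids.
#' @param m number of edges; at most `choose(length(nodes), 2)`.
#' @param seed integer seed.
#' @return a [disease_network()] with `build_seed` in its metadata.
#' @export
random_gnm <- function(nodes, m, seed) {
  nodes <- sort_c(unique(as.character(nodes)))
  n <- length(nodes)
  if (n < 2 && m > 0) bv_stop("need at least 2 nodes to place an edge", "domain")
  idx <- sample_pair_indices(n, m, seed)
  ij <- pair_decode(idx, n)
  # invariants hold by construction (i < j, sampling without replacement),
  # so the validating constructor is bypassed for speed in null loops
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (m > 0) {
    g <- igraph::add_edges(g, rbind(ij[, "i"], ij[, "j"]))
    g <- igraph::set_edge_attr(g, "weight", value = rep(1, m))
  }
  structure(list(graph = g,
                 meta = list(source_id = "gnm_null", build_seed = seed)),
            class = "disease_network")
}

degree_preserving_null <- function(template, seed) {
  g <- template$graph
  with_seed(seed, {
    g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
  })
  el <- igraph::as_edgelist(g2, names = TRUE)
  disease_network(
    data.frame(disease_a = el[, 1], disease_b = el[, 2],
               weight = rep(1, nrow(el))),
    nodes = igraph::V(g2)$name,
    meta = list(source_id = "degree_preserving_null", build_seed = seed))
}

#' Build an empirical null distribution for a network statistic
#'
#' Evaluates `statistic` on `n_reps` independent randomizations of the
#' template network. Per-replicate seeds are derived from the master seed by a
#' counter scheme, so replicate i always sees the same random graph regardless
#' of evaluation order. Replicates on which the statistic errors are excluded
#' from the samples and counted in `n_failed`.
#'
#' @param statistic function taking a [disease_network()] and returning one
#'   number.
#' @param template the observed network whose node set and edge count the
#'   randomizations preserve.
#' @param n_reps number of randomizations (>= 2); the pipeline default is
#'   1000.
#' @param seed master integer seed.
#' @param statistic_label label stored with the distribution.
#' @param null_model `"gnm"` (default) or `"degree_preserving"` (rewiring
#'   that keeps the degree sequence).
#' @return an object of class `null_distribution` with fields `samples`,
#'   `mean`, `sd` (sample, n-1 denominator), `shapiro_p`, `n_reps`,
#'   `n_failed`, `seed`.
#' @export
build_null <- function(statistic, template, n_reps = 1000L, seed = 1L,
                       statistic_label = "statistic",
                       null_model = c("gnm", "degree_preserving")) {
  null_model <- match.arg(null_model)
  if (!is_scalar_number(n_reps) || n_reps < 2) {
    bv_stop("n_reps must be at least 2", "domain")
  }
  nodes <- network_nodes(template)
  m <- n_edges(template)
  samples <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, i)
    g <- if (null_model == "gnm") {
      random_gnm(nodes, m, rep_seed)
    } else {
      degree_preserving_null(template, rep_seed)
    }
    samples[i] <- tryCatch(statistic(g), error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(samples))
  new_null_distribution(statistic_label, samples[!is.na(samples)], seed,
                        as.integer(n_reps), as.integer(n_failed))
}

#' z-score of an observed statistic against its null
#'
#' `z = (observed - mean(null)) / sd(null)`. A higher magnitude (positive or
#' negative) indicates greater statistical significance. When the null is
#' degenerate (`sd = 0`), the z-score is reported as `Inf`, `-Inf` or 0
#' according to the sign of `observed - mean`.
#'
#' @param observed the statistic on the real network.
#' @param null a `null_distribution`.
#' @return an object of class `zscore_result` with fields `observed`, `z`,
#'   `null`.
#' @export
zscore <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  z <- if (null$sd > 0) {
    (observed - null$mean) / null$sd
  } else {
    sign(observed - null$mean) * Inf
  }
  if (is.nan(z)) z <- 0  # sign() == 0 case: observed equals the constant null
  structure(list(observed = observed, z = z, null = null),
            class = "zscore_result")
}

#' @export
print.zscore_result <- function(x, ...) {
  cat(sprintf("<zscore_result: observed=%.4g z=%.3f vs '%s' null (n=%d)>\n",
              x$observed, x$z, x$null$statistic_label, length(x$null$samples)))
  invisible(x)
}

#' Shapiro-Wilk normality p-value
#'
#' Two-sided Shapiro-Wilk test p-value for a sample of null-statistic values;
#' p > 0.05 is read as consistent with normality. Downstream reports flag
#' z-scores whose null fails this check.
#'
#' @param samples numeric vector, length 3 to 5000.
#' @return p-value in \[0, 1\].
#' @export
shapiro_wilk_p <- function(samples) {
  if (length(samples) < 3 || length(samples) > 5000) {
    bv_stop("Shapiro-Wilk requires between 3 and 5000 samples", "domain")
  }
  stats::shapiro.test(samples)$p.value
}

#' Min-max normalization to \[0, 1\]
#'
#' `(x - min) / (max - min)`, used to put z-scores from different tests on a
#' comparable scale. A degenerate all-equal vector is mapped to 0.5 everywhere
#' with a warning, so a constant column neither rewards nor penalizes any
#' tool.
#'
#' @param values non-empty numeric vector.
#' @return numeric vector in \[0, 1\], same order.
#' @examples
#' minmax_normalize(c(2, 4, 6))  # 0, 0.5, 1
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0L) bv_stop("cannot normalize an empty vector", "domain")
  rng <- range(values)
  if (!all(is.finite(rng))) {
    # map infinite z (degenerate nulls) to the extremes before scaling
    finite <- values[is.finite(values)]
    hi <- if (length(finite)) max(abs(finite)) + 1 else 1
    values[values == Inf] <- hi
    values[values == -Inf] <- -hi
    rng <- range(values)
  }
  if (rng[1] == rng[2]) {
    warning("all values equal; min-max normalization returns 0.5 for each")
    return(rep(0.5, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}
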