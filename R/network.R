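#' Disease-disease similarity networks
#'
#' A `disease_network` is a weighted, undirected, simple graph whose nodes are
#' diseases and whose edge weights are entity-profile similarities in (0, 1].
#' Networks carry provenance metadata: the source label, the percentile filter
#' applied (if any, plus the realized cutoff) and the build seed for random
#' graphs.
#'
#' @param edges data frame with columns `disease_a`, `disease_b`, `weight`.
#'   Pairs are stored canonically (`disease_a < disease_b`); self-loops and
#'   weights outside (0, 1] are rejected.
#' @param nodes optional character vector of node ids; defaults to the edge
#'   endpoints. Extra ids give isolated nodes (used by random null graphs,
#'   which must keep the full node set).
#' @param meta named list of scalar metadata (`source_id`,
#'   `threshold_percentile`, `cutoff`, `build_seed`, ...).
#' @return an object of class `disease_network`.
#' @export
disease_network <- function(edges, nodes = NULL, meta = list()) {
  if (!is.data.frame(edges)) bv_stop("edges must be a data frame")
  need <- c("disease_a", "disease_b", "weight")
  miss <- setdiff(need, names(edges))
  if (length(miss)) {
    bv_stop(sprintf("edges is missing column(s): %s",
                    paste(miss, collapse = ", ")), "format")
  }
  a <- as.character(edges$disease_a)
  b <- as.character(edges$disease_b)
  w <- as.numeric(edges$weight)
  if (any(!nzchar(a)) || any(!nzchar(b))) bv_stop("node ids must be non-empty")
  if (any(a == b)) bv_stop("self-loops are not allowed")
  if (any(!is.finite(w)) || any(w <= 0) || any(w > 1)) {
    bv_stop("edge weights must lie in (0, 1]")
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keys <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(keys)) bv_stop("duplicate edges")
  nodes <- sort_c(unique(c(lo, hi, as.character(nodes %||% character(0)))))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (length(lo)) {
    ord <- order_c(lo, hi)
    g <- igraph::add_edges(g, rbind(match(lo[ord], nodes),
                                    match(hi[ord], nodes)))
    g <- igraph::set_edge_attr(g, "weight", value = w[ord])
  }
  structure(list(graph = g, meta = meta), class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("<disease_network '%s': %d nodes, %d edges%s>\n",
              x$meta$source_id %||% "?", n_nodes(x), n_edges(x),
              if (!is.null(x$meta$threshold_percentile)) {
                sprintf(", q=%g filter", x$meta$threshold_percentile)
              } else ""))
  invisible(x)
}

#' Network accessors
#'
#' @param net a [disease_network()].
#' @return `network_nodes()`: sorted character vector of node ids;
#'   `network_edges()`: data frame `disease_a`, `disease_b`, `weight` with
#'   `disease_a < disease_b`; `n_nodes()`/`n_edges()`: counts.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  sort_c(igraph::V(net$graph)$name)
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  w <- igraph::E(net$graph)$weight
  if (nrow(el) == 0L) {
    return(data.frame(disease_a = character(0), disease_b = character(0),
                      weight = numeric(0)))
  }
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  ord <- order_c(a, b)
  data.frame(disease_a = a[ord], disease_b = b[ord], weight = w[ord])
}

#' @rdname network_nodes
#' @export
n_nodes <- function(net) igraph::vcount(net$graph)

#' @rdname network_nodes
#' @export
n_edges <- function(net) igraph::ecount(net$graph)

#' Jaccard similarity of two entity sets
#'
#' `|A intersect B| / |A union B|`, i.e. one minus the Jaccard distance.
#' This is the similarity that weights every edge in the disease networks.
#'
#' @param a,b non-empty character vectors (treated as sets).
#' @return similarity in \[0, 1\].
#' @examples
#' jaccard_similarity(c("t1", "t2", "t3"), c("t2", "t3", "t4"))  # 0.5
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    bv_stop("jaccard_similarity requires non-empty sets", "domain")
  }
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' All nonzero pairwise disease similarities
#'
#' Computes the Jaccard similarity of the entity profiles of every disease
#' pair that shares at least one entity. Implemented as a sparse
#' incidence-matrix cross-product, so only co-occurring pairs are ever
#' materialized.
#'
#' @param table an [association_table()].
#' @return data frame `disease_a`, `disease_b`, `similarity` with
#'   `disease_a < disease_b` and `similarity > 0`, ordered canonically.
#' @export
pairwise_similarities <- function(table) {
  stopifnot(inherits(table, "association_table"))
  rec <- table$records
  empty <- data.frame(disease_a = character(0), disease_b = character(0),
                      similarity = numeric(0))
  if (nrow(rec) == 0L) return(empty)
  dl <- sort_c(unique(rec$disease_id))
  el <- sort_c(unique(rec$entity_id))
  if (length(dl) < 2L) return(empty)
  m <- Matrix::sparseMatrix(i = match(rec$disease_id, dl),
                            j = match(rec$entity_id, el),
                            x = 1, dims = c(length(dl), length(el)))
  sizes <- Matrix::rowSums(m)
  inter <- methods::as(methods::as(Matrix::tcrossprod(m), "generalMatrix"),
                       "TsparseMatrix")
  keep <- inter@i < inter@j & inter@x > 0
  i <- inter@i[keep] + 1L
  j <- inter@j[keep] + 1L
  x <- inter@x[keep]
  sim <- x / (sizes[i] + sizes[j] - x)
  ord <- order(i, j)
  data.frame(disease_a = dl[i][ord], disease_b = dl[j][ord],
             similarity = sim[ord])
}

#' Percentile cutoff with linear interpolation
#'
#' The q-th percentile of a set of values under the linear-interpolation
#' convention between order statistics (`stats::quantile` type 7). This is the
#' convention used by the network edge filter and is recorded in network
#' metadata.
#'
#' @param values non-empty numeric vector.
#' @param q percent in \[0, 100\].
#' @return the cutoff value.
#' @examples
#' percentile_cutoff(c(0.1, 0.2, 0.3, 0.4), 50)  # 0.25
#' @export
percentile_cutoff <- function(values, q) {
  if (length(values) == 0L) bv_stop("cannot take a percentile of no values", "domain")
  if (!is_scalar_number(q) || q < 0 || q > 100) {
    bv_stop("q must be a percent in [0, 100]", "domain")
  }
  unname(stats::quantile(values, q / 100, type = 7, names = FALSE))
}

#' Build a disease-disease similarity network
#'
#' Connects every disease pair sharing at least one entity with an edge
#' weighted by the Jaccard similarity of their entity profiles. When
#' `threshold_percentile` is set (phenotypic networks from text-extracted
#' terms; the reference omics networks are left unfiltered), only pairs whose
#' similarity is strictly above that percentile of all nonzero similarities
#' are kept — the filter that keeps text-derived networks to a workable size.
#' Diseases left without any retained edge are dropped.
#'
#' @param table an [association_table()].
#' @param threshold_percentile percent in \[0, 100\] or `NULL` (no filter).
#' @return a [disease_network()] with `source_id`, `threshold_percentile` and
#'   the realized `cutoff` in its metadata.
#' @export
build_network <- function(table, threshold_percentile = NULL) {
  sims <- pairwise_similarities(table)
  cutoff <- NULL
  if (!is.null(threshold_percentile) && nrow(sims)) {
    cutoff <- percentile_cutoff(sims$similarity, threshold_percentile)
    sims <- sims[sims$similarity > cutoff, , drop = FALSE]
  }
  disease_network(
    data.frame(disease_a = sims$disease_a, disease_b = sims$disease_b,
               weight = sims$similarity),
    meta = list(source_id = table$source_id,
                threshold_percentile = threshold_percentile,
                cutoff = cutoff,
                percentile_convention = "linear_interpolation_type7")
  )
}

# --- edge-list serialization --------------------------------------------------

serialize_meta_value <- function(v) {
  if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
}

parse_meta_value <- function(s) {
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num) && grepl("^[-+0-9.eE]+$", s)) num else s
}

#' Read and write disease networks
#'
#' The native format is a weighted edge-list TSV (`disease_a`, `disease_b`,
#' `weight`) preceded by `# key=value` metadata lines; weights are written
#' with 17 significant digits so round trips are bit-stable. Isolated nodes
#' are preserved through a `# isolated=` header line. Files ending in
#' `.graphml` are read/written as GraphML instead, with metadata stored as
#' graph attributes. Reading validates the network invariants: weights must
#' lie in (0, 1] and self-loops are rejected.
#'
#' @param path file path; `.graphml` selects the GraphML dialect.
#' @param net a [disease_network()] (for `write_network`).
#' @return `read_network`: a [disease_network()]; `write_network`: `path`,
#'   invisibly.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) bv_stop(sprintf("file not found: %s", path), "io")
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    meta <- lapply(igraph::graph_attr(g), identity)
    el <- igraph::as_edgelist(g, names = TRUE)
    w <- igraph::E(g)$weight %||% rep(1, nrow(el))
    edges <- data.frame(disease_a = el[, 1], disease_b = el[, 2], weight = w)
    return(disease_network(edges, nodes = igraph::V(g)$name, meta = meta))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- grepl("^#", lines)
  meta <- list()
  isolated <- character(0)
  for (l in lines[hdr]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    if (key == "isolated") {
      if (nzchar(val)) isolated <- strsplit(val, ",", fixed = TRUE)[[1]]
    } else {
      meta[[key]] <- parse_meta_value(val)
    }
  }
  body <- lines[!hdr]
  body <- body[nzchar(body)]
  if (length(body) == 0L) bv_stop(sprintf("no edge rows in: %s", path), "empty_input")
  con <- textConnection(body)
  on.exit(close(con), add = TRUE)
  df <- utils::read.delim(con, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"),
                          quote = "", check.names = FALSE)
  names(df) <- c("disease_a", "disease_b", "weight")
  disease_network(df, nodes = isolated, meta = meta)
}

#' @rdname read_network
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "disease_network"))
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- net$graph
    for (k in names(net$meta)) {
      v <- net$meta[[k]]
      if (!is.null(v) && length(v) == 1L) {
        g <- igraph::set_graph_attr(g, k, v)
      }
    }
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  edges <- network_edges(net)
  deg <- igraph::degree(net$graph)
  isolated <- sort_c(names(deg)[deg == 0])
  hdr <- character(0)
  for (k in names(net$meta)) {
    v <- net$meta[[k]]
    if (!is.null(v) && length(v) == 1L && !is.na(v)) {
      hdr <- c(hdr, sprintf("# %s=%s", k, serialize_meta_value(v)))
    }
  }
  if (length(isolated)) {
    hdr <- c(hdr, sprintf("# isolated=%s", paste(isolated, collapse = ",")))
  }
  body <- c("disease_a\tdisease_b\tweight",
            sprintf("%s\t%s\t%s", edges$disease_a, edges$disease_b,
                    sprintf("%.17g", edges$weight)))
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}
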