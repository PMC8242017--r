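#' Composite evaluation and ranking of bio-NER tools
#'
#' Combines the two significance tests into one score per tool. For every
#' reference network column (overlap z-scores) and every classification-system
#' column (coincidence z-scores), z-scores are min-max normalized across
#' tools; each tool then gets the mean of its normalized overlap columns and
#' the mean of its normalized coincidence columns, and the composite is the
#' equal-weight mean of the two. Tools are ranked by descending composite;
#' ties share the minimum rank.
#'
#' @param overlaps either a list of [overlap_significance()] results or a data
#'   frame with columns `tool_id`, `reference_id`, `z`.
#' @param coincidences either a list of [coincidence_significance()] results
#'   or a data frame with columns `tool_id`, `system_id`, `z`.
#' @param weights length-2 numeric weights for (overlap, coincidence); default
#'   equal.
#' @return a data frame of class `tool_evaluation`, one row per tool, ordered
#'   by rank, with columns `tool_id`, `norm_overlap_mean`,
#'   `norm_coincidence_mean`, `composite`, `rank`; the per-column raw and
#'   normalized z matrices are attached as attributes `z_overlap`,
#'   `z_coincidence`, `norm_overlap`, `norm_coincidence`.
#' @export
aggregate_evaluations <- function(overlaps, coincidences,
                                  weights = c(0.5, 0.5)) {
  ov <- as_z_table(overlaps, "reference_id")
  co <- as_z_table(coincidences, "system_id")
  if (nrow(ov) == 0L || nrow(co) == 0L) {
    bv_stop("every tool needs at least one overlap and one coincidence z-score",
            "domain")
  }
  tools <- sort_c(unique(c(ov$tool_id, co$tool_id)))
  z_ov <- z_matrix(ov, tools, "reference_id")
  z_co <- z_matrix(co, tools, "system_id")
  n_ov <- apply_minmax_columns(z_ov)
  n_co <- apply_minmax_columns(z_co)
  w <- weights / sum(weights)
  norm_overlap_mean <- rowMeans(n_ov)
  norm_coincidence_mean <- rowMeans(n_co)
  composite <- w[1] * norm_overlap_mean + w[2] * norm_coincidence_mean
  rk <- rank(-composite, ties.method = "min")
  out <- data.frame(tool_id = tools,
                    norm_overlap_mean = norm_overlap_mean,
                    norm_coincidence_mean = norm_coincidence_mean,
                    composite = composite,
                    rank = as.integer(rk),
                    row.names = NULL)
  out <- out[order(out$rank, out$tool_id), ]
  rownames(out) <- NULL
  attr(out, "z_overlap") <- z_ov
  attr(out, "z_coincidence") <- z_co
  attr(out, "norm_overlap") <- n_ov
  attr(out, "norm_coincidence") <- n_co
  attr(out, "weights") <- w
  class(out) <- c("tool_evaluation", "data.frame")
  out
}

as_z_table <- function(x, col) {
  if (is.data.frame(x)) {
    need <- c("tool_id", col, "z")
    miss <- setdiff(need, names(x))
    if (length(miss)) {
      bv_stop(sprintf("z table is missing column(s): %s",
                      paste(miss, collapse = ", ")), "format")
    }
    return(x[, need])
  }
  rows <- lapply(x, function(r) {
    if (inherits(r, "overlap_result")) {
      data.frame(tool_id = r$phenotypic_id, reference_id = r$reference_id,
                 z = r$z$z)
    } else if (inherits(r, "coincidence_result")) {
      data.frame(tool_id = r$phenotypic_id, system_id = r$system_id,
                 z = r$z$z)
    } else {
      bv_stop("unrecognized result object in aggregate_evaluations", "format")
    }
  })
  df <- do.call(rbind, rows)
  df[, c("tool_id", col, "z")]
}

z_matrix <- function(df, tools, col) {
  cols <- sort_c(unique(df[[col]]))
  m <- matrix(NA_real_, nrow = length(tools), ncol = length(cols),
              dimnames = list(tools, cols))
  m[cbind(match(df$tool_id, tools), match(df[[col]], cols))] <- df$z
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    bv_stop(sprintf("missing z-score for tool '%s' in column '%s'",
                    tools[miss[1, 1]], cols[miss[1, 2]]), "domain")
  }
  m
}

apply_minmax_columns <- function(m) {
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- minmax_normalize(m[, j])
  out
}

#' @export
print.tool_evaluation <- function(x, ...) {
  cat("<tool_evaluation>\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write the evaluation report
#'
#' Writes three files under `dir`: `evaluation.tsv` (the ranked tool table),
#' `evaluation.json` (the table plus all intermediate raw and normalized
#' z-score matrices, weights and any run metadata), and `scatter.csv`
#' (per-tool `x = norm_overlap_mean`, `y = norm_coincidence_mean` for a
#' two-test scatter plot).
#'
#' @param evals a [aggregate_evaluations()] result.
#' @param dir output directory (created if needed).
#' @param run_meta optional named list recorded verbatim in the JSON report
#'   (seeds, n_reps, configuration decisions).
#' @return named character vector of the written paths, invisibly.
#' @export
render_report <- function(evals, dir, run_meta = list()) {
  stopifnot(inherits(evals, "tool_evaluation"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) bv_stop(sprintf("cannot create output directory: %s", dir), "io")
  }
  tsv <- file.path(dir, "evaluation.tsv")
  jsn <- file.path(dir, "evaluation.json")
  csv <- file.path(dir, "scatter.csv")
  utils::write.table(as.data.frame(evals), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  payload <- list(
    evaluation = as.data.frame(evals),
    z_overlap = matrix_to_list(attr(evals, "z_overlap")),
    z_coincidence = matrix_to_list(attr(evals, "z_coincidence")),
    norm_overlap = matrix_to_list(attr(evals, "norm_overlap")),
    norm_coincidence = matrix_to_list(attr(evals, "norm_coincidence")),
    weights = attr(evals, "weights"),
    run_meta = run_meta
  )
  jsonlite::write_json(payload, jsn, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  scatter <- data.frame(tool_id = evals$tool_id,
                        x = evals$norm_overlap_mean,
                        y = evals$norm_coincidence_mean)
  utils::write.table(scatter, csv, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(tsv = tsv, json = jsn, scatter = csv))
}

matrix_to_list <- function(m) {
  if (is.null(m)) return(NULL)
  out <- lapply(seq_len(nrow(m)), function(r) {
    as.list(stats::setNames(as.numeric(m[r, ]), colnames(m)))
  })
  names(out) <- rownames(m)
  out
}
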