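#' Disease-entity association tables
#'
#' An association table holds the bipartite disease -> entity records produced
#' by one source: either a bio-NER tool run over disease-linked texts (entities
#' are clinical terms) or an omics database (entities are genes, proteins or
#' drugs). It is the common input to all network construction.
#'
#' @param source_id short label for the producing tool or omics source.
#' @param records data frame with columns `disease_id`, `entity_id` and
#'   optionally `entity_type` (one of `"term"`, `"gene"`, `"protein"`,
#'   `"drug"`, `"other"`; defaults to `"term"`). Duplicate
#'   (disease, entity) rows are collapsed.
#' @return an object of class `association_table` with elements `source_id`
#'   and `records`.
#' @examples
#' tab <- association_table("toy", data.frame(
#'   disease_id = c("d1", "d1", "d2"),
#'   entity_id  = c("t1", "t2", "t2")
#' ))
#' nrow(tab$records)
#' @export
association_table <- function(source_id, records) {
  if (!is_scalar_string(source_id)) {
    bv_stop("source_id must be a non-empty string")
  }
  if (!is.data.frame(records)) bv_stop("records must be a data frame")
  need <- c("disease_id", "entity_id")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    bv_stop(sprintf("records is missing column(s): %s",
                    paste(miss, collapse = ", ")), "format")
  }
  if (!"entity_type" %in% names(records)) {
    records$entity_type <- if (nrow(records)) "term" else character(0)
  }
  records <- records[, c("disease_id", "entity_id", "entity_type")]
  records$disease_id <- as.character(records$disease_id)
  records$entity_id <- as.character(records$entity_id)
  records$entity_type <- as.character(records$entity_type)
  if (nrow(records)) {
    if (any(is.na(records$disease_id) | !nzchar(records$disease_id))) {
      bv_stop("disease_id values must be non-empty")
    }
    if (any(is.na(records$entity_id) | !nzchar(records$entity_id))) {
      bv_stop("entity_id values must be non-empty")
    }
    bad <- setdiff(unique(records$entity_type), entity_types())
    if (length(bad)) {
      bv_stop(sprintf("unknown entity_type(s): %s",
                      paste(bad, collapse = ", ")))
    }
    records <- records[!duplicated(records[, c("disease_id", "entity_id")]), ,
                       drop = FALSE]
    records <- records[order_c(records$disease_id, records$entity_id), ,
                       drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(source_id = source_id, records = records),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table '%s': %d records, %d diseases, %d entities>\n",
              x$source_id, nrow(x$records),
              length(unique(x$records$disease_id)),
              length(unique(x$records$entity_id))))
  invisible(x)
}

entity_types <- function() c("term", "gene", "protein", "drug", "other")

#' Entity sets of an association table
#'
#' @param table an [association_table()].
#' @return named list mapping each disease_id to its character vector of
#'   entity ids.
#' @export
entity_sets <- function(table) {
  stopifnot(inherits(table, "association_table"))
  split(table$records$entity_id, table$records$disease_id)
}

# split a delimited header line; tab preferred, comma fallback
detect_delim <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

read_delimited <- function(path, required, optional = character(0)) {
  if (!file.exists(path)) bv_stop(sprintf("file not found: %s", path), "io")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) bv_stop(sprintf("empty input file: %s", path), "empty_input")
  delim <- detect_delim(first)
  df <- utils::read.delim(path, sep = delim, header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "", check.names = FALSE,
                          fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    bv_stop(sprintf("%s is missing required column(s): %s", path,
                    paste(miss, collapse = ", ")), "format")
  }
  if (nrow(df) == 0L) bv_stop(sprintf("no data rows in: %s", path), "empty_input")
  df[, c(required, intersect(optional, names(df))), drop = FALSE]
}

#' Read a disease-entity association table
#'
#' Reads a tab- or comma-delimited file with header columns `disease_id`,
#' `entity_id` and optionally `entity_type`. The delimiter is auto-detected
#' from the header line (tab preferred). Duplicate rows are collapsed.
#'
#' @param path path to the delimited file.
#' @param source_id label for the source (tool or omics database).
#' @return an [association_table()].
#' @export
read_association_table <- function(path, source_id) {
  df <- read_delimited(path, c("disease_id", "entity_id"), "entity_type")
  association_table(source_id, df)
}

#' Write a disease-entity association table
#'
#' Writes the table as UTF-8 TSV with header `disease_id`, `entity_id`,
#' `entity_type`; [read_association_table()] round-trips it exactly.
#'
#' @param table an [association_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path) {
  stopifnot(inherits(table, "association_table"))
  utils::write.table(table$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Identifier cross-maps
#'
#' A flat source-identifier -> canonical-identifier map, read from a delimited
#' file with columns `source_id`, `canonical_id`. Cross-maps are plain input
#' files: the package never queries a terminology service, so runs are
#' reproducible offline.
#'
#' @param pairs named character vector: names are source ids, values canonical
#'   ids.
#' @return an object of class `id_mapping`.
#' @export
id_mapping <- function(pairs) {
  if (length(pairs) && (is.null(names(pairs)) || any(!nzchar(names(pairs))))) {
    bv_stop("id mapping must have non-empty source ids as names")
  }
  pairs <- vapply(pairs, as.character, character(1))
  if (any(!nzchar(pairs))) bv_stop("canonical ids must be non-empty")
  if (anyDuplicated(names(pairs))) {
    bv_stop("duplicate source ids in mapping")
  }
  structure(list(pairs = pairs), class = "id_mapping")
}

#' @rdname id_mapping
#' @param path path to a delimited file with columns `source_id`,
#'   `canonical_id`.
#' @export
read_id_mapping <- function(path) {
  df <- read_delimited(path, c("source_id", "canonical_id"))
  id_mapping(stats::setNames(df$canonical_id, df$source_id))
}

#' Canonicalize disease identifiers in an association table
#'
#' Replaces disease ids by their canonical ids. Diseases that map to the same
#' canonical id have their entity sets unioned; records for unmapped diseases
#' are either dropped or kept verbatim.
#'
#' @param table an [association_table()].
#' @param mapping an [id_mapping()]; must be non-empty.
#' @param drop_unmapped if `TRUE` (default), records whose disease id is not
#'   in the mapping are dropped; if `FALSE` they are kept unchanged.
#' @return a new [association_table()].
#' @export
apply_id_mapping <- function(table, mapping, drop_unmapped = TRUE) {
  stopifnot(inherits(table, "association_table"),
            inherits(mapping, "id_mapping"))
  if (length(mapping$pairs) == 0L && !drop_unmapped) {
    return(table)
  }
  rec <- table$records
  hit <- match(rec$disease_id, names(mapping$pairs))
  mapped <- !is.na(hit)
  rec$disease_id[mapped] <- unname(mapping$pairs[hit[mapped]])
  if (drop_unmapped) rec <- rec[mapped, , drop = FALSE]
  association_table(table$source_id, rec)
}

#' Disease -> top-level category maps
#'
#' One `category_map` holds, for a single classification system (e.g. MeSH,
#' DO, ICD-10-CM), the assignment of each disease to exactly one top-level
#' category. Diseases carrying conflicting categories within one system are a
#' hard input error: resolving multi-category diseases is upstream curation,
#' not something the reader should guess at.
#'
#' @param system_id classification-system label.
#' @param assignments named character vector: names are disease ids, values
#'   category ids.
#' @return an object of class `category_map`.
#' @export
category_map <- function(system_id, assignments) {
  if (!is_scalar_string(system_id)) bv_stop("system_id must be a non-empty string")
  if (length(assignments) == 0L) bv_stop("category map is empty")
  if (is.null(names(assignments)) || any(!nzchar(names(assignments)))) {
    bv_stop("assignments must be named by disease id")
  }
  assignments <- vapply(assignments, as.character, character(1))
  if (any(!nzchar(assignments))) bv_stop("category ids must be non-empty")
  if (anyDuplicated(names(assignments))) {
    bv_stop(sprintf("duplicate disease assignment(s) in system %s", system_id))
  }
  structure(list(system_id = system_id,
                 assignments = assignments[order_c(names(assignments))]),
            class = "category_map")
}

#' Read disease-category maps
#'
#' Reads a delimited file with columns `disease_id`, `system_id`,
#' `category_id` and returns one [category_map()] per classification system.
#' A disease listed twice in the same system with different categories raises
#' a validation error naming the disease.
#'
#' @param path path to the delimited file.
#' @return named list of [category_map()] objects (names are system ids).
#' @export
read_category_map <- function(path) {
  df <- read_delimited(path, c("disease_id", "system_id", "category_id"))
  out <- lapply(split(df, df$system_id), function(d) {
    d <- d[!duplicated(d[, c("disease_id", "category_id")]), , drop = FALSE]
    dup <- unique(d$disease_id[duplicated(d$disease_id)])
    if (length(dup)) {
      bv_stop(sprintf(
        "conflicting category assignment(s) in system %s for disease(s): %s",
        d$system_id[1], paste(sort_c(dup), collapse = ", ")))
    }
    category_map(d$system_id[1], stats::setNames(d$category_id, d$disease_id))
  })
  out[order_c(names(out))]
}

#' Write disease-category maps
#'
#' @param maps a list of [category_map()] objects (or a single one).
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_category_map <- function(maps, path) {
  if (inherits(maps, "category_map")) maps <- list(maps)
  rows <- do.call(rbind, lapply(maps, function(m) {
    data.frame(disease_id = names(m$assignments),
               system_id = m$system_id,
               category_id = unname(m$assignments),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
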