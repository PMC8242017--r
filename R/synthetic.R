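#' Synthetic-world generator parameters
#'
#' The generator emulates the structure the evaluation framework relies on: a
#' set of diseases partitioned into top-level categories, where diseases of
#' the same category share clinical terms (and genes, proteins, drugs) far
#' more often than diseases of different categories. Each disease draws its
#' entities either from a category-specific pool (with probability `p_within`)
#' or from a global pool shared by all categories, so both phenotypic and
#' omics similarities carry the same planted block structure.
#'
#' Defaults are sized for desk-scale runs that still produce stable Louvain
#' structure: 600 diseases in 10 categories, 25 terms per disease drawn from
#' category pools of 150 against a global pool of 3000 with `p_within = 0.8`;
#' omics profiles are smaller (10 entities per disease) and more specific
#' (`omics_p_within = 0.9`), and reference tables cover a 0.4 fraction of
#' diseases, mirroring the concentration of curated omics data on a limited
#' disease subset.
#'
#' @param n_diseases number of diseases.
#' @param n_categories number of planted categories.
#' @param terms_per_disease term draws per disease (per-disease profile size
#'   before deduplication).
#' @param category_pool_size size of each category's private term pool.
#' @param global_pool_size size of the shared term pool.
#' @param p_within probability each term draw uses the category pool.
#' @param omics_per_disease entity draws per disease for each omics type.
#' @param omics_category_pool_size per-category omics pool size.
#' @param omics_global_pool_size shared omics pool size.
#' @param omics_p_within category-pool probability for omics draws.
#' @param reference_fraction fraction of diseases covered by each reference
#'   table.
#' @param seed integer seed; the world is reproducible from (params, seed).
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_diseases = 600L, n_categories = 10L,
                             terms_per_disease = 25L,
                             category_pool_size = 150L,
                             global_pool_size = 3000L,
                             p_within = 0.8,
                             omics_per_disease = 10L,
                             omics_category_pool_size = 60L,
                             omics_global_pool_size = 1200L,
                             omics_p_within = 0.9,
                             reference_fraction = 0.4,
                             seed = 1L) {
  p <- list(n_diseases = as.integer(n_diseases),
            n_categories = as.integer(n_categories),
            terms_per_disease = as.integer(terms_per_disease),
            category_pool_size = as.integer(category_pool_size),
            global_pool_size = as.integer(global_pool_size),
            p_within = p_within,
            omics_per_disease = as.integer(omics_per_disease),
            omics_category_pool_size = as.integer(omics_category_pool_size),
            omics_global_pool_size = as.integer(omics_global_pool_size),
            omics_p_within = omics_p_within,
            reference_fraction = reference_fraction,
            seed = as.integer(seed))
  for (k in c("p_within", "omics_p_within")) {
    if (!is_scalar_number(p[[k]]) || p[[k]] < 0 || p[[k]] > 1) {
      bv_stop(sprintf("%s must be a probability in [0, 1]", k), "domain")
    }
  }
  if (!is_scalar_number(p$reference_fraction) ||
      p$reference_fraction <= 0 || p$reference_fraction > 1) {
    bv_stop("reference_fraction must be in (0, 1]", "domain")
  }
  if (p$n_categories < 1 || p$n_diseases < p$n_categories) {
    bv_stop("need n_diseases >= n_categories >= 1", "domain")
  }
  if (p$terms_per_disease < 1 || p$omics_per_disease < 1) {
    bv_stop("per-disease entity counts must be positive", "domain")
  }
  if (p$category_pool_size < p$terms_per_disease ||
      p$global_pool_size < p$terms_per_disease) {
    bv_stop("term pools must be at least terms_per_disease", "domain")
  }
  if (p$omics_category_pool_size < p$omics_per_disease ||
      p$omics_global_pool_size < p$omics_per_disease) {
    bv_stop("omics pools must be at least omics_per_disease", "domain")
  }
  structure(p, class = "generator_params")
}

draw_profiles <- function(categories, per_disease, cat_pools, global_pool,
                          p_within) {
  lapply(seq_along(categories), function(d) {
    k <- categories[d]
    n_within <- stats::rbinom(1L, per_disease, p_within)
    unique(c(
      if (n_within > 0) sample(cat_pools[[k]], n_within),
      if (per_disease - n_within > 0) sample(global_pool,
                                             per_disease - n_within)
    ))
  })
}

make_pools <- function(prefix, n_categories, pool_size, global_size) {
  list(
    cat = lapply(seq_len(n_categories), function(k) {
      sprintf("%s.c%02d.%04d", prefix, k, seq_len(pool_size))
    }),
    global = sprintf("%s.g.%05d", prefix, seq_len(global_size))
  )
}

#' Generate a synthetic disease world
#'
#' Produces the ground truth that simulated NER tools and reference tables
#' are derived from: diseases with planted categories, true term profiles,
#' and true gene/protein/drug profiles sharing the same block structure.
#' Category pools are disjoint, so with `p_within = 1` diseases of different
#' categories have exactly zero term similarity.
#'
#' @param params a [generator_params()].
#' @return an object of class `synthetic_world`: `diseases` (data frame
#'   `disease_id`, `category_id`), `true_terms`, `true_genes`,
#'   `true_proteins`, `true_drugs` (named lists disease -> entity set),
#'   `term_global_pool`, and `params`.
#' @export
generate_world <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_diseases
  k <- params$n_categories
  ids <- sprintf("d%04d", seq_len(n))
  with_seed(params$seed, {
    categories <- sample(rep_len(seq_len(k), n))
    term_pools <- make_pools("t", k, params$category_pool_size,
                             params$global_pool_size)
    gene_pools <- make_pools("gn", k, params$omics_category_pool_size,
                             params$omics_global_pool_size)
    prot_pools <- make_pools("pr", k, params$omics_category_pool_size,
                             params$omics_global_pool_size)
    drug_pools <- make_pools("dr", k, params$omics_category_pool_size,
                             params$omics_global_pool_size)
    true_terms <- draw_profiles(categories, params$terms_per_disease,
                                term_pools$cat, term_pools$global,
                                params$p_within)
    true_genes <- draw_profiles(categories, params$omics_per_disease,
                                gene_pools$cat, gene_pools$global,
                                params$omics_p_within)
    true_proteins <- draw_profiles(categories, params$omics_per_disease,
                                   prot_pools$cat, prot_pools$global,
                                   params$omics_p_within)
    true_drugs <- draw_profiles(categories, params$omics_per_disease,
                                drug_pools$cat, drug_pools$global,
                                params$omics_p_within)
  })
  names(true_terms) <- ids
  names(true_genes) <- ids
  names(true_proteins) <- ids
  names(true_drugs) <- ids
  structure(list(
    diseases = data.frame(disease_id = ids,
                          category_id = sprintf("cat%02d", categories)),
    true_terms = true_terms,
    true_genes = true_genes,
    true_proteins = true_proteins,
    true_drugs = true_drugs,
    term_global_pool = term_pools$global,
    params = params
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world: %d diseases, %d categories, seed=%d>\n",
              x$params$n_diseases, x$params$n_categories, x$params$seed))
  invisible(x)
}

#' Category map of a synthetic world
#'
#' @param world a [generate_world()] result.
#' @param system_id label of the synthetic classification system.
#' @return a [category_map()].
#' @export
world_category_map <- function(world, system_id = "SYNCAT") {
  category_map(system_id, stats::setNames(world$diseases$category_id,
                                          world$diseases$disease_id))
}

#' Simulate an imperfect NER tool over a synthetic world
#'
#' Models extraction imperfection at the association-table level: each true
#' term is kept independently with probability `recall`, and
#' Poisson(`noise_rate` x terms_per_disease) spurious terms per disease are
#' added from the global term pool (false positives). Diseases whose
#' extracted set ends up empty are dropped, as a real tool would simply
#' return nothing for them.
#'
#' @param world a [generate_world()] result.
#' @param recall per-term retention probability in \[0, 1\].
#' @param noise_rate spurious terms per disease, as a multiple of
#'   `terms_per_disease` (>= 0).
#' @param seed integer seed.
#' @param tool_id label; defaults to one encoding recall and noise.
#' @return an [association_table()] of entity type `"term"`.
#' @export
simulate_tool <- function(world, recall, noise_rate, seed = 1L,
                          tool_id = sprintf("tool_r%02.0f_n%02.0f",
                                            100 * recall, 100 * noise_rate)) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!is_scalar_number(recall) || recall < 0 || recall > 1) {
    bv_stop("recall must be in [0, 1]", "domain")
  }
  if (!is_scalar_number(noise_rate) || noise_rate < 0) {
    bv_stop("noise_rate must be non-negative", "domain")
  }
  lambda <- noise_rate * world$params$terms_per_disease
  sets <- with_seed(seed, {
    lapply(world$true_terms, function(terms) {
      kept <- terms[stats::runif(length(terms)) < recall]
      n_spur <- stats::rpois(1L, lambda)
      n_spur <- min(n_spur, length(world$term_global_pool))
      spur <- if (n_spur > 0) sample(world$term_global_pool, n_spur) else character(0)
      unique(c(kept, spur))
    })
  })
  sets <- sets[lengths(sets) > 0]
  records <- data.frame(
    disease_id = rep(names(sets), lengths(sets)),
    entity_id = unlist(sets, use.names = FALSE) %||% character(0),
    entity_type = rep("term", sum(lengths(sets)))
  )
  association_table(tool_id, records)
}

#' Reference omics association tables of a synthetic world
#'
#' Exports the true gene, protein and drug associations as association
#' tables, each subsampled to a fraction of diseases (independently per omics
#' type) to emulate the concentration of curated omics data on a limited set
#' of diseases.
#'
#' @param world a [generate_world()] result.
#' @param fraction disease fraction covered by each table; default the
#'   world's `reference_fraction` parameter. Use 1 for full coverage.
#' @param seed integer seed for the subsampling.
#' @return named list of [association_table()] objects: `genomic`,
#'   `proteomic`, `pharmacologic`.
#' @export
reference_tables <- function(world, fraction = NULL, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  fraction <- fraction %||% world$params$reference_fraction
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 1) {
    bv_stop("fraction must be in (0, 1]", "domain")
  }
  ids <- world$diseases$disease_id
  n_keep <- max(2L, ceiling(fraction * length(ids)))
  sources <- list(genomic = list(sets = world$true_genes, type = "gene"),
                  proteomic = list(sets = world$true_proteins, type = "protein"),
                  pharmacologic = list(sets = world$true_drugs, type = "drug"))
  out <- with_seed(seed, {
    lapply(names(sources), function(nm) {
      src <- sources[[nm]]
      keep <- if (n_keep >= length(ids)) ids else sample(ids, n_keep)
      sets <- src$sets[sort_c(keep)]
      association_table(nm, data.frame(
        disease_id = rep(names(sets), lengths(sets)),
        entity_id = unlist(sets, use.names = FALSE),
        entity_type = src$type
      ))
    })
  })
  stats::setNames(out, names(sources))
}

#' Run a full synthetic benchmark scenario
#'
#' The end-to-end harness: generates a world, simulates one association table
#' per tool specification, builds the percentile-filtered phenotypic network
#' for each tool and the unfiltered reference networks, runs the overlap
#' significance against every reference and the coincidence significance
#' against the planted category system, and aggregates everything into the
#' composite ranking. The ground-truth fidelity order (descending recall,
#' ascending noise) is returned alongside, so ranking recovery can be checked.
#'
#' @param params a [generator_params()] (its `seed` is overridden by `seed`).
#' @param tool_specs data frame with columns `tool_id`, `recall`,
#'   `noise_rate`; at least 2 rows.
#' @param n_reps randomizations per significance test (pipeline default 1000;
#'   scenario default 100 keeps desk runs short).
#' @param threshold_percentile percentile filter for phenotypic networks
#'   (default 95).
#' @param seed master integer seed driving world, tools and nulls.
#' @return an object of class `benchmark_result`: `evaluations` (a
#'   [aggregate_evaluations()] table), `truth_order`, `ranked` (tool ids by
#'   composite rank), `recovered` (logical), plus the per-tool `overlaps` and
#'   `coincidences` result lists.
#' @export
benchmark_scenario <- function(params, tool_specs, n_reps = 100L,
                               threshold_percentile = 95, seed = 1L) {
  stopifnot(inherits(params, "generator_params"))
  tool_specs <- as.data.frame(tool_specs)
  need <- c("tool_id", "recall", "noise_rate")
  if (!all(need %in% names(tool_specs)) || nrow(tool_specs) < 2L) {
    bv_stop("tool_specs needs columns tool_id, recall, noise_rate and >= 2 rows",
            "domain")
  }
  params$seed <- derive_seed(seed, 1)
  world <- generate_world(params)
  refs <- reference_tables(world, seed = derive_seed(seed, 2))
  ref_nets <- lapply(refs, build_network)
  cmap <- world_category_map(world)
  overlaps <- list()
  coincidences <- list()
  for (k in seq_len(nrow(tool_specs))) {
    spec <- tool_specs[k, ]
    # seeds keyed by tool id, not list position, so reordering tool_specs
    # cannot change any tool's result
    h <- string_hash(as.character(spec$tool_id))
    tab <- simulate_tool(world, spec$recall, spec$noise_rate,
                         seed = derive_seed(seed, 10 + h),
                         tool_id = as.character(spec$tool_id))
    net <- build_network(tab, threshold_percentile)
    for (r in seq_along(ref_nets)) {
      overlaps[[length(overlaps) + 1L]] <- overlap_significance(
        net, ref_nets[[r]], n_reps = n_reps,
        seed = derive_seed(seed, 100 * h + r))
    }
    coincidences[[length(coincidences) + 1L]] <- coincidence_significance(
      net, cmap, n_reps = n_reps, seed = derive_seed(seed, 17 * h + 3))
  }
  evals <- aggregate_evaluations(overlaps, coincidences)
  truth <- tool_specs$tool_id[order(-tool_specs$recall, tool_specs$noise_rate)]
  ranked <- evals$tool_id[order(evals$rank)]
  structure(list(evaluations = evals,
                 truth_order = as.character(truth),
                 ranked = as.character(ranked),
                 recovered = identical(as.character(ranked), as.character(truth)),
                 overlaps = overlaps,
                 coincidences = coincidences,
                 seed = seed,
                 n_reps = n_reps),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result: ranked %s; truth %s; recovered=%s>\n",
              paste(x$ranked, collapse = " > "),
              paste(x$truth_order, collapse = " > "),
              x$recovered))
  invisible(x)
}
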