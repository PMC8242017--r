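# small fixtures built in code

make_assoc <- function(..., source_id = "toy") {
  sets <- list(...)
  association_table(source_id, data.frame(
    disease_id = rep(names(sets), lengths(sets)),
    entity_id = unlist(sets, use.names = FALSE)
  ))
}

# two triangles {a,b,c} and {d,e,f}, optionally joined by the bridge c-d
two_triangles <- function(bridge = FALSE, w = 1) {
  ed <- data.frame(
    disease_a = c("a", "a", "b", "d", "d", "e"),
    disease_b = c("b", "c", "c", "e", "f", "f"),
    weight = w
  )
  if (bridge) {
    ed <- rbind(ed, data.frame(disease_a = "c", disease_b = "d", weight = w))
  }
  disease_network(ed, meta = list(source_id = "triangles"))
}

path_network <- function(ids) {
  disease_network(data.frame(disease_a = ids[-length(ids)],
                             disease_b = ids[-1],
                             weight = 1),
                  meta = list(source_id = "path"))
}

complete_network <- function(ids) {
  pairs <- t(combn(ids, 2))
  disease_network(data.frame(disease_a = pairs[, 1], disease_b = pairs[, 2],
                             weight = 1),
                  meta = list(source_id = "complete"))
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

small_params <- function(...) {
  generator_params(n_diseases = 120L, n_categories = 4L,
                   terms_per_disease = 12L, category_pool_size = 60L,
                   global_pool_size = 800L,
                   omics_per_disease = 6L, omics_category_pool_size = 30L,
                   omics_global_pool_size = 400L, ...)
}
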