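test_that("Louvain recovers the two triangles joined by a bridge", {
  net <- two_triangles(bridge = TRUE)
  part <- louvain_best_partition(net, seed = 4)
  expect_equal(length(unique(part$assignment)), 2L)
  expect_setequal(partition_sets(part$assignment),
                  list(c("a", "b", "c"), c("d", "e", "f")))
  # matches the exhaustive best-modularity partition on 6 nodes
  oracle <- oracle_best_partition(net)
  expect_setequal(partition_sets(part$assignment),
                  partition_sets(oracle$assignment))
  expect_equal(part$modularity_q, oracle$q, tolerance = 1e-12)
})

test_that("Louvain is deterministic given a seed and beats singletons", {
  for (s in c(1, 7)) {
    net <- random_small_network(14, p = 0.3, seed = s + 50)
    p1 <- louvain_best_partition(net, seed = s)
    p2 <- louvain_best_partition(net, seed = s)
    expect_identical(p1$assignment, p2$assignment)
    singles <- stats::setNames(seq_along(network_nodes(net)),
                               network_nodes(net))
    expect_gte(p1$modularity_q, partition_modularity(net, singles))
    # reported Q matches recomputation from the assignment
    expect_equal(p1$modularity_q, partition_modularity(net, p1$assignment))
    expect_equal(p1$modularity_q, oracle_modularity(net, p1$assignment),
                 tolerance = 1e-12)
  }
  edgeless <- disease_network(
    data.frame(disease_a = character(0), disease_b = character(0),
               weight = numeric(0)), nodes = c("a", "b"))
  expect_error(louvain_best_partition(edgeless),
               class = "bionetval_domain_error")
})

fixed_partition <- function(assignment, q = 0) {
  structure(list(assignment = assignment, modularity_q = q, seed = 1L,
                 resolution = 1), class = "louvain_partition")
}

test_that("community coincidence computes majorities, proportions and the weighted ratio", {
  part <- fixed_partition(c(d1 = 1, d2 = 1, d3 = 1))
  cmap <- category_map("S", c(d1 = "A", d2 = "A", d3 = "B"))
  cc <- community_coincidence(part, cmap)
  expect_equal(cc$per_community$majority_category, "A")
  expect_equal(cc$per_community$proportion, 2 / 3)
  expect_equal(cc$ratio, 2 / 3)

  # two communities with mapped sizes 4 and 1, proportions 0.75 and 1
  part2 <- fixed_partition(c(a1 = 1, a2 = 1, a3 = 1, a4 = 1, b1 = 2))
  cmap2 <- category_map("S", c(a1 = "X", a2 = "X", a3 = "X", a4 = "Y",
                               b1 = "Z"))
  cc2 <- community_coincidence(part2, cmap2)
  expect_equal(cc2$ratio, 0.8)                   # (4*0.75 + 1*1)/5
  expect_equal(community_coincidence(part2, cmap2, weighted = FALSE)$ratio,
               mean(c(0.75, 1)))
})

test_that("majority ties break lexicographically and are flagged", {
  part <- fixed_partition(c(d1 = 1, d2 = 1))
  cmap <- category_map("S", c(d1 = "B", d2 = "A"))
  cc <- community_coincidence(part, cmap)
  expect_equal(cc$per_community$majority_category, "A")
  expect_true(cc$per_community$tie)
})

test_that("unmapped diseases and communities are excluded, empty maps error", {
  part <- fixed_partition(c(d1 = 1, d2 = 1, e1 = 2))
  cmap <- category_map("S", c(d1 = "A", d2 = "A"))
  cc <- community_coincidence(part, cmap)
  expect_equal(cc$n_unmapped_communities, 1L)
  expect_equal(cc$ratio, 1)

  far <- category_map("S", c(zz = "A"))
  expect_error(community_coincidence(part, far),
               class = "bionetval_domain_error")
})

test_that("coincidence ratio is invariant under community relabeling", {
  asg <- c(d1 = 1, d2 = 1, d3 = 2, d4 = 2, d5 = 2)
  cmap <- category_map("S", c(d1 = "A", d2 = "B", d3 = "B", d4 = "B",
                              d5 = "C"))
  r1 <- community_coincidence(fixed_partition(asg), cmap)$ratio
  r2 <- community_coincidence(fixed_partition(3 - asg), cmap)$ratio
  expect_equal(r1, r2)
})

test_that("a perfectly planted world gives coincidence ratio 1", {
  p <- small_params(p_within = 1, seed = 5)
  w <- generate_world(p)
  net <- build_network(simulate_tool(w, 1, 0, seed = 2), 95)
  part <- louvain_best_partition(net, seed = 1)
  cc <- community_coincidence(part, world_category_map(w))
  expect_equal(cc$ratio, 1)
})

test_that("coincidence significance is positive for planted structure and ~0 for shuffled labels", {
  p <- small_params(seed = 9)
  w <- generate_world(p)
  net <- build_network(simulate_tool(w, 0.95, 0.05, seed = 3), 95)
  cmap <- world_category_map(w)
  cc <- coincidence_significance(net, cmap, n_reps = 60, seed = 8)
  expect_gt(cc$z$z, 3)
  expect_true(cc$ratio >= 0 && cc$ratio <= 1)

  # permuting the category labels destroys the alignment: z within noise of 0
  set.seed(42)
  shuffled <- category_map("S", stats::setNames(
    sample(unname(cmap$assignments)), names(cmap$assignments)))
  cc0 <- coincidence_significance(net, shuffled, n_reps = 60, seed = 8)
  expect_lt(abs(cc0$z$z), 3)
})

test_that("category profiles report reference bars and majority percentages", {
  part <- fixed_partition(c(d1 = 1, d2 = 1, d3 = 2, d4 = 2))
  cmap <- category_map("S", c(d1 = "A", d2 = "A", d3 = "B", d4 = "B",
                              d5 = "A"))
  prof <- category_profile(part, cmap, top_k = 10)
  expect_equal(prof$category_id, c("A", "B"))
  expect_equal(prof$pct_reference, c(60, 40))
  expect_equal(prof$pct_majority, c(50, 50))
  expect_lte(sum(prof$pct_majority), 100 + 1e-9)

  single <- category_map("S", c(d1 = "only", d2 = "only"))
  prof1 <- category_profile(fixed_partition(c(d1 = 1, d2 = 1)), single)
  expect_equal(prof1$pct_reference, 100)
  expect_equal(prof1$pct_majority, 100)
})
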