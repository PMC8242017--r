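test_that("jaccard similarity matches the set formula", {
  expect_equal(jaccard_similarity(c("t1", "t2", "t3"), c("t1", "t2", "t3")), 1)
  expect_equal(jaccard_similarity("t1", "t2"), 0)
  expect_equal(jaccard_similarity(c("t1", "t2", "t3"), c("t2", "t3", "t4")), 0.5)
  expect_true(abs(jaccard_similarity(c("a", "b"), c("b", "c", "d")) - 0.25) < 1e-15)
  expect_error(jaccard_similarity(character(0), "x"),
               class = "bionetval_domain_error")
})

test_that("pairwise similarities return exactly the co-occurring pairs", {
  tab <- make_assoc(d1 = c("t1", "t2"), d2 = c("t2", "t3"), d3 = "t9")
  sims <- pairwise_similarities(tab)
  expect_equal(nrow(sims), 1L)
  expect_equal(sims$disease_a, "d1")
  expect_equal(sims$disease_b, "d2")
  expect_equal(sims$similarity, 1 / 3)

  ident <- make_assoc(d1 = c("t1", "t2"), d2 = c("t1", "t2"), d3 = c("t1", "t2"))
  s2 <- pairwise_similarities(ident)
  expect_equal(nrow(s2), 3L)
  expect_true(all(s2$similarity == 1))

  disjoint <- make_assoc(d1 = "a", d2 = "b", d3 = "c", d4 = "d")
  expect_equal(nrow(pairwise_similarities(disjoint)), 0L)
})

test_that("pairwise similarities agree with direct jaccard on random tables", {
  set.seed(11)
  for (rep in 1:5) {
    sets <- lapply(1:8, function(i) sprintf("e%02d", sample(25, sample(2:10, 1))))
    names(sets) <- sprintf("d%02d", 1:8)
    tab <- do.call(make_assoc, sets)
    sims <- pairwise_similarities(tab)
    for (r in seq_len(nrow(sims))) {
      expect_equal(sims$similarity[r],
                   jaccard_similarity(sets[[sims$disease_a[r]]],
                                      sets[[sims$disease_b[r]]]))
    }
    # completeness: every sharing pair is present
    n_sharing <- sum(combn(8, 2, function(ij) {
      length(intersect(sets[[ij[1]]], sets[[ij[2]]])) > 0
    }))
    expect_equal(nrow(sims), n_sharing)
  }
})

test_that("pairwise similarities are invariant to record order", {
  rec <- data.frame(disease_id = c("d2", "d1", "d3", "d1", "d2"),
                    entity_id = c("t2", "t1", "t2", "t2", "t3"))
  a <- pairwise_similarities(association_table("x", rec))
  b <- pairwise_similarities(association_table("x", rec[sample(nrow(rec)), ]))
  expect_identical(a, b)
})

test_that("percentile cutoff follows the linear-interpolation convention", {
  expect_equal(percentile_cutoff(c(0.1, 0.2, 0.3, 0.4), 50), 0.25)
  x <- c(0.7, 0.1, 0.4, 0.9, 0.2)
  expect_equal(percentile_cutoff(x, 100), max(x))
  expect_equal(percentile_cutoff(x, 0), min(x))
  expect_error(percentile_cutoff(numeric(0), 95),
               class = "bionetval_domain_error")
  expect_error(percentile_cutoff(c(1, 2), 101), class = "bionetval_domain_error")
})

test_that("95th percentile of many uniform draws sits near 0.95", {
  set.seed(202)
  cut <- percentile_cutoff(runif(1000), 95)
  expect_gt(cut, 0.93)
  expect_lt(cut, 0.97)
})

test_that("the percentile filter keeps strictly-above pairs only", {
  # 20 pairs with distinct similarities: q=95 retains exactly the top pair.
  # 21 diseases: d00 is the hub sharing a graded number of entities with the
  # others, giving 20 distinct hub similarities; satellite pairs also share
  # entities, so make all similarities distinct by construction instead:
  sims <- (1:20) / 40
  tab_sets <- list()
  # build 20 disjoint disease pairs with prescribed similarity k/40:
  # pair i shares k_i entities out of a union sized 40.
  sets <- list()
  for (i in 1:20) {
    shared <- sprintf("p%02d_s%02d", i, seq_len(i))       # i shared
    rest <- 40 - i                                         # union = 40
    a_only <- sprintf("p%02d_a%02d", i, seq_len(ceiling(rest / 2)))
    b_only <- sprintf("p%02d_b%02d", i, seq_len(floor(rest / 2)))
    sets[[sprintf("dA%02d", i)]] <- c(shared, a_only)
    sets[[sprintf("dB%02d", i)]] <- c(shared, b_only)
  }
  tab <- do.call(make_assoc, sets)
  sims_df <- pairwise_similarities(tab)
  expect_equal(sort(sims_df$similarity), sort(sims))
  net <- build_network(tab, 95)
  expect_equal(n_edges(net), 1L)
  expect_equal(network_edges(net)$weight, 0.5)
  expect_equal(n_nodes(net), 2L)  # isolated diseases dropped
})

test_that("all-equal similarities with q=95 yield zero edges", {
  tab <- make_assoc(d1 = c("t1", "t2"), d2 = c("t1", "t2"), d3 = c("t1", "t2"))
  net <- build_network(tab, 95)
  expect_equal(n_edges(net), 0L)
  expect_equal(n_nodes(net), 0L)
})

test_that("unfiltered networks keep every nonzero pair with its weight", {
  tab <- make_assoc(d1 = c("t1", "t2"), d2 = c("t2", "t3"))
  net <- build_network(tab)
  expect_equal(n_edges(net), 1L)
  expect_equal(network_edges(net)$weight, 1 / 3)
  expect_null(net$meta$threshold_percentile)
})

test_that("a filtered network's edges are a subset of the unfiltered ones", {
  set.seed(33)
  sets <- lapply(1:15, function(i) sprintf("e%02d", sample(30, 8)))
  names(sets) <- sprintf("d%02d", 1:15)
  tab <- do.call(make_assoc, sets)
  all_net <- build_network(tab)
  key <- function(net) {
    ed <- network_edges(net)
    paste(ed$disease_a, ed$disease_b)
  }
  for (q in c(20, 50, 95)) {
    f <- build_network(tab, q)
    expect_true(all(key(f) %in% key(all_net)))
    # strictly-above rule bounds the retained count
    n_nonzero <- n_edges(all_net)
    expect_lte(n_edges(f), ceiling((1 - q / 100) * n_nonzero))
  }
})

test_that("network constructor enforces the invariants", {
  expect_error(disease_network(data.frame(disease_a = "d1", disease_b = "d1",
                                          weight = 0.5)),
               "self-loop", class = "bionetval_validation_error")
  expect_error(disease_network(data.frame(disease_a = "d1", disease_b = "d2",
                                          weight = 1.5)),
               "weights", class = "bionetval_validation_error")
  expect_error(disease_network(data.frame(disease_a = "d1", disease_b = "d2",
                                          weight = 0)),
               "weights", class = "bionetval_validation_error")
  # canonical storage: order of endpoints does not matter
  n1 <- disease_network(data.frame(disease_a = "d2", disease_b = "d1",
                                   weight = 0.5))
  expect_equal(network_edges(n1)$disease_a, "d1")
})

test_that("networks round-trip through the edge-list format", {
  net <- disease_network(
    data.frame(disease_a = c("d1", "d2"), disease_b = c("d2", "d3"),
               weight = c(1 / 3, 0.123456789012345)),
    nodes = c("d1", "d2", "d3", "lonely"),
    meta = list(source_id = "toy", threshold_percentile = 95, cutoff = 0.2)
  )
  path <- tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_identical(network_nodes(back), network_nodes(net))
  expect_equal(network_edges(back), network_edges(net), tolerance = 1e-12)
  expect_equal(back$meta$source_id, "toy")
  expect_equal(back$meta$threshold_percentile, 95)
  expect_equal(back$meta$cutoff, 0.2)
})

test_that("networks round-trip through GraphML", {
  net <- two_triangles(bridge = TRUE, w = 0.5)
  path <- tempfile(fileext = ".graphml")
  write_network(net, path)
  back <- read_network(path)
  expect_identical(network_nodes(back), network_nodes(net))
  expect_equal(network_edges(back), network_edges(net), tolerance = 1e-12)
  expect_equal(back$meta$source_id, "triangles")
})

test_that("reading rejects invalid rows", {
  self_loop <- write_tsv_fixture(c("disease_a\tdisease_b\tweight",
                                   "d1\td1\t0.5"),
                                 tempfile(fileext = ".tsv"))
  expect_error(read_network(self_loop), "self-loop",
               class = "bionetval_validation_error")
  bad_w <- write_tsv_fixture(c("disease_a\tdisease_b\tweight",
                               "d1\td2\t1.5"),
                             tempfile(fileext = ".tsv"))
  expect_error(read_network(bad_w), "weights",
               class = "bionetval_validation_error")
})

test_that("random valid networks survive write/read round trips", {
  for (s in 1:5) {
    net <- random_small_network(sample(4:10, 1), seed = s)
    path <- tempfile(fileext = ".tsv")
    write_network(net, path)
    back <- read_network(path)
    expect_identical(network_nodes(back), network_nodes(net))
    expect_equal(network_edges(back), network_edges(net), tolerance = 1e-12)
  }
})
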