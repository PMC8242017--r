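test_that("random G(n,m) graphs have exactly m edges and valid structure", {
  net <- random_gnm(c("a", "b", "c"), 3, seed = 1)
  expect_equal(n_edges(net), 3L)
  ed <- network_edges(net)
  expect_setequal(paste(ed$disease_a, ed$disease_b),
                  c("a b", "a c", "b c"))  # the triangle is the only option
  expect_true(all(ed$weight == 1))

  big <- random_gnm(sprintf("d%03d", 1:50), 200, seed = 4)
  ed2 <- network_edges(big)
  expect_equal(nrow(ed2), 200L)
  expect_true(all(ed2$disease_a < ed2$disease_b))
  expect_false(anyDuplicated(paste(ed2$disease_a, ed2$disease_b)) > 0)
  expect_error(random_gnm(c("a", "b"), 2, seed = 1),
               class = "bionetval_domain_error")
})

test_that("random G(n,m) is seed-deterministic and seed-sensitive", {
  a <- random_gnm(sprintf("d%02d", 1:20), 40, seed = 99)
  b <- random_gnm(sprintf("d%02d", 1:20), 40, seed = 99)
  c <- random_gnm(sprintf("d%02d", 1:20), 40, seed = 100)
  expect_identical(network_edges(a), network_edges(b))
  expect_false(identical(network_edges(a), network_edges(c)))
})

test_that("G(n,m) sampling is uniform over pairs", {
  n <- 30
  m <- 60
  draws <- 2000
  ids <- sprintf("d%02d", 1:n)
  counts <- numeric(n * (n - 1) / 2)
  for (s in seq_len(draws)) {
    ed <- network_edges(random_gnm(ids, m, seed = s))
    i <- match(ed$disease_a, ids)
    j <- match(ed$disease_b, ids)
    idx <- (i - 1) * n - i * (i + 1) / 2 + j
    counts[idx] <- counts[idx] + 1
  }
  p <- m / (n * (n - 1) / 2)
  se <- sqrt(p * (1 - p) / draws)
  freq <- counts / draws
  expect_true(all(abs(freq - p) < 5 * se))
  expect_lt(mean(abs(freq - p) > 4 * se), 0.001)
})

test_that("pair-index decoding enumerates exactly the i<j pairs", {
  for (n in c(2, 3, 5, 9, 17)) {
    total <- n * (n - 1) / 2
    got <- bionetval:::pair_decode(seq_len(total), n)
    want <- t(combn(n, 2))
    expect_equal(unname(got[, "i"]), want[, 1])
    expect_equal(unname(got[, "j"]), want[, 2])
    expect_equal(bionetval:::pair_index(want[, 1], want[, 2], n),
                 seq_len(total))
  }
})

test_that("null distributions behave for constant statistics", {
  net <- two_triangles()
  nd <- build_null(function(g) 42, net, n_reps = 20, seed = 1)
  expect_equal(nd$sd, 0)
  expect_true(all(nd$samples == 42))
  ndm <- build_null(n_edges, net, n_reps = 20, seed = 1)
  expect_true(all(ndm$samples == 6))  # G(n,m) preserves the edge count
})

test_that("null construction is reproducible and records failures", {
  net <- random_gnm(sprintf("d%02d", 1:15), 25, seed = 8)
  a <- build_null(network_transitivity, net, n_reps = 30, seed = 5)
  b <- build_null(network_transitivity, net, n_reps = 30, seed = 5)
  expect_identical(a$samples, b$samples)
  expect_equal(a$n_failed, 0L)

  flaky <- local({
    k <- 0
    function(g) {
      k <<- k + 1
      if (k %% 3 == 0) stop("boom")
      network_transitivity(g)
    }
  })
  nd <- build_null(flaky, net, n_reps = 30, seed = 5)
  expect_equal(nd$n_failed, 10L)
  expect_length(nd$samples, 20L)
})

test_that("null transitivity mean matches exhaustive enumeration on G(5, 4)", {
  # exact oracle: every 4-edge subset of the 10 pairs is equally likely
  ids <- c("a", "b", "c", "d", "e")
  pairs <- t(combn(ids, 2))
  subsets <- combn(nrow(pairs), 4)
  exact <- mean(apply(subsets, 2, function(rows) {
    net <- disease_network(data.frame(disease_a = pairs[rows, 1],
                                      disease_b = pairs[rows, 2],
                                      weight = 1), nodes = ids)
    oracle_transitivity(net)
  }))
  template <- random_gnm(ids, 4, seed = 3)
  nd <- build_null(network_transitivity, template, n_reps = 600, seed = 21)
  se <- nd$sd / sqrt(length(nd$samples))
  expect_lt(abs(nd$mean - exact), 3 * se)
})

test_that("z-scores follow the definition and degenerate nulls use sentinels", {
  nd <- new_null <- build_null(function(g) 42, two_triangles(), n_reps = 10,
                               seed = 1)
  expect_equal(zscore(42, nd)$z, 0)
  expect_equal(zscore(50, nd)$z, Inf)
  expect_equal(zscore(40, nd)$z, -Inf)

  hand <- structure(list(statistic_label = "hand", samples = c(2, 4, 6),
                         mean = 4, sd = 2, shapiro_p = NA_real_,
                         n_reps = 3L, n_failed = 0L, seed = 1L),
                    class = "null_distribution")
  expect_equal(zscore(4, hand)$z, 0)
  expect_equal(zscore(8, hand)$z, 2)
  expect_equal(zscore(10, hand)$z, 3)
})

test_that("z-scores are location and scale equivariant", {
  set.seed(12)
  x <- rnorm(200, 5, 2)
  nd <- structure(list(statistic_label = "x", samples = x, mean = mean(x),
                       sd = sd(x), shapiro_p = NA_real_, n_reps = 200L,
                       n_failed = 0L, seed = 1L), class = "null_distribution")
  shifted <- structure(list(statistic_label = "x", samples = x + 7,
                            mean = mean(x) + 7, sd = sd(x),
                            shapiro_p = NA_real_, n_reps = 200L,
                            n_failed = 0L, seed = 1L),
                       class = "null_distribution")
  expect_equal(zscore(6, nd)$z, zscore(13, shifted)$z)
})

test_that("Shapiro-Wilk wrapper enforces its domain and calibrates", {
  expect_error(shapiro_wilk_p(c(1, 2)), class = "bionetval_domain_error")
  expect_error(shapiro_wilk_p(rnorm(5001)), class = "bionetval_domain_error")
  set.seed(31)
  p_normal <- replicate(60, shapiro_wilk_p(rnorm(300)))
  expect_gte(mean(p_normal > 0.05), 0.9)
  p_exp <- replicate(30, shapiro_wilk_p(rexp(300)))
  expect_true(all(p_exp <= 0.05))
})

test_that("min-max normalization scales, preserves order, flags degeneracy", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(out <- minmax_normalize(5), "equal")
  expect_equal(out, 0.5)
  set.seed(2)
  x <- rnorm(50)
  nx <- minmax_normalize(x)
  expect_true(all(nx >= 0 & nx <= 1))
  expect_equal(order(nx), order(x))
})
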