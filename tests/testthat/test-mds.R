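test_that("variable distance matrix matches closed forms", {
  ## identical variables are at distance zero
  m <- cbind(a = c(1, 5, 3, 2), b = c(1, 5, 3, 2))
  d <- variable_distance_matrix(m, scale = "none")
  expect_equal(d["a", "b"], 0)

  ## hand oracle: (1,2,3) vs (4,6,8) -> sqrt(9 + 16 + 25)
  m2 <- cbind(x = c(1, 2, 3), y = c(4, 6, 8))
  d2 <- variable_distance_matrix(m2, scale = "none")
  expect_equal(d2["x", "y"], sqrt(50), tolerance = 1e-12)

  ## a variable and its negation under column z-scoring: 2 * sqrt(n - 1)
  set.seed(7)
  v <- rnorm(9)
  m3 <- cbind(p = v, q = -v)
  d3 <- variable_distance_matrix(m3, scale = "variable")
  expect_equal(d3["p", "q"], 2 * sqrt(8), tolerance = 1e-9)
})

test_that("proximity construction validates factor scores and structure", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 1, 3))
  expect_error(variable_distance_matrix(m, factor_scores = c(1, 2)),
               class = "foodrisk_dimension_error")
  d <- variable_distance_matrix(m, factor_scores = c(0.5, -0.5, 0),
                                scale = "none")
  expect_equal(colnames(d), c("a", "b", "Factor_1"))
  expect_true(isSymmetric(unclass(d)))
  expect_equal(unname(diag(d)), rep(0, 3))
  ## PROXSCAL normalization: sum of squared upper-triangle entries = k(k-1)/2
  dn <- normalize_proximities(d)
  expect_equal(sum(dn[upper.tri(dn)]^2), 3, tolerance = 1e-12)
})

test_that("any 3-point metric embeds exactly in two dimensions", {
  prox <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  prox["a", "b"] <- prox["b", "a"] <- 3
  prox["a", "c"] <- prox["c", "a"] <- 4
  prox["b", "c"] <- prox["c", "b"] <- 5
  emb <- smacof_embed(prox, dims = 2)
  expect_lt(emb$stress1, 1e-6)
  fitted <- as.matrix(dist(emb$coordinates))
  expect_equal(fitted["a", "b"], 3, tolerance = 1e-4)
  expect_equal(fitted["b", "c"], 5, tolerance = 1e-4)
})

test_that("SMACOF is scale-equivariant and its stress trace never increases", {
  tab <- oecd2020()
  fm <- fixture_factor_model(tab)
  prox <- variable_distance_matrix(tab, factor_scores = fm$scores,
                                   scale = "case")
  emb1 <- smacof_embed(prox)
  emb2 <- smacof_embed(prox * 2)
  expect_equal(emb2$coordinates, emb1$coordinates * 2, tolerance = 1e-6)
  expect_equal(emb2$stress1, emb1$stress1, tolerance = 1e-9)
  expect_true(all(diff(emb1$stress_trace) <= 1e-12))
  expect_true(emb1$converged)
})

test_that("SMACOF validates input and flags non-convergence without error", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(smacof_embed(bad), class = "foodrisk_validation_error")
  prox <- as.matrix(dist(cbind(rnorm(5), rnorm(5))))
  expect_error(smacof_embed(prox, dims = 5),
               class = "foodrisk_validation_error")
  expect_warning(emb <- smacof_embed(prox, max_iter = 1), "convergence")
  expect_false(emb$converged)
})

test_that("random-init SMACOF is deterministic given a seed and preserves global RNG", {
  prox <- variable_distance_matrix(
    cbind(a = c(1, 9, 2, 8), b = c(3, 1, 4, 1), c = c(5, 9, 2, 6)),
    scale = "variable")
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  e1 <- smacof_embed(prox, init = "random", seed = 11)
  e2 <- smacof_embed(prox, init = "random", seed = 11)
  after <- rnorm(1)
  expect_identical(e1$coordinates, e2$coordinates)
  expect_identical(before, after)  # embedding did not consume the global stream
})

test_that("distances to the anchor match the published-configuration oracle", {
  ## direct Euclidean arithmetic on the reference common-space coordinates
  coords <- reference_configuration()
  d <- distances_to_anchor(coords, "Factor_1")
  crop_hand <- sqrt((1.351 - -0.417)^2 + (-0.220 - -0.266)^2)
  prot_hand <- sqrt((-0.408 - -0.417)^2 + (-0.250 - -0.266)^2)
  expect_equal(unname(d["crop_per_million"]), crop_hand, tolerance = 1e-12)
  expect_equal(round(crop_hand, 3), 1.769)
  expect_equal(round(prot_hand, 3), 0.018)
  expect_error(distances_to_anchor(coords, "nope"),
               class = "foodrisk_lookup_error")
  ## anchor-to-itself distance is zero by definition
  expect_equal(unname(distances_to_anchor(rbind(coords, self = coords["Factor_1", ]),
                                          "Factor_1")["self"]), 0)
})

test_that("distance-to-weight transform follows the ratio/complement arithmetic", {
  ## hand arithmetic, k = 2: d = (1, 3) -> x = (.25, .75) -> W = (.75, .25)
  w2 <- distances_to_weights(c(a = 1, b = 3))
  expect_equal(w2$ratio, c(0.25, 0.75))
  expect_equal(w2$weight, c(0.75, 0.25))

  ## equal distances give uniform weights
  w4 <- distances_to_weights(rep(2, 4))
  expect_equal(w4$weight, rep(0.25, 4))

  ## frozen full-precision transform of the published 3-dp distances
  w <- distances_to_weights(reference_distances())
  expect_equal(w$weight[w$criterion == "meat_total"],
               (1 - 0.897 / 3.925) / 5, tolerance = 1e-12)
  expect_equal(w$weight[w$criterion == "meat_total"], 0.1542929936,
               tolerance = 1e-9)
  expect_equal(w$weight[w$criterion == "producer_protection_ratio"],
               0.1990828025, tolerance = 1e-9)
  expect_equal(sum(w$ratio), 1, tolerance = 1e-12)
  expect_equal(sum(w$fixed), length(w$fixed) - 1, tolerance = 1e-12)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
})

test_that("weight transform is anti-monotone and scale-invariant", {
  set.seed(99)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    d <- sort(runif(k, 0.01, 5))   # strictly increasing distances
    w <- distances_to_weights(d)
    expect_true(all(diff(w$weight) < 0))  # larger distance, smaller weight
    w_scaled <- distances_to_weights(d * runif(1, 0.1, 50))
    expect_equal(w_scaled$weight, w$weight, tolerance = 1e-12)
  }
})

test_that("degenerate distance inputs are rejected", {
  expect_error(distances_to_weights(c(0, 0, 0)),
               class = "foodrisk_degenerate_error")
  expect_error(distances_to_weights(c(1, -0.1)),
               class = "foodrisk_domain_error")
  expect_error(distances_to_weights(2), class = "foodrisk_degenerate_error")
})
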