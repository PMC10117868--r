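test_that("normalization dialects match their closed forms", {
  m <- cbind(a = c(3, 4))
  expect_equal(unname(topsis_normalize(m, "vector")[, 1]), c(0.6, 0.8))
  ## squared dialect: d^2 / sqrt(sum d^2) = (9, 16) / 5
  expect_equal(unname(topsis_normalize(m, "squared")[, 1]), c(1.8, 3.2))
  ## zero maps to zero in both dialects
  z <- cbind(a = c(0, 2))
  expect_equal(unname(topsis_normalize(z, "squared")[1, 1]), 0)
  expect_equal(unname(topsis_normalize(z, "vector")[1, 1]), 0)
})

test_that("normalization rejects invalid matrices", {
  expect_error(topsis_normalize(cbind(a = c(-1, 2))),
               class = "foodrisk_domain_error")
  expect_error(topsis_normalize(cbind(a = c(1, 2), b = c(0, 0))),
               class = "foodrisk_degenerate_error")
})

test_that("weighting is elementwise and aligned by name", {
  r <- cbind(a = c(0.6, 0.8), b = c(0.5, 0.5))
  expect_equal(apply_weights(r, c(1, 1)), r)
  v <- apply_weights(r, c(b = 0.3, a = 0.7))   # names override position
  expect_equal(unname(v[, "a"]), c(0.42, 0.56))
  expect_equal(unname(v[, "b"]), c(0.15, 0.15))
  expect_error(apply_weights(r, c(x = 0.5, y = 0.5)),
               class = "foodrisk_alignment_error")
  expect_error(apply_weights(r, c(0.5, 0.3, 0.2)),
               class = "foodrisk_alignment_error")
  ## with weights summing to 1, column maxima scale by the weights
  w <- c(a = 0.25, b = 0.75)
  v2 <- apply_weights(r, w)
  expect_equal(apply(v2, 2, max), w * apply(r, 2, max))
})

test_that("ideal solutions respect benefit/cost directions", {
  v <- cbind(x = c(1, 3, 2), y = c(5, 4, 6))
  ide <- ideal_solutions(v, c(x = "benefit", y = "cost"))
  expect_equal(unname(ide$A_star), c(3, 4))
  expect_equal(unname(ide$A_minus), c(1, 6))
  ## flipping a direction swaps that criterion's ideal entries
  flipped <- ideal_solutions(v, c(x = "benefit", y = "benefit"))
  expect_equal(unname(flipped$A_star[2]), unname(ide$A_minus[2]))
  expect_equal(unname(flipped$A_minus[2]), unname(ide$A_star[2]))
  ## a single alternative is its own positive and negative ideal
  one <- ideal_solutions(v[1, , drop = FALSE], c("benefit", "cost"))
  expect_equal(unname(one$A_star), unname(v[1, ]))
  expect_equal(unname(one$A_minus), unname(v[1, ]))
})

test_that("closeness coefficients hit their endpoints exactly", {
  ## 2 alternatives, 1 benefit criterion, values (1, 3): C* = (0, 1)
  ts <- topsis(cbind(crit = c(1, 3)), weights = 1, directions = "benefit",
               dialect = "vector")
  expect_equal(unname(ts$C_star), c(0, 1))
  expect_equal(unname(ts$ranks), c(2L, 1L))
  ## a row equal to A* has S* = 0 hence C* = 1; equal to A- has C* = 0
  v <- cbind(a = c(0.9, 0.1, 0.5), b = c(0.8, 0.2, 0.3))
  ide <- ideal_solutions(v, c("benefit", "benefit"))
  sep <- separations_and_closeness(v, ide$A_star, ide$A_minus)
  expect_equal(unname(sep$C_star[1]), 1)
  expect_equal(unname(sep$C_star[2]), 0)
  expect_true(all(sep$C_star >= 0 & sep$C_star <= 1))
})

test_that("a single alternative cannot be scored", {
  expect_error(separations_and_closeness(cbind(a = 1, b = 2), c(1, 2), c(1, 2)),
               class = "foodrisk_degenerate_error")
})

test_that("ranking is stable under reordering and flags ties", {
  C <- c(u = 0.9, v = 0.1, w = 0.5, x = 0.7)
  rk <- topsis_rank(C)
  expect_equal(unname(rk$ranks), c(1L, 4L, 3L, 2L))
  expect_false(rk$ties)
  ## permuting the inputs permutes the ranks identically
  perm <- c(3, 1, 4, 2)
  rk2 <- topsis_rank(C[perm])
  expect_equal(rk2$ranks[names(C)], rk$ranks)
  ## total tie: ranks follow input order with the flag set
  rk3 <- topsis_rank(c(0.5, 0.5, 0.5))
  expect_equal(unname(rk3$ranks), 1:3)
  expect_true(rk3$ties)
  expect_error(topsis_rank(c(0.2, NaN)), class = "foodrisk_numerical_error")
})

test_that("full TOPSIS matches the brute-force oracle elementwise", {
  set.seed(2024)
  for (rep in 1:30) {
    m <- sample(2:5, 1); k <- sample(2:3, 1)
    values <- matrix(runif(m * k, 0.1, 10), m, k,
                     dimnames = list(paste0("alt", 1:m), paste0("c", 1:k)))
    w <- runif(k); w <- w / sum(w)
    dirs <- sample(c("benefit", "cost"), k, replace = TRUE)
    for (dialect in c("squared", "vector")) {
      got <- topsis(values, weights = w, directions = dirs, dialect = dialect)
      want <- brute_topsis(values, w, dirs, dialect)
      expect_equal(unname(got$normalized), want$normalized, tolerance = 1e-12)
      expect_equal(unname(got$weighted), want$weighted, tolerance = 1e-12)
      expect_equal(unname(got$A_star), want$A_star, tolerance = 1e-12)
      expect_equal(unname(got$A_minus), want$A_minus, tolerance = 1e-12)
      expect_equal(unname(got$S_star), want$S_star, tolerance = 1e-12)
      expect_equal(unname(got$S_minus), want$S_minus, tolerance = 1e-12)
      expect_equal(unname(got$C_star), want$C_star, tolerance = 1e-12)
    }
  }
})

test_that("vector dialect is column-scale invariant; squared dialect is not", {
  values <- cbind(c1 = c(3, 1), c2 = c(1, 2))
  w <- c(0.5, 0.5); dirs <- c("benefit", "benefit")
  scaled <- values; scaled[, "c2"] <- scaled[, "c2"] * 100

  v1 <- topsis(values, w, dirs, dialect = "vector")
  v2 <- topsis(scaled, w, dirs, dialect = "vector")
  expect_equal(v1$C_star, v2$C_star, tolerance = 1e-12)
  expect_equal(v1$ranks, v2$ranks)

  s1 <- topsis(values, w, dirs, dialect = "squared")
  s2 <- topsis(scaled, w, dirs, dialect = "squared")
  expect_false(isTRUE(all.equal(s1$C_star, s2$C_star, tolerance = 1e-6)))
  expect_false(identical(s1$ranks, s2$ranks))  # the scaling flips the winner
})

test_that("decision matrix validation catches bad inputs", {
  expect_error(decision_matrix(cbind(a = c(-1, 1)), "benefit"),
               class = "foodrisk_domain_error")
  expect_error(decision_matrix(cbind(a = c(0, 0), b = c(1, 2)),
                               c("benefit", "cost")),
               class = "foodrisk_degenerate_error")
  expect_error(decision_matrix(cbind(a = c(1, 2)), "upside"),
               class = "foodrisk_validation_error")
  expect_error(topsis(cbind(a = c(1, 2)), weights = 1, dialect = "vector"),
               class = "foodrisk_validation_error")  # no directions anywhere
})
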