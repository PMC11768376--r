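simple_table <- function(vals, dirs = "benefit") {
  m <- as.matrix(vals)
  rownames(m) <- paste0("o", seq_len(nrow(m)))
  indicator_table(m, dirs)
}

test_that("min-max standardization respects directions and bounds", {
  tab <- simple_table(cbind(A = c(2, 4, 6), B = c(2, 4, 6)),
                      c(A = "benefit", B = "cost"))
  z <- standardize_minmax(tab)
  expect_equal(unname(z[, "A"]), c(0, 0.5, 1))
  expect_equal(unname(z[, "B"]), c(1, 0.5, 0))
  expect_true(all(z >= 0 & z <= 1))
  const <- simple_table(cbind(A = c(1, 2, 3), B = c(5, 5, 5)))
  expect_error(standardize_minmax(const), "constant indicator")
  expect_warning(z2 <- standardize_minmax(const, constant = "drop"),
                 "dropping")
  expect_equal(colnames(z2), "A")
})

test_that("proportion columns sum to one before entropy", {
  tab <- random_indicator_table(9, 5, seed = 2)
  P <- column_proportions(standardize_minmax(tab))
  expect_equal(unname(colSums(P)), rep(1, 5))
  expect_true(all(P >= 0))
})

test_that("entropy hits its theoretical extremes", {
  expect_equal(entropy_value(rep(1 / 9, 9)), 1)
  expect_equal(entropy_value(c(1, rep(0, 8))), 0)
  expect_error(entropy_value(c(-0.1, 1.1)), "non-negative")
  expect_error(entropy_value(c(0.3, 0.3)), "sum to 1")
})

test_that("entropy weights normalize utility 1 - e", {
  w <- entropy_weights(c(a = 0.5, b = 0.5))
  expect_equal(w$weight, c(0.5, 0.5))
  w2 <- entropy_weights(c(a = 1, b = 0))
  expect_equal(w2$weight, c(0, 1))
  expect_error(entropy_weights(c(1, 1)), "no discriminating")
  set.seed(4)
  e <- runif(6)
  expect_equal(sum(entropy_weights(e)$weight), 1, tolerance = 1e-12)
})

test_that("ideal solutions are the column extrema", {
  tab <- random_indicator_table(7, 3, seed = 9)
  z <- standardize_minmax(tab)
  id <- ideal_solutions(z)
  expect_equal(unname(id$positive), rep(1, 3))
  expect_equal(unname(id$negative), rep(0, 3))
})

test_that("distances and closeness behave at the ideal points", {
  tab <- random_indicator_table(6, 4, seed = 5)
  z <- standardize_minmax(tab)
  w <- rep(0.25, 4)
  # an object placed at the positive ideal has d+ = 0, closeness 1
  z2 <- rbind(unclass(z), best = rep(1, 4), worst = rep(0, 4))
  class(z2) <- class(z)
  d <- topsis_distances(z2, w)
  expect_equal(d$d_plus[7], 0)
  expect_equal(d$d_minus[8], 0)
  tc <- closeness(d$d_plus[1:7], d$d_minus[1:7])
  expect_equal(tc[7], 1)
  expect_equal(closeness(2, 2), 0.5)
  expect_error(closeness(0, 0), "degenerate")
  expect_error(topsis_distances(z, w[1:2]), "align")
})

test_that("the two distance variants differ and both bound d in [0,1]", {
  tab <- random_indicator_table(8, 5, seed = 6)
  ev_lin <- ewm_topsis(tab, variant = "weights-linear")
  ev_lit <- ewm_topsis(tab, variant = "literal")
  expect_false(isTRUE(all.equal(ev_lin$result$d_plus, ev_lit$result$d_plus)))
  expect_true(all(ev_lin$result$d_plus >= 0 & ev_lin$result$d_plus <= 1))
  expect_true(all(ev_lin$result$d_minus >= 0 & ev_lin$result$d_minus <= 1))
  expect_true(all(ev_lin$result$closeness >= 0 &
                    ev_lin$result$closeness <= 1))
})

test_that("ranks are a permutation with ties broken by input order", {
  expect_equal(rank_closeness(c(0.2, 0.9, 0.5)), c(3, 1, 2))
  expect_equal(rank_closeness(rep(0.4, 4)), 1:4)
  for (seed in 1:3) {
    set.seed(seed)
    tc <- runif(9)
    expect_setequal(rank_closeness(tc), 1:9)
  }
})

test_that("evaluate matches the brute-force oracle on random matrices", {
  for (seed in 1:20) {
    tab <- random_indicator_table(4, 3, seed)
    for (variant in c("weights-linear", "literal")) {
      ev <- ewm_topsis(tab, variant = variant)
      or <- oracle_ewm_topsis(unclass(tab), attr(tab, "directions"),
                              variant)
      expect_equal(ev$weights$entropy, or$e, tolerance = 1e-10)
      expect_equal(ev$weights$weight, or$w, tolerance = 1e-10)
      expect_equal(ev$result$d_plus, or$d_plus, tolerance = 1e-10)
      expect_equal(ev$result$d_minus, or$d_minus, tolerance = 1e-10)
      expect_equal(ev$result$closeness, or$closeness, tolerance = 1e-10)
      expect_equal(ev$result$rank, or$rank)
    }
  }
})

test_that("increasing affine transforms of a raw column change nothing", {
  tab <- random_indicator_table(9, 4, seed = 8)
  base <- ewm_topsis(tab)
  vals <- unclass(tab)
  vals[, 2] <- 3.7 * vals[, 2] + 42
  vals[, 4] <- 0.01 * vals[, 4] - 5
  ev <- ewm_topsis(indicator_table(vals, attr(tab, "directions")))
  expect_equal(ev$weights$weight, base$weights$weight, tolerance = 1e-12)
  expect_equal(ev$result$closeness, base$result$closeness,
               tolerance = 1e-12)
  expect_equal(ev$result$rank, base$result$rank)
})

test_that("with fixed weights, improving a benefit value raises closeness", {
  tab <- random_indicator_table(9, 4, seed = 13)
  z <- standardize_minmax(tab)
  w <- rep(0.25, 4)
  ideals <- list(positive = rep(1, 4), negative = rep(0, 4))
  pick <- which(z[, 1] > 0.05 & z[, 1] < 0.95)[1]
  d0 <- topsis_distances(z, w, ideals)
  t0 <- closeness(d0$d_plus, d0$d_minus)[pick]
  z2 <- unclass(z)
  z2[pick, 1] <- z2[pick, 1] + 0.04  # still inside (0, 1)
  class(z2) <- class(z)
  d1 <- topsis_distances(z2, w, ideals)
  t1 <- closeness(d1$d_plus, d1$d_minus)[pick]
  expect_gt(t1, t0)
})

test_that("an object dominant in every indicator gets closeness 1, rank 1", {
  set.seed(21)
  vals <- matrix(runif(24, 1, 10), 8, 3)
  vals <- rbind(vals, apply(vals, 2, max) + 1)
  rownames(vals) <- paste0("o", 1:9)
  colnames(vals) <- paste0("x", 1:3)
  ev <- ewm_topsis(indicator_table(vals, "benefit"))
  expect_equal(ev$result$closeness[9], 1)
  expect_equal(ev$result$rank[9], 1)
})
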