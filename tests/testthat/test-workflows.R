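test_that("NRMSE is zero at identity and reduces to error/range for uniform errors", {
  Ms <- cbind(seq(-10, 10, length.out = 21))
  expect_equal(nrmse(Ms, Ms), 0)
  expect_equal(nrmse(Ms + 1, Ms), 5.0)
  # invariance to node order
  o <- sample(21)
  expect_equal(nrmse(Ms[o, , drop = FALSE] + 1, Ms[o, , drop = FALSE]), 5.0)
  expect_error(nrmse(Ms * 0, Ms * 0), "constant")
  expect_error(nrmse(list(Ms), list()), "matched")
})

test_that("the upper NRMSE limit follows the 5%-of-range recipe", {
  # all per-DOF ranges equal to the global range -> exactly 5%
  M1 <- cbind(a = seq(-50, 50, length.out = 30),
              b = seq(50, -50, length.out = 30))
  expect_equal(nrmse_upper_limit(list(M1)), 5.0, tolerance = 1e-12)
  # two DOFs with ranges {D, D/2}: closed-form 5 * sqrt(0.625)
  M2 <- cbind(a = seq(-50, 50, length.out = 30),
              b = seq(-25, 25, length.out = 30))
  expect_equal(nrmse_upper_limit(list(M2)), 5 * sqrt((1 + 0.25) / 2),
               tolerance = 1e-12)
  expect_equal(5 * sqrt(0.625), 3.9528, tolerance = 1e-4)
})

test_that("the lower NRMSE limit equals 100 over the global moment range", {
  M <- cbind(seq(-100, 100, length.out = 25)) # range 200 N m
  expect_equal(nrmse_lower_limit(list(M)), 0.5, tolerance = 1e-12)
  expect_equal(nrmse_lower_limit(list(M / 2)), 1.0, tolerance = 1e-12)
  # property: matches the closed form for random trial sets
  set.seed(3)
  for (rep in 1:5) {
    Ms <- lapply(1:2, function(s) matrix(rnorm(40, sd = 30), 10, 4))
    rng <- diff(range(unlist(Ms)))
    expect_equal(nrmse_lower_limit(Ms), 100 / rng, tolerance = 1e-10)
  }
})

test_that("the upper limit is independent of the DOF and node bookkeeping", {
  # equal per-DOF ranges at different node counts give the same limit
  M1 <- cbind(seq(-40, 40, length.out = 12))
  M2 <- cbind(seq(-40, 40, length.out = 57))
  expect_equal(nrmse_upper_limit(list(M1)), nrmse_upper_limit(list(M2)),
               tolerance = 1e-12)
})

test_that("synergy-count selection takes the largest count inside the band", {
  lim <- list(lower = 0.51, upper = 2.38)
  expect_equal(as.integer(select_num_synergies(
    c(`3` = 3.1, `4` = 1.43, `5` = 0.45), lim)), 4L)
  expect_equal(as.integer(select_num_synergies(
    c(`3` = 3.1, `4` = 1.43, `5` = 0.60), lim)), 5L)
  expect_error(select_num_synergies(c(`3` = 5.0), lim), "no admissible")
  # invariant to key order
  expect_equal(as.integer(select_num_synergies(
    c(`5` = 0.45, `3` = 3.1, `4` = 1.43), lim)), 4L)
  # boundary values are outside the strict interior
  expect_error(select_num_synergies(c(`3` = 2.38), lim), "no admissible")
})

test_that("the activation-cost threshold follows its printed definition", {
  A <- matrix(0.01, 3, 5)
  expect_equal(delta_threshold(list(A)), 0)
  A[2, 3] <- 0.5
  expect_equal(delta_threshold(list(A)), 0.5^2 - 0.49^2)
  expect_equal(0.5^2 - 0.49^2, 0.0099)
  # monotone non-decreasing in any single activation above 0.02
  vals <- vapply(seq(0.02, 1, by = 0.01), function(a) {
    A[2, 3] <- a; delta_threshold(list(A))
  }, 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("the effort-sweep decision rule fires at the first insignificant drop", {
  r <- syntorq:::select_k_from_costs(c(0, 100, 200), c(10, 6, 5.95),
                                     c(3, 0.2, 0.1))
  expect_equal(r$chosen, 100)
  expect_false(r$exhausted)
  r2 <- syntorq:::select_k_from_costs(c(0, 100, 200), c(10, 6, 2),
                                      c(0.5, 0.5, 0.5))
  expect_equal(r2$chosen, 200)
  expect_true(r2$exhausted)
})

test_that("joint-moment dimensionality counts principal components", {
  set.seed(8)
  basis <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]
  scores <- matrix(rnorm(400), 200, 2) %*% diag(c(2, 1.5))
  X2 <- scores %*% t(basis) # exactly 2-dimensional in 5-D
  expect_equal(as.integer(moment_dimensionality(list(X2), 0.9)), 2L)
  Xi <- matrix(rnorm(5 * 4000), ncol = 5) # isotropic
  expect_equal(as.integer(moment_dimensionality(list(Xi), 0.9)), 5L)
  Xf <- matrix(rnorm(500), 100, 5)
  expect_equal(as.integer(moment_dimensionality(list(Xf), 1.0)), 5L)
  expect_error(moment_dimensionality(list(matrix(rnorm(9), 3))), "samples")
  v <- attr(moment_dimensionality(list(Xi), 0.9), "variance")
  expect_equal(sum(v), 1)
})

test_that("multi-start returns the minimum-NRMSE start deterministically", {
  fx <- tiny_fixture()
  # with polishing and the consistency filter disabled, the winner is the
  # plain minimum-NRMSE start
  plain <- pure_synergy_solve(fx$trials, fx$plant$muscles, n_syn = 2,
                              n_starts = 3, seed = 21, n_polish = 0,
                              consistency_tol = Inf)
  expect_equal(plain$nrmse, min(plain$per_start_nrmse, na.rm = TRUE))
  # the full protocol records the winner's forward error and never
  # returns a solution worse than its own screened value
  res <- memo("tiny_multistart", {
    pure_synergy_solve(fx$trials, fx$plant$muscles, n_syn = 2,
                       n_starts = 3, seed = 21)
  })
  expect_true(is.finite(res$forward_nrmse) || res$consistency_fallback)
  expect_lte(res$nrmse, max(res$per_start_nrmse, na.rm = TRUE))
  one <- pure_synergy_solve(fx$trials, fx$plant$muscles, n_syn = 2,
                            n_starts = 1, seed = 21)
  one2 <- pure_synergy_solve(fx$trials, fx$plant$muscles, n_syn = 2,
                             n_starts = 1, seed = 21)
  expect_identical(one$z, one2$z)
  expect_identical(one$nrmse, one2$nrmse)
})

test_that("frozen-weight validation keeps W bitwise and fits a seen condition", {
  fx <- tiny_fixture()
  base <- memo("tiny_multistart", {
    pure_synergy_solve(fx$trials, fx$plant$muscles, n_syn = 2,
                       n_starts = 3, seed = 21)
  })
  W <- base$structure$W
  val <- validate_fixed_weights(fx$trials, W, fx$plant$muscles,
                                n_starts = 2, seed = 31)
  expect_identical(val$structure$W, W)
  # a feasible incumbent exists: the training solution itself
  expect_lte(val$nrmse, base$nrmse + 0.5)
})
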