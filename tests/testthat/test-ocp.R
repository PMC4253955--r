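test_that("joint moments are the moment-arm-weighted sums of muscle forces", {
  R <- cbind(c(0.05, -0.02))
  expect_equal(joint_moments(c(100, 50), R), 4.0)
  expect_equal(joint_moments(c(0, 0), R), 0)
  # linearity in a single muscle's force
  R2 <- matrix(c(0.05, -0.02, 0.01, 0.03), 2, 2)
  m1 <- joint_moments(c(100, 50), R2)
  m2 <- joint_moments(c(200, 50), R2)
  expect_equal(m2 - m1, 100 * R2[1, ])
  expect_error(joint_moments(c(1, 2, 3), R2), "shape mismatch")
})

test_that("the discretized cost reduces to its printed form", {
  expect_equal(cost_function(matrix(5), matrix(5), matrix(0.4), K = 0), 0)
  # single node, single DOF, 2 N m error, one muscle a = 0.5, K = 200
  expect_equal(cost_function(matrix(3), matrix(1), matrix(0.5), K = 200), 54)
  # non-negative penalty: K > 0 never decreases the cost
  M <- matrix(rnorm(6), 3); Ms <- matrix(rnorm(6), 3); A <- matrix(0.3, 3, 4)
  expect_gte(cost_function(M, Ms, A, K = 10), cost_function(M, Ms, A, K = 0))
  expect_error(cost_function(matrix(1), matrix(1:2, 1), matrix(0.5)),
               "shapes differ")
})

test_that("transcription produces the documented decision vector and defects", {
  # 1 muscle, 1 DOF, 1 synergy, 2 nodes:
  # decision vector = 1 (W) + 2 (h) + 2 (a) + 2 (l), defects = 2
  p1 <- muscle_set("m", f_max = 1000, l_opt = 0.1, l_slack = 0.2)
  tt <- c(0, 0.05)
  arms <- array(0.05, c(2, 1, 1), dimnames = list(NULL, "m", "d1"))
  tr <- trial_data("c", tt, cbind(d1 = c(10, 12)),
                   cbind(m = c(0.31, 0.312)), arms, c(0, 0.05))
  nlp <- transcribe(ocp_spec(list(tr), p1, n_syn = 1))
  expect_equal(nlp$n_var, 7L)
  cc <- nlp_constraints(nlp, rep(0.5, 7))
  expect_equal(length(unlist(cc)), 2L)
  # two conditions share only W: their index blocks are disjoint
  fx <- tiny_fixture()
  spec2 <- plant_spec(n_muscles = 4, n_dofs = 2,
                      conditions = list(list(period = 1, n_cycles = 1),
                                        list(period = 0.8, n_cycles = 1)),
                      seed = 5)
  fx2 <- synthetic_fixture(seed = 5, n_syn = 2, points = 8, spec = spec2)
  nlp2 <- transcribe(ocp_spec(fx2$trials, fx2$plant$muscles, n_syn = 2))
  idx1 <- unlist(nlp2$conds[[1]][c("iH", "iA", "iL")])
  idx2 <- unlist(nlp2$conds[[2]][c("iH", "iA", "iL")])
  expect_length(intersect(idx1, idx2), 0)
})

test_that("compiled and reference reduced evaluations agree", {
  fx <- tiny_fixture()
  nlp <- transcribe(ocp_spec(fx$trials, fx$plant$muscles, n_syn = 2,
                             K = 50))
  cn <- nlp$conds[[1]]
  set.seed(4)
  u <- matrix(runif(nlp$m * cn$P, 0.05, 0.7), nlp$m)
  a1 <- runif(4, 0.05, 0.5); l1 <- runif(4, 0.9, 1.1)
  er <- syntorq:::.reduced_cond_eval_r(nlp, cn, u, a1, l1, 500, TRUE)
  ec <- syntorq:::.reduced_cond_eval(nlp, cn, u, a1, l1, 500, TRUE)
  expect_equal(ec$value, er$value, tolerance = 1e-10)
  expect_equal(ec$GU, er$GU, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(as.numeric(ec$g_a1), as.numeric(er$g_a1), tolerance = 1e-7)
  expect_equal(as.numeric(ec$g_l1), as.numeric(er$g_l1), tolerance = 1e-7)
  expect_equal(ec$A, er$states$A, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the adjoint gradient matches finite differences of the objective", {
  fx <- tiny_fixture()
  nlp <- transcribe(ocp_spec(fx$trials, fx$plant$muscles, n_syn = 2,
                             K = 100))
  cn <- nlp$conds[[1]]
  set.seed(9)
  W <- matrix(runif(8, 0, 0.8), 4)
  H <- matrix(runif(2 * cn$P, 0.05, 0.6), 2)
  u0 <- W %*% H
  a1 <- runif(4, 0.05, 0.6); l1 <- runif(4, 0.9, 1.1)
  ev <- syntorq:::.reduced_cond_eval(nlp, cn, u0, a1, l1, 1000, TRUE)
  val <- function(u, a, l)
    syntorq:::.reduced_cond_eval(nlp, cn, u, a, l, 1000, FALSE)$value
  h <- 1e-7
  idx <- sample(length(u0), 12)
  for (i in idx) {
    up <- u0; um <- u0; up[i] <- up[i] + h; um[i] <- um[i] - h
    gn <- (val(up, a1, l1) - val(um, a1, l1)) / (2 * h)
    expect_equal(ev$GU[i], gn, tolerance = 1e-4)
  }
  for (i in 1:4) {
    ap <- a1; am <- a1; ap[i] <- ap[i] + h; am[i] <- am[i] - h
    expect_equal(ev$g_a1[i], (val(u0, ap, l1) - val(u0, am, l1)) / (2 * h),
                 tolerance = 1e-4)
    lp <- l1; lm <- l1; lp[i] <- lp[i] + h; lm[i] <- lm[i] - h
    expect_equal(ev$g_l1[i], (val(u0, a1, lp) - val(u0, a1, lm)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("solving a self-generated problem converges to near-zero cost", {
  fx <- tiny_fixture()
  spec <- ocp_spec(fx$trials, fx$plant$muscles, n_syn = 2)
  nlp <- transcribe(spec)
  guess <- make_initial_guess("sine", fx$trials, 2, seed = 6,
                              muscle_params = fx$plant$muscles)
  # replace the experimental moments by the moments the guess itself
  # produces under the defect recursion: the guess is then optimal
  z0 <- syntorq:::pack_guess(nlp, guess)
  uz <- syntorq:::unpack_z(nlp, z0)
  trials2 <- fx$trials
  for (s in seq_along(nlp$conds)) {
    cn <- nlp$conds[[s]]
    fwd <- syntorq:::.forward_pass(nlp, cn, uz$W %*% uz$conds[[s]]$H,
                                   uz$conds[[s]]$A[, 1],
                                   uz$conds[[s]]$Lh[, 1])
    mm <- syntorq:::.cond_moments(nlp, cn, fwd$Lh)
    trials2[[s]]$moments <- t(mm$M)
    colnames(trials2[[s]]$moments) <- colnames(fx$trials[[s]]$moments)
  }
  nlp2 <- transcribe(ocp_spec(trials2, fx$plant$muscles, n_syn = 2))
  res <- solve_ocp(nlp2, guess)
  expect_lt(res$objective, 1e-3)
  expect_lt(res$nrmse, 5e-2)
  # determinism: identical guess and options give identical results
  res2 <- solve_ocp(nlp2, guess)
  expect_identical(res$z, res2$z)
  expect_identical(res$nrmse, res2$nrmse)
  # descent: the solution is no worse than the (already optimal) guess
  g_cost <- cost_function(trials2[[1]]$moments, trials2[[1]]$moments,
                          matrix(0), K = 0)
  expect_lte(res$moment_cost, g_cost + 1e-3)
})

test_that("solutions satisfy defects, bounds and audit contracts", {
  fx <- tiny_fixture()
  res <- memo("tiny_solve", {
    solve_decomposition(fx$trials, fx$plant$muscles, n_syn = 2, seed = 8)
  })
  expect_lt(res$feasibility, 1e-8)
  # reported NRMSE equals recomputation from stored moments
  expect_equal(res$nrmse,
               nrmse(res$moments, res$experimental_moments))
  # objective reproducible through the exported cost function
  A <- lapply(res$states, `[[`, "A")
  expect_equal(res$objective,
               cost_function(res$moments, res$experimental_moments,
                             A, K = res$K),
               tolerance = 1e-8)
  # non-negativity and excitation bounds
  expect_true(all(res$structure$W >= 0))
  expect_true(all(sapply(res$structure$H, min) >= 0))
  u <- combine(res$structure$W, res$structure$H[[1]])
  expect_true(all(u >= 0.01 - 1e-6 & u <= 1 + 1e-6))
  # states within their box bounds (small slack for the recursion)
  for (st in res$states) {
    expect_true(all(st$A >= 0.01 - 1e-4 & st$A <= 1 + 1e-4))
  }
})

test_that("the defect recursion matches an independent trapezoidal integrator", {
  fx <- tiny_fixture()
  nlp <- transcribe(ocp_spec(fx$trials, fx$plant$muscles, n_syn = 2))
  cn <- nlp$conds[[1]]
  ts <- fx$truth_structure
  u <- ts$W %*% ts$H[[1]]
  a0 <- fx$truth$initial_states[[1]]$a
  l0 <- fx$truth$initial_states[[1]]$l
  fwd <- syntorq:::.forward_pass(nlp, cn, u, a0, l0 / nlp$p$l_opt)
  ref <- trapezoid_reference(ts$W, ts$H[[1]], cn$t,
                             cn$Lmt, a0, l0, fx$plant$muscles)
  expect_equal(fwd$A, ref$A, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fwd$Lh * nlp$p$l_opt, ref$L, tolerance = 1e-7,
               ignore_attr = TRUE)
})
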