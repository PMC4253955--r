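test_that("plants are deterministic, periodic and bidirectionally actuated", {
  spec <- plant_spec(seed = 42)
  p1 <- make_plant(spec)
  p2 <- make_plant(plant_spec(seed = 42))
  tt <- seq(0, 1, by = 0.1)
  expect_identical(p1$conditions[[1]]$lmt_fun(tt),
                   p2$conditions[[1]]$lmt_fun(tt))
  expect_identical(p1$conditions[[2]]$arm_fun(tt),
                   p2$conditions[[2]]$arm_fun(tt))
  for (cn in p1$conditions) {
    # periodicity over one gait cycle
    expect_lt(max(abs(cn$lmt_fun(0) - cn$lmt_fun(cn$period))), 1e-12)
    expect_lt(max(abs(cn$arm_fun(0) - cn$arm_fun(cn$period))), 1e-12)
    # every DOF actuated in both directions
    r0 <- cn$coef$r0
    for (j in seq_len(ncol(r0))) {
      expect_true(any(r0[, j] > 0))
      expect_true(any(r0[, j] < 0))
    }
    # moment-arm magnitudes within the stated envelope
    expect_lt(max(abs(cn$arm_fun(seq(0, cn$period, by = 0.01)))), 0.06)
  }
})

test_that("ground-truth excitations respect the admissible band", {
  fx <- default_fixture()
  for (s in seq_along(fx$truth_structure$H)) {
    u <- combine(fx$truth_structure$W, fx$truth_structure$H[[s]])
    expect_gt(min(u), 0.02)
    expect_lt(max(u), 0.95)
  }
  # the weighting matrix is shared across conditions by construction
  expect_identical(ncol(fx$truth_structure$W), 3L)
})

test_that("factorizing the true excitations recovers the true weightings", {
  fx <- default_fixture()
  U <- do.call(cbind, lapply(fx$truth_structure$H, function(h)
    combine(fx$truth_structure$W, h)))
  f <- nnmf(U, 3, seed = 5)
  got <- match_synergies(f$W, fx$truth_structure$W)
  expect_gt(mean(attr(got, "si")), 0.95)
})

test_that("generated trials close the loop on re-simulation under the truth", {
  fx <- default_fixture()
  init <- lapply(fx$truth$initial_states, function(s) list(a = s$a, l = s$l))
  sim <- integrate_synergy(fx$truth_structure, fx$trials,
                           initial_states = init,
                           muscle_params = fx$plant$muscles)
  expect_lt(nrmse(lapply(sim, `[[`, "M"),
                  lapply(fx$trials, `[[`, "moments")), 0.1)
})

test_that("moment noise is calibrated to the per-DOF ranges", {
  fx <- default_fixture()
  clean <- fx$trials
  noisy <- generate_trials(fx$truth, fx$plant, points = 36, noise = 0.02,
                           seed = 77)
  # expected NRMSE of N(0, (0.02 range_sj)^2) noise against the clean
  # moments: 2% scaled by the rms of per-condition, per-DOF range ratios
  ratios <- unlist(lapply(clean, function(tr)
    apply(tr$moments, 2, function(x) diff(range(x)))))
  rng_glob <- diff(range(sapply(clean, function(tr) range(tr$moments))))
  expect_equal(nrmse(lapply(noisy, `[[`, "moments"),
                     lapply(clean, `[[`, "moments")) / 2,
               sqrt(mean((ratios / rng_glob)^2)),
               tolerance = 0.2)
  # determinism of the noise draw
  noisy2 <- generate_trials(fx$truth, fx$plant, points = 36, noise = 0.02,
                            seed = 77)
  expect_identical(noisy[[1]]$moments, noisy2[[1]]$moments)
})

test_that("fixtures are reproducible end to end from one seed", {
  f1 <- tiny_fixture()
  spec <- plant_spec(n_muscles = 4, n_dofs = 2,
                     conditions = list(list(period = 1.0, n_cycles = 1)),
                     seed = 3)
  f2 <- synthetic_fixture(seed = 3, n_syn = 2, points = 12, spec = spec)
  expect_identical(f1$trials[[1]]$moments, f2$trials[[1]]$moments)
  expect_identical(f1$truth_structure$W, f2$truth_structure$W)
})

test_that("plant specification invariants are enforced", {
  expect_error(plant_spec(n_muscles = 3, n_dofs = 3), "exceed")
  expect_error(plant_spec(noise = -0.1), "noise")
  expect_error(plant_spec(conditions = list(list(period = -1,
                                                 n_cycles = 1))),
               "period")
})
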