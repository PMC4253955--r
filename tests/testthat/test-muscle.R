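test_that("activation rate is zero at steady state and tracks the excitation", {
  p <- tiny_muscles()
  expect_equal(activation_derivative(c(0.3, 0.3), c(0.3, 0.3), p), c(0, 0))
  expect_true(all(activation_derivative(c(0.1, 0.1), c(0.9, 0.9), p) > 0))
  expect_true(all(activation_derivative(c(0.9, 0.9), c(0.1, 0.1), p) < 0))
  # rate magnitudes follow the regime-specific time constants
  p1 <- muscle_set("m", f_max = 1000, l_opt = 0.1, l_slack = 0.2,
                   tau_act = 0.015, tau_deact = 0.05)
  expect_equal(activation_derivative(0.5, 0.2, p1), (0.2 - 0.5) / 0.05)
  expect_equal(activation_derivative(0.2, 0.5, p1), (0.5 - 0.2) / 0.015)
})

test_that("activation inputs outside [0.01, 1] raise a domain error", {
  p <- tiny_muscles()
  expect_error(activation_derivative(c(0.005, 0.5), c(0.5, 0.5), p),
               "a = 0.005")
  expect_error(activation_derivative(c(0.5, 0.5), c(1.2, 0.5), p),
               "u = 1.2")
})

test_that("integrating the activation law converges to the excitation", {
  p <- tiny_muscles()
  for (u in c(0.05, 0.4, 0.95)) {
    a <- c(0.9, 0.02)
    tend <- 10 * max(p$tau_act, p$tau_deact)
    dt <- 1e-3
    for (i in seq_len(round(tend / dt)))
      a <- a + dt * activation_derivative(a, rep(u, 2), p)
    expect_lt(max(abs(a - u)), 1e-4)
  }
})

test_that("tendon force is zero when slack and f_max exactly at eps_t_max", {
  p <- tiny_muscles()
  expect_equal(tendon_force(c(-0.01, -0.01), p), c(0, 0))
  expect_equal(tendon_force(c(0, 0), p), c(0, 0))
  at_max <- tendon_force(p$eps_t_max, p)
  expect_equal(at_max, p$f_max, tolerance = 1e-6)
})

test_that("tendon curve is continuous, non-decreasing and matches its closed form", {
  p1 <- muscle_set("m", f_max = 1000, l_opt = 0.1, l_slack = 0.2,
                   eps_t_max = 0.04)
  eps <- seq(-0.01, 0.08, by = 1e-4)
  f <- vapply(eps, function(e) tendon_force(e, p1), 0)
  expect_true(all(diff(f) >= 0))
  expect_lt(max(abs(diff(f))), 6) # no jumps on a 1e-4 grid
  # independent closed-form evaluation at a toe-region strain
  k <- muscle_curve_constants()
  eps_toe <- k$toe_frac * 0.04
  expected <- 1000 * k$ftoe / (exp(k$ktoe) - 1) *
    (exp(k$ktoe * 0.02 / eps_toe) - 1)
  expect_equal(tendon_force(0.02, p1), expected, tolerance = 1e-12)
  expect_equal(expected, 185.7115, tolerance = 1e-4) # frozen regression value
})

test_that("fiber equilibrium force reproduces definitional geometry cases", {
  p1 <- muscle_set("m", f_max = 1000, l_opt = 0.1, l_slack = 0.2,
                   alpha_opt = 0, eps_t_max = 0.04)
  expect_equal(fiber_equilibrium_force(0.1, 0.1 + 0.2 * 1.04, p1), 1000,
               tolerance = 1e-6)
  expect_equal(fiber_equilibrium_force(0.1, 0.1 + 0.2, p1), 0)
  expect_error(fiber_equilibrium_force(0.1, 0.05, p1), "tendon length")
})

test_that("pennated equilibrium force matches hand-computed geometry", {
  p1 <- muscle_set("m", f_max = 1200, l_opt = 0.1, l_slack = 0.2,
                   alpha_opt = 0.1, eps_t_max = 0.04)
  l <- 0.09; l_mt <- 0.32
  # constant-thickness pennation: l sin(alpha) = l_opt sin(alpha_opt)
  sin_a <- 0.1 * sin(0.1) / l
  lt <- l_mt - l * sqrt(1 - sin_a^2)
  eps <- lt / 0.2 - 1
  expect_equal(fiber_equilibrium_force(l, l_mt, p1),
               tendon_force(eps, p1), tolerance = 1e-12)
})

test_that("fiber velocity vanishes at isometric equilibrium and has the right sign", {
  p <- tiny_muscles()
  a <- c(0.6, 0.3)
  l_mt <- c(0.32, 0.29)
  l_eq <- equilibrium_fiber_length(a, l_mt, p)
  expect_lt(max(abs(fiber_velocity(a, l_eq, l_mt, p))), 1e-7)
  # tendon force below isometric capability -> fiber shortens
  expect_true(all(fiber_velocity(a, l_eq, l_mt - 0.005, p) < 0))
  # above -> lengthens
  expect_true(all(fiber_velocity(a, l_eq, l_mt + 0.005, p) > 0))
})

test_that("fiber velocity matches a bisection oracle on the force-velocity curve", {
  # oracle: bisect the normalized velocity so that the hyperbolic
  # force-velocity multiplier reproduces the demanded active force
  p1 <- muscle_set("m", f_max = 1000, l_opt = 0.1, l_slack = 0.2,
                   alpha_opt = 0, eps_t_max = 0.04)
  k <- muscle_curve_constants()
  fl_act <- function(ln) exp(-(ln - 1)^2 / k$gamma)
  fl_pas <- function(ln) if (ln > 1)
    (exp(k$kpe * (ln - 1) / k$eps_m0) - 1) / (exp(k$kpe) - 1) else 0
  # forward force-velocity: active force as a function of velocity
  f_of_v <- function(v, a, fl) {
    afl <- max(a * fl, 1e-6); kap <- (0.25 + 0.75 * a) * 10
    cc <- (2 + 2 / k$af) / (k$flen - 1)
    if (v <= 0) afl * (kap + v) / (kap - v / k$af)
    else afl * (kap + v * cc * k$flen) / (kap + v * cc)
  }
  for (case in list(c(a = 0.5, l = 0.095, lmt = 0.307),
                    c(a = 0.8, l = 0.105, lmt = 0.3095),
                    c(a = 0.2, l = 0.1, lmt = 0.306))) {
    a <- unname(case["a"]); l <- unname(case["l"]); lmt <- unname(case["lmt"])
    fse <- tendon_force(max((lmt - l) / 0.2 - 1, -1), p1) / 1000
    fact <- max(fse - fl_pas(l / 0.1), 0)
    fl <- fl_act(l / 0.1)
    kap <- (0.25 + 0.75 * a) * 10
    # only exercise states inside the plain branches of the curve
    if (fact > 0.95 * k$flen * a * fl) next
    lo <- -kap + 1e-9; hi <- kap * 2
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f_of_v(mid, a, fl) < fact) lo <- mid else hi <- mid
    }
    oracle_v <- (lo + hi) / 2 * 0.1 # m/s
    expect_equal(unname(fiber_velocity(a, l, lmt, p1)), oracle_v,
                 tolerance = 1e-8)
  }
})

test_that("forward integration under constant inputs reaches a fixed point", {
  p <- tiny_muscles()
  a <- c(0.1, 0.7); l <- c(0.105, 0.085); l_mt <- c(0.315, 0.285)
  u <- c(0.5, 0.3)
  dt <- 2e-4
  for (i in seq_len(25000)) {
    a <- pmin(pmax(a + dt * activation_derivative(a, u, p), 0.01), 1)
    l <- l + dt * fiber_velocity(a, l, l_mt, p)
  }
  expect_lt(max(abs(a - u)), 1e-5)
  expect_lt(max(abs(fiber_velocity(a, l, l_mt, p))), 1e-5)
})

test_that("muscle outputs stay finite over a randomized admissible sweep", {
  set.seed(42)
  for (rep in 1:20) {
    p <- muscle_set("m", f_max = runif(1, 100, 5000),
                    l_opt = runif(1, 0.05, 0.3),
                    alpha_opt = runif(1, 0, 0.4),
                    l_slack = runif(1, 0.05, 0.5),
                    eps_t_max = runif(1, 0.02, 0.12),
                    v_max = runif(1, 4, 15),
                    tau_act = runif(1, 0.005, 0.05),
                    tau_deact = runif(1, 0.02, 0.12))
    a <- runif(1, 0.01, 1)
    l <- runif(1, 0.3, 1.7) * p$l_opt
    l_mt <- l * cos(p$alpha_opt) + p$l_slack * runif(1, 0.9, 1.15)
    expect_true(is.finite(fiber_velocity(a, l, l_mt, p)))
    expect_true(is.finite(fiber_equilibrium_force(l, l_mt, p)))
    expect_true(is.finite(activation_derivative(a, runif(1, 0.01, 1), p)))
  }
})

test_that("normalized fiber-length clamps are counted", {
  p <- tiny_muscles()
  fiber_length_clamp_count(reset = TRUE)
  invisible(fiber_velocity(c(0.5, 0.5), c(0.002, 0.10), c(0.31, 0.29), p))
  expect_gte(fiber_length_clamp_count(), 1)
  fiber_length_clamp_count(reset = TRUE)
})

test_that("muscle parameter invariants are enforced and tables round-trip", {
  expect_error(muscle_set("m", f_max = -1, l_opt = 0.1, l_slack = 0.2),
               "f_max")
  expect_error(muscle_set("m", f_max = 10, l_opt = 0.1, l_slack = 0.2,
                          eps_t_max = 1.5), "eps_t_max")
  expect_error(muscle_set("m", f_max = 10, l_opt = 0.1, l_slack = 0.2,
                          alpha_opt = 2), "alpha_opt")
  p <- tiny_muscles()
  path <- withr::local_tempfile(fileext = ".csv")
  write_muscle_csv(p, path)
  p2 <- read_muscle_csv(path)
  expect_equal(as.data.frame(p), as.data.frame(p2))
})
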