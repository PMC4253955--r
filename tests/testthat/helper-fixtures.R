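# lazily built, memoized fixtures shared across test files
.tcache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .tcache)) assign(key, expr, envir = .tcache)
  get(key, envir = .tcache)
}

# small two-muscle parameter table for unit tests
tiny_muscles <- function() {
  muscle_set(name = c("flexor", "extensor"),
             f_max = c(1000, 1500), l_opt = c(0.10, 0.09),
             alpha_opt = c(0, 0.1), l_slack = c(0.20, 0.18),
             eps_t_max = c(0.04, 0.10))
}

# 4-muscle / 2-DOF / 1-condition desk fixture for solver unit tests
tiny_fixture <- function() {
  memo("tiny_fixture", {
    spec <- plant_spec(n_muscles = 4, n_dofs = 2,
                       conditions = list(list(period = 1.0, n_cycles = 1)),
                       seed = 3)
    synthetic_fixture(seed = 3, n_syn = 2, points = 12, spec = spec)
  })
}

# default acceptance-scale fixture (8 muscles, 3 DOFs, 2 conditions)
default_fixture <- function() {
  memo("default_fixture", synthetic_fixture(seed = 1))
}

# hand-rolled trapezoidal integrator of the muscle dynamics: independent
# oracle for defect-consistent trajectories (scalar Brent root-finding on
# each implicit step, one muscle at a time)
trapezoid_reference <- function(W, H, times, lmt, a0, l0, params) {
  p <- as.list(params)
  m <- nrow(lmt); P <- length(times)
  A <- matrix(0, m, P); L <- matrix(0, m, P)
  A[, 1] <- a0; L[, 1] <- l0
  u <- W %*% H
  rate_a <- function(a, uu, i)
    (uu - a) / if (uu > a) p$tau_act[i] else p$tau_deact[i]
  for (n in seq_len(P - 1)) {
    dt <- times[n + 1] - times[n]
    for (i in seq_len(m)) {
      pi1 <- params[i, , drop = FALSE]
      an <- A[i, n]; ln <- L[i, n]
      fa_n <- rate_a(an, u[i, n], i)
      fl_n <- fiber_velocity(min(max(an, 0.01), 1), ln, lmt[i, n], pi1)
      ga <- function(x) x - an - dt / 2 * (fa_n + rate_a(x, u[i, n + 1], i))
      A[i, n + 1] <- stats::uniroot(ga, c(0, 1.5), tol = 1e-14)$root
      gl <- function(x) x - ln - dt / 2 *
        (fl_n + fiber_velocity(min(max(A[i, n + 1], 0.01), 1), x,
                               lmt[i, n + 1], pi1))
      L[i, n + 1] <- stats::uniroot(gl, c(0.02, 3.5) * p$l_opt[i],
                                    tol = 1e-14)$root
    }
  }
  list(A = A, L = L)
}
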