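#' Hill-type muscle-tendon model
#'
#' The muscle model used throughout the package is a Hill-type
#' muscle-tendon unit with a Gaussian active force-length curve, an
#' exponential passive force-length curve, an exponential-toe/linear
#' tendon, a hyperbolic force-velocity relation evaluated in its inverted
#' (velocity-from-force) form, and a two-regime first-order activation
#' law. All curve constants are recorded in [muscle_curve_constants()] so
#' that the model is fully specified by this package.
#'
#' @name muscle_model
#' @keywords internal
NULL

# Curve shape constants (dimensionless). gamma: active force-length width;
# kpe / eps_m0: passive exponential shape and passive strain at f_max;
# ftoe / ktoe: normalized tendon force and exponential shape at the end of
# the toe region; toe_frac: fraction of eps_t_max where the toe region ends
# (the linear-region slope is then fixed by requiring the tendon to carry
# exactly f_max at eps_t_max); af: force-velocity shape; flen: eccentric
# force plateau; ecc_clamp: fraction of the eccentric asymptote beyond which
# the velocity-from-force curve is linearly extrapolated.
.mus_const <- list(
  gamma = 0.45,
  kpe = 5, eps_m0 = 0.6,
  ftoe = 0.33, ktoe = 3, toe_frac = 0.609,
  af = 0.25, flen = 1.4, ecc_clamp = 0.95,
  lnorm_min = 0.05, lnorm_max = 1.8
)

#' Curve constants of the muscle model
#'
#' Returns the dimensionless shape constants of the force-length,
#' force-velocity, passive and tendon curves used by all muscle-dynamics
#' functions. The linear-region tendon slope is not a free constant: it is
#' `(1 - ftoe) / (eps_t_max - toe_frac * eps_t_max)` so that tendon force
#' equals the maximum isometric force exactly at the strain `eps_t_max`.
#'
#' @return Named list of constants.
#' @export
muscle_curve_constants <- function() .mus_const

# package-local state: clamp counter for out-of-range normalized fiber
# lengths inside curve evaluations
.syntorq_state <- new.env(parent = emptyenv())
.syntorq_state$clamp_count <- 0L

#' Count of normalized fiber-length clamps
#'
#' Curve evaluations clamp the normalized fiber length to
#' \[0.05, 1.8\] to keep the model differentiable; each clamped value
#' increments a package-level counter.
#'
#' @param reset If `TRUE`, reset the counter to zero after reading.
#' @return Integer count of clamped evaluations since the last reset.
#' @export
fiber_length_clamp_count <- function(reset = FALSE) {
  n <- .syntorq_state$clamp_count
  if (reset) .syntorq_state$clamp_count <- 0L
  n
}

#' Construct a muscle parameter set
#'
#' One row per muscle. Invariants are checked on construction.
#'
#' @param name Character vector of muscle labels.
#' @param f_max Maximum isometric force, N.
#' @param l_opt Optimal fiber length, m.
#' @param alpha_opt Pennation angle at optimal fiber length, rad.
#' @param l_slack Tendon slack length, m.
#' @param eps_t_max Tendon strain at which tendon force equals `f_max`.
#' @param v_max Maximum contraction velocity, optimal fiber lengths per s.
#' @param tau_act,tau_deact Activation / deactivation time constants, s.
#' @return A `data.frame` of class `muscle_set`.
#' @export
muscle_set <- function(name, f_max, l_opt, alpha_opt = 0, l_slack,
                       eps_t_max = 0.04, v_max = 10,
                       tau_act = 0.015, tau_deact = 0.06) {
  p <- data.frame(name = as.character(name), f_max = f_max, l_opt = l_opt,
                  alpha_opt = alpha_opt, l_slack = l_slack,
                  eps_t_max = eps_t_max, v_max = v_max,
                  tau_act = tau_act, tau_deact = tau_deact,
                  stringsAsFactors = FALSE)
  validate_muscle_set(p)
  class(p) <- c("muscle_set", "data.frame")
  p
}

validate_muscle_set <- function(p) {
  stopifnot(is.data.frame(p))
  need <- c("name", "f_max", "l_opt", "alpha_opt", "l_slack", "eps_t_max",
            "v_max", "tau_act", "tau_deact")
  miss <- setdiff(need, names(p))
  if (length(miss) > 0)
    stop("muscle_set is missing columns: ", paste(miss, collapse = ", "))
  with(p, {
    if (any(f_max <= 0)) stop("f_max must be > 0")
    if (any(l_opt <= 0)) stop("l_opt must be > 0")
    if (any(l_slack < 0)) stop("l_slack must be >= 0")
    if (any(eps_t_max <= 0 | eps_t_max >= 1))
      stop("eps_t_max must lie in (0, 1)")
    if (any(alpha_opt < 0 | alpha_opt >= pi / 2))
      stop("alpha_opt must lie in [0, pi/2)")
    if (any(tau_act <= 0) || any(tau_deact <= 0))
      stop("activation time constants must be > 0")
    if (any(v_max <= 0)) stop("v_max must be > 0")
  })
  if (anyDuplicated(p$name)) stop("duplicate muscle names")
  invisible(p)
}

#' Read a muscle parameter table from CSV
#'
#' One row per muscle; columns named exactly as the `muscle_set` fields.
#'
#' @param path CSV file path.
#' @return A `muscle_set`.
#' @export
read_muscle_csv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  do.call(muscle_set, p[c("name", "f_max", "l_opt", "alpha_opt", "l_slack",
                          "eps_t_max", "v_max", "tau_act", "tau_deact")])
}

#' Write a muscle parameter table to CSV
#' @param params A `muscle_set`.
#' @param path Output path.
#' @export
write_muscle_csv <- function(params, path) {
  utils::write.csv(as.data.frame(params), path, row.names = FALSE)
  invisible(path)
}

# ---- internal vectorized curve evaluations -------------------------------
# All internal functions accept states as length-m vectors or m x P
# matrices; per-muscle parameters (length m) recycle down columns.

.clamp_lnorm <- function(lnorm) {
  k <- .mus_const
  out <- sum(lnorm < k$lnorm_min | lnorm > k$lnorm_max)
  if (out > 0)
    .syntorq_state$clamp_count <- .syntorq_state$clamp_count + out
  pmin(pmax(lnorm, k$lnorm_min), k$lnorm_max)
}

.fl_active <- function(lnorm) exp(-(lnorm - 1)^2 / .mus_const$gamma)

.fl_passive <- function(lnorm) {
  k <- .mus_const
  f <- (exp(k$kpe * (lnorm - 1) / k$eps_m0) - 1) / (exp(k$kpe) - 1)
  f[lnorm <= 1] <- 0
  f
}

# normalized tendon force as a function of strain (per-muscle eps_t_max)
.ft_norm <- function(eps, eps_t_max) {
  k <- .mus_const
  eps_toe <- k$toe_frac * eps_t_max
  klin <- (1 - k$ftoe) / (eps_t_max - eps_toe)
  f <- ifelse(eps <= eps_toe,
              k$ftoe / (exp(k$ktoe) - 1) *
                (exp(k$ktoe * eps / pmax(eps_toe, 1e-12)) - 1),
              k$ftoe + klin * (eps - eps_toe))
  f[eps <= 0] <- 0
  f
}

# cosine of the pennation angle under the constant-thickness relation
# l * sin(alpha(l)) = l_opt * sin(alpha_opt)
.cos_penn <- function(l, l_opt, alpha_opt) {
  h <- l_opt * sin(alpha_opt)
  s <- pmin(h / pmax(l, 1e-9), 0.9995)
  sqrt(1 - s^2)
}

.tendon_strain <- function(l, l_mt, p) {
  cosp <- .cos_penn(l, p$l_opt, p$alpha_opt)
  lt <- l_mt - l * cosp
  lt / p$l_slack - 1
}

# fiber force along the tendon, N (geometry-implied; internal, no checks)
.fiber_force <- function(l, l_mt, p) {
  p$f_max * .ft_norm(.tendon_strain(l, l_mt, p), p$eps_t_max)
}

# activation rate, two-regime first-order law (He et al. family)
.act_rate <- function(a, u, p) {
  tau <- ifelse(u > a, p$tau_act, p$tau_deact)
  (u - a) / tau
}

# fiber velocity dl/dt (m/s) from the inverted force-velocity relation.
# The active fiber-direction force demanded by tendon equilibrium is
#   f_active = F_T / (f_max cos(alpha)) - f_passive(lnorm),
# clamped to [0, ecc_clamp * flen * a * fl] with linear extrapolation of
# the velocity curve beyond the eccentric clamp.
.fiber_vel <- function(a, l, l_mt, p) {
  k <- .mus_const
  lnorm <- .clamp_lnorm(l / p$l_opt)
  cosp <- .cos_penn(l, p$l_opt, p$alpha_opt)
  fse <- .ft_norm(.tendon_strain(l, l_mt, p), p$eps_t_max) / cosp
  fl <- .fl_active(lnorm)
  fpe <- .fl_passive(lnorm)
  fact <- pmax(fse - fpe, 0)
  afl <- pmax(a * fl, 1e-6)
  kap <- (0.25 + 0.75 * a) * p$v_max
  cc <- (2 + 2 / k$af) / (k$flen - 1)
  fcap <- k$ecc_clamp * k$flen * afl

  conc <- fact <= afl
  b <- ifelse(conc, afl + fact / k$af, cc * (k$flen * afl - pmin(fact, fcap)))
  v <- kap * (pmin(fact, fcap) - afl) / b
  # linear extrapolation beyond the eccentric clamp, saturated at the
  # same magnitude as maximal shortening
  over <- fact > fcap
  if (any(over)) {
    b0 <- cc * (k$flen * afl - fcap)
    slope <- kap * (b0 + cc * (fcap - afl)) / b0^2
    v <- ifelse(over, pmin(v + slope * (fact - fcap), kap), v)
  }
  v * p$l_opt
}

.plist <- function(params) {
  stopifnot(inherits(params, "muscle_set") || is.data.frame(params))
  as.list(params)
}

# ---- exported operations -------------------------------------------------

#' Activation dynamics rate
#'
#' First-order activation dynamics with separate activation and
#' deactivation time constants: `da/dt = (u - a) / tau`, with
#' `tau = tau_act` when the excitation exceeds the activation and
#' `tau_deact` otherwise.
#'
#' @param a Activation, in `[0.01, 1]`. Vector (one per muscle) or matrix
#'   (muscles x time points).
#' @param u Excitation, in `[0.01, 1]`, same shape as `a`.
#' @param params A [muscle_set()].
#' @return `da/dt` in 1/s, same shape as `a`.
#' @export
activation_derivative <- function(a, u, params) {
  .check_unit_bounds(a, "a")
  .check_unit_bounds(u, "u")
  .act_rate(a, u, .plist(params))
}

.check_unit_bounds <- function(x, label, lo = 0.01, hi = 1, tol = 1e-9) {
  if (any(!is.finite(x))) stop("non-finite ", label)
  bad <- x < lo - tol | x > hi + tol
  if (any(bad))
    stop(sprintf("%s = %.6g outside [%g, %g]", label, x[which(bad)[1]],
                 lo, hi))
}

#' Tendon force from tendon strain
#'
#' Exponential-toe / linear tendon curve. Zero at or below zero strain,
#' strictly increasing for positive strain, and exactly `f_max` at the
#' strain `eps_t_max`.
#'
#' @param eps_t Tendon strain, dimensionless. Vector or matrix.
#' @param params A [muscle_set()].
#' @return Tendon force, N.
#' @export
tendon_force <- function(eps_t, params) {
  if (any(!is.finite(eps_t))) stop("non-finite tendon strain")
  p <- .plist(params)
  p$f_max * .ft_norm(eps_t, p$eps_t_max)
}

#' Muscle force implied by fiber geometry
#'
#' Computes the tendon length `L_mt - l * cos(alpha(l))` under the
#' constant-thickness pennation relation, converts it to tendon strain and
#' returns the tendon force. This is the model's static force-from-length
#' map: fiber and tendon force balance is implicit in the geometry.
#'
#' @param l Fiber length, m. Vector or matrix (muscles x time points).
#' @param l_mt Muscle-tendon length, m, same shape.
#' @param params A [muscle_set()].
#' @return Muscle force transmitted by the tendon, N.
#' @export
fiber_equilibrium_force <- function(l, l_mt, params) {
  if (any(l <= 0)) stop("fiber length must be > 0")
  if (any(l_mt <= 0)) stop("muscle-tendon length must be > 0")
  p <- .plist(params)
  cosp <- .cos_penn(l, p$l_opt, p$alpha_opt)
  lt <- l_mt - l * cosp
  if (any(lt <= 0))
    stop("geometrically impossible configuration: tendon length <= 0")
  p$f_max * .ft_norm(lt / p$l_slack - 1, p$eps_t_max)
}

#' Fiber velocity from the inverted force-velocity relation
#'
#' Solves the force balance between the active + passive fiber force along
#' the tendon and the geometry-implied tendon force for the fiber velocity,
#' using the closed-form inversion of the hyperbolic force-velocity curve.
#' Shortening is negative. At the isometric equilibrium the result is zero;
#' the magnitude is bounded by roughly `v_max * l_opt` on the concentric
#' side and by the eccentric plateau (with linear extrapolation beyond 95%
#' of the eccentric asymptote) on the lengthening side.
#'
#' @inheritParams fiber_equilibrium_force
#' @param a Activation in `[0.01, 1]`, same shape as `l`.
#' @return `dl/dt`, m/s.
#' @export
fiber_velocity <- function(a, l, l_mt, params) {
  .check_unit_bounds(a, "a")
  if (any(l <= 0)) stop("fiber length must be > 0")
  if (any(l_mt <= 0)) stop("muscle-tendon length must be > 0")
  .fiber_vel(a, l, l_mt, .plist(params))
}

#' Fiber length at isometric equilibrium
#'
#' Finds, per muscle, the fiber length at which the fiber velocity is zero
#' for a given activation and muscle-tendon length (safeguarded bisection
#' on the normalized fiber length).
#'
#' @param a Activation vector (length m).
#' @param l_mt Muscle-tendon length vector, m.
#' @param params A [muscle_set()].
#' @return Fiber length vector, m.
#' @export
equilibrium_fiber_length <- function(a, l_mt, params) {
  p <- .plist(params)
  m <- length(p$l_opt)
  a <- rep_len(a, m); l_mt <- rep_len(l_mt, m)
  k <- .mus_const
  out <- numeric(m)
  for (i in seq_len(m)) {
    pi1 <- lapply(p, `[`, i)
    g <- function(ln) {
      l <- ln * pi1$l_opt
      cosp <- .cos_penn(l, pi1$l_opt, pi1$alpha_opt)
      fse <- .ft_norm(.tendon_strain(l, l_mt[i], pi1), pi1$eps_t_max) / cosp
      fse - .fl_passive(ln) - a[i] * .fl_active(ln)
    }
    lo <- k$lnorm_min + 1e-3; hi <- k$lnorm_max - 1e-3
    glo <- g(lo); ghi <- g(hi)
    if (glo <= 0) { out[i] <- lo * pi1$l_opt; next }
    if (ghi >= 0) { out[i] <- hi * pi1$l_opt; next }
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    out[i] <- (lo + hi) / 2 * pi1$l_opt
  }
  out
}
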