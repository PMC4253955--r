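#' Forward integration of the synergy-driven muscle dynamics
#'
#' Integrates the muscle activation and contraction dynamics under
#' excitations produced by linear synergy combination, and maps the
#' resulting muscle forces through the experimental moment arms to joint
#' moments. This is the dynamic-consistency oracle for the collocation
#' solution and the moment generator of the synthetic plant.
#'
#' @name forward_simulation
#' @keywords internal
NULL

# fast row-wise linear interpolator: returns f(t) -> one value per row
.interp_rows <- function(x, Y) {
  funs <- lapply(seq_len(nrow(Y)), function(i)
    stats::approxfun(x, Y[i, ], rule = 2))
  function(t) vapply(funs, function(f) f(t), numeric(length(t)))
}

# integrate one condition. h_fun(t) -> synergy controls (length n),
# lmt_fun(t) -> muscle-tendon lengths (length m). y0 = c(a0, lnorm0).
.integrate_condition <- function(W, h_fun, lmt_fun, y0, p, times,
                                 rtol = 1e-7) {
  m <- length(p$l_opt)
  clamps <- 0L
  rhs <- function(t, y, parms) {
    a <- y[1:m]; lnorm <- y[m + 1:m]
    u <- drop(W %*% h_fun(t))
    nc <- sum(u < 0.01 | u > 1)
    if (nc > 0) clamps <<- clamps + nc
    u <- pmin(pmax(u, 0.01), 1)
    ac <- pmin(pmax(a, 0.01), 1)
    tau <- ifelse(u > ac, p$tau_act, p$tau_deact)
    da <- (u - ac) / tau
    dl <- .fiber_vel(ac, lnorm * p$l_opt, lmt_fun(t), p) / p$l_opt
    list(c(da, dl))
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = rtol * 1e-2)
  if (attr(sol, "istate")[1] < 0)
    stop("forward integration failed (lsoda istate ",
         attr(sol, "istate")[1], ")")
  A <- sol[, 1 + 1:m, drop = FALSE]
  Ln <- sol[, 1 + m + 1:m, drop = FALSE]
  if (any(!is.finite(A)) || any(!is.finite(Ln)) ||
      any(Ln < 0.02) || any(Ln > 2)) {
    bad <- which(!is.finite(Ln) | Ln < 0.02 | Ln > 2, arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(!is.finite(A), arr.ind = TRUE)
    stop(sprintf("state left the admissible region: muscle %d at t = %.4g s",
                 bad[1, 2], times[bad[1, 1]]))
  }
  list(time = times, A = A, Lnorm = Ln, clamps = clamps)
}

#' Forward-integrate a synergy structure over a set of trials
#'
#' Excitations are formed by [combine()] at every integrator step, with the
#' control signals linearly interpolated between their samples; states are
#' advanced by an adaptive integrator (lsoda); forces come from the static
#' fiber-force map and moments from the experimental moment arms. Outputs
#' are sampled on each trial's time grid.
#'
#' @param structure A [synergy_structure()] whose control samples span the
#'   trial time windows.
#' @param trials List of [trial_data()] objects.
#' @param initial_states Optional per-condition list with fields `a`
#'   (activations) and `l` (fiber lengths, m); defaults to the isometric
#'   equilibrium under the initial excitation.
#' @param muscle_params A [muscle_set()].
#' @param rtol Relative integration tolerance.
#' @return Per condition: `time`, `A` and `L` (time points x muscles:
#'   activation and fiber length), `F` (muscle forces, N), `M` (joint
#'   moments, time points x DOFs, N m) and the excitation clamp count.
#' @export
integrate_synergy <- function(structure, trials, initial_states = NULL,
                              muscle_params, rtol = 1e-7) {
  trials <- as_trial_list(trials)
  p <- .plist(muscle_params)
  m <- length(p$l_opt)
  out <- vector("list", length(trials))
  for (s in seq_along(trials)) {
    tr <- trials[[s]]
    H <- structure$H[[s]]; ts <- structure$time[[s]]
    h_fun <- .interp_rows(ts, H)
    lmt_fun <- .interp_rows(tr$time, t(tr$mt_lengths))
    if (is.null(initial_states)) {
      u0 <- pmin(pmax(drop(structure$W %*% h_fun(tr$time[1])), 0.01), 1)
      a0 <- u0
      l0 <- equilibrium_fiber_length(a0, lmt_fun(tr$time[1]), muscle_params)
    } else {
      a0 <- initial_states[[s]]$a
      l0 <- initial_states[[s]]$l
    }
    tt <- .integrate_condition(structure$W, h_fun, lmt_fun,
                               c(a0, l0 / p$l_opt), p, tr$time, rtol)
    L <- sweep(tt$Lnorm, 2, p$l_opt, "*")
    Fm <- t(.fiber_force(t(L), t(tr$mt_lengths), p))
    M <- matrix(0, length(tr$time), ncol(tr$moments),
                dimnames = list(NULL, colnames(tr$moments)))
    for (j in seq_len(ncol(M)))
      M[, j] <- rowSums(tr$moment_arms[, , j] * Fm)
    out[[s]] <- list(time = tr$time, A = tt$A, L = L, F = Fm, M = M,
                     clamps = tt$clamps, condition = tr$condition)
  }
  names(out) <- vapply(trials, `[[`, "", "condition")
  out
}

#' Dynamic-consistency check of a collocation solution
#'
#' Forward-integrates the governing dynamics from the solution's initial
#' states under the solution's synergy structure and compares the
#' resulting joint moments against (a) the experimental moments and (b)
#' the collocation moments, both as NRMSE percentages.
#'
#' @param solution A `solve_result` from [solve_ocp()].
#' @param trials The trials the solution was computed from.
#' @param muscle_params A [muscle_set()].
#' @param rtol Relative integration tolerance.
#' @return List with `nrmse_vs_experimental`, `nrmse_vs_collocation` (both
#'   %), and the forward trajectories.
#' @export
consistency_check <- function(solution, trials, muscle_params,
                              rtol = 1e-7) {
  trials <- as_trial_list(trials)
  trials <- lapply(seq_along(trials), function(s)
    resample_trial(trials[[s]], solution$structure$time[[s]]))
  init <- lapply(solution$states, function(st)
    list(a = st$A[, 1], l = st$L[, 1]))
  fwd <- integrate_synergy(solution$structure, trials,
                           initial_states = init,
                           muscle_params = muscle_params, rtol = rtol)
  Mf <- lapply(fwd, `[[`, "M")
  Mstar <- lapply(trials, `[[`, "moments")
  list(nrmse_vs_experimental = nrmse(Mf, Mstar),
       nrmse_vs_collocation = nrmse(Mf, solution$moments),
       forward = fwd)
}
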