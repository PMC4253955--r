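#' Direct collocation for synergy-constrained torque decomposition
#'
#' The decomposition is posed as an optimal control problem: find a shared
#' non-negative weighting matrix `W`, per-condition non-negative synergy
#' controls `h(t)`, and muscle states (activation `a`, fiber length `l`)
#' such that the muscle forces, mapped through the experimental moment
#' arms, reproduce the experimental joint moments while the states satisfy
#' the muscle activation and contraction dynamics. Trapezoidal defect
#' constraints between adjacent equispaced collocation nodes replace the
#' differential equations; the resulting nonlinear program is solved by a
#' bound-constrained quasi-Newton method in the reduced space of the
#' transcription, with exact adjoint gradients.
#'
#' @name ocp_collocation
#' @keywords internal
NULL

#' Joint moments from muscle forces
#'
#' `M_j = sum_i R_ij F_i` for one time instant.
#'
#' @param forces Muscle force vector, length m, N.
#' @param moment_arms Signed moment-arm matrix, m x DOFs, m.
#' @return Moment vector, length = DOFs, N m.
#' @export
joint_moments <- function(forces, moment_arms) {
  moment_arms <- as.matrix(moment_arms)
  if (length(forces) != nrow(moment_arms))
    stop("shape mismatch: ", length(forces), " forces vs ",
         nrow(moment_arms), " moment-arm rows")
  drop(crossprod(moment_arms, forces))
}

#' Discretized tracking-plus-effort cost
#'
#' `J = sum_s sum_n ( sum_j (M_jn - M*_jn)^2 + K sum_i a_in^2 )`, a plain
#' sum over conditions and collocation nodes (no time-step weighting).
#' With `K = 0` this is the discretized pure moment-tracking cost.
#'
#' @param M Simulated moments: matrix or list of matrices (per condition).
#' @param M_star Experimental moments, same shapes as `M`.
#' @param a Activations: matrix or list of matrices (per condition).
#' @param K Effort weight, `>= 0`, dimensionless.
#' @return Scalar cost (N^2 m^2 for the tracking part).
#' @export
cost_function <- function(M, M_star, a, K = 0) {
  if (K < 0) stop("K must be >= 0")
  if (!is.list(M)) M <- list(M)
  if (!is.list(M_star)) M_star <- list(M_star)
  if (!is.list(a)) a <- list(a)
  track <- 0
  for (s in seq_along(M)) {
    if (!all(dim(as.matrix(M[[s]])) == dim(as.matrix(M_star[[s]]))))
      stop("M and M_star shapes differ in condition ", s)
    track <- track + sum((as.matrix(M[[s]]) - as.matrix(M_star[[s]]))^2)
  }
  track + K * sum(vapply(a, function(x) sum(x^2), 0))
}

#' Specify a torque-decomposition problem
#'
#' @param trials List of [trial_data()] objects (the movement conditions).
#' @param muscle_params A [muscle_set()].
#' @param n_syn Number of synergies.
#' @param K Effort weight (0 for the pure-synergy problem).
#' @param W_fixed Optional frozen weighting matrix: when supplied, only the
#'   controls and states are free (held-out-condition validation).
#' @param options Solver options overriding the defaults in
#'   [load_config()] (`restarts`, `maxit`, `factr`, `tol_feas`,
#'   `hinge_weight`).
#' @return Object of class `ocp_spec`.
#' @export
ocp_spec <- function(trials, muscle_params, n_syn, K = 0, W_fixed = NULL,
                     options = list()) {
  trials <- as_trial_list(trials)
  if (n_syn < 1) stop("n_syn must be >= 1")
  if (K < 0) stop("K must be >= 0")
  opts <- utils::modifyList(config_defaults()$solver, options)
  if (!is.null(W_fixed)) {
    W_fixed <- as.matrix(W_fixed)
    if (nrow(W_fixed) != nrow(muscle_params) || ncol(W_fixed) != n_syn)
      stop("W_fixed must be muscles x n_syn")
  }
  structure(list(trials = trials, muscle_params = muscle_params,
                 n_syn = n_syn, K = K, W_fixed = W_fixed, options = opts),
            class = "ocp_spec")
}

#' Transcribe the decomposition into a nonlinear program
#'
#' Decision vector: shared `W` (unless frozen), and per condition the
#' synergy controls `h` and the muscle states `a` and normalized fiber
#' length at every collocation node. Constraints: trapezoidal defect
#' equations for the activation and contraction dynamics between adjacent
#' nodes, per condition (conditions are dynamically independent and share
#' only `W`), plus excitation bounds `0.01 <= W h <= 1` enforced by a
#' quadratic hinge penalty.
#' Experimental series are linearly interpolated onto the grid nodes.
#'
#' @param spec An [ocp_spec()].
#' @param grid A [collocation_grid()], or `NULL` to use the trials' grids.
#' @return Object of class `syntorq_nlp`.
#' @export
transcribe <- function(spec, grid = NULL) {
  stopifnot(inherits(spec, "ocp_spec"))
  trials <- spec$trials
  if (is.null(grid)) grid <- collocation_grid(trials)
  if (length(grid) != length(trials)) stop("grid/trial mismatch")
  p <- .plist(spec$muscle_params)
  m <- length(p$f_max)
  nsyn <- spec$n_syn
  conds <- vector("list", length(trials))
  all_M <- c()
  for (s in seq_along(trials)) {
    tr <- trials[[s]]
    g <- grid[[s]]
    if (g$t[1] < tr$time[1] - 1e-9 ||
        g$t[g$P] > tr$time[length(tr$time)] + 1e-9)
      stop("grid for condition ", s, " exceeds the trial time window")
    tr <- resample_trial(tr, g$t)
    nj <- ncol(tr$moments)
    Rj <- lapply(seq_len(nj), function(j) t(tr$moment_arms[, , j]))
    conds[[s]] <- list(label = tr$condition, t = g$t, dt = g$dt, P = g$P,
                       Mstar = t(tr$moments), Lmt = t(tr$mt_lengths),
                       Rj = Rj, nj = nj, cycles = tr$cycles,
                       dofs = colnames(tr$moments))
    all_M <- c(all_M, tr$moments)
  }
  mrange <- max(all_M) - min(all_M)
  if (mrange <= 0) stop("experimental moments have zero range")
  nW <- if (is.null(spec$W_fixed)) m * nsyn else 0L
  off <- nW
  for (s in seq_along(conds)) {
    P <- conds[[s]]$P
    conds[[s]]$iH <- off + seq_len(nsyn * P); off <- off + nsyn * P
    conds[[s]]$iA <- off + seq_len(m * P); off <- off + m * P
    conds[[s]]$iL <- off + seq_len(m * P); off <- off + m * P
  }
  lower <- numeric(off); upper <- numeric(off)
  if (nW > 0) { lower[1:nW] <- 0; upper[1:nW] <- Inf }
  for (s in seq_along(conds)) {
    lower[conds[[s]]$iH] <- 0;    upper[conds[[s]]$iH] <- Inf
    lower[conds[[s]]$iA] <- 0.01; upper[conds[[s]]$iA] <- 1
    lower[conds[[s]]$iL] <- 0.2;  upper[conds[[s]]$iL] <- 1.8
  }
  structure(list(conds = conds, p = p, m = m, nj = conds[[1]]$nj,
                 n_syn = nsyn, K = spec$K, W_fixed = spec$W_fixed,
                 n_var = off, lower = lower, upper = upper,
                 w_scale = 1 / mrange^2, mrange = mrange,
                 muscle_params = spec$muscle_params,
                 options = spec$options),
            class = "syntorq_nlp")
}

#' @export
print.syntorq_nlp <- function(x, ...) {
  nd <- sum(vapply(x$conds, function(cn) 2L * x$m * (cn$P - 1L), 1L))
  cat(sprintf(
    "collocation NLP: %d variables, %d defect constraints, %d condition(s)%s\n",
    x$n_var, nd, length(x$conds),
    if (is.null(x$W_fixed)) "" else " [W frozen]"))
  invisible(x)
}

# pack a guess (structure + states) into the decision vector
pack_guess <- function(nlp, guess) {
  z <- numeric(nlp$n_var)
  st <- guess$structure
  if (is.null(nlp$W_fixed)) {
    W <- as.matrix(st$W)
    if (!all(dim(W) == c(nlp$m, nlp$n_syn)))
      stop("guess W has wrong shape")
    z[seq_len(nlp$m * nlp$n_syn)] <- as.vector(W)
  }
  for (s in seq_along(nlp$conds)) {
    cn <- nlp$conds[[s]]
    H <- as.matrix(st$H[[s]]); A <- as.matrix(guess$states[[s]]$A)
    L <- as.matrix(guess$states[[s]]$L) / nlp$p$l_opt
    if (ncol(H) != cn$P || ncol(A) != cn$P || ncol(L) != cn$P)
      stop("guess for condition ", s, " is not on the collocation grid")
    z[cn$iH] <- as.vector(H); z[cn$iA] <- as.vector(A)
    z[cn$iL] <- as.vector(L)
  }
  pmin(pmax(z, nlp$lower), nlp$upper)
}

unpack_z <- function(nlp, z) {
  W <- if (is.null(nlp$W_fixed)) {
    matrix(z[seq_len(nlp$m * nlp$n_syn)], nlp$m, nlp$n_syn)
  } else nlp$W_fixed
  conds <- lapply(nlp$conds, function(cn) {
    list(H = matrix(z[cn$iH], nlp$n_syn, cn$P),
         A = matrix(z[cn$iA], nlp$m, cn$P),
         Lh = matrix(z[cn$iL], nlp$m, cn$P))
  })
  list(W = W, conds = conds)
}

# defect residuals for one condition (A, Lh are muscles x P)
.defects <- function(nlp, cn, W, H, A, Lh) {
  p <- nlp$p
  u <- W %*% H
  tau <- ifelse(u > A, p$tau_act, p$tau_deact)
  fa <- (u - A) / tau
  fl <- .fiber_vel(A, Lh * p$l_opt, cn$Lmt, p) / p$l_opt
  P <- cn$P
  i1 <- seq_len(P - 1); i2 <- i1 + 1L
  list(Ca = A[, i2, drop = FALSE] - A[, i1, drop = FALSE] -
         cn$dt / 2 * (fa[, i1, drop = FALSE] + fa[, i2, drop = FALSE]),
       Cl = Lh[, i2, drop = FALSE] - Lh[, i1, drop = FALSE] -
         cn$dt / 2 * (fl[, i1, drop = FALSE] + fl[, i2, drop = FALSE]),
       u = u, fa = fa, fl = fl, tau = tau)
}

#' Defect-constraint residuals at a decision vector
#' @param nlp A `syntorq_nlp`.
#' @param z Decision vector.
#' @return Per-condition list of `Ca` and `Cl` residual matrices
#'   (muscles x intervals).
#' @export
nlp_constraints <- function(nlp, z) {
  uz <- unpack_z(nlp, z)
  lapply(seq_along(nlp$conds), function(s) {
    d <- .defects(nlp, nlp$conds[[s]], uz$W, uz$conds[[s]]$H,
                  uz$conds[[s]]$A, uz$conds[[s]]$Lh)
    d[c("Ca", "Cl")]
  })
}

# simulated moments (DOFs x P) and forces for one condition
.cond_moments <- function(nlp, cn, Lh) {
  p <- nlp$p
  Fm <- .fiber_force(Lh * p$l_opt, cn$Lmt, p)
  M <- matrix(0, cn$nj, cn$P)
  for (j in seq_len(cn$nj)) M[j, ] <- colSums(cn$Rj[[j]] * Fm)
  list(F = Fm, M = M)
}

# ---- reduced-space evaluation of the collocation NLP ---------------------
# The trapezoidal defect equations define the states uniquely from (W, H,
# initial states): the activation step has a closed-form implicit solution
# (the rate law is piecewise linear in the unknown) and the fiber-length
# step is solved by a safeguarded Newton iteration, vectorized over
# muscles. Optimizing over the reduced variables with the exact adjoint
# gradient solves the same nonlinear program with every defect satisfied
# to machine precision by construction (a condensed transcription).

# forward sweep of the defect recursion for one condition
.forward_pass <- function(nlp, cn, u, a1, l1) {
  p <- nlp$p; P <- cn$P; dt <- cn$dt; m <- nlp$m
  A <- matrix(0, m, P); Lh <- matrix(0, m, P)
  tau_n <- matrix(0, m, P - 1); beta <- matrix(0, m, P - 1)
  A[, 1] <- a1; Lh[, 1] <- l1
  fv <- function(aa, llh, n) .fiber_vel(aa, llh * p$l_opt,
                                        cn$Lmt[, n], p) / p$l_opt
  fl_n <- fv(A[, 1], Lh[, 1], 1)
  hfd <- 1e-6
  for (n in seq_len(P - 1)) {
    an <- A[, n]; un <- u[, n]; up <- u[, n + 1]
    tn <- ifelse(un > an, p$tau_act, p$tau_deact)
    Cc <- an + dt / 2 * (un - an) / tn
    tp <- ifelse(up > Cc, p$tau_act, p$tau_deact)
    b <- dt / (2 * tp)
    ap <- (Cc + b * up) / (1 + b)
    A[, n + 1] <- ap
    tau_n[, n] <- tn; beta[, n] <- b
    # implicit trapezoidal step for the fiber length: safeguarded Newton
    # (the residual is monotone increasing in the unknown, so a bisection
    # bracket guarantees convergence)
    gres <- function(x) x - Lh[, n] - dt / 2 * (fl_n + fv(ap, x, n + 1))
    lo <- rep(0.02, m); hi <- rep(3.5, m)
    x <- pmin(pmax(Lh[, n] + dt * fl_n, lo), hi)
    ok <- FALSE
    for (it in seq_len(120)) {
      g <- gres(x)
      if (max(abs(g)) < 1e-11 || max(hi - lo) < 1e-13) { ok <- TRUE; break }
      lo <- ifelse(g < 0, pmax(lo, x), lo)
      hi <- ifelse(g > 0, pmin(hi, x), hi)
      if (it %% 2 == 0) {
        # forced bisection keeps the bracket shrinking where the residual
        # is near-vertical and Newton only creeps
        x <- (lo + hi) / 2
      } else {
        dfx <- (fv(ap, x + hfd, n + 1) - fv(ap, x - hfd, n + 1)) / (2 * hfd)
        xn <- x - g / (1 - dt / 2 * dfx)
        bad <- !is.finite(xn) | xn <= lo | xn >= hi
        x <- ifelse(bad, (lo + hi) / 2, xn)
      }
    }
    if (!ok && max(hi - lo) > 1e-6)
      stop("fiber-length step did not converge at node ", n + 1,
           " (model-infeasible state)")
    Lh[, n + 1] <- x
    fl_n <- fv(ap, x, n + 1)
  }
  list(A = A, Lh = Lh, tau_n = tau_n, beta = beta)
}

# value and adjoint gradient of the reduced objective for one condition;
# returns d/du (muscles x P) plus d/d(a1) and d/d(l1). Production path is
# the compiled implementation; this R version is the reference kept in
# step by a parity test.
.reduced_cond_eval_r <- function(nlp, cn, u, a1, l1, hinge_w, want_grad) {
  p <- nlp$p; P <- cn$P; dt <- cn$dt; m <- nlp$m; w <- nlp$w_scale
  fwd <- .forward_pass(nlp, cn, u, a1, l1)
  A <- fwd$A; Lh <- fwd$Lh
  mm <- .cond_moments(nlp, cn, Lh)
  E <- mm$M - cn$Mstar
  plo <- pmax(0.01 - u, 0); phi <- pmax(u - 1, 0)
  val <- w * (sum(E * E) + nlp$K * sum(A * A)) +
    hinge_w * (sum(plo^2) + sum(phi^2))
  if (!want_grad)
    return(list(value = val, states = fwd, M = mm$M))
  hfd <- 1e-6
  fvp <- function(aa, llh) .fiber_vel(aa, llh * p$l_opt, cn$Lmt, p) / p$l_opt
  DFL_da <- (fvp(A + hfd, Lh) - fvp(A - hfd, Lh)) / (2 * hfd)
  DFL_dl <- (fvp(A, Lh + hfd) - fvp(A, Lh - hfd)) / (2 * hfd)
  dF_dl <- (.fiber_force((Lh + hfd) * p$l_opt, cn$Lmt, p) -
              .fiber_force((Lh - hfd) * p$l_opt, cn$Lmt, p)) / (2 * hfd)
  Tm <- matrix(0, m, P)
  for (j in seq_len(cn$nj))
    Tm <- Tm + cn$Rj[[j]] * matrix(E[j, ], m, P, byrow = TRUE)
  dJdl <- w * 2 * Tm * dF_dl
  dJda <- w * nlp$K * 2 * A
  dJdu <- hinge_w * 2 * (phi - plo)
  # backward (adjoint) sweep through the step recursions
  GU <- dJdu
  beta <- fwd$beta; tau_n <- fwd$tau_n
  Dk <- 1 - dt / 2 * DFL_dl[, 2:P, drop = FALSE] # Newton denominators
  pa <- dJda[, P]; pl <- dJdl[, P]
  q <- pa + (dt / 2 * DFL_da[, P] / Dk[, P - 1]) * pl
  GU[, P] <- GU[, P] + (beta[, P - 1] / (1 + beta[, P - 1])) * q
  for (n in seq(P - 1, 1)) {
    dA_dan <- (1 - dt / (2 * tau_n[, n])) / (1 + beta[, n])
    dA_dun <- (dt / (2 * tau_n[, n])) / (1 + beta[, n])
    dL_dan <- (dt / 2 * DFL_da[, n]) / Dk[, n]
    dL_dln <- (1 + dt / 2 * DFL_dl[, n]) / Dk[, n]
    pa_n <- dJda[, n] + dA_dan * q + dL_dan * pl
    pl_n <- dJdl[, n] + dL_dln * pl
    GU[, n] <- GU[, n] + dA_dun * q
    if (n > 1) {
      q <- pa_n + (dt / 2 * DFL_da[, n] / Dk[, n - 1]) * pl_n
      GU[, n] <- GU[, n] + (beta[, n - 1] / (1 + beta[, n - 1])) * q
    }
    pa <- pa_n; pl <- pl_n
  }
  list(value = val, GU = GU, g_a1 = pa, g_l1 = pl, states = fwd, M = mm$M)
}

.reduced_cond_eval <- function(nlp, cn, u, a1, l1, hinge_w, want_grad,
                               states = NULL) {
  .reduced_cond_eval_cpp(u, a1, l1, nlp$p[c("f_max", "l_opt", "alpha_opt",
                                            "l_slack", "eps_t_max", "v_max",
                                            "tau_act", "tau_deact")],
                         cn$Lmt, cn$Mstar, cn$Rj, cn$dt, nlp$K,
                         nlp$w_scale, hinge_w, want_grad,
                         states$A, states$Lh)
}

# unscaled cost terms and moments at a decision vector
.nlp_costs <- function(nlp, z) {
  uz <- unpack_z(nlp, z)
  M <- list(); Fm <- list(); track <- 0; act <- 0
  for (s in seq_along(nlp$conds)) {
    cn <- nlp$conds[[s]]
    mm <- .cond_moments(nlp, cn, uz$conds[[s]]$Lh)
    M[[s]] <- mm$M; Fm[[s]] <- mm$F
    track <- track + sum((mm$M - cn$Mstar)^2)
    act <- act + sum(uz$conds[[s]]$A^2)
  }
  list(M = M, F = Fm, track = track, act = act,
       objective = track + nlp$K * act)
}

#' Solve the transcribed nonlinear program
#'
#' Reduced-space strategy: the trapezoidal defect equations are solved
#' exactly along the sweep (closed-form implicit activation step, Newton
#' fiber-length step), so the bound-constrained quasi-Newton iterations
#' (L-BFGS-B with the exact adjoint gradient) run over the weightings,
#' controls and initial states only. Excitation bounds are enforced by a
#' quadratic hinge penalty (`hinge_weight`). Deterministic given the guess
#' and options. Solver failure is reported in the `status` field, never
#' silently dropped.
#'
#' @param nlp A `syntorq_nlp` from [transcribe()].
#' @param guess Either the list returned by [make_initial_guess()] (fields
#'   `structure` and `states`) or a previous `solve_result` (warm start).
#' @param options Optional overrides of the NLP's solver options
#'   (`restarts`, `maxit`, `factr`, `tol_feas`, `hinge_weight`).
#' @return Object of class `solve_result`: the optimized
#'   [synergy_structure()], state and moment trajectories per condition,
#'   `nrmse` (%), cost terms, and solver diagnostics.
#' @export
solve_ocp <- function(nlp, guess, options = NULL) {
  opts <- nlp$options
  if (!is.null(options)) opts <- utils::modifyList(opts, options)
  if (inherits(guess, "solve_result")) {
    guess <- list(structure = guess$structure,
                  states = lapply(guess$states, function(st)
                    list(A = st$A, L = st$L)))
  }
  # reduced decision vector: [vec(W) | per condition vec(H), a1, l1]
  m <- nlp$m; nsyn <- nlp$n_syn
  nW <- if (is.null(nlp$W_fixed)) m * nsyn else 0L
  off <- nW
  ridx <- vector("list", length(nlp$conds))
  for (s in seq_along(nlp$conds)) {
    P <- nlp$conds[[s]]$P
    ridx[[s]] <- list(H = off + seq_len(nsyn * P),
                      a1 = off + nsyn * P + seq_len(m),
                      l1 = off + nsyn * P + m + seq_len(m))
    off <- off + nsyn * P + 2L * m
  }
  rlower <- numeric(off); rupper <- numeric(off)
  if (nW > 0) { rlower[1:nW] <- 0; rupper[1:nW] <- Inf }
  for (s in seq_along(nlp$conds)) {
    rlower[ridx[[s]]$H] <- 0;     rupper[ridx[[s]]$H] <- Inf
    rlower[ridx[[s]]$a1] <- 0.01; rupper[ridx[[s]]$a1] <- 1
    rlower[ridx[[s]]$l1] <- 0.2;  rupper[ridx[[s]]$l1] <- 1.8
  }
  zfull0 <- pack_guess(nlp, guess)
  uz0 <- unpack_z(nlp, zfull0)
  zr <- numeric(off)
  if (nW > 0) zr[1:nW] <- as.vector(uz0$W)
  for (s in seq_along(nlp$conds)) {
    zr[ridx[[s]]$H] <- as.vector(uz0$conds[[s]]$H)
    zr[ridx[[s]]$a1] <- uz0$conds[[s]]$A[, 1]
    zr[ridx[[s]]$l1] <- uz0$conds[[s]]$Lh[, 1]
  }
  zr <- pmin(pmax(zr, rlower), rupper)
  evals <- 0L
  hw <- opts$hinge_weight
  # states from a value call are reused by the paired gradient call at the
  # same point, skipping the Newton sweeps there
  scache <- new.env(parent = emptyenv())
  scache$zz <- NULL
  reval <- function(zz, want_grad) {
    evals <<- evals + 1L
    W <- if (nW > 0) matrix(zz[1:nW], m, nsyn) else nlp$W_fixed
    val <- 0
    grad <- if (want_grad) numeric(off) else NULL
    GW <- if (want_grad && nW > 0) matrix(0, m, nsyn) else NULL
    reuse <- want_grad && !is.null(scache$zz) && identical(zz, scache$zz)
    if (!want_grad) scache$states <- vector("list", length(nlp$conds))
    for (s in seq_along(nlp$conds)) {
      P <- nlp$conds[[s]]$P
      H <- matrix(zz[ridx[[s]]$H], nsyn, P)
      u <- W %*% H
      ce <- .reduced_cond_eval(nlp, nlp$conds[[s]], u,
                               zz[ridx[[s]]$a1], zz[ridx[[s]]$l1],
                               hw, want_grad,
                               states = if (reuse) scache$states[[s]])
      val <- val + ce$value
      if (want_grad) {
        grad[ridx[[s]]$H] <- as.vector(crossprod(W, ce$GU))
        grad[ridx[[s]]$a1] <- ce$g_a1
        grad[ridx[[s]]$l1] <- ce$g_l1
        if (nW > 0) GW <- GW + ce$GU %*% t(H)
      } else {
        scache$states[[s]] <- list(A = ce$A, Lh = ce$Lh)
      }
    }
    if (!want_grad) scache$zz <- zz
    if (want_grad && nW > 0) grad[1:nW] <- as.vector(GW)
    list(value = val, grad = grad)
  }
  status <- "converged"
  inner_total <- 0L
  val_prev <- Inf
  for (round in seq_len(opts$restarts)) {
    opt <- tryCatch(
      stats::optim(zr, function(zz) reval(zz, FALSE)$value,
                   function(zz) reval(zz, TRUE)$grad,
                   method = "L-BFGS-B", lower = rlower, upper = rupper,
                   control = list(maxit = opts$maxit, factr = opts$factr,
                                  lmm = 20)),
      error = function(e) e)
    if (inherits(opt, "error")) {
      if (round == 1) {
        return(structure(list(status = paste("failed:",
                                             conditionMessage(opt)),
                              nrmse = Inf, structure = guess$structure),
                         class = "solve_result"))
      }
      break
    }
    zr <- opt$par
    inner_total <- inner_total + opt$counts[1]
    if (abs(val_prev - opt$value) <= 1e-9 * max(1, abs(opt$value))) break
    val_prev <- opt$value
  }
  if (opt$convergence != 0 && opt$convergence != 1)
    status <- paste0("solver_warning_", opt$convergence)
  # expand the reduced solution into the full collocation decision vector
  W <- if (nW > 0) matrix(zr[1:nW], m, nsyn) else nlp$W_fixed
  z <- numeric(nlp$n_var)
  if (is.null(nlp$W_fixed)) z[seq_len(m * nsyn)] <- as.vector(W)
  for (s in seq_along(nlp$conds)) {
    cn <- nlp$conds[[s]]
    H <- matrix(zr[ridx[[s]]$H], nsyn, cn$P)
    fwd <- .forward_pass(nlp, cn, W %*% H, zr[ridx[[s]]$a1],
                         zr[ridx[[s]]$l1])
    z[cn$iH] <- as.vector(H)
    z[cn$iA] <- as.vector(fwd$A)
    z[cn$iL] <- as.vector(fwd$Lh)
  }
  cc <- nlp_constraints(nlp, z)
  cmax <- max(vapply(cc, function(d) max(abs(d$Ca), abs(d$Cl)), 0))
  if (cmax > opts$tol_feas) status <- "infeasible"
  uz <- unpack_z(nlp, z)
  outer <- round
  costs <- .nlp_costs(nlp, z)
  states <- lapply(seq_along(nlp$conds), function(s)
    list(A = uz$conds[[s]]$A, L = uz$conds[[s]]$Lh * nlp$p$l_opt))
  moments <- lapply(seq_along(nlp$conds), function(s) {
    M <- t(costs$M[[s]])
    colnames(M) <- nlp$conds[[s]]$dofs
    M
  })
  mstar <- lapply(nlp$conds, function(cn) t(cn$Mstar))
  st <- synergy_structure(
    uz$W, lapply(uz$conds, `[[`, "H"),
    time = lapply(nlp$conds, `[[`, "t"),
    cycles = lapply(nlp$conds, `[[`, "cycles"),
    conditions = vapply(nlp$conds, `[[`, "", "label"))
  rownames(st$W) <- nlp$p$name
  res <- list(structure = st, states = states, moments = moments,
              experimental_moments = mstar,
              nrmse = nrmse(moments, mstar),
              moment_cost = costs$track, activation_cost = costs$act,
              objective = costs$objective, K = nlp$K,
              status = status, feasibility = cmax,
              outer_iterations = outer, inner_iterations = inner_total,
              n_evals = evals, z = z)
  class(res) <- "solve_result"
  res
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf(
    "torque decomposition: %d synergies, K = %g | NRMSE = %.3f%% | %s\n",
    ncol(x$structure$W), x$K, x$nrmse, x$status))
  cat(sprintf("  objective %.6g (tracking %.6g, activation %.6g), feasibility %.2e\n",
              x$objective, x$moment_cost, x$activation_cost, x$feasibility))
  invisible(x)
}

#' One-call decomposition of a trial set
#'
#' Transcribes and solves the problem from a single seeded initial guess.
#' See [pure_synergy_solve()] for the multi-start protocol.
#'
#' @inheritParams ocp_spec
#' @param seed Seed for the initial guess.
#' @param pattern Initial-guess excitation pattern family.
#' @param grid Optional [collocation_grid()].
#' @return A `solve_result`.
#' @export
solve_decomposition <- function(trials, muscle_params, n_syn, K = 0,
                                seed = 1L, pattern = "constant",
                                W_fixed = NULL, grid = NULL,
                                options = list()) {
  spec <- ocp_spec(trials, muscle_params, n_syn, K = K, W_fixed = W_fixed,
                   options = options)
  nlp <- transcribe(spec, grid)
  guess <- make_initial_guess(pattern, spec$trials, n_syn, seed = seed,
                              muscle_params = muscle_params)
  solve_ocp(nlp, guess)
}
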