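#' Decomposition experiment protocols
#'
#' The normalized moment-error statistic and its admissibility limits, the
#' synergy-count selection rule, the multi-start pure-synergy protocol,
#' held-out-condition validation with frozen weightings, the
#' effort-penalty sweep with its termination statistic, and the
#' joint-moment dimensionality check.
#'
#' @name decomposition_workflows
#' @keywords internal
NULL

#' Normalized root-mean-square moment error
#'
#' `NRMSE = sqrt(sum_s sum_n sum_j (M - M*)^2) /
#'  ((max M* - min M*) * sqrt(NJ * sum_s P_s))`, in percent. The moment
#' range in the denominator is taken cumulatively over all conditions,
#' nodes and DOFs. Zero iff the moment sets are identical.
#'
#' @param M Simulated moments: matrix (time points x DOFs) or list of
#'   matrices, one per condition.
#' @param M_star Experimental moments, same shapes.
#' @return NRMSE in percent.
#' @export
nrmse <- function(M, M_star) {
  if (!is.list(M)) M <- list(M)
  if (!is.list(M_star)) M_star <- list(M_star)
  if (length(M) != length(M_star) || length(M) == 0)
    stop("M and M_star must be matched, nonempty condition lists")
  sq <- 0; n_tot <- 0; nj <- NULL
  rng <- range(unlist(lapply(M_star, as.matrix)))
  if (diff(rng) <= 0)
    stop("experimental moments are constant; NRMSE is undefined")
  for (s in seq_along(M)) {
    a <- as.matrix(M[[s]]); b <- as.matrix(M_star[[s]])
    if (!all(dim(a) == dim(b))) stop("shape mismatch in condition ", s)
    if (is.null(nj)) nj <- ncol(b)
    sq <- sq + sum((a - b)^2)
    n_tot <- n_tot + nrow(b)
  }
  100 * sqrt(sq) / (diff(rng) * sqrt(nj * n_tot))
}

#' Upper admissibility limit on the NRMSE
#'
#' Evaluates the NRMSE formula with every moment error replaced by 5% of
#' the moment range at the respective DOF and condition. A solution below
#' this limit reproduces each moment channel to within a twentieth of its
#' own excursion.
#'
#' @param trials List of [trial_data()] objects (or matrices of
#'   experimental moments).
#' @return Limit in percent.
#' @export
nrmse_upper_limit <- function(trials) {
  Mstar <- .moment_list(trials)
  E <- lapply(Mstar, function(ms) {
    d <- apply(ms, 2, function(x) diff(range(x)))
    if (any(d <= 0)) stop("a DOF has zero moment range")
    sweep(ms * 0, 2, 0.05 * d, "+")
  })
  nrmse(mapply(`+`, Mstar, E, SIMPLIFY = FALSE), Mstar)
}

#' Lower admissibility limit on the NRMSE
#'
#' Evaluates the NRMSE formula with a constant 1 N m error at every DOF,
#' condition and node; algebraically this equals `100 / (global moment
#' range in N m)`. Solutions below this limit fit better than a 1 N m
#' moment error everywhere, flagging biomechanically redundant synergies.
#'
#' @inheritParams nrmse_upper_limit
#' @return Limit in percent.
#' @export
nrmse_lower_limit <- function(trials) {
  Mstar <- .moment_list(trials)
  if (diff(range(unlist(Mstar))) <= 0) stop("zero global moment range")
  nrmse(lapply(Mstar, function(ms) ms + 1), Mstar)
}

.moment_list <- function(trials) {
  trials <- as_trial_list(trials)
  lapply(trials, function(tr)
    if (inherits(tr, "trial_data")) tr$moments else as.matrix(tr))
}

#' NRMSE limits as a pair
#' @inheritParams nrmse_upper_limit
#' @return List with `upper` and `lower` (percent).
#' @export
nrmse_limits <- function(trials) {
  lim <- list(upper = nrmse_upper_limit(trials),
              lower = nrmse_lower_limit(trials))
  if (lim$upper <= lim$lower)
    warning("upper NRMSE limit does not exceed the lower limit")
  lim
}

#' Select the minimum number of synergies
#'
#' Returns the largest synergy count whose NRMSE lies strictly inside the
#' (lower, upper) admissibility band. Counts below the lower limit are
#' treated as biomechanically redundant; above the upper limit as
#' inadequate.
#'
#' @param nrmse_by_nsyn Named numeric vector or list mapping synergy count
#'   to NRMSE (%).
#' @param limits List with `upper` and `lower`, e.g. from [nrmse_limits()].
#' @return The selected count (integer), with the full decision table in
#'   attribute `"table"`.
#' @export
select_num_synergies <- function(nrmse_by_nsyn, limits) {
  v <- unlist(nrmse_by_nsyn)
  if (length(v) == 0) stop("empty NRMSE map")
  ns <- as.integer(names(v))
  if (anyNA(ns)) stop("nrmse_by_nsyn must be named by synergy count")
  o <- order(ns)
  ns <- ns[o]; v <- v[o]
  ok <- v > limits$lower & v < limits$upper
  tab <- data.frame(n_syn = ns, nrmse = as.numeric(v), admissible = ok)
  if (!any(ok))
    stop("no admissible synergy count: no NRMSE lies strictly within (",
         signif(limits$lower, 4), ", ", signif(limits$upper, 4), ")%")
  out <- max(ns[ok])
  attr(out, "table") <- tab
  out
}

#' Multi-start pure-synergy decomposition
#'
#' Solves the pure tracking problem (`K = 0`) from `n_starts` seeded
#' arbitrary initial guesses (alternating constant and sine-pulse
#' excitation families) and returns the solution with the smallest NRMSE,
#' together with the per-start NRMSE list.
#'
#' @param trials List of [trial_data()] objects.
#' @param muscle_params A [muscle_set()].
#' @param n_syn Number of synergies.
#' @param n_starts Number of initial guesses (default 15).
#' @param seed Base seed; start `i` uses `seed + i`.
#' @param grid Optional [collocation_grid()].
#' @param options Solver option overrides.
#' @param n_polish The best `n_polish` screened starts are re-solved at a
#'   2x deeper iteration budget before the winner is chosen (0 disables
#'   polishing). Screening ranks basins cheaply; polishing decides between
#'   them at convergence.
#' @param consistency_tol Maximum forward-vs-collocation NRMSE (%) for a
#'   polished candidate to count as dynamically consistent. Collocation
#'   admits spurious minima that track the moments by exploiting the
#'   temporal discretization; such solutions cannot be reproduced by a
#'   forward simulation of the governing dynamics, which adherence the
#'   protocol demands, so the winner is the minimum-NRMSE candidate among
#'   the consistent ones (with a `consistency_fallback` flag when no
#'   candidate qualifies). `Inf` disables the filter.
#' @return The best `solve_result`, with `per_start_nrmse`,
#'   `per_start_status` and `forward_nrmse` fields added (screened values;
#'   the winning starts are then polished).
#' @export
pure_synergy_solve <- function(trials, muscle_params, n_syn,
                               n_starts = 15L, seed = 1L, grid = NULL,
                               options = list(), n_polish = 2L,
                               consistency_tol = 2) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  spec <- ocp_spec(trials, muscle_params, n_syn, K = 0, options = options)
  nlp <- transcribe(spec, grid)
  patterns <- rep(c("constant", "sine"), length.out = n_starts)
  results <- vector("list", n_starts)
  nr <- rep(NA_real_, n_starts); stat <- character(n_starts)
  errs <- character(0)
  for (i in seq_len(n_starts)) {
    res <- tryCatch({
      g <- make_initial_guess(patterns[i], spec$trials, n_syn,
                              seed = seed + i, muscle_params = muscle_params)
      solve_ocp(nlp, g)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      stat[i] <- "error"
      errs <- c(errs, conditionMessage(res))
      next
    }
    results[[i]] <- res
    nr[i] <- res$nrmse; stat[i] <- res$status
  }
  if (all(is.na(nr)))
    stop("all ", n_starts, " starts failed: ",
         paste(unique(errs), collapse = "; "))
  top <- order(nr)[seq_len(min(max(n_polish, 1L), sum(!is.na(nr))))]
  cands <- list()
  if (n_polish > 0) {
    popts <- nlp$options
    popts$maxit <- 2L * popts$maxit
    popts$restarts <- popts$restarts + 1L
    for (i in top) {
      pol <- tryCatch(solve_ocp(nlp, results[[i]], options = popts),
                      error = function(e) results[[i]])
      if (pol$nrmse > results[[i]]$nrmse) pol <- results[[i]]
      cands[[length(cands) + 1]] <- pol
    }
  } else {
    cands <- list(results[[top[1]]])
  }
  # dynamic-consistency filter: discard candidates whose collocation
  # moments cannot be reproduced by forward integration
  fwd <- vapply(cands, function(r) {
    tryCatch(consistency_check(r, trials,
                               muscle_params)$nrmse_vs_collocation,
             error = function(e) Inf)
  }, 0)
  ok <- which(is.finite(fwd) & fwd <= consistency_tol)
  fallback <- length(ok) == 0
  pick <- if (fallback) {
    which.min(vapply(cands, `[[`, 0, "nrmse"))
  } else {
    ok[which.min(vapply(cands[ok], `[[`, 0, "nrmse"))]
  }
  best <- cands[[pick]]
  best$forward_nrmse <- fwd[pick]
  best$consistency_fallback <- fallback
  best$per_start_nrmse <- nr
  best$per_start_status <- stat
  best
}

#' Validate frozen weightings on held-out conditions
#'
#' Re-solves the decomposition on new conditions with the muscle
#' weightings held fixed; only the synergy controls and muscle states are
#' free. Reports the NRMSE achieved on the held-out data.
#'
#' @param trials_new List of [trial_data()] for the held-out conditions.
#' @param W Weighting matrix from a prior solve (muscles x synergies).
#' @param muscle_params A [muscle_set()].
#' @param n_starts Number of seeded initial guesses.
#' @param seed Base seed.
#' @param grid,options As in [pure_synergy_solve()].
#' @return The best `solve_result`; its structure carries `W` unchanged.
#' @export
validate_fixed_weights <- function(trials_new, W, muscle_params,
                                   n_starts = 5L, seed = 1L, grid = NULL,
                                   options = list()) {
  W <- as.matrix(W)
  trials_new <- as_trial_list(trials_new)
  n_syn <- ncol(W)
  spec <- ocp_spec(trials_new, muscle_params, n_syn, K = 0, W_fixed = W,
                   options = options)
  nlp <- transcribe(spec, grid)
  m <- nrow(muscle_params)
  patterns <- rep(c("constant", "sine"), length.out = n_starts)
  best <- NULL; nr <- rep(NA_real_, n_starts)
  for (i in seq_len(n_starts)) {
    res <- tryCatch({
      Es <- lapply(seq_along(spec$trials), function(s) {
        tr <- spec$trials[[s]]
        arbitrary_excitations(patterns[i], tr$time,
                              mean(diff(tr$cycles)), m, seed + i + 11L * s)
      })
      H <- lapply(Es, function(E) nnmf_fixed_w(E, W, seed = seed + i))
      st <- synergy_structure(W, H,
                              time = lapply(spec$trials, `[[`, "time"),
                              cycles = lapply(spec$trials, `[[`, "cycles"),
                              conditions = vapply(spec$trials, `[[`, "",
                                                  "condition"))
      traj <- integrate_synergy(st, spec$trials,
                                muscle_params = muscle_params)
      guess <- list(structure = st,
                    states = lapply(traj, function(tt)
                      list(A = t(tt$A), L = t(tt$L))))
      solve_ocp(nlp, guess)
    }, error = function(e) e)
    if (inherits(res, "error")) next
    nr[i] <- res$nrmse
    if (is.null(best) || res$nrmse < best$nrmse) best <- res
  }
  if (is.null(best)) stop("all validation starts failed")
  best$per_start_nrmse <- nr
  best
}

#' Termination statistic for the effort-penalty sweep
#'
#' The minimum meaningful reduction in activation cost between successive
#' penalty weights: the cost change obtained by hypothetically lowering
#' every activation by 0.01 (the activation lower bound), floored at that
#' bound: `Delta = sum (a^2 - max(0.01, a - 0.01)^2)` over all conditions,
#' nodes and muscles.
#'
#' @param result A `solve_result`, or a list of activation matrices.
#' @return Non-negative scalar.
#' @export
delta_threshold <- function(result) {
  A <- if (inherits(result, "solve_result"))
    lapply(result$states, `[[`, "A") else result
  if (!is.list(A)) A <- list(A)
  sum(vapply(A, function(a) sum(a^2 - pmax(0.01, a - 0.01)^2), 0))
}

# pure decision rule of the sweep: first K whose activation-cost drop to
# the next K falls below that K's threshold
select_k_from_costs <- function(k_grid, act_costs, deltas) {
  for (i in seq_len(length(k_grid) - 1)) {
    if ((act_costs[i] - act_costs[i + 1]) < deltas[i])
      return(list(chosen = k_grid[i], exhausted = FALSE))
  }
  list(chosen = k_grid[length(k_grid)], exhausted = TRUE)
}

#' Effort-penalty sweep for the optimal-synergy solution
#'
#' Solves the decomposition for increasing effort weights `K` (warm-started
#' from the previous weight's solution by default) and stops at the first
#' `K` whose activation-cost reduction to the next weight falls below the
#' [delta_threshold()] of the `K` solution. The chosen solution's NRMSE is
#' checked against the upper admissibility limit and the check recorded.
#'
#' @inheritParams pure_synergy_solve
#' @param k_grid Increasing effort weights starting at 0.
#' @param n_starts Multi-start count for the `K = 0` solve.
#' @param warm_start Warm-start each `K` from the previous solution
#'   (`FALSE` re-runs the full multi-start protocol per `K`).
#' @param k0_result Optional precomputed `K = 0` solve_result (saves the
#'   multi-start solve when already available).
#' @return Object of class `sweep_result`: per-K results, activation
#'   costs, thresholds, chosen `K`, exhaustion flag and the NRMSE check.
#' @export
optimal_synergy_sweep <- function(trials, muscle_params, n_syn,
                                  k_grid = seq(0, 500, by = 100),
                                  n_starts = 15L, seed = 1L, grid = NULL,
                                  options = list(), warm_start = TRUE,
                                  k0_result = NULL) {
  if (is.unsorted(k_grid, strictly = TRUE) || k_grid[1] != 0)
    stop("k_grid must be increasing and start at 0")
  results <- vector("list", length(k_grid))
  names(results) <- as.character(k_grid)
  results[[1]] <- if (is.null(k0_result)) {
    pure_synergy_solve(trials, muscle_params, n_syn, n_starts = n_starts,
                       seed = seed, grid = grid, options = options)
  } else k0_result
  act <- numeric(length(k_grid)); act[1] <- results[[1]]$activation_cost
  deltas <- numeric(length(k_grid))
  deltas[1] <- delta_threshold(results[[1]])
  chosen <- NULL; exhausted <- TRUE
  for (i in seq_len(length(k_grid))[-1]) {
    spec <- ocp_spec(trials, muscle_params, n_syn, K = k_grid[i],
                     options = options)
    nlp <- transcribe(spec, grid)
    results[[i]] <- if (warm_start) {
      solve_ocp(nlp, results[[i - 1]])
    } else {
      g <- make_initial_guess("constant", spec$trials, n_syn,
                              seed = seed + i, muscle_params = muscle_params)
      solve_ocp(nlp, g)
    }
    act[i] <- results[[i]]$activation_cost
    deltas[i] <- delta_threshold(results[[i]])
    if ((act[i - 1] - act[i]) < deltas[i - 1]) {
      chosen <- k_grid[i - 1]; exhausted <- FALSE
      break
    }
  }
  if (is.null(chosen)) chosen <- k_grid[length(k_grid)]
  solved <- !vapply(results, is.null, TRUE)
  upper <- nrmse_upper_limit(trials)
  chosen_res <- results[[as.character(chosen)]]
  out <- list(k_grid = k_grid[solved], results = results[solved],
              activation_costs = act[solved], deltas = deltas[solved],
              chosen_k = chosen, exhausted = exhausted,
              chosen_result = chosen_res,
              nrmse_check = list(nrmse = chosen_res$nrmse, upper = upper,
                                 within = chosen_res$nrmse < upper))
  class(out) <- "sweep_result"
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("effort-penalty sweep: chosen K =", x$chosen_k,
      if (x$exhausted) "(sweep exhausted)" else "(threshold rule)", "\n")
  cat(sprintf("  NRMSE at chosen K: %.3f%% (upper limit %.3f%%)\n",
              x$nrmse_check$nrmse, x$nrmse_check$upper))
  invisible(x)
}

#' Dimensionality of the joint moments
#'
#' Principal component analysis of the pooled instantaneous joint-moment
#' vectors across all conditions; returns the smallest number of
#' components whose cumulative explained variance reaches the threshold.
#'
#' @param trials List of [trial_data()] (or moment matrices).
#' @param variance_threshold Fraction of variance to explain, in (0, 1].
#' @return Component count, with the explained-variance spectrum in
#'   attribute `"variance"`.
#' @export
moment_dimensionality <- function(trials, variance_threshold = 0.9) {
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must lie in (0, 1]")
  Mstar <- .moment_list(trials)
  X <- do.call(rbind, Mstar)
  if (nrow(X) <= ncol(X)) stop("fewer moment samples than DOFs")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(v) >= variance_threshold - 1e-12)[1]
  out <- as.integer(k)
  attr(out, "variance") <- v
  out
}

#' Full decomposition protocol: synergy-count sweep and selection
#'
#' Runs the multi-start pure-synergy decomposition over a range of synergy
#' counts, computes the NRMSE admissibility limits, and applies the
#' selection rule.
#'
#' @inheritParams pure_synergy_solve
#' @param n_syn_range Synergy counts to evaluate (contiguous).
#' @return List with the per-count results, the NRMSE table, limits, the
#'   selected count (`NULL` with a recorded reason if none admissible) and
#'   the best solution at the selected count.
#' @export
decompose <- function(trials, muscle_params, n_syn_range = 3:7,
                      n_starts = 15L, seed = 1L, grid = NULL,
                      options = list()) {
  trials <- as_trial_list(trials)
  results <- list()
  nr <- numeric(0)
  for (ns in n_syn_range) {
    res <- pure_synergy_solve(trials, muscle_params, ns,
                              n_starts = n_starts, seed = seed,
                              grid = grid, options = options)
    results[[as.character(ns)]] <- res
    nr[as.character(ns)] <- res$nrmse
  }
  limits <- nrmse_limits(trials)
  sel <- tryCatch(select_num_synergies(nr, limits), error = function(e) e)
  if (inherits(sel, "error")) {
    list(results = results, nrmse_by_nsyn = nr, limits = limits,
         selected = NULL, selection_error = conditionMessage(sel),
         best = NULL)
  } else {
    list(results = results, nrmse_by_nsyn = nr, limits = limits,
         selected = as.integer(sel), selection_table = attr(sel, "table"),
         best = results[[as.character(sel)]])
  }
}
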