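#' Synergy structures and non-negative factorization
#'
#' A synergy structure holds one shared non-negative weighting matrix `W`
#' (muscles x synergies) and, per movement condition, a non-negative
#' control-signal matrix `H` (synergies x time points) sampled on that
#' condition's time grid. Muscle excitations arise by linear combination,
#' `u = W %*% h`.
#'
#' @name synergy_model
#' @keywords internal
NULL

#' Construct a synergy structure
#'
#' @param W Non-negative weighting matrix, muscles x synergies.
#' @param H List (one per condition) of non-negative control matrices,
#'   synergies x time points.
#' @param time List of time vectors, one per condition, matching the
#'   columns of each `H`.
#' @param cycles List of gait-cycle boundary time vectors, one per
#'   condition (first and last entries delimit the analyzed window).
#' @param conditions Character labels, one per condition.
#' @return An object of class `synergy_structure`.
#' @export
synergy_structure <- function(W, H, time, cycles = NULL, conditions = NULL) {
  W <- as.matrix(W)
  if (!is.list(H)) H <- list(H)
  H <- lapply(H, as.matrix)
  if (!is.list(time)) time <- list(time)
  if (is.null(conditions)) conditions <- paste0("cond", seq_along(H))
  if (any(W < 0)) stop("W must be non-negative")
  for (s in seq_along(H)) {
    if (any(H[[s]] < 0)) stop("H must be non-negative")
    if (nrow(H[[s]]) != ncol(W))
      stop("H[[", s, "]] must have one row per synergy")
    if (ncol(H[[s]]) != length(time[[s]]))
      stop("H[[", s, "]] columns must match the condition time grid")
  }
  structure(list(W = W, H = H, time = time, cycles = cycles,
                 conditions = conditions),
            class = "synergy_structure")
}

#' @export
print.synergy_structure <- function(x, ...) {
  cat("synergy structure:", nrow(x$W), "muscles,", ncol(x$W), "synergies,",
      length(x$H), "condition(s)\n")
  invisible(x)
}

#' Linear synergy combination
#'
#' Muscle excitations from weightings and controls: `u_i = sum_k W_ik h_k`.
#'
#' @param W Non-negative weighting matrix, muscles x synergies.
#' @param h Non-negative control vector (length = synergies) or matrix
#'   (synergies x time points).
#' @return Excitation vector (length = muscles) or matrix
#'   (muscles x time points).
#' @export
combine <- function(W, h) {
  W <- as.matrix(W)
  hm <- if (is.matrix(h)) h else matrix(h, ncol = 1)
  if (ncol(W) != nrow(hm))
    stop("shape mismatch: W has ", ncol(W), " synergies but h has ",
         nrow(hm))
  if (any(W < 0) || any(hm < 0)) stop("W and h must be non-negative")
  u <- W %*% hm
  if (is.matrix(h)) u else drop(u)
}

#' Non-negative matrix factorization
#'
#' Lee-Seung multiplicative updates minimizing the Frobenius
#' reconstruction error. Deterministic given `seed` (random non-negative
#' initialization); the caller's random-number state is left untouched.
#'
#' @param U Non-negative matrix, m x P.
#' @param n_components Number of components, in `[1, min(m, P)]`.
#' @param seed Integer seed for the initialization.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Relative-improvement stopping tolerance on the error.
#' @return List with `W` (m x n), `H` (n x P), `rel_error` (Frobenius
#'   error over `norm(U, "F")`) and `iterations`.
#' @export
nnmf <- function(U, n_components, seed = 1L, max_iter = 2000, tol = 1e-8) {
  U <- as.matrix(U)
  if (any(U < 0)) stop("U must be non-negative")
  nU <- norm(U, "F")
  if (nU == 0) stop("U is all zero; nothing to factorize")
  m <- nrow(U); P <- ncol(U)
  if (n_components < 1 || n_components > min(m, P))
    stop("n_components must lie in [1, min(m, P)]")
  scale0 <- sqrt(mean(U) / n_components)
  init <- with_local_seed(seed, {
    list(W = matrix(stats::runif(m * n_components, 0.1, 1) * scale0, m),
         H = matrix(stats::runif(n_components * P, 0.1, 1) * scale0,
                    n_components))
  })
  W <- init$W; H <- init$H
  eps <- 1e-12
  err_prev <- Inf; it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, U)) / (crossprod(W, W %*% H) + eps)
    W <- W * (U %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      err <- norm(U - W %*% H, "F") / nU
      if (is.finite(err_prev) && abs(err_prev - err) < tol * max(err, 1e-16))
        break
      err_prev <- err
    }
  }
  list(W = W, H = H, rel_error = norm(U - W %*% H, "F") / nU,
       iterations = it)
}

# update only H for a fixed W (used when weightings are frozen)
nnmf_fixed_w <- function(U, W, seed = 1L, max_iter = 2000, tol = 1e-8) {
  U <- as.matrix(U); W <- as.matrix(W)
  nU <- norm(U, "F")
  H <- with_local_seed(seed, {
    matrix(stats::runif(ncol(W) * ncol(U), 0.1, 1) *
             sqrt(mean(U) / ncol(W)), ncol(W))
  })
  eps <- 1e-12
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, U)) / (crossprod(W, W %*% H) + eps)
    if (it %% 10 == 0) {
      err <- norm(U - W %*% H, "F") / nU
      if (is.finite(err_prev) && abs(err_prev - err) < tol * max(err, 1e-16))
        break
      err_prev <- err
    }
  }
  H
}

# evaluate a block of code with a local RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Rescale a synergy structure
#'
#' Applies the scale exchange `(W D, D^-1 H)` so that each weighting
#' column has either unit maximum (`"max"`) or unit Euclidean norm
#' (`"norm"`). Excitations are unchanged.
#'
#' @param structure A [synergy_structure()].
#' @param mode `"max"` or `"norm"`.
#' @return The rescaled structure.
#' @export
normalize_structure <- function(structure, mode = c("max", "norm")) {
  mode <- match.arg(mode)
  d <- switch(mode,
              max = apply(structure$W, 2, max),
              norm = sqrt(colSums(structure$W^2)))
  d[d == 0] <- 1
  structure$W <- sweep(structure$W, 2, d, "/")
  structure$H <- lapply(structure$H, function(h) h * d)
  structure
}

# seeded arbitrary excitation patterns: per-muscle constants, or 1-3
# half-sine pulses per gait cycle with seeded onset, width and amplitude
arbitrary_excitations <- function(pattern, time, period, m, seed) {
  with_local_seed(seed, {
    P <- length(time)
    E <- matrix(0, m, P)
    if (pattern == "constant") {
      E[] <- rep(stats::runif(m, 0.05, 0.6), P)
    } else {
      for (i in seq_len(m)) {
        n_pulse <- sample(1:3, 1)
        e <- rep(0.02, P)
        for (q in seq_len(n_pulse)) {
          amp <- stats::runif(1, 0.05, 0.6)
          width <- stats::runif(1, 0.15, 0.5) * period
          onset <- stats::runif(1, 0, period)
          ph <- (time - onset) %% period
          idx <- ph < width
          e[idx] <- e[idx] + amp * sin(pi * ph[idx] / width)
        }
        E[i, ] <- e
      }
    }
    pmin(pmax(E, 0), 1)
  })
}

#' Seeded initial guess for the decomposition
#'
#' Builds an arbitrary muscle-excitation matrix over all conditions from
#' the chosen pattern family (per-muscle constants or seeded half-sine
#' pulse trains), factorizes it with [nnmf()] into a shared `W` and
#' per-condition controls, then forward-integrates the muscle activation
#' and contraction dynamics under the reconstructed excitations to obtain
#' admissible state trajectories at every collocation point.
#'
#' @param pattern `"constant"` or `"sine"`.
#' @param trials List of [trial_data()] objects.
#' @param n_syn Number of synergies.
#' @param seed Integer seed.
#' @param muscle_params A [muscle_set()].
#' @return List with `structure` (a [synergy_structure()]) and `states`, a
#'   per-condition list of `A` and `L` matrices (muscles x time points;
#'   `L` is fiber length in m).
#' @export
make_initial_guess <- function(pattern = c("constant", "sine"), trials,
                               n_syn, seed = 1L, muscle_params) {
  pattern <- match.arg(pattern)
  if (length(trials) == 0) stop("no trials supplied")
  if (n_syn < 1) stop("n_syn must be >= 1")
  trials <- as_trial_list(trials)
  m <- nrow(muscle_params)
  Es <- lapply(seq_along(trials), function(s) {
    tr <- trials[[s]]
    period <- mean(diff(tr$cycles))
    arbitrary_excitations(pattern, tr$time, period, m, seed + 7L * s)
  })
  fac <- nnmf(do.call(cbind, Es), n_syn, seed = seed)
  Pcum <- c(0, cumsum(vapply(trials, function(tr) length(tr$time), 1L)))
  H <- lapply(seq_along(trials), function(s) {
    fac$H[, (Pcum[s] + 1):Pcum[s + 1], drop = FALSE]
  })
  st <- synergy_structure(fac$W, H,
                          time = lapply(trials, `[[`, "time"),
                          cycles = lapply(trials, `[[`, "cycles"),
                          conditions = vapply(trials, `[[`, "",
                                              "condition"))
  traj <- integrate_synergy(st, trials, muscle_params = muscle_params)
  states <- lapply(traj, function(tt) list(A = t(tt$A), L = t(tt$L)))
  list(structure = st, states = states)
}
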