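#' Experimental data for one movement condition
#'
#' A trial holds, on one strictly increasing time grid: experimental joint
#' moments (time points x DOFs, N m), muscle-tendon lengths (time points x
#' muscles, m), signed moment arms (time points x muscles x DOFs, m) and
#' gait-cycle boundary times.
#'
#' @param condition Condition label (e.g. `"slow"`).
#' @param time Strictly increasing time vector, s.
#' @param moments Matrix, time points x DOFs, with DOF column names.
#' @param mt_lengths Matrix, time points x muscles, with muscle names.
#' @param moment_arms Array, time points x muscles x DOFs.
#' @param cycles Gait-cycle boundary times (length = cycles + 1), within
#'   the time window.
#' @return An object of class `trial_data`.
#' @export
trial_data <- function(condition, time, moments, mt_lengths, moment_arms,
                       cycles) {
  moments <- as.matrix(moments)
  mt_lengths <- as.matrix(mt_lengths)
  P <- length(time)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (nrow(moments) != P || nrow(mt_lengths) != P ||
      dim(moment_arms)[1] != P)
    stop("inconsistent number of time points across trial arrays")
  if (dim(moment_arms)[2] != ncol(mt_lengths) ||
      dim(moment_arms)[3] != ncol(moments))
    stop("moment_arms must be time points x muscles x DOFs")
  if (anyNA(moments) || anyNA(mt_lengths) || anyNA(moment_arms))
    stop("trial arrays must not contain missing values")
  if (min(cycles) < time[1] - 1e-9 || max(cycles) > time[P] + 1e-9)
    stop("cycle boundaries must lie within the time window")
  structure(list(condition = as.character(condition), time = as.numeric(time),
                 moments = moments, mt_lengths = mt_lengths,
                 moment_arms = moment_arms, cycles = sort(as.numeric(cycles))),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("trial '%s': %d time points, %d DOFs, %d muscles, %d cycle(s)\n",
              x$condition, length(x$time), ncol(x$moments),
              ncol(x$mt_lengths), length(x$cycles) - 1))
  invisible(x)
}

as_trial_list <- function(trials) {
  if (inherits(trials, "trial_data")) list(trials) else trials
}

#' Resample a trial onto a new time grid
#'
#' Linear interpolation of all series (moments, muscle-tendon lengths,
#' moment arms) onto `t_new`. Inputs are smooth inverse-dynamics outputs,
#' so linear interpolation between samples is adequate.
#'
#' @param trial A [trial_data()].
#' @param t_new New strictly increasing time grid, within the trial window.
#' @return A [trial_data()] on `t_new`.
#' @export
resample_trial <- function(trial, t_new) {
  interp_cols <- function(mat) {
    apply(mat, 2, function(y) stats::approx(trial$time, y, t_new,
                                            rule = 2)$y)
  }
  P <- length(t_new)
  m <- ncol(trial$mt_lengths); nj <- ncol(trial$moments)
  arms <- array(0, c(P, m, nj),
                dimnames = dimnames(trial$moment_arms))
  for (j in seq_len(nj)) {
    aj <- array(trial$moment_arms[, , j],
                dim = dim(trial$moment_arms)[1:2])
    arms[, , j] <- interp_cols(aj)
  }
  cyc <- unique(pmin(pmax(trial$cycles, t_new[1]), t_new[P]))
  trial_data(trial$condition, t_new,
             interp_cols(trial$moments), interp_cols(trial$mt_lengths),
             arms, cyc)
}

#' Collocation grid over a set of trials
#'
#' Builds, per condition, a uniform grid of `points` collocation nodes
#' spanning the condition's time window. With `points = NULL` the trials'
#' own time grids are used unchanged.
#'
#' @param trials List of [trial_data()] objects.
#' @param points Integer vector of node counts (recycled over conditions),
#'   or `NULL`.
#' @return Object of class `collocation_grid`: per condition, `P`, `dt`
#'   and the node time vector `t`.
#' @export
collocation_grid <- function(trials, points = NULL) {
  trials <- as_trial_list(trials)
  if (!is.null(points)) points <- rep_len(points, length(trials))
  g <- lapply(seq_along(trials), function(s) {
    tr <- trials[[s]]
    if (is.null(points)) {
      tt <- tr$time
      dt <- mean(diff(tt))
      if (max(abs(diff(tt) - dt)) > 1e-6 * dt)
        tt <- seq(tr$time[1], tr$time[length(tr$time)],
                  length.out = length(tr$time))
    } else {
      if (points[s] < 2) stop("each condition needs at least 2 nodes")
      tt <- seq(tr$time[1], tr$time[length(tr$time)],
                length.out = points[s])
    }
    list(P = length(tt), dt = diff(tt[1:2]), t = tt,
         duration = tt[length(tt)] - tt[1])
  })
  names(g) <- vapply(trials, `[[`, "", "condition")
  structure(g, class = "collocation_grid")
}
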