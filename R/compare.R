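#' Synergy comparison statistics
#'
#' Similarity index of muscle weightings, optimal synergy correspondence,
#' Pearson correlations of control signals on a normalized gait-cycle
#' grid, and the qualitative similarity bands.
#'
#' @name synergy_comparison
#' @keywords internal
NULL

#' Similarity index of two weighting vectors
#'
#' Dot product of the unit-normalized (Euclidean norm) weighting vectors.
#' Equals 1 for identical muscle groupings and is invariant to positive
#' rescaling of either vector.
#'
#' @param w1,w2 Non-negative weighting vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
similarity_index <- function(w1, w2) {
  if (length(w1) != length(w2)) stop("weighting vectors differ in length")
  if (any(w1 < 0) || any(w2 < 0)) stop("weightings must be non-negative")
  n1 <- sqrt(sum(w1^2)); n2 <- sqrt(sum(w2^2))
  if (n1 == 0 || n2 == 0) stop("zero weighting vector")
  sum(w1 * w2) / (n1 * n2)
}

# Hungarian algorithm (potentials + augmenting paths), O(n^3), minimizing
# the total cost of a square assignment. Deterministic.
hungarian_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1) # index 1 is the virtual col 0
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]; p[j0 + 1] <- p[j1 + 1]; j0 <- j1
      if (j0 == 0) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j + 1]] <- j
  perm
}

#' Match synergies between two weighting sets
#'
#' Finds the bijection from the synergies of `W_a` to those of `W_b` that
#' maximizes the total pairwise similarity index (optimal assignment via
#' the Hungarian algorithm; deterministic).
#'
#' @param W_a,W_b Weighting matrices over the same muscle set, same
#'   synergy count.
#' @return Integer permutation `perm` (`perm[k]` is the synergy of `W_b`
#'   matched to synergy `k` of `W_a`), with the matched similarity indices
#'   in attribute `"si"` and the full SI matrix in attribute `"si_matrix"`.
#' @export
match_synergies <- function(W_a, W_b) {
  W_a <- as.matrix(W_a); W_b <- as.matrix(W_b)
  if (!all(dim(W_a) == dim(W_b))) stop("weighting matrices differ in shape")
  n <- ncol(W_a)
  S <- matrix(0, n, n)
  for (k in seq_len(n)) for (l in seq_len(n))
    S[k, l] <- similarity_index(W_a[, k], W_b[, l])
  perm <- hungarian_assignment(-S)
  out <- perm
  attr(out, "si") <- S[cbind(seq_len(n), perm)]
  attr(out, "si_matrix") <- S
  out
}

#' Pearson correlation of two control signals
#'
#' @param h_a,h_b Equal-length signal vectors on a common sampling grid.
#' @return List with `rho` and `p_value`.
#' @export
control_correlation <- function(h_a, h_b) {
  if (length(h_a) != length(h_b)) stop("signals differ in length")
  if (stats::sd(h_a) == 0 || stats::sd(h_b) == 0)
    stop("constant control signal: correlation undefined")
  ct <- stats::cor.test(h_a, h_b, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

# per-condition, per-synergy controls resampled to n_points equally spaced
# time points over each gait cycle (cycle-averaged by default); returns a
# list [condition][synergy] of numeric vectors
resample_controls <- function(structure, n_points = 30,
                              cycle_average = TRUE) {
  lapply(seq_along(structure$H), function(s) {
    tt <- structure$time[[s]]
    bnd <- structure$cycles[[s]]
    if (is.null(bnd)) bnd <- range(tt)
    lapply(seq_len(nrow(structure$H[[s]])), function(k) {
      h <- structure$H[[s]][k, ]
      per_cycle <- lapply(seq_len(length(bnd) - 1), function(cidx) {
        tq <- seq(bnd[cidx], bnd[cidx + 1], length.out = n_points)
        stats::approx(tt, h, tq, rule = 2)$y
      })
      if (cycle_average) Reduce(`+`, per_cycle) / length(per_cycle)
      else unlist(per_cycle)
    })
  })
}

#' Mean correlation coefficient of two control-signal sets
#'
#' Each control signal (per synergy, per condition) is linearly
#' interpolated at `n_points` equally spaced time points over a gait cycle
#' (cycle-averaged when the condition spans several cycles), the resampled
#' signals are concatenated in a fixed synergy-major order (synergy, then
#' condition), and a single Pearson correlation between the two
#' concatenated vectors is returned.
#'
#' @param struct_a,struct_b [synergy_structure()] objects over matched
#'   condition sets, with cycle boundaries.
#' @param correspondence Optional permutation from [match_synergies()]
#'   (defaults to the identity).
#' @param n_points Samples per gait cycle (default 30).
#' @param cycle_average Average across cycles before concatenation.
#' @return List with `rho` and `p_value`.
#' @export
mean_correlation <- function(struct_a, struct_b, correspondence = NULL,
                             n_points = 30, cycle_average = TRUE) {
  if (length(struct_a$H) != length(struct_b$H))
    stop("condition sets differ between structures")
  n <- ncol(struct_a$W)
  if (n != ncol(struct_b$W)) stop("synergy counts differ")
  if (is.null(correspondence)) correspondence <- seq_len(n)
  ra <- resample_controls(struct_a, n_points, cycle_average)
  rb <- resample_controls(struct_b, n_points, cycle_average)
  va <- c(); vb <- c()
  for (k in seq_len(n)) {
    for (s in seq_along(ra)) {
      va <- c(va, ra[[s]][[k]])
      vb <- c(vb, rb[[s]][[correspondence[k]]])
    }
  }
  control_correlation(va, vb)
}

#' Qualitative similarity band
#'
#' Values above 0.8 indicate high similarity, values in `[0.5, 0.8]`
#' moderate, and values below 0.5 low (both boundaries assigned to the
#' moderate band).
#'
#' @param value Similarity index or correlation coefficient.
#' @return `"high"`, `"moderate"` or `"low"` (vectorized).
#' @export
classify_similarity <- function(value) {
  if (any(!is.finite(value))) stop("non-finite similarity value")
  ifelse(value > 0.8, "high", ifelse(value >= 0.5, "moderate", "low"))
}

#' Compare two synergy structures
#'
#' Matches synergies by similarity index, then reports per-synergy and
#' mean similarity indices, per-signal Pearson correlations of the synergy
#' controls on the normalized gait-cycle grid, the mean correlation
#' coefficient, and the qualitative bands. When `muscles` is supplied the
#' weighting comparison is restricted to those (shared) muscles.
#'
#' @param struct_a,struct_b [synergy_structure()] objects.
#' @param muscles Optional character vector of muscle names to restrict
#'   the weighting comparison to.
#' @param n_points,cycle_average See [mean_correlation()].
#' @return Object of class `comparison_report`.
#' @export
compare_structures <- function(struct_a, struct_b, muscles = NULL,
                               n_points = 30, cycle_average = TRUE) {
  Wa <- struct_a$W; Wb <- struct_b$W
  if (!is.null(muscles)) {
    if (is.null(rownames(Wa)) || is.null(rownames(Wb)))
      stop("muscle-restricted comparison needs named weighting rows")
    Wa <- Wa[muscles, , drop = FALSE]
    Wb <- Wb[muscles, , drop = FALSE]
  }
  corr <- match_synergies(Wa, Wb)
  si <- attr(corr, "si")
  ra <- resample_controls(struct_a, n_points, cycle_average)
  rb <- resample_controls(struct_b, n_points, cycle_average)
  n <- ncol(Wa)
  rho <- matrix(NA_real_, n, length(ra),
                dimnames = list(paste0("syn", seq_len(n)),
                                struct_a$conditions))
  for (k in seq_len(n)) for (s in seq_along(ra)) {
    # a degenerate (constant) control leaves that entry undefined
    rho[k, s] <- tryCatch(control_correlation(ra[[s]][[k]],
                                              rb[[s]][[corr[k]]])$rho,
                          error = function(e) NA_real_)
  }
  mc <- mean_correlation(struct_a, struct_b, corr, n_points, cycle_average)
  out <- list(correspondence = as.integer(corr),
              si_per_synergy = si,
              si_mean = mean(si), si_sd = stats::sd(si),
              rho_per_signal = rho,
              rho_mean = mc$rho, rho_mean_p = mc$p_value,
              bands = list(si_mean = classify_similarity(mean(si)),
                           rho_mean = classify_similarity(mc$rho)))
  class(out) <- "comparison_report"
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("synergy comparison: mean SI = %.3f (%s), mean rho = %.3f (%s)\n",
              x$si_mean, x$bands$si_mean, x$rho_mean, x$bands$rho_mean))
  cat("  correspondence:", paste(seq_along(x$correspondence),
                                 x$correspondence, sep = "->",
                                 collapse = ", "), "\n")
  invisible(x)
}
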