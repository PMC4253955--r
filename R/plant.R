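#' Synthetic gait-like plant
#'
#' Generates fully synthetic movement conditions — smooth periodic
#' muscle-tendon lengths, signed moment arms, and joint moments produced by
#' forward simulation of a known ground-truth synergy structure — so that
#' every workflow can be tested by parameter recovery without external
#' data. Moment arms are generated independently of the muscle-tendon
#' lengths (the plant has no joint-angle coordinate); the decomposition
#' consumes both as independent experimental inputs, so this is a
#' deliberate physical simplification.
#'
#' @name synthetic_plant
#' @keywords internal
NULL

#' Specify a synthetic plant
#'
#' @param n_muscles Number of muscles (must exceed `n_dofs`).
#' @param n_dofs Number of degrees of freedom.
#' @param conditions List of conditions, each with `period` (gait-cycle
#'   duration, s) and `n_cycles`. The defaults use one cycle per condition
#'   so that a ~36-node grid has ~0.03 s node spacing, which resolves the
#'   activation dynamics (time constant 0.015 s); coarser grids cannot be
#'   reproduced by forward simulation.
#' @param seed Integer seed; the plant is deterministic given the seed.
#' @param noise Relative moment noise amplitude (fraction of each DOF's
#'   moment range) added by [generate_trials()].
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(n_muscles = 8L, n_dofs = 3L,
                       conditions = list(list(period = 1.1, n_cycles = 1L),
                                         list(period = 0.85, n_cycles = 1L)),
                       seed = 1L, noise = 0) {
  if (n_muscles <= n_dofs) stop("n_muscles must exceed n_dofs")
  if (noise < 0) stop("noise must be >= 0")
  for (cn in conditions)
    if (is.null(cn$period) || cn$period <= 0 || is.null(cn$n_cycles))
      stop("each condition needs a positive period and n_cycles")
  structure(list(n_muscles = as.integer(n_muscles),
                 n_dofs = as.integer(n_dofs), conditions = conditions,
                 seed = as.integer(seed), noise = noise),
            class = "plant_spec")
}

# seeded, physiologically plausible muscle parameter table
default_muscle_params <- function(n_muscles, seed = 1L) {
  with_local_seed(seed, {
    l_opt <- stats::runif(n_muscles, 0.08, 0.12)
    muscle_set(
      name = sprintf("mus%02d", seq_len(n_muscles)),
      f_max = stats::runif(n_muscles, 1500, 3500),
      l_opt = l_opt,
      alpha_opt = stats::runif(n_muscles, 0, 0.15),
      l_slack = stats::runif(n_muscles, 1.5, 2.5) * l_opt,
      eps_t_max = ifelse(seq_len(n_muscles) %% 4 == 0, 0.10, 0.04),
      v_max = 10, tau_act = 0.015, tau_deact = 0.06)
  })
}

#' Build a synthetic plant
#'
#' Per muscle and condition, a smooth periodic muscle-tendon length (mean
#' at a mid-range tendon strain plus two seeded low-order harmonics whose
#' excursion keeps the resting normalized fiber length within
#' `[0.6, 1.3]`); per muscle and DOF, smooth periodic signed moment arms
#' with magnitudes within 0.06 m, sparse so each muscle spans 1-2 DOFs,
#' and with both moment directions actuated at every DOF. Deterministic
#' given the seed; geometry draws failing the feasibility check are
#' redrawn (at most 100 attempts).
#'
#' @param spec A [plant_spec()].
#' @return Object of class `synthetic_plant` with the muscle table and,
#'   per condition, vectorized `lmt_fun(t)` (muscles x time) and
#'   `arm_fun(t)` (muscles x DOFs x time) generators.
#' @export
make_plant <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  m <- spec$n_muscles; nj <- spec$n_dofs
  muscles <- default_muscle_params(m, spec$seed)
  p <- .plist(muscles)
  # mean length: fiber at optimal length, tendon at ~55% of eps_t_max
  L0 <- p$l_opt * cos(p$alpha_opt) + p$l_slack * (1 + 0.55 * p$eps_t_max)

  for (attempt in seq_len(100)) {
    sub <- spec$seed + 1000L * attempt
    built <- with_local_seed(sub, {
      conds <- lapply(seq_along(spec$conditions), function(s) {
        T <- spec$conditions[[s]]$period
        a1 <- stats::runif(m, 0.04, 0.09) * p$l_opt
        a2 <- stats::runif(m, 0.01, 0.03) * p$l_opt
        ph1 <- stats::runif(m, 0, 2 * pi); ph2 <- stats::runif(m, 0, 2 * pi)
        # moment-arm sparsity: primary DOF round-robin with alternating
        # sign blocks, optional weaker secondary DOF
        r0 <- matrix(0, m, nj); r1 <- matrix(0, m, nj)
        phr <- matrix(stats::runif(m * nj, 0, 2 * pi), m, nj)
        for (i in seq_len(m)) {
          d <- (i - 1) %% nj + 1
          # consecutive blocks of nj muscles alternate sign, so each DOF
          # sees agonists and antagonists
          sgn <- if (((i - 1) %/% nj) %% 2 == 0) 1 else -1
          r0[i, d] <- sgn * stats::runif(1, 0.035, 0.049)
          if (stats::runif(1) < 0.5) {
            d2 <- sample(setdiff(seq_len(nj), d), 1)
            r0[i, d2] <- sample(c(-1, 1), 1) * stats::runif(1, 0.01, 0.02)
          }
        }
        # ripple kept small enough that |r0| + |r1| stays within 0.06 m
        r1 <- r0 * matrix(stats::runif(m * nj, 0.1, 0.2), m, nj)
        list(period = T, n_cycles = spec$conditions[[s]]$n_cycles,
             duration = T * spec$conditions[[s]]$n_cycles,
             a1 = a1, a2 = a2, ph1 = ph1, ph2 = ph2,
             r0 = r0, r1 = r1, phr = phr)
      })
      conds
    })
    conds <- lapply(built, function(cf) {
      force(cf)
      lmt_fun <- function(t) {
        w <- 2 * pi / cf$period
        outer(cf$a1, rep(1, length(t))) * sin(outer(cf$ph1, w * t, `+`)) +
          outer(cf$a2, rep(1, length(t))) * sin(outer(cf$ph2, 2 * w * t, `+`)) +
          L0
      }
      arm_fun <- function(t) {
        w <- 2 * pi / cf$period
        out <- array(0, c(m, nj, length(t)))
        for (j in seq_len(nj))
          out[, j, ] <- cf$r0[, j] +
            outer(cf$r1[, j], rep(1, length(t))) *
              sin(outer(cf$phr[, j], w * t, `+`))
        out
      }
      list(period = cf$period, n_cycles = cf$n_cycles,
           duration = cf$duration, lmt_fun = lmt_fun, arm_fun = arm_fun,
           coef = cf)
    })
    # feasibility: bidirectional actuation and resting fiber-length range
    ok <- TRUE
    for (cn in conds) {
      for (j in seq_len(nj)) {
        rj <- cn$coef$r0[, j]
        if (!any(rj > 0) || !any(rj < 0)) ok <- FALSE
      }
      tchk <- seq(0, cn$period, length.out = 13)
      lrest <- vapply(tchk, function(t)
        equilibrium_fiber_length(rep(0.01, m), drop(cn$lmt_fun(t)),
                                 muscles) / p$l_opt,
        numeric(m))
      if (any(lrest < 0.6) || any(lrest > 1.3)) ok <- FALSE
    }
    if (ok) {
      return(structure(list(spec = spec, muscles = muscles,
                            conditions = conds, seed = spec$seed),
                       class = "synthetic_plant"))
    }
  }
  stop("could not draw a feasible plant geometry in 100 attempts")
}

# raised-cosine bump train: one smooth burst per gait cycle
.rc_bump <- function(t, period, onset, width) {
  x <- (t - onset) %% period
  ifelse(x < width, 0.5 * (1 - cos(2 * pi * x / width)), 0)
}

#' Draw a ground-truth synergy structure for a plant
#'
#' Sparse non-negative weightings (each synergy dominated by 2-4 muscles)
#' shared across conditions; per-condition controls are smooth
#' raised-cosine burst trains phase-locked to the gait cycle (one burst
#' per cycle, width 0.4-0.6 cycle, on a small tonic baseline), redrawn and
#' rescaled until all excitations lie within (0.02, 0.95).
#'
#' @param plant A [make_plant()] result.
#' @param n_syn Number of true synergies.
#' @param seed Integer seed.
#' @return Object of class `ground_truth`: `W`, per-condition control
#'   functions `h_funs`, the muscle table and initial states.
#' @export
make_ground_truth <- function(plant, n_syn = 3L, seed = 1L) {
  m <- plant$spec$n_muscles
  if (n_syn >= m) stop("n_syn must be below the muscle count")
  for (attempt in seq_len(100)) {
    draw <- with_local_seed(seed + 1000L * attempt, {
      W <- matrix(0, m, n_syn)
      for (i in seq_len(m)) {
        k <- (i - 1) %% n_syn + 1
        W[i, k] <- stats::runif(1, 0.6, 1)
        if (stats::runif(1) < 0.4) {
          k2 <- sample(setdiff(seq_len(n_syn), k), 1)
          W[i, k2] <- stats::runif(1, 0.05, 0.25)
        }
      }
      hpars <- lapply(plant$conditions, function(cn) {
        list(base = stats::runif(n_syn, 0.04, 0.08),
             amp = stats::runif(n_syn, 0.3, 0.5),
             width = stats::runif(n_syn, 0.4, 0.6) * cn$period,
             onset = stats::runif(n_syn, 0, cn$period))
      })
      list(W = W, hpars = hpars)
    })
    W <- draw$W
    # scale bases so min excitation clears the 0.02 floor
    umin <- min(W %*% vapply(draw$hpars, `[[`, numeric(n_syn), "base"))
    if (umin <= 0) next
    fb <- max(1, 0.03 / umin)
    for (s in seq_along(draw$hpars))
      draw$hpars[[s]]$base <- draw$hpars[[s]]$base * fb
    # scale burst amplitudes so peak excitation sits in [0.8, 0.9],
    # the upper part of the admissible (0.02, 0.95) band: strong bursts
    # are what make the moments gait-scale
    peak_u <- function() {
      umax <- 0
      for (s in seq_along(plant$conditions)) {
        cn <- plant$conditions[[s]]
        hp <- draw$hpars[[s]]
        tt <- seq(0, cn$duration, length.out = 400)
        H <- t(vapply(seq_len(n_syn), function(k)
          hp$base[k] + hp$amp[k] * .rc_bump(tt, cn$period, hp$onset[k],
                                            hp$width[k]),
          numeric(length(tt))))
        umax <- max(umax, max(W %*% H))
      }
      umax
    }
    for (it in seq_len(200)) {
      umax <- peak_u()
      if (umax <= 0.9 && umax >= 0.8) break
      fac <- if (umax > 0.9) 0.92 else 1.1
      for (s in seq_along(draw$hpars))
        draw$hpars[[s]]$amp <- draw$hpars[[s]]$amp * fac
    }
    if (umax > 0.9 || umax < 0.8) next
    h_funs <- lapply(seq_along(plant$conditions), function(s) {
      cn <- plant$conditions[[s]]
      hp <- draw$hpars[[s]]
      force(hp); force(cn)
      function(t) vapply(seq_len(n_syn), function(k)
        hp$base[k] + hp$amp[k] * .rc_bump(t, cn$period, hp$onset[k],
                                          hp$width[k]), numeric(length(t)))
    })
    a0 <- lapply(seq_along(plant$conditions), function(s) {
      u0 <- pmin(pmax(drop(W %*% h_funs[[s]](0)), 0.01), 1)
      l0 <- equilibrium_fiber_length(u0, drop(plant$conditions[[s]]$lmt_fun(0)),
                                     plant$muscles)
      list(a = u0, l = l0)
    })
    rownames(W) <- plant$muscles$name
    return(structure(list(W = W, h_funs = h_funs, hpars = draw$hpars,
                          muscles = plant$muscles, initial_states = a0,
                          n_syn = n_syn, seed = seed),
                     class = "ground_truth"))
  }
  stop("could not draw an admissible ground truth in 100 attempts")
}

#' Generate synthetic trials from a ground truth
#'
#' Forward-integrates the muscle dynamics under the true synergy structure
#' over each condition, samples moments, muscle-tendon lengths and moment
#' arms on a uniform collocation grid, and (optionally) adds seeded
#' Gaussian noise to the moments only (standard deviation = `noise` times
#' each DOF's noise-free moment range).
#'
#' @param truth A [make_ground_truth()] result.
#' @param plant The matching [make_plant()] result.
#' @param points Nodes per condition (recycled), default 36.
#' @param noise Relative moment noise amplitude (overrides the plant
#'   spec's value when given).
#' @param seed Seed for the noise draw.
#' @param rtol Integration tolerance.
#' @return List of [trial_data()] objects, with the true structure sampled
#'   on the same grids in attribute `"truth_structure"`.
#' @export
generate_trials <- function(truth, plant, points = 36L, noise = NULL,
                            seed = 1L, rtol = 1e-8) {
  if (is.null(noise)) noise <- plant$spec$noise
  p <- .plist(plant$muscles)
  m <- plant$spec$n_muscles
  points <- rep_len(as.integer(points), length(plant$conditions))
  trials <- list(); Hs <- list(); tsl <- list(); cyc <- list()
  for (s in seq_along(plant$conditions)) {
    cn <- plant$conditions[[s]]
    tt <- seq(0, cn$duration, length.out = points[s])
    # controls are sampled at the grid nodes and linearly interpolated
    # between them: the generated moments then correspond exactly to the
    # piecewise-linear control parameterization the decomposition uses
    Hnod <- t(truth$h_funs[[s]](tt))
    h_fun <- .interp_rows(tt, Hnod)
    # lengths are likewise node-sampled and linearly interpolated: the
    # sampled trial arrays are the ground truth the decomposition sees
    Lmt_nod <- cn$lmt_fun(tt) # muscles x nodes
    lmt_fun <- .interp_rows(tt, Lmt_nod)
    y0 <- c(truth$initial_states[[s]]$a,
            truth$initial_states[[s]]$l / p$l_opt)
    sim <- .integrate_condition(truth$W, h_fun, lmt_fun, y0, p, tt, rtol)
    L <- sweep(sim$Lnorm, 2, p$l_opt, "*")
    Lmt <- t(Lmt_nod)
    colnames(Lmt) <- p$name
    Fm <- t(.fiber_force(t(L), t(Lmt), p))
    arms <- aperm(cn$arm_fun(tt), c(3, 1, 2))
    dimnames(arms) <- list(NULL, p$name, paste0("dof", seq_len(dim(arms)[3])))
    M <- matrix(0, length(tt), dim(arms)[3],
                dimnames = list(NULL, paste0("dof", seq_len(dim(arms)[3]))))
    for (j in seq_len(ncol(M))) M[, j] <- rowSums(arms[, , j] * Fm)
    if (noise > 0) {
      sdj <- noise * apply(M, 2, function(x) diff(range(x)))
      M <- M + with_local_seed(seed + 31L * s, {
        matrix(stats::rnorm(length(M)), nrow(M)) %*% diag(sdj, ncol(M))
      })
    }
    cycles <- seq(0, cn$duration, by = cn$period)
    trials[[s]] <- trial_data(paste0("cond", s), tt, M, Lmt, arms, cycles)
    Hs[[s]] <- Hnod
    tsl[[s]] <- tt; cyc[[s]] <- cycles
  }
  ts <- synergy_structure(truth$W, Hs, tsl, cyc,
                          vapply(trials, `[[`, "", "condition"))
  attr(trials, "truth_structure") <- ts
  trials
}

#' One-call synthetic fixture
#'
#' Builds the default plant, ground truth and noise-free trials used by
#' the package's recovery experiments.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_syn True synergy count (default 3).
#' @param points Collocation nodes per condition (default 36).
#' @param spec Optional [plant_spec()] override.
#' @return List with `plant`, `truth`, `trials` and `truth_structure`.
#' @export
synthetic_fixture <- function(seed = 1L, n_syn = 3L, points = 36L,
                              spec = NULL) {
  if (is.null(spec)) spec <- plant_spec(seed = seed)
  plant <- make_plant(spec)
  truth <- make_ground_truth(plant, n_syn = n_syn, seed = seed + 1L)
  trials <- generate_trials(truth, plant, points = points,
                            noise = spec$noise, seed = seed + 2L)
  list(plant = plant, truth = truth, trials = trials,
       truth_structure = attr(trials, "truth_structure"))
}
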