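test_that("the similarity index is the normalized dot product", {
  expect_equal(similarity_index(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(similarity_index(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(similarity_index(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_equal(round(similarity_index(c(1, 1, 0), c(1, 0, 0)), 4), 0.7071)
  # scale invariance
  for (cc in c(0.1, 3, 250))
    expect_equal(similarity_index(c(0.2, 0.5, 0.1), cc * c(0.2, 0.5, 0.1)), 1)
  expect_error(similarity_index(c(0, 0), c(1, 1)), "zero")
  expect_error(similarity_index(c(1, 2), c(1, 2, 3)), "length")
  expect_error(similarity_index(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("synergy matching recovers permutations and rescalings", {
  set.seed(12)
  W <- matrix(runif(15, 0, 1), 5, 3)
  perm <- c(3, 1, 2)
  Wb <- W[, perm] %*% diag(c(2, 0.5, 7))
  got <- match_synergies(W, Wb)
  expect_equal(as.integer(got), order(perm))
  expect_equal(attr(got, "si"), rep(1, 3), tolerance = 1e-12)
})

test_that("optimal matching agrees with exhaustive permutation search", {
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    out <- NULL
    for (i in seq_len(n)) {
      sub <- perms(n - 1)
      out <- rbind(out, cbind(i, matrix((seq_len(n))[-i][sub],
                                        nrow(sub))))
    }
    out
  }
  set.seed(77)
  for (n in 2:5) {
    for (rep in 1:4) {
      Wa <- matrix(runif(6 * n, 0, 1), 6, n)
      Wb <- matrix(runif(6 * n, 0, 1), 6, n)
      got <- match_synergies(Wa, Wb)
      S <- attr(got, "si_matrix")
      pm <- perms(n)
      scores <- apply(pm, 1, function(pp) sum(S[cbind(seq_len(n), pp)]))
      expect_equal(sum(S[cbind(seq_len(n), as.integer(got))]),
                   max(scores), tolerance = 1e-12)
    }
  }
})

test_that("control correlations follow Pearson's definition", {
  h <- c(0.1, 0.5, 0.9, 0.4, 0.2)
  expect_equal(control_correlation(h, 2 * h + 1)$rho, 1)
  expect_equal(control_correlation(h, -h)$rho, -1)
  r <- control_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_error(control_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("the mean correlation concatenates cycle-normalized controls", {
  fx <- default_fixture()
  st <- fx$truth_structure
  expect_equal(mean_correlation(st, st)$rho, 1)
  # per-signal positive rescaling: must equal a direct evaluation of the
  # definition on the concatenated 30-point vectors
  st2 <- st
  scales <- c(2.0, 0.5, 1.7)
  st2$H <- lapply(st2$H, function(h) h * scales)
  got <- mean_correlation(st, st2)$rho
  ra <- syntorq:::resample_controls(st, 30, TRUE)
  va <- c(); vb <- c()
  for (k in seq_len(nrow(st$H[[1]]))) for (s in seq_along(ra)) {
    va <- c(va, ra[[s]][[k]])
    vb <- c(vb, ra[[s]][[k]] * scales[k])
  }
  expect_equal(got, stats::cor(va, vb), tolerance = 1e-12)
  # symmetry
  expect_equal(mean_correlation(st2, st)$rho, got, tolerance = 1e-12)
})

test_that("the 30-point resampling makes the statistic sampling-rate invariant", {
  fx <- default_fixture()
  st <- fx$truth_structure
  # upsample one structure's controls onto a 4x finer grid
  st_fine <- st
  for (s in seq_along(st$H)) {
    tt <- st$time[[s]]
    tf <- seq(tt[1], tt[length(tt)], length.out = 4 * length(tt))
    st_fine$H[[s]] <- t(apply(st$H[[s]], 1, function(h)
      stats::approx(tt, h, tf)$y))
    st_fine$time[[s]] <- tf
  }
  expect_equal(mean_correlation(st, st_fine)$rho, 1, tolerance = 1e-3)
})

test_that("similarity bands follow the published cutoffs", {
  expect_equal(classify_similarity(0.86), "high")
  expect_equal(classify_similarity(0.60), "moderate")
  expect_equal(classify_similarity(0.49), "low")
  expect_equal(classify_similarity(0.8), "moderate")
  expect_equal(classify_similarity(0.5), "moderate")
  expect_equal(classify_similarity(c(0.9, 0.2)), c("high", "low"))
  expect_error(classify_similarity(NaN), "non-finite")
})

test_that("structure comparison reports a coherent correspondence", {
  fx <- default_fixture()
  st <- fx$truth_structure
  st2 <- st
  st2$W <- st$W[, c(2, 3, 1)] * 1.4
  st2$H <- lapply(st$H, function(h) h[c(2, 3, 1), ] / 1.4)
  rep <- compare_structures(st, st2)
  expect_equal(rep$correspondence, c(3, 1, 2))
  expect_equal(rep$si_mean, 1, tolerance = 1e-12)
  expect_equal(rep$rho_mean, 1, tolerance = 1e-12)
  expect_equal(rep$bands$si_mean, "high")
})
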