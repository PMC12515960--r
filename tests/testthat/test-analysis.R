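make_phase_info <- function(P, S, labels) {
  data.frame(label = labels, P = P, S = S, stringsAsFactors = FALSE)
}

test_that("PE classification applies both thresholds", {
  pop <- population_spec(n_pc = 4, n_pv = 1, n_som = 8, n_vip = 1,
                         martinotti_fraction = 0.5, n_groups = 4)
  bank <- assign_preferred_stimuli(pop, feature_space = 0:3)
  info <- make_phase_info(P = c("0", "0"), S = c("0", "1"),
                          labels = c("match", "mismatch"))
  # neuron 2 prefers 1: baseline 1.25, match 1.30 (4%), mismatch 2.0 (60%)
  resp <- rbind(match = c(1.30, 1.30, 1.30, 1.30),
                mismatch = c(2.0, 2.0, 1.45, 1.45))
  cls <- classify_pe(resp, info, rep(1.25, 4), bank)
  expect_true(cls$is_pe[2])        # 4% match, 60% mismatch
  expect_false(cls$is_pe[3])       # mismatch only 16% < 20%
  # match violation: 16% > 10%
  resp2 <- rbind(match = c(1.45, 1.45, 1.45, 1.45),
                 mismatch = c(2.0, 2.0, 2.0, 2.0))
  cls2 <- classify_pe(resp2, info, rep(1.25, 4), bank)
  expect_false(any(cls2$is_pe))
  # scale invariance: alpha * rates leaves dR/R and the verdict unchanged
  cls3 <- classify_pe(3 * resp, info, rep(3 * 1.25, 4), bank)
  expect_identical(cls$is_pe, cls3$is_pe)
  expect_equal(cls$delta_r, cls3$delta_r, tolerance = 1e-12)
  # zero baseline flagged unclassifiable
  cls4 <- classify_pe(resp, info, c(0, rep(1.25, 3)), bank)
  expect_true(is.na(cls4$is_pe[1]))
})

test_that("selectivity coefficient matches brute-force moments", {
  # brute force: population moments of the group means
  brute <- function(m) {
    d <- m - mean(m)
    if (mean(d^2) < 1e-12) 0 else mean(d^3) / mean(d^2)^1.5
  }
  cases <- list(c(0.5, 1.25, 1.25, 1.25), c(2, 1, 4, 3), c(5, 5, 5, 1e-7 + 5))
  for (m in cases) {
    expect_equal(selectivity_coefficient(m)$gamma, brute(m), tolerance = 1e-9)
  }
  expect_equal(selectivity_coefficient(c(0.5, 1.25, 1.25, 1.25))$gamma,
               -1.154701, tolerance = 1e-5)
  # degenerate: equal group means give exactly zero
  expect_identical(selectivity_coefficient(rep(2, 4))$gamma, 0)
  # translation and scale invariance
  m <- c(0.4, 1.1, 1.9, 0.8)
  expect_equal(selectivity_coefficient(m)$gamma,
               selectivity_coefficient(m + 10)$gamma, tolerance = 1e-9)
  expect_equal(selectivity_coefficient(m)$gamma,
               selectivity_coefficient(5 * m)$gamma, tolerance = 1e-9)
  expect_error(selectivity_coefficient(c(1, 2)), "3 groups")
})

test_that("similarity follows the tuning ratio (1-D) and norm form (2-D)", {
  bank <- list(sigma_pc = 0.8)
  expect_equal(similarity(1, 1, bank), 1)
  expect_equal(similarity(0, 1, bank), exp(-1 / (2 * 0.64)))
  expect_equal(similarity(c(0, 2), c(0, 2), bank), 1)
  expect_equal(similarity(c(0, 2), c(0, 3), bank), 1 - mean(c(0, 1 / 5)))
  expect_error(similarity(c(0, 0), c(0, 0), bank), "zero-norm")
})

test_that("tuning fits recover noiseless Gaussian parameters", {
  x <- 0:3
  truth <- data.frame(a = c(10, 8), mu = c(1, 2.2), s = c(0.9, 1.1))
  y <- t(sapply(seq_len(2), function(g) {
    truth$a[g] * exp(-(x - truth$mu[g])^2 / (2 * truth$s[g]^2))
  }))
  fits <- fit_tuning_curves(x, y)
  expect_true(all(fits$converged))
  expect_lt(max(abs(fits$mu - truth$mu)), 1e-3)
  # amplitude-only scaling leaves the fitted peak unchanged
  fits2 <- fit_tuning_curves(x, 3 * y)
  expect_equal(fits2$mu, fits$mu, tolerance = 1e-6)
})

test_that("mismatch scaling table orders and averages distances", {
  pop <- population_spec(n_pc = 4, n_pv = 1, n_som = 8, n_vip = 1,
                         martinotti_fraction = 0.5, n_groups = 4)
  bank <- assign_preferred_stimuli(pop, feature_space = 0:3)
  info <- make_phase_info(P = rep("0", 4), S = c("1", "2", "3", "1"),
                          labels = rep("mismatch", 4))
  resp <- rbind(c(0, 2, 0, 0), c(0, 0, 5, 0), c(0, 0, 0, 9), c(0, 4, 0, 0))
  ms <- mismatch_scaling(resp, info, pop, bank)
  # duplicate distance 1 averaged: (2 + 4) / 2
  expect_equal(ms$table$mean_response, c(3, 5, 9))
  expect_equal(ms$table$distance, c(1, 2, 3))
  expect_true(ms$monotone_increasing)
  expect_equal(ms$spearman_rho, 1)
  expect_error(mismatch_scaling(resp[1, , drop = FALSE], info[1, ], pop, bank),
               "two mismatch")
})

test_that("pathway decomposition satisfies the conservation identity", {
  set.seed(31)
  for (rep in seq_len(10)) {
    n <- 3
    W <- matrix(rnorm(81), 9, 9) - 5 * diag(9)   # well-conditioned
    S <- abs(rnorm(9))
    pd <- pathway_decomposition(W, S, n_groups = n, n_dendrites = 2)
    M <- solve(W)
    for (comp in seq_len(3)) {
      ii <- (comp - 1) * n + seq_len(n)
      tab <- pd$table[pd$table$compartment ==
                        c("soma", "dend1", "dend2")[comp], ]
      expect_equal(tab$path_E - tab$path_I,
                   drop(M[ii, ii] %*% S[ii]), tolerance = 1e-10)
      expect_true(all(tab$path_E >= 0) && all(tab$path_I >= 0))
    }
  }
  expect_error(pathway_decomposition(matrix(0, 2, 2), c(1, 1), 1), "singular")
})

test_that("2x2 diagonal case reduces to elementwise sign splits", {
  W <- diag(c(-2, -4))
  S <- c(3, 8)
  pd <- pathway_decomposition(W, S, n_groups = 2, n_dendrites = 0)
  tab <- pd$table
  # M = diag(-1/2, -1/4); all entries negative: path_E = 0, path_I = |M S|
  expect_equal(tab$path_E, c(0, 0))
  expect_equal(tab$path_I, c(1.5, 2))
  # r = -M S recovers the expected steady state
  expect_equal(linear_steady_state(W, S), c(1.5, 2))
})

test_that("condition comparison reports both tests sensibly", {
  set.seed(5)
  a <- rnorm(50)
  cmp_same <- compare_conditions(a, a)
  expect_lt(abs(cmp_same$t_statistic), 1e-10)
  expect_gt(cmp_same$u_p, 0.9)
  b <- rnorm(50, mean = 10)
  cmp_diff <- compare_conditions(a, b)
  expect_lt(cmp_diff$t_p, 1e-6)
  expect_lt(cmp_diff$u_p, 1e-6)
  expect_error(compare_conditions(1, a), "2 samples")
})
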