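test_that("softplus is stable, correct and invertible", {
  expect_equal(softplus(0), log(2))
  expect_equal(softplus(50), 50, tolerance = 1e-12)
  expect_equal(softplus(-745), 0, tolerance = 1e-300)
  expect_true(is.finite(softplus(1e4)) && softplus(1e4) == 1e4)
  expect_equal(softplus_inverse(softplus(1.3)), 1.3, tolerance = 1e-10)
  v <- seq(-30, 30, by = 0.5)
  expect_equal(softplus_inverse(softplus(v)), v, tolerance = 1e-8)
  expect_error(softplus_inverse(0), "positive")
})

fake_steady <- function(net, r_E, r_P, r_S, r_V, A = NULL) {
  if (is.null(A)) A <- matrix(0, net$pop$n_pc, net$pop$n_dendrites)
  structure(list(r_E = r_E, r_P = r_P, r_S = r_S, r_V = r_V, A_dend = A),
            class = "pe_state")
}

test_that("somatic rule: magnitude, gating and fixed point", {
  net <- default_net_1d(seed = 12)
  plast <- plasticity_params()
  # at target: no update
  st <- fake_steady(net, rep(1.25, 280), rep(1, 40), rep(1, 40), rep(1, 40))
  expect_true(all(update_soma_inhibition(st, net$conn, net$pop, plast, "P") == 0))
  # unit error, unit presynaptic rate, saturated gradient -> eta
  conn <- net$conn
  conn$v$EP[conn$mask$EP > 0] <- 50   # logistic ~ 1
  st2 <- fake_steady(net, rep(1.25 + 1, 280), rep(1, 40), rep(1, 40), rep(1, 40))
  dv <- update_soma_inhibition(st2, conn, net$pop, plast, "P")
  on <- conn$mask$EP > 0
  expect_equal(unique(round(dv[on], 12)), 1e-4)
  expect_true(all(dv[!on] == 0))
  # silent presynaptic interneuron: no update
  st3 <- fake_steady(net, rep(2, 280), rep(0, 40), rep(1, 40), rep(1, 40))
  expect_true(all(update_soma_inhibition(st3, net$conn, net$pop, plast, "P") == 0))
})

test_that("dendritic rule combines somatic and dendritic errors", {
  net <- default_net_1d(seed = 12)
  plast <- plasticity_params()
  eps <- matrix(2, 280, 1)
  # r at target and A at epsilon: no update
  st <- fake_steady(net, rep(1.25, 280), rep(1, 40), rep(2, 40), rep(1, 40),
                    A = eps)
  expect_true(all(update_dendrite_inhibition(st, net$conn, net$pop, plast,
                                             net$params, eps, 1) == 0))
  # dendritic deviation of 10, rate at target, presynaptic Martinotti at 2
  conn <- net$conn
  conn$v$D1M[conn$mask$D1M > 0] <- 50
  st2 <- fake_steady(net, rep(1.25, 280), rep(1, 40), rep(2, 40), rep(1, 40),
                     A = eps + 10)
  dv <- update_dendrite_inhibition(st2, conn, net$pop, plast, net$params,
                                   eps, 1)
  on <- conn$mask$D1M > 0
  expect_equal(unique(round(dv[on], 12)), 1e-6 * 10 * 2)
  # silent Martinotti cells: no update
  st3 <- fake_steady(net, rep(2, 280), rep(1, 40), rep(0, 40), rep(1, 40),
                     A = eps + 10)
  expect_true(all(update_dendrite_inhibition(st3, net$conn, net$pop, plast,
                                             net$params, eps, 1) == 0))
})

test_that("PV-afferent rule backpropagates the PC error with opposite sign", {
  net <- default_net_1d(seed = 12)
  plast <- plasticity_params()
  # all PCs at target: no update
  st <- fake_steady(net, rep(1.25, 280), rep(1, 40), rep(1, 40), rep(1, 40))
  expect_true(all(update_pv_afferents(st, net$conn, net$pop, plast, "S") == 0))
  # PCs uniformly above target with positive E<-PV weights: SOM->PV and
  # VIP->PV weights decrease (PV disinhibited, PCs more inhibited)
  st2 <- fake_steady(net, rep(3, 280), rep(1, 40), rep(1, 40), rep(1, 40))
  for (pw in c("S", "V")) {
    dv <- update_pv_afferents(st2, net$conn, net$pop, plast, pw)
    nm <- if (pw == "S") "PS" else "PV"
    on <- net$conn$mask[[nm]] > 0
    expect_true(all(dv[on] <= 0) && any(dv[on] < 0))
  }
  # silent presynaptic population: no update
  st3 <- fake_steady(net, rep(3, 280), rep(1, 40), rep(0, 40), rep(0, 40))
  expect_true(all(update_pv_afferents(st3, net$conn, net$pop, plast, "S") == 0))
  expect_true(all(update_pv_afferents(st3, net$conn, net$pop, plast, "V") == 0))
})

test_that("all rules vanish simultaneously at the joint fixed point", {
  net <- default_net_1d(seed = 13)
  plast <- plasticity_params()
  eps <- matrix(1.5, 280, 1)
  st <- fake_steady(net, rep(plast$rho, 280), rep(2, 40), rep(2, 40),
                    rep(2, 40), A = eps)
  conn2 <- pecircuit:::apply_all_updates(net$conn, st, net$pop, net$params,
                                         plast, eps)
  for (nm in net$conn$plastic) {
    expect_equal(conn2$W[[nm]], net$conn$W[[nm]], tolerance = 1e-14)
  }
})

test_that("weights stay positive under arbitrary updates", {
  net <- default_net_1d(seed = 14)
  conn <- net$conn
  set.seed(1)
  for (nm in conn$plastic) {
    conn$v[[nm]] <- conn$v[[nm]] - matrix(abs(rnorm(length(conn$v[[nm]]), 5)),
                                          nrow(conn$v[[nm]]))
    w <- softplus(conn$v[[nm]]) * conn$mask[[nm]]
    expect_true(all(w[conn$mask[[nm]] > 0] > 0))
  }
})

test_that("zero learning rates leave the connectivity unchanged", {
  net <- default_net_1d(seed = 2)
  plast <- plasticity_params(eta_EP = 0, eta_ES = 0, eta_DS = 0, eta_PS = 0,
                             eta_PV = 0, n_presentations = 3)
  tr <- train_network(net$conn, net$pop, net$bank, net$params, plast,
                      seed = 1)
  for (nm in names(net$conn$W)) {
    expect_equal(tr$conn$W[[nm]], net$conn$W[[nm]], tolerance = 1e-15)
  }
})

test_that("training drives match-phase rates towards the target", {
  tn <- trained_1d()
  h <- tn$training$history
  early <- mean(head(h$err_match, 3))
  late <- mean(tail(h$err_match, 3))
  expect_lt(late, early / 5)
})

test_that("training differentiates inhibitory weights by PC preference", {
  tn <- trained_1d()
  # somatic SOM inhibition becomes preference-aligned: after training a PC
  # receives systematically stronger weights from non-Martinotti cells of
  # its own selectivity group than from cross-preference cells
  same_cross_ratio <- function(conn) {
    W <- conn$W$EnM
    nm_grp <- tn$pop$som_group[tn$pop$idx_nM]
    same <- cross <- numeric(tn$pop$n_pc)
    for (i in seq_len(tn$pop$n_pc)) {
      g <- tn$pop$pc_group[i]
      same[i] <- sum(W[i, nm_grp == g])
      cross[i] <- sum(W[i, nm_grp != g])
    }
    # per-cell normalization: 1 own group vs n_groups - 1 others
    (mean(same)) / (mean(cross) / (tn$pop$n_groups - 1))
  }
  r0 <- same_cross_ratio(tn$conn)
  r1 <- same_cross_ratio(tn$conn_trained)
  expect_lt(abs(r0 - 1), 0.25)   # untrained: exchangeable
  expect_gt(r1, 2 * r0)          # trained: preference-aligned
})
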