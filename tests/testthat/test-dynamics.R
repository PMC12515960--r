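test_that("single-unit fixed point matches the closed form", {
  # one PC, no recurrence, constant input I: h* = I - theta, r* = [h*]_+
  pop <- population_spec(n_pc = 1, n_pv = 1, n_som = 2, n_vip = 1,
                         martinotti_fraction = 0.5, n_groups = 1)
  prob <- default_connection_probs() * 0
  spec <- connectivity_spec(prob = prob)
  conn <- suppressWarnings(sample_connectivity(pop, spec, seed = 1))
  params <- model_params(c_amp = 0)
  inputs <- list(x_E = 20 / (1 - params$lambda_E), x_D = matrix(0, 1, 1),
                 x_P = 0, x_S = c(0, 0), x_V = 0)
  st <- run_to_steady_state(conn, inputs, pop, params, duration = 1.5,
                            method = "euler")
  expect_true(st$converged)
  expect_equal(st$r_E, 20 - 14, tolerance = 1e-6)
  # zero drive decays to zero rate
  inputs$x_E <- 0
  st0 <- run_to_steady_state(conn, inputs, pop, params, method = "euler")
  expect_equal(st0$r_E, 0)
})

test_that("current computations follow the compartment equations", {
  net <- default_net_1d(seed = 4)
  rates <- list(r_E = runif(280, 0, 5), r_P = runif(40, 0, 5),
                r_S = runif(40, 0, 5), r_V = runif(40, 0, 5))
  x_E <- rep(28, 280)
  I_E <- somatic_synaptic_input(rates, net$conn, net$pop, x_E)
  expect_equal(I_E,
               drop(x_E + net$conn$W$EE %*% rates$r_E -
                      net$conn$W$EP %*% rates$r_P -
                      net$conn$W$EnM %*% rates$r_S[net$pop$idx_nM]))
  # doubling rates doubles the recurrent part
  rates2 <- lapply(rates, `*`, 2)
  I_E2 <- somatic_synaptic_input(rates2, net$conn, net$pop, x_E)
  expect_equal(I_E2 - x_E, 2 * (I_E - x_E), tolerance = 1e-12)
  expect_error(dendritic_synaptic_input(rates, net$conn, net$pop, 0, k = 2),
               "branch")
})

test_that("calcium events use the strict threshold convention", {
  params <- model_params()
  expect_equal(dendritic_calcium(30, params), 7)
  expect_equal(dendritic_calcium(0, params), 0)
  expect_equal(dendritic_calcium(28, params), 0)   # H(0) = 0 at boundary
  expect_equal(dendritic_calcium(28 + 1e-9, params), 7)
})

test_that("total somatic current applies leak fractions and rectification", {
  params <- model_params()
  # one branch above threshold: 0.69 * 10 + 0.27 * 20
  expect_equal(total_somatic_current(10, 13, 7, params), 0.69 * 10 + 0.27 * 20)
  # negative dendritic bracket is rectified away
  expect_equal(total_somatic_current(10, -13, 7, params), 0.69 * 10)
  # two identical branches contribute twice one branch's term
  expect_equal(total_somatic_current(10, cbind(13, 13), cbind(7, 7), params),
               0.69 * 10 + 2 * 0.27 * 20)
})

test_that("compiled drive equals the R reference on a random state", {
  net <- default_net_1d(seed = 6)
  set.seed(1)
  state <- list(h_E = rnorm(280, 2, 2), h_P = rnorm(40, 2, 2),
                h_S = rnorm(40, 2, 2), h_V = rnorm(40, 2, 2))
  inp <- phase_inputs(stimulus_phase(0, 1), net$bank, net$pop, net$params)
  # advance the compiled integrator one step from the frozen state
  one <- run_to_steady_state(net$conn, inp, net$pop,
                             net$params, state0 = state,
                             duration = net$params$dt, method = "euler")
  rates <- lapply(state, pmax, 0)
  names(rates) <- c("r_E", "r_P", "r_S", "r_V")
  I_E <- somatic_synaptic_input(rates, net$conn, net$pop, inp$x_E)
  I_D <- dendritic_synaptic_input(rates, net$conn, net$pop, inp$x_D[, 1], 1)
  I0 <- net$params$lambda_E * I_E + (1 - net$params$lambda_D) * I_D
  cal <- dendritic_calcium(I0, net$params)
  I <- total_somatic_current(I_E, I_D, cal, net$params)
  h_exp <- state$h_E + net$params$dt / net$params$tau_E *
    (I - net$params$theta - state$h_E)
  expect_equal(one$h_E, h_exp, tolerance = 1e-10)
})

test_that("steady state is consistent under dt halving", {
  net <- linear_toy_net()
  inp <- phase_inputs(stimulus_phase(0, 0), net$bank, net$pop, net$params)
  st1 <- run_to_steady_state(net$conn, inp, net$pop, net$params,
                             duration = 1.5, method = "euler")
  params2 <- net$params; params2$dt <- net$params$dt / 2
  st2 <- run_to_steady_state(net$conn, inp, net$pop, params2,
                             duration = 1.5, method = "euler")
  expect_true(st1$converged && st2$converged)
  expect_lt(max(abs(st1$r_E - st2$r_E)), net$params$steady_tol)
})

test_that("steady state is independent of the initial condition", {
  net <- default_net_1d(seed = 8)
  inp <- phase_inputs(stimulus_phase(0, 2), net$bank, net$pop, net$params)
  set.seed(2)
  s1 <- list(h_E = runif(280, 0, 10), h_P = runif(40, 0, 10),
             h_S = runif(40, 0, 10), h_V = runif(40, 0, 10))
  s2 <- list(h_E = runif(280, 0, 10), h_P = runif(40, 0, 10),
             h_S = runif(40, 0, 10), h_V = runif(40, 0, 10))
  a <- run_to_steady_state(net$conn, inp, net$pop, net$params, state0 = s1,
                           duration = 2, method = "euler")
  b <- run_to_steady_state(net$conn, inp, net$pop, net$params, state0 = s2,
                           duration = 2, method = "euler")
  expect_lt(max(abs(a$r_E - b$r_E)), 1e-4)
})

test_that("rates are nonnegative and the steady-state identity holds", {
  net <- default_net_1d(seed = 1)
  for (ph in list(stimulus_phase(-1, -1), stimulus_phase(0, 3))) {
    inp <- phase_inputs(ph, net$bank, net$pop, net$params)
    st <- run_to_steady_state(net$conn, inp, net$pop, net$params,
                              method = "newton")
    expect_true(all(st$r_E >= 0) && all(st$r_P >= 0) &&
                  all(st$r_S >= 0) && all(st$r_V >= 0))
    # -h + drive = 0 at the fixed point, componentwise
    expect_true(st$converged)
    expect_lt(st$resid, 1e-7)
  }
})

test_that("newton solver agrees with Euler integration on the full network", {
  net <- default_net_1d(seed = 1)
  for (ph in list(stimulus_phase(-1, -1), stimulus_phase(0, 0),
                  stimulus_phase(0, -1))) {
    inp <- phase_inputs(ph, net$bank, net$pop, net$params)
    sn <- run_to_steady_state(net$conn, inp, net$pop, net$params,
                              method = "newton")
    se <- run_to_steady_state(net$conn, inp, net$pop, net$params,
                              duration = 2.5, method = "euler")
    expect_true(sn$converged)
    expect_lt(max(abs(sn$r_E - se$r_E)), 1e-4)
  }
})

test_that("grouped linear solver matches the simulator in the linear regime", {
  net <- linear_toy_net()
  Wg <- grouped_weight_matrix(net$conn, net$pop, net$params)
  for (ph in list(stimulus_phase(-1, -1), stimulus_phase(1, 1))) {
    inp <- phase_inputs(ph, net$bank, net$pop, net$params)
    Sg <- grouped_input_vector(inp, net$pop, net$params)
    r_lin <- linear_steady_state(Wg, Sg)
    soma <- r_lin[seq_len(net$pop$n_groups)]
    # the direct solver lands on the linear solution to machine precision
    sn <- run_to_steady_state(net$conn, inp, net$pop, net$params,
                              method = "newton")
    gm_n <- group_means(sn$r_E, net$pop)
    expect_true(all(gm_n > 0))
    expect_lt(max(abs(gm_n - soma) / abs(soma)), 1e-9)
    # Euler integration agrees to its own convergence floor
    # (steady_tol * tau_E of residual drift)
    st <- run_to_steady_state(net$conn, inp, net$pop, net$params,
                              duration = 3, method = "euler")
    gm <- group_means(st$r_E, net$pop)
    expect_lt(max(abs(gm - soma) / pmax(abs(soma), 1e-9)), 1e-5)
    # interneuron blocks agree too
    expect_equal(unname(r_lin["P"]), mean(sn$r_P), tolerance = 1e-9)
    expect_equal(unname(r_lin["V"]), mean(sn$r_V), tolerance = 1e-9)
  }
})

test_that("scalar linear steady state follows r = s / (1 - w)", {
  W <- matrix(0.4 - 1, 1, 1)
  expect_equal(linear_steady_state(W, 3), 3 / (1 - 0.4))
  expect_equal(linear_steady_state(W, 0), 0)
  expect_error(linear_steady_state(matrix(0, 1, 1), 1), "singular")
})
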