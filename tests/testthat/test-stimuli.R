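test_that("gaussian response matches direct evaluation", {
  # peak response, off-peak value, and the attention-scaled value
  expect_equal(gaussian_response(0, 0, sigma = 0.8, r_max = 30), 30)
  expect_equal(gaussian_response(0, 1, sigma = 0.8, r_max = 30),
               30 * exp(-1 / (2 * 0.64)))
  expect_equal(gaussian_response(0, 1, sigma = 0.8, r_max = 30, gain = 1.2),
               30 * exp(-1.44 / 1.28))
  # symmetric in the signed difference and maximal exactly at the peak
  # (offsets keep the probe clear of the -1 absence sentinel)
  s <- seq(-0.9, 0.9, by = 0.15)
  f <- vapply(s, function(x) gaussian_response(1, 1 + x, 0.8), 0)
  expect_equal(f, rev(f))
  expect_equal(which.max(f), which.min(abs(s)))
})

test_that("attention narrows tuning without changing the peak", {
  off <- seq(0.25, 2, by = 0.25)
  f1 <- vapply(off, function(x) gaussian_response(0, x, 0.8, gain = 1), 0)
  f2 <- vapply(off, function(x) gaussian_response(0, x, 0.8, gain = 1.2), 0)
  expect_true(all(f2 < f1))
  expect_equal(gaussian_response(0, 0, 0.8, gain = 1.2), 30)
})

test_that("absent dimensions contribute no term", {
  # 2-D response with one dimension absent equals the 1-D factor
  expect_equal(gaussian_response(c(0, 2), c(1, -1), sigma = 0.8),
               gaussian_response(0, 1, sigma = 0.8))
  expect_equal(gaussian_response(c(0, 2), c(-1, -1), sigma = 0.8), 0)
  expect_error(gaussian_response(c(0, 2), 1, sigma = 0.8), "dimension")
})

test_that("preferred stimuli are evenly distributed", {
  pop <- population_spec()
  bank <- assign_preferred_stimuli(pop)
  expect_equal(as.numeric(table(bank$preferred_pc)), rep(70, 4))
  expect_equal(as.numeric(table(bank$preferred_som)), rep(10, 4))
  pop2 <- population_spec(n_dendrites = 2)
  bank2 <- assign_preferred_stimuli(pop2)
  expect_equal(nrow(unique(bank2$preferred_pc)), 4)
  expect_error(assign_preferred_stimuli(pop, feature_space = 0:4))
})

test_that("baseline phase inputs are exactly the background constants", {
  net <- default_net_1d()
  inp <- phase_inputs(stimulus_phase(-1, -1), net$bank, net$pop, net$params)
  expect_equal(inp$x_E, rep(28, 280))
  expect_equal(unique(inp$x_P), 2)
  expect_equal(unique(inp$x_S), 2)
  expect_equal(unique(inp$x_V), 2)
  expect_true(all(inp$x_D == 0))
})

test_that("match-phase inputs stack tuned drive on the background", {
  net <- default_net_1d()
  inp <- phase_inputs(stimulus_phase(0, 0), net$bank, net$pop, net$params,
                      noise_sigma = 0)
  g0 <- net$pop$pc_group == 1
  expect_equal(unique(inp$x_E[g0]), 28 + 30)
  expect_equal(unique(inp$x_D[g0, 1]), 0 + 30)
  # SOM tuned with its own width; PV and VIP untuned
  s0 <- net$pop$som_group == 1
  expect_equal(unique(inp$x_S[s0]), 2 + 30)
  expect_equal(unique(inp$x_S[net$pop$som_group == 2]),
               2 + 30 * exp(-1 / 2))
  expect_equal(unique(inp$x_P), 2 + 30)
  expect_equal(unique(inp$x_V), 2 + 30)
})

test_that("the -1 convention silences only the absent dimension's pathway", {
  net <- default_net_2d()
  inp <- phase_inputs(stimulus_phase(c(0, -1), c(-1, -1)), net$bank,
                      net$pop, net$params)
  expect_true(all(inp$x_D[, 2] == 0))
  g02 <- net$pop$pc_group == 1   # prefers (0, 2)
  expect_equal(unique(inp$x_D[g02, 1]), 30)
  # prediction present in one dimension still drives VIP
  expect_equal(unique(inp$x_V), 2 + 30)
  # sensory absent: no somatic or PV drive
  expect_equal(unique(inp$x_E), 28)
  expect_equal(unique(inp$x_P), 2)
})

test_that("phase inputs are deterministic without noise and seeded with it", {
  net <- default_net_1d()
  ph <- stimulus_phase(0, 0)
  a <- phase_inputs(ph, net$bank, net$pop, net$params, noise_sigma = 0)
  b <- phase_inputs(ph, net$bank, net$pop, net$params, noise_sigma = 0)
  expect_identical(a, b)
  set.seed(9); c1 <- phase_inputs(ph, net$bank, net$pop, net$params, 0.35)
  set.seed(9); c2 <- phase_inputs(ph, net$bank, net$pop, net$params, 0.35)
  expect_identical(c1, c2)
  expect_false(identical(a$x_E, c1$x_E))
})

test_that("protocols follow the published phase sequences", {
  tr <- build_protocol("train_1d", repetitions = 100)
  expect_length(tr$phases, 200)
  expect_equal(tr$phases[[1]]$label, "match")
  expect_equal(tr$phases[[2]]$label, "baseline")
  te <- build_protocol("test_1d")
  labs <- vapply(te$phases, `[[`, "", "label")
  expect_true("prediction_only" %in% labs)
  po <- te$phases[[which(labs == "prediction_only")[1]]]
  expect_equal(po$P, 0); expect_equal(po$S, -1)
  att <- build_protocol("attention", attended = 1)
  stim <- Filter(function(p) p$label != "baseline", att$phases)
  gains <- t(vapply(stim, `[[`, numeric(2), "attention_gain"))
  expect_true(all(gains[, 1] == 1.2 & gains[, 2] == 1))
  expect_equal(build_protocol("train_1d")$noise_sigma, 0.35)
})
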