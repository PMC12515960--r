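# Shared fixtures, built in code. Expensive trained networks are memoised in
# this environment so every test file reuses the same training run.
.fixtures <- new.env(parent = emptyenv())

default_net_1d <- function(seed = 1) {
  pop <- population_spec()
  list(pop = pop,
       bank = assign_preferred_stimuli(pop),
       conn = sample_connectivity(pop, connectivity_spec(), seed = seed),
       params = model_params())
}

default_net_2d <- function(seed = 1) {
  pop <- population_spec(n_dendrites = 2)
  list(pop = pop,
       bank = assign_preferred_stimuli(pop),
       conn = sample_connectivity(pop, connectivity_spec(), seed = seed),
       params = model_params())
}

# A small fully connected network in the linear regime: all probabilities 1
# (so homogenized groups are exactly homogeneous), weak weights, calcium off.
# Used for the equivalence checks against the grouped linear solver.
linear_toy_net <- function(n_per_group = 4, n_groups = 4, seed = 42,
                           n_dendrites = 1) {
  pop <- population_spec(n_pc = n_per_group * n_groups, n_pv = 4, n_som = 8,
                         martinotti_fraction = 0.5, n_groups = n_groups,
                         n_dendrites = n_dendrites, n_vip = 4)
  prob <- default_connection_probs()
  prob[prob > 0] <- 1
  spec <- connectivity_spec(prob = prob, init_spread = 0)
  conn <- sample_connectivity(pop, spec, seed = seed)
  # scale recurrent excitation down so every rectifier stays interior
  for (nm in names(conn$W)) conn$W[[nm]] <- 0.2 * conn$W[[nm]]
  params <- model_params(c_amp = 0)
  fs <- if (n_dendrites == 1) matrix(seq_len(n_groups) - 1, ncol = 1) else
    cbind(c(0, 0, 1, 1), c(2, 3, 2, 3))
  # weak tuned/untuned drive keeps every rectifier interior under stimuli
  bank <- assign_preferred_stimuli(pop, feature_space = fs, r_max = 3,
                                   untuned_amp_pv = 3, untuned_amp_vip = 3)
  list(pop = pop, bank = bank, conn = conn, params = params)
}

# Trained 1-D network, shared across test files. Training length is reduced
# relative to the package default to keep the suite fast; the methods
# vignette states the problem sizes used.
trained_1d <- function() {
  if (is.null(.fixtures$trained_1d)) {
    net <- default_net_1d(seed = 1)
    plast <- plasticity_params()
    .fixtures$trained_1d <- c(net, list(
      training = train_network(net$conn, net$pop, net$bank, net$params,
                               plast, seed = 1)))
    .fixtures$trained_1d$conn_trained <- .fixtures$trained_1d$training$conn
  }
  .fixtures$trained_1d
}

trained_2d <- function() {
  if (is.null(.fixtures$trained_2d)) {
    net <- default_net_2d(seed = 1)
    plast <- plasticity_params()
    .fixtures$trained_2d <- c(net, list(
      training = train_network(net$conn, net$pop, net$bank, net$params,
                               plast, seed = 1)))
    .fixtures$trained_2d$conn_trained <- .fixtures$trained_2d$training$conn
  }
  .fixtures$trained_2d
}

# steady PC rates for one noise-free phase
steady_rates <- function(conn, net, P, S, ...) {
  inp <- phase_inputs(stimulus_phase(P, S), net$bank, net$pop, net$params, ...)
  run_to_steady_state(conn, inp, net$pop, net$params, method = "newton")
}

group_means <- function(rates, pop) {
  as.numeric(tapply(rates, pop$pc_group, mean))
}

trained_1d_ablated <- function() {
  if (is.null(.fixtures$trained_1d_ablated)) {
    net <- default_net_1d(seed = 1)
    plast <- plasticity_params()
    .fixtures$trained_1d_ablated <- c(net, list(
      training = train_network(net$conn, net$pop, net$bank, net$params,
                               plast, seed = 1, som_untuned = TRUE)))
    .fixtures$trained_1d_ablated$conn_trained <-
      .fixtures$trained_1d_ablated$training$conn
  }
  .fixtures$trained_1d_ablated
}
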