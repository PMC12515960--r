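#' Softplus and its inverse
#'
#' The plastic inhibitory weights are reparameterized as `w = softplus(v) =
#' log(1 + exp(v))`, which keeps them strictly positive under arbitrary
#' updates; the gradient factor `dw/dv` is the logistic function. Both
#' directions are computed in a numerically stable form for large `|v|`.
#'
#' @param v unconstrained pre-activation (any numeric).
#' @return `softplus(v)`, elementwise.
#' @export
softplus <- function(v) {
  pmax(v, 0) + log1p(exp(-abs(v)))
}

#' @rdname softplus
#' @param w positive weight magnitude.
#' @return `softplus_inverse(w)`, elementwise; errors on non-positive `w`.
#' @export
softplus_inverse <- function(w) {
  if (any(w <= 0)) stop("softplus_inverse requires strictly positive weights")
  # log(exp(w) - 1) = w + log(1 - exp(-w))
  w + log(-expm1(-w))
}

logistic <- function(v) 1 / (1 + exp(-v))

clip <- function(x, bound) {
  if (is.finite(bound)) pmin(pmax(x, -bound), bound) else x
}

# smallest admissible weight magnitude in weight-space updates; keeps the
# softplus pre-activation defined
W_FLOOR <- 1e-12

# dw/dv factor for the literal softplus-gradient rule; 1 for weight-space
# updates (the update then is the increment of the weight magnitude itself)
grad_factor <- function(conn, nm, plast) {
  if (identical(plast$gradient, "softplus")) logistic(conn$v[[nm]]) else 1
}

#' Plasticity update for somatic inhibition
#'
#' Pre-activation update for the PV -> PC-soma (`pathway = "P"`) or
#' non-Martinotti-SOM -> PC-soma (`pathway = "nM"`) weights:
#' `delta v_ij = eta (r_i^E - rho_i) logistic(v_ij) r_j`, applied on existing
#' synapses only. Inhibition onto a PC above (below) its target rate is
#' strengthened (weakened) in proportion to presynaptic activity.
#'
#' @param steady a `pe_state` at steady state.
#' @param conn a `pe_connectivity`.
#' @param pop the `pe_population`.
#' @param plast [plasticity_params()].
#' @param pathway `"P"` (PV) or `"nM"` (non-Martinotti SOM).
#' @return The `delta v` matrix (zero off-mask).
#' @export
update_soma_inhibition <- function(steady, conn, pop, plast,
                                   pathway = c("P", "nM")) {
  pathway <- match.arg(pathway)
  err <- steady$r_E - plast$rho
  if (pathway == "P") {
    eta <- plast$eta_EP; nm <- "EP"; r_pre <- steady$r_P
  } else {
    eta <- plast$eta_ES; nm <- "EnM"; r_pre <- steady$r_S[pop$idx_nM]
  }
  dv <- eta * outer(err, r_pre) * grad_factor(conn, nm, plast) *
    conn$mask[[nm]]
  clip(dv, plast$update_clip)
}

#' Plasticity update for dendritic inhibition
#'
#' Pre-activation update for the Martinotti-SOM -> dendrite weights of
#' branch `k`:
#' `delta v_ij = eta (lambda_D (r_i^E - rho_i) + (A_i^k - epsilon_i^k))
#' logistic(v_ij) r_j^M`, where `A^k = I_Dk_syn + c_k` is the dendritic
#' activity and `epsilon` its target.
#'
#' @inheritParams update_soma_inhibition
#' @param params [model_params()] (for `lambda_D`).
#' @param epsilon dendritic target, `n_pc` x branches matrix.
#' @param k dendritic branch index.
#' @return The `delta v` matrix for pathway `DkM`.
#' @export
update_dendrite_inhibition <- function(steady, conn, pop, plast, params,
                                       epsilon, k = 1) {
  nm <- paste0("D", k, "M")
  A <- as.matrix(steady$A_dend)[, k]
  eps <- as.matrix(epsilon)[, k]
  err <- params$lambda_D * (steady$r_E - plast$rho) + (A - eps)
  dv <- plast$eta_DS * outer(err, steady$r_S[pop$idx_M]) *
    grad_factor(conn, nm, plast) * conn$mask[[nm]]
  clip(dv, plast$update_clip)
}

#' Plasticity update for PV afferents
#'
#' Pre-activation update for the SOM -> PV (`pathway = "S"`) or VIP -> PV
#' (`pathway = "V"`) weights, the backpropagated-error rule:
#' `delta v_ij = -eta [sum_k (r_k^E - rho_k) W_ki^EP] logistic(v_ij) r_j`.
#' The bracket backpropagates the PC rate error through the PV -> soma
#' weights onto PV neuron `i`, so that PV activity is steered in the
#' direction that reduces the PC error.
#'
#' @inheritParams update_soma_inhibition
#' @param pathway `"S"` (SOM) or `"V"` (VIP).
#' @return The `delta v` matrix for pathway `PS` or `PV`.
#' @export
update_pv_afferents <- function(steady, conn, pop, plast,
                                pathway = c("S", "V")) {
  pathway <- match.arg(pathway)
  err <- steady$r_E - plast$rho
  bp <- drop(crossprod(conn$W$EP, err))   # length n_pv
  if (pathway == "S") {
    eta <- plast$eta_PS; nm <- "PS"; r_pre <- steady$r_S
  } else {
    eta <- plast$eta_PV; nm <- "PV"; r_pre <- steady$r_V
  }
  dv <- -eta * outer(bp, r_pre) * grad_factor(conn, nm, plast) *
    conn$mask[[nm]]
  clip(dv, plast$update_clip)
}

apply_all_updates <- function(conn, steady, pop, params, plast, epsilon) {
  dv <- list(
    EP = update_soma_inhibition(steady, conn, pop, plast, "P"),
    EnM = update_soma_inhibition(steady, conn, pop, plast, "nM"),
    PS = update_pv_afferents(steady, conn, pop, plast, "S"),
    PV = update_pv_afferents(steady, conn, pop, plast, "V"))
  for (k in seq_len(pop$n_dendrites)) {
    dv[[paste0("D", k, "M")]] <-
      update_dendrite_inhibition(steady, conn, pop, plast, params, epsilon, k)
  }
  for (nm in names(dv)) {
    m <- conn$mask[[nm]] > 0
    if (identical(plast$gradient, "softplus")) {
      conn$v[[nm]] <- conn$v[[nm]] + dv[[nm]]
      conn$W[[nm]] <- softplus(conn$v[[nm]]) * conn$mask[[nm]]
    } else {
      w <- pmax(conn$W[[nm]] + dv[[nm]], W_FLOOR) * conn$mask[[nm]]
      conn$W[[nm]] <- w
      conn$v[[nm]][m] <- softplus_inverse(w[m])
    }
  }
  conn
}

#' Measure the dendritic activity target
#'
#' Runs the (untrained) network through a baseline phase and returns the
#' rectified dendritic activity per PC and branch, the default dendritic
#' target `epsilon` of the plasticity rule.
#'
#' @param conn,pop,bank,params network ingredients.
#' @return `n_pc` x branches matrix.
#' @export
measure_dendritic_target <- function(conn, pop, bank, params = model_params()) {
  ph <- stimulus_phase(rep(-1, bank$n_dim), rep(-1, bank$n_dim))
  inp <- phase_inputs(ph, bank, pop, params, noise_sigma = 0)
  st <- run_to_steady_state(conn, inp, pop, params, method = "newton")
  pmax(as.matrix(st$A_dend), 0)
}

#' Train the network with inhibitory plasticity
#'
#' The training loop: for each presentation, draw a noisy match phase
#' (`P = S =` the training feature), run the network to steady state, apply
#' all plastic updates synchronously from that frozen steady state, then do
#' the same for a baseline phase (unless `update_baseline` is off, in which
#' case the baseline steady state is still computed for the history but
#' triggers no update). Training stops early once the match-phase somatic
#' error stays below the configured fraction of the target rate for the
#' configured window.
#'
#' @param conn an untrained `pe_connectivity`.
#' @param pop,bank,params network ingredients.
#' @param plast [plasticity_params()].
#' @param train_feature feature vector of the match phases; defaults to 0
#'   (1-D) or (0, 2) (2-D).
#' @param noise_sigma feature noise SD during training, default 0.35.
#' @param seed integer seed for the noise stream.
#' @param record_every thin the history to every so-many presentations
#'   (default 10).
#' @param verbose print progress every 200 presentations (R engine only).
#' @param engine `"compiled"` (default; the full loop runs in C++ with the
#'   same update rules and noise stream) or `"r"` (reference implementation
#'   in plain R, used as its oracle in tests).
#' @param som_untuned train the selectivity-ablated model (SOM cells receive
#'   untuned sensory drive).
#' @return A list with the trained `conn`, the measured `epsilon`, and a
#'   `history` data frame (presentation, match/baseline mean somatic error,
#'   mean dendritic deviation).
#' @export
train_network <- function(conn, pop, bank, params = model_params(),
                          plast = plasticity_params(),
                          train_feature = NULL, noise_sigma = 0.35,
                          seed = 1L, record_every = 10, verbose = FALSE,
                          engine = c("compiled", "r"), som_untuned = FALSE) {
  engine <- match.arg(engine)
  set.seed(as.integer(seed))
  if (is.null(train_feature)) {
    train_feature <- if (bank$n_dim == 1) 0 else c(0, 2)
  }
  epsilon <- if (is.null(plast$epsilon)) {
    measure_dendritic_target(conn, pop, bank, params)
  } else {
    matrix(plast$epsilon, pop$n_pc, pop$n_dendrites)
  }
  if (engine == "compiled") {
    bg <- stimulus_phase(rep(-1, bank$n_dim), rep(-1, bank$n_dim))
    x0 <- phase_inputs(bg, bank, pop, params, noise_sigma = 0)
    out <- train_loop_cpp(
      conn$W, conn$v, conn$mask, x0[c("x_E", "x_D", "x_P", "x_S", "x_V")],
      cpp_pars(params), plast, pop$idx_M, pop$idx_nM,
      bank$preferred_pc, bank$preferred_som,
      bank[c("sigma_pc", "sigma_som", "r_max", "untuned_amp_pv",
             "untuned_amp_vip")],
      train_feature, epsilon,
      as.integer(plast$n_presentations), noise_sigma,
      plast$update_baseline, som_untuned,
      plast$early_stop_frac, as.integer(plast$early_stop_window),
      as.integer(record_every), 60L, params$newton_tol,
      params$dt, params$steady_tol)
    for (nm in names(conn$W)) conn$W[[nm]] <- out$W[[nm]]
    for (nm in names(conn$v)) conn$v[[nm]] <- out$v[[nm]]
    return(list(conn = conn, epsilon = epsilon, history = out$history,
                presentations = out$presentations,
                early_stopped = out$early_stopped))
  }
  match_ph <- stimulus_phase(train_feature, train_feature)
  base_ph <- stimulus_phase(rep(-1, bank$n_dim), rep(-1, bank$n_dim))
  wnorm <- function() vapply(conn$plastic, function(nm) sum(conn$W[[nm]]), 0)

  hist_rows <- list()
  quiet <- 0
  st_match <- NULL; st_base <- NULL
  n_done <- 0
  loss0 <- NULL
  for (t in seq_len(plast$n_presentations)) {
    inp <- phase_inputs(match_ph, bank, pop, params, noise_sigma = noise_sigma,
                        som_untuned = som_untuned)
    st_match <- run_to_steady_state(conn, inp, pop, params,
                                    state0 = st_match, method = "newton")
    conn <- apply_all_updates(conn, st_match, pop, params, plast, epsilon)
    err_match <- mean(abs(st_match$r_E - plast$rho))

    inp <- phase_inputs(base_ph, bank, pop, params, noise_sigma = noise_sigma)
    st_base <- run_to_steady_state(conn, inp, pop, params,
                                   state0 = st_base, method = "newton")
    if (plast$update_baseline) {
      conn <- apply_all_updates(conn, st_base, pop, params, plast, epsilon)
    }
    err_base <- mean(abs(st_base$r_E - plast$rho))
    dend_dev <- mean(abs(as.matrix(st_match$A_dend) - epsilon))
    n_done <- t

    if (t %% record_every == 0 || t == 1) {
      hist_rows[[length(hist_rows) + 1]] <- data.frame(
        presentation = t, err_match = err_match, err_base = err_base,
        dend_dev = dend_dev, t(wnorm()))
    }
    if (is.null(loss0)) loss0 <- err_match
    if (err_match > 10 * max(loss0, 1)) {
      warning("training diverged (match error grew 10-fold); aborting")
      break
    }
    if (plast$early_stop_frac > 0 &&
        err_match < plast$early_stop_frac * plast$rho &&
        err_base < plast$early_stop_frac * plast$rho) {
      quiet <- quiet + 1
      if (quiet >= plast$early_stop_window) break
    } else {
      quiet <- 0
    }
    if (verbose && t %% 200 == 0) {
      message(sprintf("presentation %d: match err %.4f, baseline err %.4f",
                      t, err_match, err_base))
    }
  }
  history <- do.call(rbind, hist_rows)
  list(conn = conn, epsilon = epsilon, history = history,
       presentations = n_done)
}
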