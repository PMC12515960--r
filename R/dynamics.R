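#' Initial network state
#'
#' Zero activation variables for all populations.
#'
#' @param pop a [population_spec()].
#' @return A list of activation vectors `h_E`, `h_P`, `h_S`, `h_V`.
#' @export
network_state_init <- function(pop) {
  list(h_E = numeric(pop$n_pc), h_P = numeric(pop$n_pv),
       h_S = numeric(pop$n_som), h_V = numeric(pop$n_vip))
}

cpp_pars <- function(params) {
  params[c("tau_E", "tau_I", "theta", "lambda_D", "lambda_E",
           "c_amp", "theta_c", "calcium_shared")]
}

#' Somatic synaptic input (reference implementation)
#'
#' `I = x_E + W_EE r_E - W_EP r_P - W_EnM r_nM`, with PC self-connections
#' excluded at sampling time. This plain-R version mirrors the compiled
#' integrator and is used as its oracle in tests.
#'
#' @param rates list with `r_E`, `r_P`, `r_S` (rectified rates).
#' @param conn a `pe_connectivity`.
#' @param pop the `pe_population`.
#' @param x_E external input vector to PC somata.
#' @return Per-PC somatic synaptic current.
#' @export
somatic_synaptic_input <- function(rates, conn, pop, x_E) {
  stopifnot(length(x_E) == pop$n_pc)
  drop(x_E + conn$W$EE %*% rates$r_E - conn$W$EP %*% rates$r_P -
         conn$W$EnM %*% rates$r_S[pop$idx_nM])
}

#' Dendritic synaptic input (reference implementation)
#'
#' `I = x_D + W_DkE r_E - W_DkM r_M` for branch `k`.
#'
#' @inheritParams somatic_synaptic_input
#' @param x_D external input vector to branch `k`.
#' @param k dendritic branch index.
#' @return Per-PC dendritic synaptic current of branch `k`.
#' @export
dendritic_synaptic_input <- function(rates, conn, pop, x_D, k = 1) {
  if (!k %in% seq_len(pop$n_dendrites)) stop("invalid dendritic branch index")
  de <- conn$W[[paste0("D", k, "E")]]
  dm <- conn$W[[paste0("D", k, "M")]]
  drop(x_D + de %*% rates$r_E - dm %*% rates$r_S[pop$idx_M])
}

#' Dendritic calcium event
#'
#' Returns `c_amp` where the within-dendrite current
#' `I0 = lambda_E I_E_syn + (1 - lambda_D) I_Dk_syn` strictly exceeds the
#' calcium threshold `theta_c`, else 0 (`H(0) = 0` convention).
#'
#' @param I0 within-dendrite current (vector).
#' @param params [model_params()].
#' @return Calcium current contribution per PC.
#' @export
dendritic_calcium <- function(I0, params) {
  params$c_amp * (I0 > params$theta_c)
}

#' Total somatic current
#'
#' `I = (1 - lambda_E) I_E_syn + sum_k lambda_D [I_Dk_syn + c_k]_+`.
#'
#' @param I_E_syn somatic synaptic current.
#' @param I_D_syn dendritic synaptic currents, a matrix with one column per
#'   branch (or a vector for a single branch).
#' @param calcium calcium currents, same shape as `I_D_syn`.
#' @param params [model_params()].
#' @return Per-PC total somatic current.
#' @export
total_somatic_current <- function(I_E_syn, I_D_syn, calcium, params) {
  I_D_syn <- as.matrix(I_D_syn)
  calcium <- as.matrix(calcium)
  I <- (1 - params$lambda_E) * I_E_syn
  for (k in seq_len(ncol(I_D_syn))) {
    I <- I + params$lambda_D * pmax(I_D_syn[, k] + calcium[, k], 0)
  }
  I
}

#' Run the network to steady state for one phase
#'
#' Integrates the rate equations under constant external inputs.
#' `method = "euler"` performs explicit Euler integration with step
#' `params$dt` for (at least) the phase duration, reporting convergence as
#' `max |dr| / dt < steady_tol` sustained over a 1 ms window;
#' `method = "newton"` solves for the same fixed point directly: the steady
#' state is piecewise linear in the rectification pattern (which units are
#' above threshold, which dendritic brackets are open, which branches carry
#' a calcium event), so the solver alternates between solving the linear
#' system for the current pattern and recomputing the pattern, and verifies
#' the full nonlinear residual on exit (falling back to Euler integration
#' if it did not converge). Both methods share the compiled drive
#' computation, so they agree wherever the dynamics settle to a fixed
#' point; the training loop uses `"newton"` for speed.
#'
#' @param conn a `pe_connectivity`.
#' @param inputs external inputs from [phase_inputs()] (or a hand-built list
#'   with the same fields).
#' @param pop the `pe_population`.
#' @param params [model_params()].
#' @param state0 initial state (default [network_state_init()]); warm starts
#'   accelerate the solver.
#' @param duration integration time in seconds (default 1).
#' @param method `"euler"` or `"newton"`.
#' @param early_exit allow the Euler integrator to stop as soon as the
#'   steady-state criterion holds (default `FALSE`: integrate the full
#'   duration).
#' @param max_iter pattern-iteration cap for the newton solver (default 60).
#' @return A `pe_state` list: activation variables, rectified rates,
#'   per-compartment currents (`I_E_syn`, `I_D_syn`, `calcium`, `A_dend`),
#'   a `converged` flag and the step/iteration count.
#' @export
run_to_steady_state <- function(conn, inputs, pop, params = model_params(),
                                state0 = NULL, duration = 1,
                                method = c("euler", "newton"),
                                early_exit = FALSE, max_iter = 60) {
  method <- match.arg(method)
  if (is.null(state0)) state0 <- network_state_init(pop)
  state0 <- state0[c("h_E", "h_P", "h_S", "h_V")]
  x <- inputs[c("x_E", "x_D", "x_P", "x_S", "x_V")]
  x$x_D <- as.matrix(x$x_D)
  if (method == "newton") {
    out <- solve_newton_cpp(conn$W, x, state0, cpp_pars(params),
                            pop$idx_M, pop$idx_nM, as.integer(max_iter),
                            params$newton_tol)
    if (!out$converged) {
      out <- sim_euler_cpp(conn$W, x, state0, cpp_pars(params),
                           pop$idx_M, pop$idx_nM, params$dt,
                           as.integer(ceiling(duration / params$dt)),
                           params$steady_tol, TRUE,
                           as.integer(ceiling(0.001 / params$dt)))
    }
  } else {
    out <- sim_euler_cpp(conn$W, x, state0, cpp_pars(params),
                         pop$idx_M, pop$idx_nM, params$dt,
                         as.integer(ceiling(duration / params$dt)),
                         params$steady_tol, early_exit,
                         as.integer(ceiling(0.001 / params$dt)))
  }
  for (nm in c("h_E", "h_P", "h_S", "h_V", "r_E", "r_P", "r_S", "r_V",
               "I_E_syn")) {
    out[[nm]] <- drop(out[[nm]])
  }
  out$inputs <- inputs
  class(out) <- "pe_state"
  out
}

#' Steady-state responses for every phase of a protocol
#'
#' Convenience runner: evaluates [phase_inputs()] and
#' [run_to_steady_state()] for each phase, optionally averaging several
#' noisy repetitions, and collects PC steady rates plus phase metadata.
#'
#' @param conn,pop,bank,params network ingredients.
#' @param protocol a [build_protocol()] result (or list of phases).
#' @param repetitions number of independent noise draws to average per phase
#'   (default 1).
#' @param noise_sigma overrides the protocol's feature-noise SD if not
#'   `NULL`.
#' @param method steady-state method, default `"newton"`.
#' @param som_untuned passed to [phase_inputs()].
#' @param keep_states if `TRUE`, attach the full `pe_state` of the last
#'   repetition of each phase.
#' @return A list with `rates` (phases x PC matrix of steady PC rates),
#'   `phase_info` (data frame: label, P, S as strings), and optionally
#'   `states`.
#' @export
steady_responses <- function(conn, pop, bank, protocol,
                             params = model_params(), repetitions = 1,
                             noise_sigma = NULL, method = "newton",
                             som_untuned = FALSE, keep_states = FALSE) {
  phases <- if (inherits(protocol, "pe_protocol")) protocol$phases else protocol
  ns <- if (!is.null(noise_sigma)) noise_sigma
        else if (inherits(protocol, "pe_protocol")) protocol$noise_sigma else 0
  rates <- matrix(0, length(phases), pop$n_pc)
  states <- vector("list", length(phases))
  info <- data.frame(label = character(length(phases)),
                     P = character(length(phases)),
                     S = character(length(phases)),
                     stringsAsFactors = FALSE)
  st <- NULL
  for (i in seq_along(phases)) {
    ph <- phases[[i]]
    acc <- 0
    for (rep in seq_len(repetitions)) {
      inp <- phase_inputs(ph, bank, pop, params, noise_sigma = ns,
                          som_untuned = som_untuned)
      st <- run_to_steady_state(conn, inp, pop, params, state0 = st,
                                duration = ph$duration, method = method)
      acc <- acc + st$r_E
    }
    rates[i, ] <- acc / repetitions
    if (keep_states) states[[i]] <- st
    info$label[i] <- ph$label
    info$P[i] <- paste(ph$P, collapse = ",")
    info$S[i] <- paste(ph$S, collapse = ",")
  }
  out <- list(rates = rates, phase_info = info)
  if (keep_states) out$states <- states
  out
}
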