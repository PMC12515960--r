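#' Model parameters for the rate dynamics
#'
#' Scalar constants of the two-compartment pyramidal-cell / interneuron rate
#' model: time constants, leak fractions of the soma--dendrite coupling, the
#' dendritic calcium event, background inputs and the integration settings.
#'
#' All times are in seconds and all rates/currents in 1/s (Hz). The somatic
#' rheobase `theta` is subtracted from the total somatic current before it
#' drives the activation variable; firing rates are the rectified activation
#' variables. `lambda_E` and `lambda_D` are the fractions of current leaking
#' from the soma into the dendrites and vice versa, so the somatic drive is
#' `(1 - lambda_E) * I_soma + sum_k lambda_D * [I_dend_k + c_k]_+`.
#'
#' @param tau_E excitatory rate time constant (s), default 0.060.
#' @param tau_I interneuron rate time constant (s), default 0.002.
#' @param theta somatic rheobase (1/s), default 14.
#' @param lambda_D,lambda_E dendritic and somatic current leak fractions,
#'   defaults 0.27 and 0.31; both must lie in (0, 1).
#' @param c_amp amplitude of the dendritic calcium event (1/s), default 7.
#'   Set to 0 to disable calcium events.
#' @param theta_c threshold of the within-dendrite current that triggers a
#'   calcium event (1/s), default 28. The Heaviside convention is strict:
#'   a current exactly at threshold does not trigger an event.
#' @param x_E,x_P,x_S,x_V,x_D constant background inputs (Hz) to PC somata,
#'   PV, SOM, VIP and PC dendrites; defaults 28, 2, 2, 2, 0.
#' @param rho_E target (baseline) PC firing rate (Hz), default 1.25.
#' @param dt Euler integration step (s), default 1e-4.
#' @param steady_tol convergence tolerance on `max |dr| / dt` (1/s^2) used by
#'   the Euler steady-state check, default 1e-4.
#' @param newton_tol residual tolerance (Hz) of the direct piecewise-linear
#'   steady-state solver, default 1e-8.
#' @param calcium_shared if `TRUE`, a single calcium event (triggered by any
#'   branch) is shared across branches; default `FALSE` (per-branch events).
#' @return An object of class `pe_model_params` (a named list).
#' @export
model_params <- function(tau_E = 0.060, tau_I = 0.002, theta = 14,
                         lambda_D = 0.27, lambda_E = 0.31,
                         c_amp = 7, theta_c = 28,
                         x_E = 28, x_P = 2, x_S = 2, x_V = 2, x_D = 0,
                         rho_E = 1.25, dt = 1e-4,
                         steady_tol = 1e-4, newton_tol = 1e-8,
                         calcium_shared = FALSE) {
  stopifnot(tau_E > 0, tau_I > 0, dt > 0,
            lambda_D > 0, lambda_D < 1, lambda_E > 0, lambda_E < 1)
  if (dt > tau_I / 10 + 1e-12) {
    stop("dt must not exceed tau_I / 10 (stability of the Euler integrator)")
  }
  structure(list(
    tau_E = tau_E, tau_I = tau_I, theta = theta,
    lambda_D = lambda_D, lambda_E = lambda_E,
    c_amp = c_amp, theta_c = theta_c,
    x_E = x_E, x_P = x_P, x_S = x_S, x_V = x_V, x_D = x_D,
    rho_E = rho_E, dt = dt, steady_tol = steady_tol,
    newton_tol = newton_tol,
    calcium_shared = calcium_shared
  ), class = "pe_model_params")
}

#' Plasticity parameters
#'
#' Learning rates of the five plastic inhibitory pathways, the somatic and
#' dendritic targets, and the training-loop controls. Defaults:
#' `eta_EP = 1e-4` (PV onto PC soma), `eta_ES = 1e-4` (non-Martinotti SOM
#' onto PC soma), `eta_DS = 1e-6` (Martinotti SOM onto PC dendrites),
#' `eta_PS = eta_PV = 1e-6` (SOM and VIP onto PV). The `eta_ES` default
#' matches its sibling somatic rule `eta_EP`: the tuned soma-targeting
#' pathway must co-adapt with the untuned one for the somatic compartment
#' to balance at both stimulus and baseline phases (see the methods
#' vignette); a much smaller value leaves that pathway effectively frozen
#' and the circuit cannot reach joint balance at any practical training
#' length.
#'
#' @param eta_EP,eta_ES,eta_DS,eta_PS,eta_PV learning rates (dimensionless,
#'   applied to the softplus pre-activations).
#' @param rho target baseline PC rate (Hz), default 1.25.
#' @param epsilon dendritic activity target. `NULL` (default) measures it
#'   per neuron and branch as the rectified dendritic input of the untrained
#'   network during a baseline phase; a scalar overrides that measurement.
#' @param n_presentations number of match/baseline presentation pairs,
#'   default 8000 (the five pathways co-adapt on different timescales; the
#'   slowest, quieting the PV response to matched stimuli through its SOM
#'   and VIP afferents, needs several thousand pairs).
#' @param update_baseline also apply updates after baseline phases
#'   (default `TRUE`).
#' @param early_stop_frac stop early once the mean somatic error
#'   `|r_E - rho|` on match phases stays below `early_stop_frac * rho` for
#'   `early_stop_window` consecutive presentations; defaults 0.05 and 100.
#'   Set `early_stop_frac = 0` to disable.
#' @param early_stop_window see `early_stop_frac`.
#' @param update_clip optional bound on the update magnitude (default `Inf`).
#' @param gradient parameterization of the updates. `"weight"` (default)
#'   applies the derived error terms directly to the weight magnitudes with
#'   non-negativity enforced (the form of classic homeostatic inhibitory
#'   plasticity); `"softplus"` applies them to the softplus pre-activations
#'   with the logistic `dw/dv` factor (the literal gradient-descent form).
#'   The two coincide up to the `dw/dv` factor; at the network's
#'   initialization scale the literal form is slower by two to four orders
#'   of magnitude on the SOM- and VIP-related pathways, which freezes them
#'   at practical training lengths — see the methods vignette.
#' @return An object of class `pe_plasticity_params`.
#' @export
plasticity_params <- function(eta_EP = 1e-4, eta_ES = 1e-4, eta_DS = 1e-6,
                              eta_PS = 1e-6, eta_PV = 1e-6,
                              rho = 1.25, epsilon = NULL,
                              n_presentations = 8000,
                              update_baseline = TRUE,
                              early_stop_frac = 0.05,
                              early_stop_window = 100,
                              update_clip = Inf,
                              gradient = c("weight", "softplus")) {
  gradient <- match.arg(gradient)
  stopifnot(eta_EP >= 0, eta_ES >= 0, eta_DS >= 0, eta_PS >= 0, eta_PV >= 0,
            rho > 0, n_presentations >= 0)
  structure(list(
    eta_EP = eta_EP, eta_ES = eta_ES, eta_DS = eta_DS,
    eta_PS = eta_PS, eta_PV = eta_PV,
    rho = rho, epsilon = epsilon,
    n_presentations = n_presentations,
    update_baseline = update_baseline,
    early_stop_frac = early_stop_frac,
    early_stop_window = early_stop_window,
    update_clip = update_clip,
    gradient = gradient
  ), class = "pe_plasticity_params")
}
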