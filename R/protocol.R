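#' Construct a stimulus phase
#'
#' A phase is a constant-stimulus epoch: a prediction feature vector `P`
#' (top-down, motor-related), a sensory feature vector `S` (bottom-up), a
#' duration, and a per-dimension attention gain. The value -1 marks an
#' absent dimension; a baseline phase has all entries of both vectors
#' absent.
#'
#' @param P,S numeric feature vectors (-1 = absent per dimension).
#' @param duration phase duration in seconds, default 1.
#' @param attention_gain per-dimension gain, default 1 (recycled).
#' @param label one of `baseline`, `match`, `mismatch`, `prediction_only`,
#'   `sensory_only`; `NULL` infers the label from `P` and `S`.
#' @return An object of class `pe_phase`.
#' @export
stimulus_phase <- function(P, S, duration = 1, attention_gain = 1,
                           label = NULL) {
  stopifnot(length(P) == length(S), duration > 0)
  p_absent <- all(P == -1); s_absent <- all(S == -1)
  if (is.null(label)) {
    label <- if (p_absent && s_absent) "baseline"
    else if (p_absent) "sensory_only"
    else if (s_absent) "prediction_only"
    else if (all(P == S)) "match"
    else "mismatch"
  }
  label <- match.arg(label, c("baseline", "match", "mismatch",
                              "prediction_only", "sensory_only"))
  if (label == "baseline" && !(p_absent && s_absent)) {
    stop("a baseline phase must have all entries of P and S absent (-1)")
  }
  structure(list(P = P, S = S, duration = duration,
                 attention_gain = rep_len(attention_gain, length(P)),
                 label = label),
            class = "pe_phase")
}

#' Build a named stimulus protocol
#'
#' Returns the phase sequences used by the in-silico experiments:
#' * `train_1d` / `train_2d`: `repetitions` pairs of a match phase
#'   (`P = S = 0`, or `(0, 2)` in 2-D) alternating with baseline phases.
#' * `test_1d`: the test panel `0-0, 0-1, 0-2, 0-3` plus the
#'   prediction-only phase (`P = 0, S = -1`), each preceded by a baseline.
#' * `test_2d`: `P = (0, 2)` against all four feature combinations plus
#'   prediction-only.
#' * `attention`: the `test_2d` mismatch grid with an attention gain of
#'   `gain` (default 1.2) on the attended dimension.
#' * `reduction`: the dimensional-reduction cases `P = (0, -1)` with
#'   `S in {(0, -1), (1, -1)}` and `P = (-1, 2)` with
#'   `S in {(-1, 2), (-1, 3)}`.
#'
#' @param kind protocol kind, see above.
#' @param repetitions number of match/baseline pairs for training protocols
#'   (default 100).
#' @param noise_sigma standard deviation of the additive Gaussian feature
#'   noise applied to every present stimulus dimension (default 0.35).
#' @param attended for `attention`: 0 (unbiased), 1 or 2.
#' @param gain attention gain on the attended dimension, default 1.2.
#' @param duration phase duration (s), default 1.
#' @return An object of class `pe_protocol`: a list of [stimulus_phase()]s
#'   plus the noise scale.
#' @export
build_protocol <- function(kind = c("train_1d", "test_1d", "train_2d",
                                    "test_2d", "attention", "reduction"),
                           repetitions = 100, noise_sigma = 0.35,
                           attended = 0, gain = 1.2, duration = 1) {
  kind <- match.arg(kind)
  bl1 <- stimulus_phase(-1, -1, duration)
  bl2 <- stimulus_phase(c(-1, -1), c(-1, -1), duration)
  phases <- switch(kind,
    train_1d = rep(list(stimulus_phase(0, 0, duration), bl1), repetitions),
    train_2d = rep(list(stimulus_phase(c(0, 2), c(0, 2), duration), bl2),
                   repetitions),
    test_1d = {
      out <- list()
      for (s in 0:3) out <- c(out, list(bl1, stimulus_phase(0, s, duration)))
      c(out, list(bl1, stimulus_phase(0, -1, duration)))
    },
    test_2d = {
      out <- list()
      for (s in list(c(0, 2), c(0, 3), c(1, 2), c(1, 3))) {
        out <- c(out, list(bl2, stimulus_phase(c(0, 2), s, duration)))
      }
      c(out, list(bl2, stimulus_phase(c(0, 2), c(-1, -1), duration)))
    },
    attention = {
      g <- c(1, 1)
      if (attended %in% 1:2) g[attended] <- gain
      out <- list()
      for (s in list(c(0, 2), c(0, 3), c(1, 2), c(1, 3))) {
        out <- c(out, list(bl2, stimulus_phase(c(0, 2), s, duration,
                                               attention_gain = g)))
      }
      out
    },
    reduction = list(
      bl2, stimulus_phase(c(0, -1), c(0, -1), duration),
      bl2, stimulus_phase(c(0, -1), c(1, -1), duration),
      bl2, stimulus_phase(c(-1, 2), c(-1, 2), duration),
      bl2, stimulus_phase(c(-1, 2), c(-1, 3), duration)))
  structure(list(kind = kind, phases = phases, noise_sigma = noise_sigma),
            class = "pe_protocol")
}

#' External input vectors for one phase
#'
#' Assembles the per-population external inputs for a stimulus phase. All
#' populations always receive their constant background input. When the
#' sensory stimulus `S` is present, PC somata and SOM cells additionally
#' receive Gaussian-tuned drive (widths `sigma_pc`, `sigma_som`) and PV
#' cells an untuned sensory drive; when the prediction `P` is present, each
#' dendritic branch receives the 1-D Gaussian drive of its feature dimension
#' and VIP cells an untuned prediction drive. Feature values are perturbed
#' once per phase (per stimulus channel, not per neuron) by additive
#' Gaussian noise of standard deviation `noise_sigma` before the tuning
#' curves are evaluated; absent dimensions stay absent. Attention gains act
#' on the PC pathways only.
#'
#' @param phase a [stimulus_phase()].
#' @param bank a [assign_preferred_stimuli()] tuning bank.
#' @param pop the `pe_population`.
#' @param params [model_params()] (background input constants).
#' @param noise_sigma feature noise SD; 0 disables noise. Uses the current
#'   R random number stream.
#' @param noise_as_variance if `TRUE`, interpret `noise_sigma` as a variance.
#' @param som_untuned if `TRUE`, SOM cells receive the untuned sensory
#'   amplitude instead of tuned drive (selectivity ablation).
#' @return A list with `x_E` (length `n_pc`), `x_D` (`n_pc` x branches
#'   matrix), `x_P`, `x_S`, `x_V`, and the realized (noisy) `P` and `S`.
#' @export
phase_inputs <- function(phase, bank, pop, params = model_params(),
                         noise_sigma = 0, noise_as_variance = FALSE,
                         som_untuned = FALSE) {
  stopifnot(inherits(phase, "pe_phase"), inherits(bank, "pe_tuning_bank"))
  d <- bank$n_dim
  if (length(phase$P) != d) stop("phase dimensionality does not match the tuning bank")
  sdv <- if (noise_as_variance) sqrt(noise_sigma) else noise_sigma
  jitter <- function(x) {
    pres <- x != -1
    if (any(pres) && sdv > 0) x[pres] <- x[pres] + rnorm(sum(pres), 0, sdv)
    x
  }
  P <- jitter(phase$P); S <- jitter(phase$S)
  g <- phase$attention_gain

  x_E <- rep(params$x_E, pop$n_pc)
  x_S <- rep(params$x_S, pop$n_som)
  x_P <- rep(params$x_P, pop$n_pv)
  x_V <- rep(params$x_V, pop$n_vip)
  x_D <- matrix(params$x_D, pop$n_pc, pop$n_dendrites)

  if (any(S != -1)) {
    x_E <- x_E + gaussian_response(bank$preferred_pc, S, bank$sigma_pc,
                                   bank$r_max, gain = g)
    x_S <- x_S + if (som_untuned) bank$untuned_amp_pv else
      gaussian_response(bank$preferred_som, S, bank$sigma_som, bank$r_max)
    x_P <- x_P + bank$untuned_amp_pv
  }
  if (any(P != -1)) {
    for (k in seq_len(pop$n_dendrites)) {
      if (P[k] != -1) {
        x_D[, k] <- x_D[, k] +
          gaussian_response(bank$preferred_pc[, k, drop = FALSE], P[k],
                            bank$sigma_pc, bank$r_max, gain = g[k])
      }
    }
    x_V <- x_V + bank$untuned_amp_vip
  }
  list(x_E = x_E, x_D = x_D, x_P = x_P, x_S = x_S, x_V = x_V, P = P, S = S)
}
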