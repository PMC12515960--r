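#' Gaussian tuning response
#'
#' Response of a neuron with preferred stimulus `s_max` to a stimulus `s`,
#' `r_max * exp(-sum_d (g_d (s_d - s_max_d))^2 / (2 sigma^2))`, taken over
#' the dimensions in which the stimulus is present. A value of -1 in a
#' dimension of `s` means that dimension is absent and contributes no term;
#' if all dimensions are absent the response is 0 (no drive). The attention
#' gain `g_d` scales the difference term of dimension `d` before squaring,
#' which narrows the tuning of the attended dimension while leaving the peak
#' response unchanged.
#'
#' @param s_max preferred stimulus: a numeric vector (one neuron) or a matrix
#'   with one row per neuron.
#' @param s stimulus vector; entries equal to -1 mark absent dimensions.
#' @param sigma tuning width (common to all dimensions).
#' @param r_max peak rate (Hz), default 30.
#' @param gain per-dimension attention gain (recycled), default 1.
#' @return Numeric vector of responses, one per row of `s_max`.
#' @export
gaussian_response <- function(s_max, s, sigma, r_max = 30, gain = 1) {
  if (is.null(dim(s_max))) s_max <- matrix(s_max, nrow = 1)
  d <- ncol(s_max)
  if (length(s) != d) stop("dimension mismatch between s_max and s")
  gain <- rep_len(gain, d)
  present <- s != -1
  if (!any(present)) return(rep(0, nrow(s_max)))
  diff <- sweep(s_max[, present, drop = FALSE], 2, s[present], "-")
  diff <- sweep(diff, 2, gain[present], "*")
  r_max * exp(-rowSums(diff^2) / (2 * sigma^2))
}

#' Assign evenly distributed preferred stimuli
#'
#' Builds the tuning bank: every feature value of the configured feature
#' space is assigned to exactly `n_pc / |space|` PCs and `n_som / |space|`
#' SOM cells, in group order. The default 1-D feature space is `{0, 1, 2, 3}`
#' and the default 2-D space is `{(0,2), (0,3), (1,2), (1,3)}`.
#'
#' @param pop a [population_spec()]; `n_groups` must equal the number of
#'   feature values.
#' @param feature_space numeric vector (1-D) or matrix with one row per
#'   feature value (2-D). `NULL` picks the default space for
#'   `pop$n_dendrites` dimensions.
#' @param sigma_pc PC tuning width, default 0.8.
#' @param sigma_som SOM tuning width, default 1.0 (broader than PCs).
#' @param r_max peak rate of the tuned inputs (Hz), default 30.
#' @param untuned_amp_pv amplitude of the untuned sensory drive to PV cells
#'   whenever a sensory stimulus is present; defaults to `r_max` (PV cells
#'   are strongly but unselectively visually driven).
#' @param untuned_amp_vip amplitude of the untuned prediction drive to VIP
#'   cells whenever a prediction is present; defaults to `r_max`.
#' @return An object of class `pe_tuning_bank` with per-neuron preferred
#'   stimuli (`preferred_pc`, `preferred_som`; matrices, one row per neuron)
#'   and the group-level feature table.
#' @export
assign_preferred_stimuli <- function(pop, feature_space = NULL,
                                     sigma_pc = 0.8, sigma_som = 1.0,
                                     r_max = 30, untuned_amp_pv = r_max,
                                     untuned_amp_vip = r_max) {
  stopifnot(inherits(pop, "pe_population"))
  if (is.null(feature_space)) {
    feature_space <- if (pop$n_dendrites == 1) {
      matrix(0:3, ncol = 1)
    } else {
      cbind(c(0, 0, 1, 1), c(2, 3, 2, 3))
    }
  }
  if (is.null(dim(feature_space))) feature_space <- matrix(feature_space, ncol = 1)
  n_feat <- nrow(feature_space)
  if (n_feat != pop$n_groups) {
    stop("feature space size must equal the number of selectivity groups")
  }
  if (ncol(feature_space) != pop$n_dendrites) {
    stop("feature dimensionality must equal the number of dendritic branches")
  }
  structure(list(
    feature_space = feature_space,
    preferred_pc = feature_space[pop$pc_group, , drop = FALSE],
    preferred_som = feature_space[pop$som_group, , drop = FALSE],
    sigma_pc = sigma_pc, sigma_som = sigma_som,
    r_max = r_max, untuned_amp_pv = untuned_amp_pv,
    untuned_amp_vip = untuned_amp_vip,
    n_dim = ncol(feature_space)
  ), class = "pe_tuning_bank")
}
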