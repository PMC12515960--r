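#' Classify prediction-error neurons
#'
#' A PC is a prediction-error (PE) neuron when its baseline-normalized rate
#' change `dR/R = (r - r_BL) / r_BL` exceeds `mismatch_min` (default 20%)
#' in its corresponding mismatch phase and stays below `match_max` (default
#' 10%) in absolute value during the match phase. The corresponding
#' mismatch phase of a neuron is the mismatch phase whose actual stimulus
#' equals the neuron's preferred feature; for neurons whose preferred
#' feature equals the prediction (so that this phase is the match phase),
#' the mismatch phase with the actual stimulus closest to the preference is
#' used instead.
#'
#' @param responses phases x neurons matrix of steady rates (e.g.
#'   `steady_responses()$rates`).
#' @param phase_info the matching `phase_info` data frame (columns `label`,
#'   `S`).
#' @param baseline_rates per-neuron baseline rates (> 0; zero-baseline
#'   neurons are flagged unclassifiable).
#' @param bank tuning bank (preferred stimuli).
#' @param mismatch_min,match_max classification thresholds, defaults 0.20
#'   and 0.10.
#' @return A list with `delta_r` (phases x neurons matrix of dR/R),
#'   `is_pe` (logical per neuron, `NA` = unclassifiable), `fraction_pe`,
#'   and the per-neuron phase indices used.
#' @export
classify_pe <- function(responses, phase_info, baseline_rates, bank,
                        mismatch_min = 0.20, match_max = 0.10) {
  stopifnot(nrow(responses) == nrow(phase_info),
            ncol(responses) == length(baseline_rates))
  delta_r <- sweep(sweep(responses, 2, baseline_rates, "-"), 2,
                   baseline_rates, "/")
  i_match <- which(phase_info$label == "match")
  i_mm <- which(phase_info$label == "mismatch")
  if (length(i_match) < 1 || length(i_mm) < 1) {
    stop("protocol must contain a match phase and at least one mismatch phase")
  }
  i_match <- i_match[1]
  mm_S <- lapply(strsplit(phase_info$S[i_mm], ","), as.numeric)
  n <- ncol(responses)
  pick <- integer(n)
  for (j in seq_len(n)) {
    pref <- bank$preferred_pc[j, ]
    dist <- vapply(mm_S, function(s) {
      pres <- s != -1
      if (!any(pres)) Inf else sqrt(sum((s[pres] - pref[pres])^2))
    }, 0)
    exact <- which(dist == 0)
    pick[j] <- if (length(exact)) i_mm[exact[1]] else i_mm[which.min(dist)]
  }
  is_pe <- rep(NA, n)
  ok <- baseline_rates > 0
  mm_dr <- delta_r[cbind(pick, seq_len(n))]
  is_pe[ok] <- (mm_dr[ok] > mismatch_min) &
    (abs(delta_r[i_match, ok]) < match_max)
  list(delta_r = delta_r, is_pe = is_pe,
       fraction_pe = mean(is_pe, na.rm = TRUE),
       match_phase = i_match, mismatch_phase = pick,
       thresholds = c(mismatch_min = mismatch_min, match_max = match_max))
}

#' Selectivity coefficient
#'
#' Skewness-style statistic over the group-mean steady rates under a given
#' prediction stimulus:
#' `gamma = <(m_s - m)^3>_s / <(m_s - m)^2>_s^{3/2}`,
#' with `<.>_s` the plain average over selectivity groups (optionally
#' weighted by group size), `m_s` the group means and `m` their grand mean.
#' `|gamma| > 0.5` is taken as significant feature-selective modulation.
#' Degenerate inputs (across-group variance below `1e-12`) return exactly 0.
#'
#' @param group_means numeric vector of group-mean rates (>= 3 groups).
#' @param weights optional group weights (e.g. neuron counts); default
#'   unweighted.
#' @return An object of class `pe_selectivity`: `gamma`, `group_means`,
#'   `grand_mean`, `significant`.
#' @export
selectivity_coefficient <- function(group_means, weights = NULL) {
  if (length(group_means) < 3) {
    stop("selectivity coefficient requires at least 3 groups")
  }
  w <- if (is.null(weights)) rep(1, length(group_means)) else weights
  w <- w / sum(w)
  m <- sum(w * group_means)
  m2 <- sum(w * (group_means - m)^2)
  m3 <- sum(w * (group_means - m)^3)
  gamma <- if (m2 < 1e-12) 0 else m3 / m2^1.5
  structure(list(gamma = gamma, group_means = group_means, grand_mean = m,
                 significant = abs(gamma) > 0.5),
            class = "pe_selectivity")
}

#' @export
print.pe_selectivity <- function(x, ...) {
  cat(sprintf("gamma = %.4f (%ssignificant at |gamma| > 0.5)\n", x$gamma,
              if (x$significant) "" else "not "))
  invisible(x)
}

#' Similarity between a preference and a stimulus
#'
#' 1-D mode: the tuning-curve ratio `f(s_max, s0) / f_max`, i.e. the
#' Gaussian evaluated at the feature distance. 2-D mode:
#' `1 - mean_d |s_max_d - s0_d| / (||s_max|| + ||s0||)` with Euclidean
#' norms.
#'
#' @param s_max preferred stimulus (vector).
#' @param s0 probe stimulus (vector, same length).
#' @param bank tuning bank (for the 1-D tuning width).
#' @param mode `"1d"` or `"2d"`; default picks by dimensionality.
#' @return Similarity in `[0, 1]`.
#' @export
similarity <- function(s_max, s0, bank, mode = NULL) {
  stopifnot(length(s_max) == length(s0))
  if (is.null(mode)) mode <- if (length(s_max) == 1) "1d" else "2d"
  mode <- match.arg(mode, c("1d", "2d"))
  if (mode == "1d") {
    exp(-sum((s0 - s_max)^2) / (2 * bank$sigma_pc^2))
  } else {
    denom <- sqrt(sum(s_max^2)) + sqrt(sum(s0^2))
    if (denom == 0) stop("2-D similarity undefined for two zero-norm vectors")
    1 - mean(abs(s_max - s0) / denom)
  }
}

#' Fit Gaussian tuning curves to group responses
#'
#' Least-squares Gaussian fit `a * exp(-(x - mu)^2 / (2 s^2))` per
#' selectivity group of the group-mean steady responses across a sweep of
#' actual stimuli, used to check that training does not shift the tuning
#' peaks. Requires at least 4 stimulus values. Non-convergent fits are
#' flagged and returned with `NA` parameters.
#'
#' @param stim_values numeric vector of probe stimulus values (one feature
#'   dimension).
#' @param group_responses groups x stimuli matrix of mean responses.
#' @return Data frame, one row per group: amplitude, peak location `mu`,
#'   width `sigma`, and a `converged` flag.
#' @export
fit_tuning_curves <- function(stim_values, group_responses) {
  stopifnot(length(stim_values) >= 4,
            ncol(group_responses) == length(stim_values))
  out <- lapply(seq_len(nrow(group_responses)), function(g) {
    y <- group_responses[g, ]
    df <- data.frame(x = stim_values, y = y)
    start <- list(a = max(y), mu = stim_values[which.max(y)], s = 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(group = g, amplitude = NA, mu = NA, sigma = NA,
                 converged = FALSE)
    } else {
      cf <- coef(fit)
      data.frame(group = g, amplitude = unname(cf["a"]),
                 mu = unname(cf["mu"]), sigma = abs(unname(cf["s"])),
                 converged = TRUE)
    }
  })
  do.call(rbind, out)
}

#' Mismatch scaling table
#'
#' For a test protocol with fixed prediction `P` and varying actual
#' stimulus `S`, tabulates the feature distance `|S - P|` against the mean
#' response of the PC group preferring each `S`, and reports a monotonicity
#' verdict (sign of the Spearman rank correlation).
#'
#' @param responses phases x neurons steady-rate matrix.
#' @param phase_info matching phase metadata.
#' @param pop,bank population and tuning bank.
#' @return A list with the `table` (distance, stimulus, mean response) and
#'   `spearman_rho` / `monotone_increasing`.
#' @export
mismatch_scaling <- function(responses, phase_info, pop, bank) {
  i_mm <- which(phase_info$label == "mismatch")
  if (length(i_mm) < 2) stop("need at least two mismatch phases")
  rows <- lapply(i_mm, function(i) {
    S <- as.numeric(strsplit(phase_info$S[i], ",")[[1]])
    P <- as.numeric(strsplit(phase_info$P[i], ",")[[1]])
    pres <- S != -1 & P != -1
    d <- sqrt(sum((S[pres] - P[pres])^2))
    grp <- which(apply(bank$feature_space, 1, function(f) all(f == S)))
    if (!length(grp)) return(NULL)
    data.frame(distance = d, S = paste(S, collapse = ","),
               mean_response = mean(responses[i, pop$pc_group == grp]))
  })
  tab <- do.call(rbind, rows)
  tab <- stats::aggregate(mean_response ~ distance + S, tab, mean)
  tab <- tab[order(tab$distance), ]
  rho <- suppressWarnings(cor(tab$distance, tab$mean_response,
                              method = "spearman"))
  list(table = tab, spearman_rho = rho,
       monotone_increasing = isTRUE(rho > 0 &&
                                      !is.unsorted(tab$mean_response)))
}

#' Pathway excitation/inhibition decomposition
#'
#' From the grouped weight matrix inverse `M = W^{-1}`, the contribution of
#' the direct input channels to each compartment is split into its
#' excitatory and inhibitory parts by masking the sign pattern of the
#' corresponding `M` block (Hadamard products with the positive- and
#' negative-part indicators) and applying it to the matching slice of the
#' grouped input vector. The conservation identity
#' `path_E - path_I = M_X S_X` (for nonnegative `S_X`) is exact.
#'
#' @param W_grouped grouped weight matrix ([grouped_weight_matrix()]).
#' @param S_grouped grouped input vector ([grouped_input_vector()]).
#' @param n_groups number of PC selectivity groups `n`; the first `n`
#'   entries are somatic, the following `n` per branch dendritic.
#' @param n_dendrites number of dendritic branches (default deduced from
#'   the matrix attribute, else 1).
#' @return An object of class `pe_pathways`: per-compartment data frames
#'   with `path_E`, `path_I`, `net` per group, and the inverse matrix `M`.
#' @export
pathway_decomposition <- function(W_grouped, S_grouped, n_groups,
                                  n_dendrites = NULL) {
  if (is.null(n_dendrites)) {
    n_dendrites <- attr(W_grouped, "n_dendrites")
    if (is.null(n_dendrites)) n_dendrites <- 1
  }
  rc <- rcond(W_grouped)
  if (!is.finite(rc) || rc < 1e-12) {
    stop(sprintf("singular grouped matrix: rcond = %.3g", rc))
  }
  M <- solve(W_grouped)
  n <- n_groups
  comp_idx <- list(soma = seq_len(n))
  for (k in seq_len(n_dendrites)) {
    comp_idx[[paste0("dend", k)]] <- n * k + seq_len(n)
  }
  comps <- lapply(names(comp_idx), function(nm) {
    ii <- comp_idx[[nm]]
    Mx <- M[ii, ii, drop = FALSE]
    Sx <- S_grouped[ii]
    path_E <- drop((Mx * (Mx > 0)) %*% Sx)
    path_I <- abs(drop((Mx * (Mx < 0)) %*% Sx))
    data.frame(compartment = nm, group = seq_len(n),
               path_E = path_E, path_I = path_I,
               net = drop(Mx %*% Sx))
  })
  structure(list(table = do.call(rbind, comps), M = M,
                 n_groups = n, n_dendrites = n_dendrites),
            class = "pe_pathways")
}

#' Compare PC responses between two conditions
#'
#' Two-sample comparison of per-neuron responses (e.g. tuned- versus
#' untuned-SOM models under prediction-only input) with both the two-sample
#' t-test and the Mann-Whitney U-test. No multiple-comparison correction is
#' applied; both raw p-values are reported.
#'
#' @param a,b numeric vectors of per-neuron responses (length >= 2 each).
#' @return A list with the two statistics and p-values.
#' @export
compare_conditions <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 samples per condition")
  tt <- t.test(a, b)
  ut <- suppressWarnings(wilcox.test(a, b))
  list(t_statistic = unname(tt$statistic), t_p = tt$p.value,
       u_statistic = unname(ut$statistic), u_p = ut$p.value,
       mean_a = mean(a), mean_b = mean(b))
}
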