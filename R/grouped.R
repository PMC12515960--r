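#' Grouped (population-level) weight matrix
#'
#' Collapses the realized connectivity onto the homogeneous selectivity
#' groups and linearizes the steady state around the regime where every
#' rectifier is interior and calcium is off. Row/column blocks are, in
#' order: the `n` PC soma groups, the `n` dendritic groups of each branch,
#' PV (one group, untuned), the `n` Martinotti SOM groups, the `n`
#' non-Martinotti SOM groups, and VIP (one group). Block entries are the
#' mean total connection strengths between groups with inhibitory signs
#' applied; somatic rows carry the leak factors `(1 - lambda_E)` and
#' `lambda_D` of the soma--dendrite coupling, and every row carries the
#' `-1` self term of the rate unit (dendritic rows are algebraic with a
#' `-1` identity), so that the linear steady state is minus the product of
#' the inverse matrix with the grouped input (see [linear_steady_state()]).
#'
#' @param conn a `pe_connectivity`.
#' @param pop the matching `pe_population`.
#' @param params [model_params()] supplying the leak fractions.
#' @return A square numeric matrix with labelled rows/columns and
#'   attributes `n_groups`, `n_dendrites`, `blocks` (the index list).
#' @export
grouped_weight_matrix <- function(conn, pop, params = model_params()) {
  n <- pop$n_groups
  K <- pop$n_dendrites
  pc_groups <- split(seq_len(pop$n_pc), pop$pc_group)
  m_groups <- split(pop$idx_M, pop$som_group[pop$idx_M])
  nm_groups <- split(pop$idx_nM, pop$som_group[pop$idx_nM])
  if (any(lengths(pc_groups) == 0) || length(m_groups) != n ||
      length(nm_groups) != n || pop$n_pv < 1 || pop$n_vip < 1) {
    stop("grouped weight matrix requires non-empty groups for every population")
  }
  p_groups <- list(seq_len(pop$n_pv))
  v_groups <- list(seq_len(pop$n_vip))

  # mean over postsynaptic group of the summed afferent weight from the
  # presynaptic group
  gb <- function(Wm, post, pre) {
    out <- matrix(0, length(post), length(pre))
    for (a in seq_along(post)) {
      for (b in seq_along(pre)) {
        out[a, b] <- mean(rowSums(Wm[post[[a]], pre[[b]], drop = FALSE]))
      }
    }
    out
  }
  # SOM-column pathways are indexed over the full SOM population
  som_cols <- function(Wm, post, subtype_groups) gb(Wm, post, subtype_groups)

  lab <- c(paste0("soma_", seq_len(n)),
           unlist(lapply(seq_len(K), function(k) paste0("dend", k, "_", seq_len(n)))),
           "P", paste0("M_", seq_len(n)), paste0("nM_", seq_len(n)), "V")
  N <- length(lab)
  W <- matrix(0, N, N, dimnames = list(lab, lab))
  idx <- list(soma = seq_len(n))
  for (k in seq_len(K)) idx[[paste0("dend", k)]] <- n * k + seq_len(n)
  iP <- n * (K + 1) + 1
  idx$P <- iP
  idx$M <- iP + seq_len(n)
  idx$nM <- iP + n + seq_len(n)
  idx$V <- iP + 2 * n + 1

  lE <- params$lambda_E; lD <- params$lambda_D
  # soma rows
  W[idx$soma, idx$soma] <- (1 - lE) * gb(conn$W$EE, pc_groups, pc_groups) - diag(n)
  for (k in seq_len(K)) {
    W[idx$soma, idx[[paste0("dend", k)]]] <- lD * diag(n)
  }
  W[idx$soma, idx$P] <- -(1 - lE) * gb(conn$W$EP, pc_groups, p_groups)
  W[idx$soma, idx$nM] <- -(1 - lE) * gb(conn$W$EnM, pc_groups,
                                        lapply(nm_groups, function(g) match(g, pop$idx_nM)))
  # dendritic rows (algebraic)
  for (k in seq_len(K)) {
    dk <- idx[[paste0("dend", k)]]
    W[dk, idx$soma] <- gb(conn$W[[paste0("D", k, "E")]], pc_groups, pc_groups)
    W[dk, dk] <- W[dk, dk] - diag(n)
    W[dk, idx$M] <- -gb(conn$W[[paste0("D", k, "M")]], pc_groups,
                        lapply(m_groups, function(g) match(g, pop$idx_M)))
  }
  # PV row
  W[idx$P, idx$soma] <- gb(conn$W$PE, p_groups, pc_groups)
  W[idx$P, idx$P] <- -gb(conn$W$PP, p_groups, p_groups) - 1
  W[idx$P, idx$M] <- -som_cols(conn$W$PS, p_groups, m_groups)
  W[idx$P, idx$nM] <- -som_cols(conn$W$PS, p_groups, nm_groups)
  W[idx$P, idx$V] <- -gb(conn$W$PV, p_groups, v_groups)
  # SOM rows (M then nM), receiving PC excitation and VIP inhibition
  W[idx$M, idx$soma] <- gb(conn$W$SE, m_groups, pc_groups)
  W[idx$M, idx$M] <- W[idx$M, idx$M] - diag(n)
  W[idx$M, idx$V] <- -gb(conn$W$SV, m_groups, v_groups)
  W[idx$nM, idx$soma] <- gb(conn$W$SE, nm_groups, pc_groups)
  W[idx$nM, idx$nM] <- W[idx$nM, idx$nM] - diag(n)
  W[idx$nM, idx$V] <- -gb(conn$W$SV, nm_groups, v_groups)
  # VIP row
  W[idx$V, idx$soma] <- gb(conn$W$VE, v_groups, pc_groups)
  W[idx$V, idx$M] <- -som_cols(conn$W$VS, v_groups, m_groups)
  W[idx$V, idx$nM] <- -som_cols(conn$W$VS, v_groups, nm_groups)
  W[idx$V, idx$V] <- -1

  structure(W, n_groups = n, n_dendrites = K, blocks = idx)
}

#' Grouped external-input vector
#'
#' Group-averages a [phase_inputs()] result into the block layout of
#' [grouped_weight_matrix()]. Somatic entries carry the leak factor and the
#' rheobase (`(1 - lambda_E) x_E - theta`), matching the linearized
#' steady-state convention.
#'
#' @param inputs a [phase_inputs()] list.
#' @param pop the `pe_population`.
#' @param params [model_params()].
#' @return Numeric vector aligned with the grouped matrix.
#' @export
grouped_input_vector <- function(inputs, pop, params = model_params()) {
  n <- pop$n_groups
  pc_groups <- split(seq_len(pop$n_pc), pop$pc_group)
  m_groups <- split(pop$idx_M, pop$som_group[pop$idx_M])
  nm_groups <- split(pop$idx_nM, pop$som_group[pop$idx_nM])
  soma <- vapply(pc_groups, function(g) mean(inputs$x_E[g]), 0) *
    (1 - params$lambda_E) - params$theta
  x_D <- as.matrix(inputs$x_D)
  dend <- unlist(lapply(seq_len(pop$n_dendrites), function(k) {
    vapply(pc_groups, function(g) mean(x_D[g, k]), 0)
  }))
  c(soma, dend,
    mean(inputs$x_P),
    vapply(m_groups, function(g) mean(inputs$x_S[g]), 0),
    vapply(nm_groups, function(g) mean(inputs$x_S[g]), 0),
    mean(inputs$x_V))
}

#' Linear steady state of the grouped network
#'
#' Solves the grouped steady state, minus the product of the inverse
#' grouped matrix with the grouped input vector: the linear fixed point of
#' the rate dynamics when all rectifiers are interior and calcium is
#' disabled.
#'
#' @param W_grouped matrix from [grouped_weight_matrix()] (or any square
#'   linearized system with the `-1` self terms included).
#' @param S_grouped input vector from [grouped_input_vector()].
#' @return Grouped steady rates (named like the matrix rows).
#' @export
linear_steady_state <- function(W_grouped, S_grouped) {
  stopifnot(nrow(W_grouped) == length(S_grouped))
  rc <- rcond(W_grouped)
  if (!is.finite(rc) || rc < 1e-12) {
    stop(sprintf("grouped weight matrix is (near-)singular: rcond = %.3g", rc))
  }
  drop(solve(W_grouped, -S_grouped))
}
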