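#' Population specification
#'
#' Sizes and group structure of the network: 280 pyramidal cells (PCs) and 40
#' each of PV, SOM and VIP interneurons by default. SOM cells are split into
#' Martinotti cells (dendrite-targeting) and non-Martinotti cells
#' (soma-targeting) at a 7:3 ratio. PCs and SOM cells are partitioned into
#' `n_groups` homogeneous selectivity groups (evenly, in index order); the
#' Martinotti / non-Martinotti split is applied within each SOM group so that
#' every group carries the same subtype composition.
#'
#' @param n_pc number of pyramidal cells (default 280).
#' @param n_pv,n_som,n_vip interneuron counts (default 40 each).
#' @param martinotti_fraction fraction of SOM cells that are Martinotti
#'   (default 0.7).
#' @param n_dendrites dendritic branches per PC: 1 (one feature dimension) or
#'   2 (two dimensions).
#' @param n_groups number of homogeneous PC/SOM selectivity groups
#'   (default 4). `n_pc` and `n_som` must be divisible by `n_groups`.
#' @return An object of class `pe_population` with group and SOM-subtype
#'   assignments.
#' @export
population_spec <- function(n_pc = 280, n_pv = 40, n_som = 40, n_vip = 40,
                            martinotti_fraction = 0.7, n_dendrites = 1,
                            n_groups = 4) {
  stopifnot(n_pc > 0, n_pv >= 0, n_som > 0, n_vip >= 0,
            martinotti_fraction >= 0, martinotti_fraction <= 1,
            n_dendrites %in% c(1L, 2L), n_groups >= 1)
  if (n_pc %% n_groups != 0) {
    stop("n_pc must be divisible by n_groups (even distribution of preferred stimuli)")
  }
  if (n_som %% n_groups != 0) {
    stop("n_som must be divisible by n_groups")
  }
  pc_group <- rep(seq_len(n_groups), each = n_pc / n_groups)
  som_group <- rep(seq_len(n_groups), each = n_som / n_groups)
  per_group <- n_som / n_groups
  n_m_per_group <- round(martinotti_fraction * per_group)
  stopifnot(n_m_per_group + round((1 - martinotti_fraction) * per_group) == per_group)
  subtype <- rep(rep(c("M", "nM"), c(n_m_per_group, per_group - n_m_per_group)),
                 n_groups)
  structure(list(
    n_pc = as.integer(n_pc), n_pv = as.integer(n_pv),
    n_som = as.integer(n_som), n_vip = as.integer(n_vip),
    martinotti_fraction = martinotti_fraction,
    n_dendrites = as.integer(n_dendrites),
    n_groups = as.integer(n_groups),
    pc_group = pc_group,
    som_group = som_group,
    som_subtype = subtype,
    idx_M = which(subtype == "M"),
    idx_nM = which(subtype == "nM")
  ), class = "pe_population")
}

#' @export
print.pe_population <- function(x, ...) {
  cat(sprintf(
    "<pe_population> %d PC (%d groups, %d dendrite%s), %d PV, %d SOM (%d M / %d nM), %d VIP\n",
    x$n_pc, x$n_groups, x$n_dendrites, if (x$n_dendrites > 1) "s" else "",
    x$n_pv, x$n_som, length(x$idx_M), length(x$idx_nM), x$n_vip))
  invisible(x)
}
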