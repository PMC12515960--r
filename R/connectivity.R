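#' Default connection-probability table
#'
#' 5x5 table of directed connection probabilities `p[post, pre]` over the
#' compartment/population types E (PC soma), D (PC dendrite), P (PV),
#' S (SOM), V (VIP). The `[E, D]` entry equals 1 but denotes the structural
#' within-cell dendro-somatic coupling already expressed by the leak factors
#' of the somatic current equation, not a synaptic pathway; it is therefore
#' never sampled.
#'
#' @return A 5x5 numeric matrix with dimnames `E, D, P, S, V`.
#' @export
default_connection_probs <- function() {
  p <- rbind(
    E = c(0.80, 1.00, 0.60, 0.54, 0.00),
    D = c(0.10, 0.00, 0.00, 0.55, 0.00),
    P = c(0.45, 0.00, 0.50, 0.60, 0.50),
    S = c(0.35, 0.00, 0.00, 0.00, 0.50),
    V = c(0.10, 0.00, 0.00, 0.45, 0.00))
  colnames(p) <- rownames(p)
  p
}

#' Default mean total connection strengths
#'
#' 5x5 table of the average total synaptic strength `w[post, pre]` a unit of
#' the postsynaptic type receives from the presynaptic population. `NA` marks
#' absent pathways. Plastic entries (adapted by the inhibitory learning
#' rules) are `[E,P]`, `[E,S]` (delivered by non-Martinotti SOM cells),
#' `[D,S]` (Martinotti cells), `[P,S]` and `[P,V]`.
#'
#' @return A 5x5 numeric matrix with dimnames `E, D, P, S, V` and an
#'   attribute `plastic` (logical matrix of the same shape).
#' @export
default_mean_weights <- function() {
  w <- rbind(
    E = c(0.42, NA, 1.75, 0.35, NA),
    D = c(0.42, NA, NA, 0.35, NA),
    P = c(2.50, NA, 0.50, 0.30, 0.60),
    S = c(1.00, NA, NA, NA, 0.60),
    V = c(1.00, NA, NA, 0.50, NA))
  colnames(w) <- rownames(w)
  pl <- matrix(FALSE, 5, 5, dimnames = dimnames(w))
  pl["E", "P"] <- pl["E", "S"] <- pl["D", "S"] <- TRUE
  pl["P", "S"] <- pl["P", "V"] <- TRUE
  attr(w, "plastic") <- pl
  w
}

#' Connectivity specification
#'
#' Bundles the connection-probability and mean-weight tables with the
#' initialization spread. Individual entries of either table may be
#' overridden to explore variants of the default circuit.
#'
#' @param prob 5x5 probability table, see [default_connection_probs()].
#' @param mean_weight 5x5 mean strength table, see [default_mean_weights()].
#' @param init_spread half-width of the uniform initialization relative to
#'   the mean: each synapse is drawn from
#'   `U((1 - init_spread) w, (1 + init_spread) w) / N_w` (default 0.5).
#' @return An object of class `pe_connectivity_spec`.
#' @export
connectivity_spec <- function(prob = default_connection_probs(),
                              mean_weight = default_mean_weights(),
                              init_spread = 0.5) {
  stopifnot(is.matrix(prob), all(dim(prob) == c(5, 5)),
            is.matrix(mean_weight), all(dim(mean_weight) == c(5, 5)),
            init_spread >= 0, init_spread < 1)
  if (any(prob < 0 | prob > 1)) {
    stop("connection probabilities must lie in [0, 1]")
  }
  if (is.null(attr(mean_weight, "plastic"))) {
    attr(mean_weight, "plastic") <- attr(default_mean_weights(), "plastic")
  }
  structure(list(prob = prob, mean_weight = mean_weight,
                 init_spread = init_spread),
            class = "pe_connectivity_spec")
}

## Internal pathway table: one realized weight matrix per entry.
## post/pre give population sizes; type_post/type_pre index the 5x5 tables;
## pre_subset restricts the presynaptic population (SOM subtypes).
pathway_table <- function(pop) {
  base <- list(
    list(name = "EE", post = "E", pre = "E", tp = "E", tq = "E"),
    list(name = "EP", post = "E", pre = "P", tp = "E", tq = "P"),
    list(name = "EnM", post = "E", pre = "nM", tp = "E", tq = "S"),
    list(name = "PE", post = "P", pre = "E", tp = "P", tq = "E"),
    list(name = "PP", post = "P", pre = "P", tp = "P", tq = "P"),
    list(name = "PS", post = "P", pre = "S", tp = "P", tq = "S"),
    list(name = "PV", post = "P", pre = "V", tp = "P", tq = "V"),
    list(name = "SE", post = "S", pre = "E", tp = "S", tq = "E"),
    list(name = "SV", post = "S", pre = "V", tp = "S", tq = "V"),
    list(name = "VE", post = "V", pre = "E", tp = "V", tq = "E"),
    list(name = "VS", post = "V", pre = "S", tp = "V", tq = "S"))
  for (k in seq_len(pop$n_dendrites)) {
    base <- c(base, list(
      list(name = paste0("D", k, "E"), post = "E", pre = "E", tp = "D", tq = "E"),
      list(name = paste0("D", k, "M"), post = "E", pre = "M", tp = "D", tq = "S")))
  }
  base
}

pop_size <- function(pop, who) {
  switch(who,
         E = pop$n_pc, P = pop$n_pv, S = pop$n_som, V = pop$n_vip,
         M = length(pop$idx_M), nM = length(pop$idx_nM))
}

plastic_pathways <- function(pop) {
  c("EP", "EnM", paste0("D", seq_len(pop$n_dendrites), "M"), "PS", "PV")
}

#' Sample a random connectivity
#'
#' Realizes the random network: for each pathway, synapses exist
#' independently with the pathway's connection probability (PC self-synapses
#' excluded), and each existing synapse is drawn from
#' `U((1-s) w, (1+s) w) / N_w`, where `w` is the pathway's mean total
#' strength, `s` the initialization spread and `N_w` the postsynaptic
#' neuron's realized afferent count for that pathway, so that the expected
#' total input per neuron equals `w` exactly. Plastic pathways additionally
#' carry the softplus pre-activations `v = softplus_inverse(w_ij)`.
#'
#' Dendrite-targeting SOM input comes from Martinotti cells, soma-targeting
#' SOM input from non-Martinotti cells; PV and VIP receive input from the
#' full SOM population.
#'
#' @param pop a [population_spec()].
#' @param spec a [connectivity_spec()].
#' @param seed integer seed; the same seed reproduces the connectivity
#'   exactly.
#' @return An object of class `pe_connectivity`: lists `W` (nonnegative
#'   weight magnitudes, signs are applied by the dynamics), `mask` (0/1
#'   adjacency) and `v` (softplus pre-activations for plastic pathways),
#'   indexed by pathway name (`EE`, `EP`, `EnM`, `D1E`, `D1M`, ..., `PE`,
#'   `PP`, `PS`, `PV`, `SE`, `SV`, `VE`, `VS`), rows = postsynaptic units.
#' @export
sample_connectivity <- function(pop, spec = connectivity_spec(), seed = 1L) {
  stopifnot(inherits(pop, "pe_population"), inherits(spec, "pe_connectivity_spec"))
  set.seed(as.integer(seed))
  W <- list(); mask <- list(); v <- list()
  plastic <- plastic_pathways(pop)
  for (pw in pathway_table(pop)) {
    n_post <- pop_size(pop, pw$post)
    n_pre <- pop_size(pop, pw$pre)
    p <- spec$prob[pw$tp, pw$tq]
    wbar <- spec$mean_weight[pw$tp, pw$tq]
    if (p <= 0 || is.na(wbar)) {
      W[[pw$name]] <- matrix(0, n_post, n_pre)
      mask[[pw$name]] <- matrix(0, n_post, n_pre)
      next
    }
    m <- matrix(runif(n_post * n_pre) < p, n_post, n_pre) * 1
    if (pw$post == "E" && pw$pre == "E") diag(m) <- 0
    nw <- rowSums(m)
    if (any(nw == 0)) {
      warning(sprintf("pathway %s: %d postsynaptic unit(s) received no afferents; row(s) left zero",
                      pw$name, sum(nw == 0)))
    }
    s <- spec$init_spread
    draw <- matrix(runif(n_post * n_pre, (1 - s) * wbar, (1 + s) * wbar),
                   n_post, n_pre)
    wm <- m * draw / ifelse(nw > 0, nw, 1)
    W[[pw$name]] <- wm
    mask[[pw$name]] <- m
    if (pw$name %in% plastic) {
      vm <- matrix(0, n_post, n_pre)
      vm[m > 0] <- softplus_inverse(wm[m > 0])
      v[[pw$name]] <- vm
    }
  }
  structure(list(W = W, mask = mask, v = v, plastic = plastic,
                 spec = spec, n_dendrites = pop$n_dendrites),
            class = "pe_connectivity")
}

#' Set plastic weights to their pathway means
#'
#' Replaces every existing plastic synapse by the homogeneous value
#' `w / N_w` (pathway mean total strength divided by the neuron's realized
#' afferent count), so that every postsynaptic unit receives exactly the
#' mean total inhibition through each plastic pathway. This is the
#' "homogeneous weights" condition used to probe the circuit before
#' training.
#'
#' @param conn a `pe_connectivity`.
#' @param pop the matching `pe_population`.
#' @return The modified connectivity.
#' @export
homogenize_plastic_weights <- function(conn, pop) {
  stopifnot(inherits(conn, "pe_connectivity"))
  tab <- pathway_table(pop)
  names(tab) <- vapply(tab, `[[`, "", "name")
  for (nm in conn$plastic) {
    pw <- tab[[nm]]
    wbar <- conn$spec$mean_weight[pw$tp, pw$tq]
    m <- conn$mask[[nm]]
    nw <- rowSums(m)
    wm <- m * (wbar / ifelse(nw > 0, nw, 1))
    conn$W[[nm]] <- wm
    vm <- matrix(0, nrow(m), ncol(m))
    vm[m > 0] <- softplus_inverse(wm[m > 0])
    conn$v[[nm]] <- vm
  }
  conn
}

#' Perturb all weights multiplicatively
#'
#' Robustness check: every nonzero weight is multiplied by an independent
#' draw from `U(1 - range_fraction, 1 + range_fraction)`; adjacency masks are
#' unchanged and plastic pre-activations are recomputed.
#'
#' @param conn a `pe_connectivity`.
#' @param range_fraction half-width of the uniform scaling, in `[0, 1)`.
#' @param seed integer seed.
#' @return The perturbed connectivity.
#' @export
perturb_connectivity <- function(conn, range_fraction, seed = 1L) {
  stopifnot(inherits(conn, "pe_connectivity"))
  if (range_fraction < 0 || range_fraction >= 1) {
    stop("range_fraction must lie in [0, 1)")
  }
  set.seed(as.integer(seed))
  for (nm in names(conn$W)) {
    w <- conn$W[[nm]]
    nz <- which(w > 0)
    if (!length(nz)) next
    w[nz] <- w[nz] * runif(length(nz), 1 - range_fraction, 1 + range_fraction)
    conn$W[[nm]] <- w
    if (nm %in% conn$plastic) {
      vm <- conn$v[[nm]]
      vm[nz] <- softplus_inverse(w[nz])
      conn$v[[nm]] <- vm
    }
  }
  conn
}

#' @export
print.pe_connectivity <- function(x, ...) {
  cat(sprintf("<pe_connectivity> pathways: %s\n", paste(names(x$W), collapse = ", ")))
  cat(sprintf("  plastic: %s\n", paste(x$plastic, collapse = ", ")))
  invisible(x)
}
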