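#' Experiment configuration
#'
#' Bundles everything an end-to-end run needs; a run is fully determined by
#' `(config, seed)`. Ablations: `som_untuned` replaces the tuned SOM
#' sensory drive by the untuned amplitude, `sigma_som_equals_pc` sets the
#' SOM tuning width to the PC width, `calcium_off` disables dendritic
#' calcium events.
#'
#' @param name experiment name (used in output file names).
#' @param dims 1 or 2 feature dimensions.
#' @param train whether to train before testing (default `TRUE`).
#' @param test_kind test protocol kind (default `test_1d` / `test_2d` by
#'   `dims`).
#' @param n_presentations training length (passed to
#'   [plasticity_params()]).
#' @param test_repetitions noisy repetitions averaged per test phase
#'   (default 5).
#' @param noise_sigma feature noise SD (default 0.35).
#' @param som_untuned,sigma_som_equals_pc,calcium_off ablation flags.
#' @param seeds integer vector of seeds (default 1:5).
#' @param params,plast optional [model_params()] / [plasticity_params()]
#'   overrides.
#' @return An object of class `pe_experiment_config`.
#' @export
experiment_config <- function(name, dims = 1, train = TRUE, test_kind = NULL,
                              n_presentations = 8000, test_repetitions = 5,
                              noise_sigma = 0.35, som_untuned = FALSE,
                              sigma_som_equals_pc = FALSE, calcium_off = FALSE,
                              seeds = 1:5, params = NULL, plast = NULL) {
  stopifnot(dims %in% 1:2)
  if (is.null(test_kind)) test_kind <- if (dims == 1) "test_1d" else "test_2d"
  if (is.null(params)) params <- model_params()
  if (calcium_off) params$c_amp <- 0
  if (is.null(plast)) plast <- plasticity_params(n_presentations = n_presentations)
  structure(list(name = name, dims = dims, train = train,
                 test_kind = test_kind, n_presentations = n_presentations,
                 test_repetitions = test_repetitions,
                 noise_sigma = noise_sigma, som_untuned = som_untuned,
                 sigma_som_equals_pc = sigma_som_equals_pc,
                 calcium_off = calcium_off, seeds = as.integer(seeds),
                 params = params, plast = plast),
            class = "pe_experiment_config")
}

build_default_network <- function(config, seed) {
  pop <- population_spec(n_dendrites = config$dims)
  bank <- assign_preferred_stimuli(
    pop, sigma_som = if (config$sigma_som_equals_pc) 0.8 else 1.0)
  conn <- sample_connectivity(pop, connectivity_spec(), seed = seed)
  list(pop = pop, bank = bank, conn = conn)
}

run_one_seed <- function(config, seed) {
  net <- build_default_network(config, seed)
  pop <- net$pop; bank <- net$bank; conn <- net$conn
  params <- config$params
  training <- NULL
  if (config$train) {
    training <- train_network(conn, pop, bank, params, config$plast,
                              noise_sigma = config$noise_sigma,
                              seed = seed + 10000L)
    conn <- training$conn
  }
  proto <- build_protocol(config$test_kind, noise_sigma = config$noise_sigma)
  set.seed(seed + 20000L)
  resp <- steady_responses(conn, pop, bank, proto, params,
                           repetitions = config$test_repetitions,
                           som_untuned = config$som_untuned)
  # baseline rates from the (noise-free) baseline phase
  bl_phase <- stimulus_phase(rep(-1, bank$n_dim), rep(-1, bank$n_dim))
  bl_inp <- phase_inputs(bl_phase, bank, pop, params)
  bl <- run_to_steady_state(conn, bl_inp, pop, params, method = "newton")

  cls <- tryCatch(
    classify_pe(resp$rates, resp$phase_info, bl$r_E, bank),
    error = function(e) NULL)
  # selectivity under prediction-only input
  i_pred <- which(resp$phase_info$label == "prediction_only")
  gamma <- NA_real_
  if (length(i_pred)) {
    gm <- vapply(seq_len(pop$n_groups), function(g) {
      mean(resp$rates[i_pred[1], pop$pc_group == g])
    }, 0)
    gamma <- selectivity_coefficient(gm)$gamma
  }
  list(seed = seed, pop = pop, bank = bank, conn = conn,
       responses = resp, baseline = bl, classification = cls,
       gamma = gamma, training = training)
}

#' Run an experiment end-to-end
#'
#' For each seed: build the default network, optionally train it, run the
#' test protocol, classify PE neurons and compute the selectivity
#' coefficient, and write per-phase steady rates, the classification table
#' and a machine-readable summary to `output_dir`.
#'
#' @param config an [experiment_config()].
#' @param output_dir output directory (created); `NULL` skips writing.
#' @return A list of per-seed results plus the `summary` data frame.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pe_experiment_config"))
  results <- lapply(config$seeds, function(s) run_one_seed(config, s))
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(seed = r$seed, gamma = r$gamma,
               fraction_pe = if (is.null(r$classification)) NA
                             else r$classification$fraction_pe,
               baseline_rate = mean(r$baseline$r_E),
               presentations = if (is.null(r$training)) 0
                               else r$training$presentations)
  }))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in results) {
      stem <- file.path(output_dir, sprintf("%s_seed%d", config$name, r$seed))
      rates <- data.frame(r$responses$phase_info,
                          r$responses$rates, check.names = FALSE)
      write.csv(rates, paste0(stem, "_rates.csv"), row.names = FALSE)
      if (!is.null(r$classification)) {
        write.csv(data.frame(neuron = seq_along(r$classification$is_pe),
                             group = r$pop$pc_group,
                             is_pe = r$classification$is_pe),
                  paste0(stem, "_pe.csv"), row.names = FALSE)
      }
    }
    write.csv(summary, file.path(output_dir, paste0(config$name, "_summary.csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(name = config$name, dims = config$dims,
           seeds = config$seeds,
           gamma_mean = mean(summary$gamma, na.rm = TRUE),
           gamma_sd = sd(summary$gamma),
           fraction_pe_mean = mean(summary$fraction_pe, na.rm = TRUE),
           baseline_rate_mean = mean(summary$baseline_rate)),
      file.path(output_dir, paste0(config$name, "_summary.json")),
      auto_unbox = TRUE, digits = NA)
  }
  list(results = results, summary = summary, config = config)
}

#' Aggregate experiment summaries across seeds
#'
#' Reads all `*_summary.csv` files in a results directory and reports mean
#' and SD of the selectivity coefficient, PE fraction and baseline rate per
#' experiment.
#'
#' @param results_dir directory written by [run_experiment()].
#' @return Data frame, one row per experiment.
#' @export
summarize_experiments <- function(results_dir) {
  files <- list.files(results_dir, pattern = "_summary\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop("no experiment summaries found in ", results_dir)
  do.call(rbind, lapply(files, function(f) {
    s <- read.csv(f)
    data.frame(experiment = sub("_summary\\.csv$", "", basename(f)),
               n_seeds = nrow(s),
               gamma_mean = mean(s$gamma, na.rm = TRUE),
               gamma_sd = if (nrow(s) > 1) sd(s$gamma) else 0,
               fraction_pe_mean = mean(s$fraction_pe, na.rm = TRUE),
               baseline_rate_mean = mean(s$baseline_rate))
  }))
}
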