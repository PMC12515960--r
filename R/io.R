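#' Write / read a connectivity as a directory of CSV matrices
#'
#' One CSV file per pathway (rows = postsynaptic units) plus the adjacency
#' masks, so a trained network can be archived and reloaded exactly.
#'
#' @param conn a `pe_connectivity`.
#' @param dir target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_connectivity_csv <- function(conn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(conn$W)) {
    write.csv(conn$W[[nm]], file.path(dir, paste0("W_", nm, ".csv")),
              row.names = FALSE)
    write.csv(conn$mask[[nm]], file.path(dir, paste0("mask_", nm, ".csv")),
              row.names = FALSE)
  }
  meta <- list(plastic = conn$plastic, n_dendrites = conn$n_dendrites,
               init_spread = conn$spec$init_spread)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_connectivity_csv
#' @param spec the `pe_connectivity_spec` to attach to the reloaded object
#'   (defaults to [connectivity_spec()]).
#' @export
read_connectivity_csv <- function(dir, spec = connectivity_spec()) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  files <- list.files(dir, pattern = "^W_.*\\.csv$")
  W <- list(); mask <- list(); v <- list()
  for (f in files) {
    nm <- sub("^W_(.*)\\.csv$", "\\1", f)
    W[[nm]] <- as.matrix(read.csv(file.path(dir, f)))
    mask[[nm]] <- as.matrix(read.csv(file.path(dir, paste0("mask_", nm, ".csv"))))
    dimnames(W[[nm]]) <- dimnames(mask[[nm]]) <- NULL
    if (nm %in% meta$plastic) {
      vm <- matrix(0, nrow(W[[nm]]), ncol(W[[nm]]))
      pos <- mask[[nm]] > 0 & W[[nm]] > 0
      vm[pos] <- softplus_inverse(W[[nm]][pos])
      v[[nm]] <- vm
    }
  }
  structure(list(W = W, mask = mask, v = v, plastic = meta$plastic,
                 spec = spec, n_dendrites = meta$n_dendrites),
            class = "pe_connectivity")
}

#' Export a protocol as a phase table
#'
#' @param protocol a [build_protocol()] result.
#' @param file optional CSV path; if `NULL` the data frame is returned only.
#' @return Data frame with one row per phase (index, label, P, S, duration,
#'   attention gains).
#' @export
protocol_to_csv <- function(protocol, file = NULL) {
  phases <- protocol$phases
  df <- do.call(rbind, lapply(seq_along(phases), function(i) {
    ph <- phases[[i]]
    data.frame(phase = i, label = ph$label,
               P = paste(ph$P, collapse = ","),
               S = paste(ph$S, collapse = ","),
               duration = ph$duration,
               attention_gain = paste(ph$attention_gain, collapse = ","))
  }))
  if (!is.null(file)) write.csv(df, file, row.names = FALSE)
  df
}
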