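#' Write / read model parameter files
#'
#' Model parameter sets serialize to JSON with explicit field names, a
#' canonical key order and full float precision, so that
#' load-then-save round-trips are byte-identical.  Units follow the
#' package convention (mV, ms, pA, nS, pF).
#'
#' @param model A [gif_params()]-family object or a
#'   [potassium_current_model()].
#' @param path Output file path.
#' @return `path`, invisibly (`write_model_json`); the reconstructed
#'   object (`read_model_json`).
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

model_to_list <- function(model) {
  if (inherits(model, "k_current_model")) {
    return(list(kind = "k_current_model",
                g_A_bar = model$g_A_bar, g_K_bar = model$g_K_bar,
                E_K = model$E_K, tau_h = model$tau_h,
                m_gate = unclass(model$m_gate),
                h_gate = unclass(model$h_gate),
                n_gate = unclass(model$n_gate)))
  }
  stopifnot(inherits(model, "gif_params"))
  kind <- if (inherits(model, "agif_params")) "agif"
          else if (inherits(model, "igif_params")) "igif" else "gif"
  out <- list(kind = kind, units = "mV.ms.pA.nS.pF",
              C = model$C, g_l = model$g_l, E_l = model$E_l,
              V_T_star = model$V_T_star, DeltaV = model$DeltaV,
              V_reset = model$V_reset, T_ref = model$T_ref,
              lambda_0 = model$lambda_0,
              eta = list(weights = model$eta$weights,
                         timescales = model$eta$timescales),
              gamma = list(weights = model$gamma$weights,
                           timescales = model$gamma$timescales))
  if (kind == "agif") out$k_currents <- model_to_list(model$k_currents)
  if (kind == "igif") {
    out$theta_steps <- model$theta_steps
    out$bin_edges <- model$bin_edges
    out$tau_theta <- model$tau_theta
  }
  out
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list_to_model(x)
}

list_to_model <- function(x) {
  if (identical(x$kind, "k_current_model")) {
    return(potassium_current_model(
      g_A_bar = x$g_A_bar, g_K_bar = x$g_K_bar, E_K = x$E_K,
      tau_h = x$tau_h,
      m_gate = gating_params(x$m_gate$A, x$m_gate$k, x$m_gate$V_star),
      h_gate = gating_params(x$h_gate$A, x$h_gate$k, x$h_gate$V_star),
      n_gate = gating_params(x$n_gate$A, x$n_gate$k, x$n_gate$V_star)))
  }
  eta <- filter_coeffs(x$eta$weights, x$eta$timescales)
  gamma <- filter_coeffs(x$gamma$weights, x$gamma$timescales)
  switch(x$kind,
    gif = gif_params(x$C, x$g_l, x$E_l, eta, gamma, x$V_T_star, x$DeltaV,
                     x$V_reset, x$T_ref, x$lambda_0),
    agif = agif_params(x$C, x$g_l, x$E_l, eta, gamma, x$V_T_star, x$DeltaV,
                       x$V_reset, x$T_ref,
                       k_currents = list_to_model(x$k_currents),
                       lambda_0 = x$lambda_0),
    igif = igif_params(x$C, x$g_l, x$E_l, eta, gamma, x$V_T_star, x$DeltaV,
                       x$V_reset, x$T_ref, theta_steps = x$theta_steps,
                       bin_edges = x$bin_edges, tau_theta = x$tau_theta,
                       lambda_0 = x$lambda_0),
    abort(sprintf("unknown model kind in file: %s", x$kind)))
}

#' Write / read a recording as CSV with a JSON sidecar
#'
#' The sweep table goes to `<path>` as plain CSV (`sweep,t,V,I`); the
#' sample interval, cell type and metadata go to `<path>.json`.
#'
#' @param rec A [recording()].
#' @param path CSV file path.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  jsonlite::write_json(
    list(dt = attr(rec, "dt"), cell_type = attr(rec, "cell_type"),
         metadata = attr(rec, "metadata")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  sw <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  recording(sw, dt = side$dt, cell_type = side$cell_type,
            metadata = side$metadata %||% list())
}

#' Run manifest
#'
#' Records the configuration, seeds and package version of a stochastic
#' run so it can be reproduced bitwise.
#'
#' @param config Named list of configuration values.
#' @param seeds Named list or vector of seeds used.
#' @param path Optional JSON output path.
#' @return The manifest list (invisibly if written).
#' @export
run_manifest <- function(config = list(), seeds = list(), path = NULL) {
  m <- list(package = "raphenet",
            version = as.character(utils::packageVersion("raphenet")),
            config = config, seeds = seeds)
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(m))
  }
  m
}
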