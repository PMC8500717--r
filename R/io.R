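#' Read a frequency-domain response from CSV
#'
#' Expects a header with columns `frequency_mhz`, `phase_deg`, `modulation`
#' (optionally `n`, `d`); lines starting with `#` are comments. Frequencies
#' must be strictly ascending; phase outside (0, 90) degrees or modulation
#' outside (0, 1] is physically suspect for a simple decay and raises a
#' warning naming the offending rows, but the data are returned as read.
#'
#' @param path CSV file path.
#' @return A [frequency_response()].
#' @export
read_frequency_response <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", strip.white = TRUE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  need <- c("frequency_mhz", "phase_deg", "modulation")
  if (nrow(df) == 0 || !all(need %in% names(df)))
    stop("parse error in ", path,
         ": need columns frequency_mhz, phase_deg, modulation")
  bad_rows <- which(!stats::complete.cases(df[need]))
  if (length(bad_rows))
    stop("parse error in ", path, ": malformed rows ",
         paste(bad_rows, collapse = ", "))
  if (any(diff(df$frequency_mhz) <= 0))
    stop("frequencies in ", path, " must be strictly ascending")
  odd <- which(df$phase_deg <= 0 | df$phase_deg >= 90 |
                 df$modulation <= 0 | df$modulation > 1)
  if (length(odd))
    warning("rows ", paste(odd, collapse = ", "), " of ", path,
            " fall outside the physical phase/modulation range")
  frequency_response(df$frequency_mhz, df$phase_deg, df$modulation,
                     n = df$n, d = df$d)
}

#' Write a frequency-domain response to CSV
#'
#' @param response A [frequency_response()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_response <- function(response, path) {
  stopifnot(inherits(response, "frequency_response"))
  utils::write.csv(as.data.frame(response), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a model parameter vector as JSON
#'
#' The 12-parameter vector is serialized as a flat JSON object keyed by
#' parameter name.
#'
#' @param path JSON file path.
#' @return [read_parameters()]: an [fd_parameters()] vector.
#' @export
read_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(fd_parameters, as.list(x))
}

#' @rdname read_parameters
#' @param p An [fd_parameters()] vector.
#' @export
write_parameters <- function(p, path) {
  validate_fd_parameters(p)
  jsonlite::write_json(as.list(unclass(p)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the full staged analysis from a configuration
#'
#' Drives the pipeline end to end: read (or accept in-memory) per-condition
#' frequency responses, run the staged fitting protocol, and write the fit
#' parameters (JSON), the fitted distance-distribution curves (CSV, one
#' density column per acceptor-bearing condition), and the per-condition
#' phasor coordinates (CSV). Reruns with identical inputs and seeds are
#' bit-identical.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   `conditions` (list of entries with `label` and either `path` to a
#'   response CSV or an in-memory `response`, plus optional
#'   `steady_state_e`), `r0`, `acceptor`, optional `f_d_acceptor`,
#'   `weights` (list of s_phase/s_mod/s_e), `n_starts`, `seed`,
#'   `phasor_frequency`, and `output_dir` (omit to skip writing).
#' @return A list of class `tmfret_run` with the protocol fit, the final
#'   parameters, the distance-distribution curves and the phasor table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = FALSE)
  if (is.null(config$conditions) || is.null(config$r0))
    stop("config must provide conditions and r0")
  weights <- do.call(chi_weights, config$weights %||% list())
  conditions <- lapply(config$conditions, function(entry) {
    resp <- if (!is.null(entry$response)) entry$response
            else read_frequency_response(entry$path)
    bg <- attr(resp, "background_phasor")
    experiment_condition(entry$label, resp,
                         steady_state_e = entry$steady_state_e,
                         background_phasor = bg %||%
                           unmodulated_background(resp$frequency_mhz))
  })
  fit <- fit_protocol(conditions, r0 = config$r0,
                      acceptor = config$acceptor %||% "cu_tetac",
                      f_d_acceptor = config$f_d_acceptor,
                      weights = weights,
                      n_starts = config$n_starts %||% 4,
                      seed = config$seed %||% 1234)

  # distance-distribution curves per fitted acceptor condition
  r_grid <- seq(2, 40, by = 0.1)
  stage_names <- setdiff(names(fit), "parameters")
  curves <- data.frame(r_angstrom = r_grid)
  for (nm in stage_names) {
    if (fit[[nm]]$label %in% c("donor_only", "reversal")) next
    curves[[nm]] <- distance_density(.dist_from(fit[[nm]]$parameters), r_grid)
  }

  phasor_freq <- config$phasor_frequency %||% 10
  phas <- do.call(rbind, lapply(seq_along(conditions), function(i)
    to_phasor(conditions[[i]]$response, phasor_freq,
              group = sprintf("%02d_%s", i, conditions[[i]]$label))))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_parameters(fit$parameters,
                     file.path(config$output_dir, "fit_parameters.json"))
    fitjson <- lapply(fit[stage_names], function(f)
      list(label = f$label, free = f$free, chi2 = f$chi2, n_obs = f$n_obs,
           converged = f$converged,
           parameters = as.list(unclass(f$parameters))))
    jsonlite::write_json(fitjson,
                         file.path(config$output_dir, "fit_stages.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(curves,
                     file.path(config$output_dir, "distance_distributions.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(phas),
                     file.path(config$output_dir, "phasor.csv"),
                     row.names = FALSE)
  }
  structure(list(fit = fit, parameters = fit$parameters,
                 distance_curves = curves, phasor = phas,
                 seed = config$seed %||% 1234),
            class = "tmfret_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
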