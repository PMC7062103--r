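# YAML/JSON run configuration shared by the command-line driver and scripted
# use.

#' Read a run configuration file
#'
#' Accepts YAML or JSON with any of the keys `n`, `k`, `f_th`,
#' `incompatible_count`, `beta`, `alpha`, `lambda`, `mu`, `eps`, `dt`,
#' `check_interval`, `tol`, `max_time`, `seed`, `n_seeds`, `jump_threshold`,
#' `gap_tol`, `output_dir`; missing keys fall back to the model defaults
#' (n = 6, k = 1, beta = 1, alpha = 0, lambda = 0.999, mu = 0.001,
#' eps = 0.01).
#'
#' @param path Configuration file path (`.json` is parsed as JSON, anything
#'   else as YAML).
#' @return A named list of class `culture_config` with `params`
#'   ([dynamics_params()]), `settings` ([integrator_settings()]) and the
#'   remaining scalar options.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 reads a bare key `n` as the boolean FALSE; undo that
  names(raw)[names(raw) %in% c("FALSE", "no")] <- "n"
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param config Named list of configuration values (as parsed from a file).
#' @export
as_run_config <- function(config = list()) {
  default <- list(n = 6, k = 1, f_th = 0, incompatible_count = NULL,
                  beta = 1, alpha = 0, lambda = 0.999, mu = 0.001,
                  eps = 0.01, dt = 0.1, check_interval = 100, tol = 1e-4,
                  max_time = 1e5, seed = 1, n_seeds = 1,
                  jump_threshold = 0.9, gap_tol = 0.05, output_dir = ".")
  unknown <- setdiff(names(config), names(default))
  if (length(unknown) > 0) {
    stop("Unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(default, config, keep.null = TRUE)
  cfg$params <- dynamics_params(cfg$lambda, cfg$mu, cfg$beta, cfg$alpha)
  cfg$settings <- integrator_settings(cfg$dt, cfg$check_interval, cfg$tol,
                                      cfg$max_time)
  structure(cfg, class = "culture_config")
}

#' Build the landscape pair described by a configuration
#'
#' @param cfg A `culture_config`.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A `landscape_pair`.
#' @export
config_landscape_pair <- function(cfg, seed = NULL) {
  landscape_pair(cfg$n, cfg$k, seed = seed %||% cfg$seed, f_th = cfg$f_th,
                 incompatible_count = cfg$incompatible_count)
}
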