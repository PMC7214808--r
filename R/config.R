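# Run configuration: defaults, validation, YAML/JSON round-trip.
# The defaults reproduce the benchmark conditions: simulation step
# h = 0.1 ms, communication interval 1 ms, gap weight g = 0.1 nS, step
# noise 200 +/- 250 pA, waveform relaxation with at most 5 iterations,
# tolerance 1e-5 and interpolation order 3; ring topology with K_gap = 60
# gap junctions per neuron and 185 neurons per rank.

#' Default run configuration
#'
#' @return named list of all configuration fields with benchmark defaults
#' @export
default_config <- function() {
  list(
    M = 2L, T = 12L,
    N = 370L, K_gap = 60L, g = 0.1,
    network = "ring",
    noise = list(mean = 200, std = 250),
    params = list(),
    wfr = list(max_iterations = 5L, tolerance = 1e-5,
               interpolation_order = 3L),
    h = 0.1, comm_interval = 1,
    abs_tol = 1e-6,
    duration_ms = 500, init_ms = 10,
    mode = "alltoallv",
    record_gids = NULL,
    init_V = NULL,
    seed = 1L
  )
}

#' Resolve a partial configuration against the defaults
#'
#' Unknown fields are rejected; nested lists (`noise`, `wfr`, `params`) are
#' merged field-wise. The resolved configuration is validated.
#'
#' @param config named list of overrides (possibly empty)
#' @return complete validated configuration
#' @export
resolve_config <- function(config = list()) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (nm %in% c("noise", "wfr") && is.list(config[[nm]])) {
      sub <- def[[nm]]
      bad <- setdiff(names(config[[nm]]), names(sub))
      if (length(bad))
        stop("unknown field(s) in '", nm, "': ", paste(bad, collapse = ", "))
      sub[names(config[[nm]])] <- config[[nm]]
      def[[nm]] <- sub
    } else {
      def[nm] <- list(config[[nm]])
    }
  }
  validate_config(def)
  def
}

#' Validate a configuration, reporting offending fields by name
#'
#' @param cfg a complete configuration list
#' @return invisibly TRUE; stops with a field-level message otherwise
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$M) && cfg$M >= 1, "M: must be a positive integer")
  chk(is.numeric(cfg$T) && cfg$T >= 1, "T: must be a positive integer")
  chk(is.numeric(cfg$N) && cfg$N >= 2, "N: must be at least 2")
  chk(is.numeric(cfg$K_gap) && cfg$K_gap >= 2 && cfg$K_gap %% 2 == 0,
      "K_gap: must be a positive even integer")
  chk(cfg$K_gap < cfg$N, "K_gap: must be smaller than N")
  chk(cfg$g >= 0, "g: must be non-negative")
  chk(cfg$network %in% c("ring", "random"),
      "network: must be 'ring' or 'random'")
  chk(cfg$noise$std >= 0, "noise$std: must be non-negative")
  chk(cfg$wfr$max_iterations >= 1, "wfr$max_iterations: must be >= 1")
  chk(cfg$wfr$tolerance > 0, "wfr$tolerance: must be positive")
  chk(cfg$wfr$interpolation_order %in% c(1L, 3L),
      "wfr$interpolation_order: must be 1 or 3")
  chk(cfg$h > 0, "h: must be positive")
  chk(abs(cfg$comm_interval / cfg$h -
            round(cfg$comm_interval / cfg$h)) < 1e-9,
      "comm_interval: must be an integer multiple of h")
  chk(cfg$abs_tol > 0, "abs_tol: must be positive")
  chk(cfg$duration_ms >= 0, "duration_ms: must be non-negative")
  chk(cfg$init_ms >= 0, "init_ms: must be non-negative")
  for (f in c("duration_ms", "init_ms")) {
    v <- cfg[[f]]
    chk(abs(v / cfg$comm_interval - round(v / cfg$comm_interval)) < 1e-9,
        paste0(f, ": must be an integer multiple of comm_interval"))
  }
  chk(cfg$mode %in% c("alltoallv", "allgather"),
      "mode: must be 'alltoallv' or 'allgather'")
  if (!is.null(cfg$init_V))
    chk(length(cfg$init_V) == cfg$N && all(is.finite(cfg$init_V)),
        "init_V: must be a finite vector of length N")
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

#' Read a configuration from a YAML or JSON file
#'
#' @param path file path (`.yaml`/`.yml` or `.json`)
#' @return resolved configuration list
#' @export
config_read <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$record_gids)) raw$record_gids <- as.integer(raw$record_gids)
  resolve_config(raw)
}

#' Write a resolved configuration to YAML
#'
#' @param cfg configuration list
#' @param path output path
#' @return invisibly `path`
#' @export
config_write <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
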