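#' Default run configuration
#'
#' The defaults define the standard experiment: landscape
#' (a=1e-2, b=2, c=1, d=6, e=2e2), dynamics (omega=3.14, epsilon=0.37,
#' dt=0.01, t_max=1e5, arrival_delta=0.5, no-return on, m = n-1),
#' experiment (n in {12, 24, 36}, alpha grid 0 to 1 by 0.05, 200
#' replicates per cell).
#'
#' @return A nested list of class `run_config` with sections `landscape`,
#'   `dynamics`, `experiment`, `output`.
#' @export
default_config <- function() {
  structure(list(
    landscape = list(a = 1e-2, b = 2, c = 1, d = 6, e = 2e2),
    dynamics = list(alpha = 0, omega = 3.14, epsilon = 0.37, dt = 0.01,
                    m = NULL, t_max = 1e5, arrival_delta = 0.5,
                    no_return = TRUE, jitter_sd = 0),
    experiment = list(n = c(12L, 24L, 36L),
                      alphas = seq(0, 1, by = 0.05),
                      reps = 200L, master_seed = 1L, record_every = 100L),
    output = list(dir = ".", format = "tsv", write_plots = FALSE)),
    class = "run_config")
}

merge_section <- function(base, override, section) {
  unknown <- setdiff(names(override), names(base))
  if (length(unknown))
    stop("unknown key(s) in [", section, "]: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base
}

#' Load a JSON run configuration
#'
#' Reads a JSON file with any of the sections `landscape`, `dynamics`,
#' `experiment`, `output`, merges it over [default_config()], and
#' validates. Unknown sections or keys are rejected (typo guard); an empty
#' file yields the full default configuration.
#'
#' @param path Path to a JSON config file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  override <- if (nzchar(trimws(txt)))
    jsonlite::fromJSON(txt, simplifyVector = TRUE) else list()
  if (!is.list(override))
    stop("malformed config: top level must be a JSON object", call. = FALSE)
  cfg <- default_config()
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in names(override))
    cfg[[sec]] <- merge_section(cfg[[sec]], override[[sec]], sec)
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg A `run_config` list.
#' @return The config, invisibly usable, after range and consistency checks.
#' @export
validate_config <- function(cfg) {
  # landscape positivity is enforced by the constructor
  ls <- do.call(quartic_landscape, cfg$landscape)
  dyn <- cfg$dynamics
  p <- dynamics_params(alpha = dyn$alpha, omega = dyn$omega,
                       epsilon = dyn$epsilon, dt = dyn$dt, m = dyn$m,
                       t_max = dyn$t_max, arrival_delta = dyn$arrival_delta,
                       no_return = dyn$no_return, jitter_sd = dyn$jitter_sd)
  ex <- cfg$experiment
  if (any(ex$n < 1 | ex$n != round(ex$n)))
    stop("experiment$n must be positive integers", call. = FALSE)
  if (any(ex$alphas < 0 | ex$alphas > 1))
    stop("experiment$alphas must lie in [0, 1]", call. = FALSE)
  if (ex$reps < 1) stop("experiment$reps must be >= 1", call. = FALSE)
  if (!is.null(dyn$m) && any(dyn$m > ex$n - 1))
    stop("m = ", dyn$m, " violates m <= n-1 for n = ",
         paste(ex$n[dyn$m > ex$n - 1], collapse = ", "), call. = FALSE)
  cfg$landscape_object <- ls
  cfg$params_object <- p
  cfg
}
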