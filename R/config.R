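# Validated analysis configuration. A single YAML file (or in-code list)
# carries every threshold the headline numbers are sensitive to; unknown
# keys are rejected so typos cannot silently fall back to defaults.

.config_defaults <- function() {
  list(
    grid = list(nx = 500L, ny = 500L),
    h_bulk = 4.76,          # nm, bulk membrane thickness reference
    delta = 0.15,           # nm, thinning threshold for segmentation
    cutoff = 1.6,           # nm, proximity cutoff for local selections
    temperature = 320,      # K
    gamma = c(1, 3),        # pN, line-tension range
    wham = list(bins = 200L, tol = 1e-6, burn_in = 0L),
    bootstrap = list(n = 50L, seed = 1L),
    selections = list(phosphorus = "P", protein = "CA"),
    frames_per_block = 50L,
    min_cells = 4L,
    smooth_sigma = 0,
    perimeters = NULL,      # optional: list(isolated = c(...), associated = x)
    systems = NULL,         # optional: membrane-mode inputs
    manifest = NULL,        # optional: binding-mode window manifest CSV
    intervals = NULL        # optional: list(bound = c(..), reference = c(..))
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop("unknown config key: '", paste0(path, key), "'")
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]])))
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       paste0(path, key, "."))
    else
      defaults[[key]] <- user[[key]]
  }
  defaults
}

.validate_config <- function(cfg) {
  stopifnot(cfg$grid$nx >= 8, cfg$grid$ny >= 8,
            cfg$h_bulk > 0, cfg$delta > 0, cfg$cutoff > 0,
            cfg$temperature > 0,
            length(cfg$gamma) == 2L, cfg$gamma[1] > 0,
            cfg$gamma[1] <= cfg$gamma[2],
            cfg$wham$bins >= 10L, cfg$wham$tol > 0, cfg$wham$burn_in >= 0,
            cfg$bootstrap$n >= 2L, cfg$frames_per_block >= 1L)
  cfg
}

#' Build an analysis configuration
#'
#' @param ... Named overrides of the defaults (nested lists merged by key;
#'   unknown keys are an error).
#' @return A validated `mismatch_config` list.
#' @export
analysis_config <- function(...) {
  user <- list(...)
  cfg <- .validate_config(.merge_config(.config_defaults(), user))
  class(cfg) <- "mismatch_config"
  cfg
}

#' Read an analysis configuration from YAML
#' @param path YAML file path.
#' @return A validated `mismatch_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- .validate_config(.merge_config(.config_defaults(), user))
  class(cfg) <- "mismatch_config"
  cfg
}

#' @export
print.mismatch_config <- function(x, ...) {
  cat(sprintf(paste0("<mismatch_config: grid %dx%d, h_bulk %.2f nm, ",
                     "delta %.2f nm, T %g K, gamma %g-%g pN>\n"),
              x$grid$nx, x$grid$ny, x$h_bulk, x$delta, x$temperature,
              x$gamma[1], x$gamma[2]))
  invisible(x)
}
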