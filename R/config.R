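## Run configuration: one nested list holds every tunable of the pipeline
## and generator; YAML files are merged onto the defaults with unknown keys
## rejected and every numeric validated against its operation's
## preconditions at load time.

#' Default run configuration
#'
#' @return Nested list with components \code{spectral} (hue windows),
#'   \code{geometry} (tissue/span/vascular thresholds), \code{sampling}
#'   (transect count and edge margin), \code{binning}, \code{generator}
#'   (synthetic-section geometry, noise and treatment effects) and
#'   \code{stats} (alpha, LSD grouping scope).
#' @export
defaultRunConfig <- function() {
  win <- function(lo, hi) list(hue_low = lo, hue_high = hi,
                               sat_min = 0.2, val_min = 0.04)
  list(
    spectral = list(yellow = win(30, 90), red_a = win(330, 360),
                    red_b = win(0, 30), blue = win(190, 270)),
    geometry = list(bg_threshold = 0.02, min_span_px = 5L,
                    gap_tolerance_px = 2L, vascular_frac = 0.15,
                    dilate_cols = 3L),
    sampling = list(n_transects = 5L, edge_margin_frac = 0.03),
    binning = list(n_bins = 5L),
    generator = list(geometry = geometryDefaults(), noise = noiseDefaults(),
                     effects = gradientDefaults(), n_sections = 3L),
    stats = list(alpha = 0.05, lsd_grouping = "within_variety")
  )
}

mergeConfig <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop(sprintf("unknown config key(s): %s",
                 paste0(sub("^\\.", "", paste0(path, ".", extra)),
                        collapse = ", ")))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]))
      mergeConfig(defaults[[k]], user[[k]], paste0(path, ".", k))
    else user[[k]]
  }
  defaults
}

validateRunConfig <- function(cfg) {
  windowsFromConfig(cfg)  # errors BAD_WINDOW on malformed windows
  g <- cfg$geometry
  stopifnot(g$bg_threshold > 0, g$bg_threshold < 1,
            g$min_span_px >= 1, g$gap_tolerance_px >= 0,
            g$vascular_frac > 0, g$vascular_frac < 1, g$dilate_cols >= 0)
  s <- cfg$sampling
  stopifnot(s$n_transects >= 1, s$edge_margin_frac >= 0,
            s$edge_margin_frac < 0.2)
  stopifnot(cfg$binning$n_bins >= 1)
  stopifnot(cfg$stats$alpha > 0, cfg$stats$alpha < 1,
            cfg$stats$lsd_grouping %in% c("within_variety", "pooled"))
  stopifnot(cfg$generator$noise$fullWell >= 0,
            cfg$generator$noise$gaussianSd >= 0,
            cfg$generator$n_sections >= 1)
  invisible(cfg)
}

#' Read and validate a run configuration file
#'
#' Reads a YAML file, merges it onto \code{\link{defaultRunConfig}}
#' (unknown keys are rejected) and validates every field against its
#' operation's preconditions.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- mergeConfig(cfg, user)
  }
  validateRunConfig(cfg)
}

# HueWindow objects from the spectral config block.
windowsFromConfig <- function(cfg) {
  lapply(cfg$spectral, function(w)
    hueWindow(w$hue_low, w$hue_high, w$sat_min, w$val_min))
}
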