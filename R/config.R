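#' Analysis configuration
#'
#' Collects every numeric parameter of the pipeline in one validated object.
#' Defaults are the values used throughout the analysis: a 1.5 um fracture
#' threshold, dendritic-cell category boundaries at 1.5/3.5/5.0 um and
#' fibroblast boundaries at 1.5/3.0 um, a two-time-point cell-level fracture
#' criterion, 0.35 um intensity-ratio ROIs, a 5 um line profile normalized to
#' its first and last four samples, 50-bin (fine) or 2-bin (front/back)
#' polarity profiles with a 1.5 um exclusion disk around each centriole, and
#' nearest-neighbour linking with a 3-frame gap allowance.
#'
#' @param fracture_threshold micrometers; inter-centriole distance at or above
#'   which a frame counts as fractured.
#' @param dc_category_bounds strictly increasing micrometer boundaries of the
#'   dendritic-cell distance categories (close/near/short/long).
#' @param fibroblast_category_bounds boundaries of the fibroblast scheme
#'   (close/near/far).
#' @param min_fractured_timepoints number of (not necessarily consecutive)
#'   fractured frames required to call a cell fractured.
#' @param roi_radius micrometers; radius of the circular intensity-ratio ROIs.
#' @param profile_line_length micrometers; length of the intensity line profile.
#' @param profile_norm_tail samples averaged at each profile end for
#'   normalization.
#' @param polarity_bins number of back-to-front segments (50 fine, 2 coarse).
#' @param centriole_exclusion_radius micrometers; radius of the disk excluded
#'   around each centriole in the polarity analysis.
#' @param linker_max_distance micrometers; maximum frame-to-frame displacement
#'   accepted by the spot linker.
#' @param linker_gap_size frames; maximum detection gap bridged by the linker.
#' @param min_polarity_timepoints minimum usable time points per cell for the
#'   polarity profile.
#' @param rejoin_frames frames of sustained re-cohesion required to call a
#'   fractured cell repaired.
#' @param velocity_window frames in the sliding window of the separation
#'   velocity estimator.
#' @param search_radius pixels; half-width of the displacement search in the
#'   bulk velocimetry stage.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(fracture_threshold = 1.5,
                            dc_category_bounds = c(1.5, 3.5, 5.0),
                            fibroblast_category_bounds = c(1.5, 3.0),
                            min_fractured_timepoints = 2L,
                            roi_radius = 0.35,
                            profile_line_length = 5.0,
                            profile_norm_tail = 4L,
                            polarity_bins = 50L,
                            centriole_exclusion_radius = 1.5,
                            linker_max_distance = 25,
                            linker_gap_size = 3L,
                            min_polarity_timepoints = 6L,
                            rejoin_frames = 3L,
                            velocity_window = 3L,
                            search_radius = 25L) {
  cfg <- list(
    fracture_threshold = fracture_threshold,
    dc_category_bounds = dc_category_bounds,
    fibroblast_category_bounds = fibroblast_category_bounds,
    min_fractured_timepoints = as.integer(min_fractured_timepoints),
    roi_radius = roi_radius,
    profile_line_length = profile_line_length,
    profile_norm_tail = as.integer(profile_norm_tail),
    polarity_bins = as.integer(polarity_bins),
    centriole_exclusion_radius = centriole_exclusion_radius,
    linker_max_distance = linker_max_distance,
    linker_gap_size = as.integer(linker_gap_size),
    min_polarity_timepoints = as.integer(min_polarity_timepoints),
    rejoin_frames = as.integer(rejoin_frames),
    velocity_window = as.integer(velocity_window),
    search_radius = as.integer(search_radius)
  )
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  lens <- c("fracture_threshold", "roi_radius", "profile_line_length",
            "centriole_exclusion_radius", "linker_max_distance")
  for (nm in lens) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0) {
      stop("config field '", nm, "' must be a single positive length")
    }
  }
  for (nm in c("dc_category_bounds", "fibroblast_category_bounds")) {
    b <- cfg[[nm]]
    if (any(b <= 0) || any(diff(b) <= 0)) {
      stop("config field '", nm, "' must be strictly increasing positive bounds")
    }
  }
  if (cfg$min_fractured_timepoints < 1L) {
    stop("'min_fractured_timepoints' must be >= 1")
  }
  counts <- c("profile_norm_tail", "polarity_bins", "linker_gap_size",
              "min_polarity_timepoints", "rejoin_frames", "velocity_window",
              "search_radius")
  for (nm in counts) {
    if (cfg[[nm]] < 1L) stop("config field '", nm, "' must be >= 1")
  }
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Write an analysis configuration to YAML
#'
#' @param config an `analysis_config`.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
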