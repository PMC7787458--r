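#' Analysis configuration
#'
#' Bundles the tunable thresholds used by the motility and contact modules.
#' Defaults follow the conventions of intravital T cell imaging: cells moving
#' slower than 2 µm/min are counted as arrested, and contacts lasting more
#' than 20 minutes are counted as long-lived (stable-synapse) contacts.
#'
#' @param arrest_threshold instantaneous speed below which a step counts as
#'   arrested, µm/min. Default 2.
#' @param long_contact_min minimum duration (strictly exceeded) for a contact
#'   episode to count as a long contact, minutes. Default 20.
#' @param contact_radius centroid-to-centroid distance at or below which a
#'   T cell and a tumor cell are scored in contact, µm. Default 12,
#'   approximately the sum of typical lymphocyte and lymphoma cell radii;
#'   this is a declared surrogate for surface contact, which centroid data
#'   cannot measure.
#' @param contact_gap_tolerance number of non-contact frames that may
#'   interrupt a contact episode without splitting it. Default 1.
#' @param min_track_frames minimum number of positions a track needs to be
#'   eligible for motility metrics. Default 3.
#' @return an object of class `ivm_analysis_config` (a validated list).
#' @examples
#' analysis_config()
#' analysis_config(contact_radius = 10)
#' @export
analysis_config <- function(arrest_threshold = 2,
                            long_contact_min = 20,
                            contact_radius = 12,
                            contact_gap_tolerance = 1,
                            min_track_frames = 3) {
  cfg <- list(
    arrest_threshold = arrest_threshold,
    long_contact_min = long_contact_min,
    contact_radius = contact_radius,
    contact_gap_tolerance = contact_gap_tolerance,
    min_track_frames = min_track_frames
  )
  for (nm in c("arrest_threshold", "long_contact_min", "contact_radius")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_usage(sprintf("`%s` must be a single positive number.", nm))
    }
  }
  if (!is.numeric(cfg$contact_gap_tolerance) || cfg$contact_gap_tolerance < 0 ||
      cfg$contact_gap_tolerance != round(cfg$contact_gap_tolerance)) {
    stop_usage("`contact_gap_tolerance` must be a non-negative integer.")
  }
  if (!is.numeric(cfg$min_track_frames) || cfg$min_track_frames < 2 ||
      cfg$min_track_frames != round(cfg$min_track_frames)) {
    stop_usage("`min_track_frames` must be an integer >= 2.")
  }
  structure(cfg, class = "ivm_analysis_config")
}

#' @export
print.ivm_analysis_config <- function(x, ...) {
  cat("<ivm_analysis_config>\n")
  cat(sprintf("  arrest_threshold:      %g um/min\n", x$arrest_threshold))
  cat(sprintf("  long_contact_min:      %g min\n", x$long_contact_min))
  cat(sprintf("  contact_radius:        %g um\n", x$contact_radius))
  cat(sprintf("  contact_gap_tolerance: %d frames\n", as.integer(x$contact_gap_tolerance)))
  cat(sprintf("  min_track_frames:      %d\n", as.integer(x$min_track_frames)))
  invisible(x)
}
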