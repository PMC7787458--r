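#' Construct a movie of cell tracks
#'
#' A movie bundles the per-frame centroid positions of all tracked cells in
#' one imaging field with its acquisition metadata. Positions are stored in a
#' single tibble with columns `track_id`, `label`, `t` (seconds from movie
#' start), `x`, `y` and optionally `z` (micrometers). Either every position
#' has a `z` coordinate or none does: 2D and 3D tracks are never mixed
#' within a movie.
#'
#' Tracks interrupted by a gap longer than `3 * frame_interval` (a long
#' occlusion) are split into separate tracks with suffixed ids, so that a
#' missed cell re-appearing far away does not fabricate a straight
#' high-speed step.
#'
#' @param positions data frame with columns `track_id`, `label`, `t`, `x`,
#'   `y` and optionally `z`. `label` must be one of `t_cell_resident`,
#'   `t_cell_peripheral`, `tumor`.
#' @param movie_id opaque movie identifier.
#' @param group free-text group label (e.g. `"vehicle"`, `"CD20-TCB"`).
#' @param frame_interval nominal time between frames, seconds. Default 45,
#'   the standard sequential-stack interval for intravital two-photon
#'   acquisition of a 40 µm deep volume.
#' @param field_size_x,field_size_y imaged field dimensions, micrometers.
#' @param timepoint_h hours post treatment, or `NA` if not applicable.
#' @param bounds_margin how far (µm) positions may exceed the nominal field
#'   before a warning; cells touching the field edge routinely localize
#'   slightly outside it, so the default allows 3 standard deviations of a
#'   typical 0.3 µm localization noise.
#' @param split_gaps logical; split tracks at gaps longer than
#'   `3 * frame_interval` (default `TRUE`).
#' @return an object of class `ivm_movie`.
#' @examples
#' pos <- tibble::tibble(
#'   track_id = c("a", "a", "b", "b"),
#'   label = c("t_cell_resident", "t_cell_resident", "tumor", "tumor"),
#'   t = c(0, 45, 0, 45), x = c(0, 3, 30, 30), y = 0, z = 0
#' )
#' movie(pos, movie_id = "m1", group = "vehicle")
#' @export
movie <- function(positions, movie_id = "movie", group = "unspecified",
                  frame_interval = 45, field_size_x = 400, field_size_y = 400,
                  timepoint_h = NA_real_, bounds_margin = 0.9,
                  split_gaps = TRUE) {
  positions <- as_tibble(positions)
  needed <- c("track_id", "label", "t", "x", "y")
  missing_cols <- setdiff(needed, names(positions))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("positions table lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop_usage("`frame_interval` must be > 0 seconds.")
  }
  if (field_size_x <= 0 || field_size_y <= 0) {
    stop_usage("field sizes must be positive (micrometers).")
  }
  has_z <- "z" %in% names(positions)
  keep <- c(needed, if (has_z) "z")
  positions <- positions[keep]
  positions$track_id <- as.character(positions$track_id)
  positions$label <- as.character(positions$label)

  bad_label <- setdiff(unique(positions$label), CELL_LABELS)
  if (length(bad_label) > 0) {
    stop_data(sprintf("unknown cell class label(s): %s (expected %s)",
                      paste(bad_label, collapse = ", "),
                      paste(CELL_LABELS, collapse = ", ")))
  }
  if (nrow(positions) > 0) {
    if (any(!is.finite(positions$t))) stop_data("non-finite time values.")
    if (any(positions$t < 0)) stop_data("negative time values are not allowed.")
    coord_cols <- c("x", "y", if (has_z) "z")
    for (cc in coord_cols) {
      if (any(!is.finite(positions[[cc]]))) {
        stop_data(sprintf("non-finite values in coordinate `%s`.", cc))
      }
    }
    if (has_z && anyNA(positions$z)) {
      stop_data("`z` must be present for all positions or absent for the whole movie.")
    }
    dup <- duplicated(positions[c("track_id", "t")])
    if (any(dup)) {
      stop_data(sprintf("duplicate (track_id, t) pair(s), e.g. track %s at t = %g s.",
                        positions$track_id[dup][1], positions$t[dup][1]))
    }
    one_label <- tapply(positions$label, positions$track_id,
                        function(l) length(unique(l)))
    if (any(one_label > 1)) {
      stop_data("a track carries more than one cell class label.")
    }
    positions <- positions[order(positions$track_id, positions$t), ]
    out_x <- positions$x < -bounds_margin | positions$x > field_size_x + bounds_margin
    out_y <- positions$y < -bounds_margin | positions$y > field_size_y + bounds_margin
    if (any(out_x | out_y)) {
      warn(sprintf("%d position(s) fall more than %g um outside the nominal field.",
                   sum(out_x | out_y), bounds_margin))
    }
  }

  m <- structure(
    list(movie_id = as.character(movie_id), group = as.character(group),
         timepoint_h = as.numeric(timepoint_h),
         frame_interval = as.numeric(frame_interval),
         field_size_x = as.numeric(field_size_x),
         field_size_y = as.numeric(field_size_y),
         has_z = has_z, positions = positions),
    class = "ivm_movie"
  )
  if (split_gaps) m <- split_track_gaps(m) else m
}

#' Split tracks at long temporal gaps
#'
#' A gap longer than `max_gap` (default three frame intervals) between
#' consecutive positions of the same track splits the track into separate
#' tracks, suffixed `.1`, `.2`, ... Long occlusions should not be bridged by
#' a fabricated straight-line step.
#'
#' @param m an `ivm_movie`.
#' @param max_gap maximum bridgeable gap in seconds; default
#'   `3 * frame_interval`.
#' @return an `ivm_movie` with split tracks.
#' @export
split_track_gaps <- function(m, max_gap = 3 * m$frame_interval) {
  stopifnot(inherits(m, "ivm_movie"))
  p <- m$positions
  if (nrow(p) == 0) return(m)
  p <- p[order(p$track_id, p$t), ]
  new_id <- unlist(lapply(split(p$t, p$track_id), function(tt) {
    seg <- cumsum(c(0, diff(tt) > max_gap))
    if (max(seg) == 0) rep("", length(tt)) else paste0(".", seg + 1L)
  }), use.names = FALSE)
  # split() orders by factor level of track_id; p is sorted the same way
  p$track_id <- paste0(p$track_id, new_id)
  m$positions <- p
  m
}

#' @export
print.ivm_movie <- function(x, ...) {
  n_tracks <- length(unique(x$positions$track_id))
  cat(sprintf("<ivm_movie> %s [group: %s]\n", x$movie_id, x$group))
  cat(sprintf("  %d tracks, %d positions, %s\n", n_tracks, nrow(x$positions),
              if (x$has_z) "3D" else "2D"))
  cat(sprintf("  frame interval %g s, field %g x %g um\n",
              x$frame_interval, x$field_size_x, x$field_size_y))
  if (is.finite(x$timepoint_h)) cat(sprintf("  timepoint %g h\n", x$timepoint_h))
  invisible(x)
}

#' Extract per-track position tables from a movie
#'
#' @param m an `ivm_movie`.
#' @param labels cell class labels to keep (default all).
#' @return named list of tibbles (one per track), each time-ordered with
#'   columns `t`, `x`, `y`[, `z`] and attributes `label`.
#' @export
movie_tracks <- function(m, labels = CELL_LABELS) {
  stopifnot(inherits(m, "ivm_movie"))
  p <- m$positions[m$positions$label %in% labels, , drop = FALSE]
  if (nrow(p) == 0) return(structure(list(), names = character()))
  sp <- split(p, p$track_id)
  lapply(sp, function(d) {
    d <- d[order(d$t), ]
    tr <- d[setdiff(names(d), c("track_id", "label"))]
    attr(tr, "track_id") <- d$track_id[1]
    attr(tr, "label") <- d$label[1]
    tr
  })
}
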