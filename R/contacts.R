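#' Detect T cell-tumor contact episodes
#'
#' Scores, frame by frame, each T cell as "in contact" with the nearest
#' tumor centroid lying within `config$contact_radius` (ties broken by the
#' lexicographically lower tumor id, deterministically). Maximal runs of
#' in-contact frames with the same tumor partner, allowing interruptions of
#' at most `config$contact_gap_tolerance` frames, form contact episodes.
#' An episode observed in a single frame is credited one frame interval of
#' contact time.
#'
#' The centroid-distance criterion is a declared surrogate for surface
#' contact: rendered-surface overlap cannot be recovered from centroids, so
#' the radius (default 12 µm, roughly the sum of typical lymphocyte and
#' lymphoma cell radii) is configurable and its sensitivity should be
#' reported alongside results.
#'
#' Positions are mapped to the movie's frame grid by rounding `t /
#' frame_interval`; a position farther than a quarter frame interval from
#' the nearest grid point makes partner assignment ambiguous and raises a
#' data error.
#'
#' @param movie an [movie()] containing at least one T cell and one tumor
#'   track.
#' @param config an [analysis_config()].
#' @return tibble of episodes: `tcell_id`, `tumor_id`, `start` and `end`
#'   (seconds), `duration_min`, `n_frames` (in-contact frames).
#' @examples
#' pos <- tibble::tibble(
#'   track_id = rep(c("t1", "u1"), each = 5),
#'   label = rep(c("t_cell_resident", "tumor"), each = 5),
#'   t = rep(seq(0, 180, 45), 2),
#'   x = c(rep(0, 5), rep(10, 5)), y = 0, z = 0
#' )
#' detect_contacts(movie(pos))
#' @export
detect_contacts <- function(movie, config = analysis_config()) {
  stopifnot(inherits(movie, "ivm_movie"))
  p <- movie$positions
  if (!any(p$label == "tumor")) {
    stop_usage("movie contains no tumor tracks; contact detection needs both cell classes.")
  }
  if (!any(p$label %in% T_CELL_LABELS)) {
    stop_usage("movie contains no T cell tracks.")
  }
  dt <- movie$frame_interval
  frame <- round(p$t / dt)
  if (any(abs(p$t - frame * dt) > dt / 4)) {
    stop_data("positions are not aligned to the movie's frame grid (mismatched time grids).")
  }
  p$frame <- as.integer(frame)

  coord_cols <- c("x", "y", if (movie$has_z) "z")
  tum <- p[p$label == "tumor", , drop = FALSE]
  tc <- p[p$label %in% T_CELL_LABELS, , drop = FALSE]

  # per frame, nearest in-radius tumor partner of every T cell
  partner <- vector("list", length(unique(tc$frame)))
  tum_by_frame <- split(tum, tum$frame)
  tc_by_frame <- split(tc, tc$frame)
  rows <- list()
  for (f in names(tc_by_frame)) {
    a <- tc_by_frame[[f]]
    b <- tum_by_frame[[f]]
    if (is.null(b) || nrow(b) == 0) next
    am <- as.matrix(a[coord_cols])
    bm <- as.matrix(b[coord_cols])
    # squared distances, n_tcell x n_tumor
    d2 <- outer(rowSums(am^2), rowSums(bm^2), `+`) - 2 * am %*% t(bm)
    d2[d2 < 0] <- 0
    ord <- order(b$track_id)  # tie-break: lower tumor id wins
    d2 <- d2[, ord, drop = FALSE]
    ids <- b$track_id[ord]
    j <- apply(d2, 1L, which.min)
    dmin <- sqrt(d2[cbind(seq_len(nrow(a)), j)])
    hit <- dmin <= config$contact_radius
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- tibble(
        tcell_id = a$track_id[hit], tumor_id = ids[j[hit]],
        frame = a$frame[hit], t = a$t[hit]
      )
    }
  }
  empty <- tibble(tcell_id = character(), tumor_id = character(),
                  start = numeric(), end = numeric(),
                  duration_min = numeric(), n_frames = integer())
  if (length(rows) == 0) return(empty)
  hits <- dplyr::bind_rows(rows)
  hits <- hits[order(hits$tcell_id, hits$tumor_id, hits$frame), ]

  out <- lapply(split(hits, paste(hits$tcell_id, hits$tumor_id, sep = "\r")),
                function(h) {
    gap <- c(0L, diff(h$frame) - 1L)
    ep <- cumsum(gap > config$contact_gap_tolerance)
    dplyr::bind_rows(lapply(split(h, ep), function(e) {
      start <- e$t[1]
      end <- e$t[nrow(e)]
      if (end <= start) end <- start + movie$frame_interval
      tibble(tcell_id = e$tcell_id[1], tumor_id = e$tumor_id[1],
             start = start, end = end, duration_min = (end - start) / 60,
             n_frames = nrow(e))
    }))
  })
  ep <- dplyr::bind_rows(out)
  ep[order(ep$tcell_id, ep$start, ep$tumor_id), ]
}

#' Percentage of long-lived contacts
#'
#' Fraction (as a percentage) of contact episodes whose duration strictly
#' exceeds `config$long_contact_min` minutes (default 20 min, the usual
#' threshold for stable synapse-like engagement).
#'
#' @param episodes episode tibble from [detect_contacts()].
#' @param config an [analysis_config()].
#' @return percentage in \[0, 100\].
#' @export
percent_long_contacts <- function(episodes, config = analysis_config()) {
  if (is.null(episodes) || nrow(episodes) == 0) {
    stop_undefined("no contact episodes; long-contact percentage is undefined.")
  }
  100 * sum(episodes$duration_min > config$long_contact_min) / nrow(episodes)
}

#' Mean contact duration
#'
#' @param episodes episode tibble from [detect_contacts()].
#' @return arithmetic mean of episode durations, minutes.
#' @export
mean_contact_duration <- function(episodes) {
  if (is.null(episodes) || nrow(episodes) == 0) {
    stop_undefined("no contact episodes; mean contact duration is undefined.")
  }
  mean(episodes$duration_min)
}

#' Cell density in the imaged field
#'
#' Counts distinct tracks of one cell class present at the frame nearest
#' `at_time` and divides by the nominal field area in mm². The full nominal
#' field area is used (not a hull of observed cells), matching the
#' count-per-field convention of intravital quantification.
#'
#' @param movie an [movie()].
#' @param label cell class to count (`t_cell_peripheral` by default, the
#'   recruited-cell readout).
#' @param at_time time point in seconds; default: the movie's last frame.
#' @return a one-row tibble: `group`, `label`, `at_time`, `n_cells`,
#'   `area_mm2`, `density` (cells per mm²).
#' @examples
#' m <- simulate_tracks(preset_config("inflamed_ratio_1_10", seed = 2))$movie
#' cell_density(m)
#' @export
cell_density <- function(movie, label = "t_cell_peripheral", at_time = NULL) {
  stopifnot(inherits(movie, "ivm_movie"))
  if (!label %in% CELL_LABELS) {
    stop_usage(sprintf("unknown cell class label `%s`.", label))
  }
  p <- movie$positions
  if (nrow(p) == 0) {
    at_time <- at_time %||% 0
    frame_t <- at_time
  } else {
    at_time <- at_time %||% max(p$t)
    if (at_time < min(p$t) - movie$frame_interval / 2 ||
        at_time > max(p$t) + movie$frame_interval / 2) {
      stop_usage("`at_time` lies outside the movie's time span.")
    }
    grid <- sort(unique(round(p$t / movie$frame_interval)))
    frame_t <- grid[which.min(abs(grid * movie$frame_interval - at_time))] *
      movie$frame_interval
  }
  sel <- p$label == label &
    abs(p$t - frame_t) <= movie$frame_interval / 4
  n <- length(unique(p$track_id[sel]))
  area <- movie$field_size_x * movie$field_size_y / 1e6
  tibble(group = movie$group, label = label, at_time = frame_t,
         n_cells = n, area_mm2 = area, density = n / area)
}
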