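#' Per-track motility indices
#'
#' The five dynamic indices standard in intravital T cell imaging, computed
#' from a time-ordered table of centroid positions:
#'
#' * **instantaneous speeds** — Euclidean step length between consecutive
#'   frames divided by the true time gap, reported in µm/min. Missing frames
#'   are bridged by the actual time delta, never interpolated.
#' * **track speed** — total path length over total duration (the
#'   time-weighted mean of instantaneous speeds), µm/min.
#' * **track displacement** — straight-line distance from first to last
#'   position, µm.
#' * **meandering index** — displacement / path length, in \[0, 1\]:
#'   1 for perfectly directional motion, ~0.5 for a random walk, 0 for a
#'   cell that returns to its origin (fully engaged on a target).
#' * **arrest coefficient** — percentage of instantaneous speeds strictly
#'   below the arrest threshold (default 2 µm/min); high values indicate
#'   engaged, arrested cells.
#'
#' Positions are micrometers and time is seconds; speeds are converted to
#' µm/min exactly once, at reporting.
#'
#' @param track a data frame with numeric columns `t` (seconds), `x`, `y`
#'   and optionally `z` (micrometers), strictly increasing in `t`.
#' @param config an [analysis_config()].
#' @return `instantaneous_speeds()`: numeric vector of length
#'   `nrow(track) - 1`, µm/min. `track_speed()`, `track_displacement()`,
#'   `path_length()`, `meandering_index()`, `arrest_coefficient()`: a single
#'   number.
#' @examples
#' tr <- data.frame(t = c(0, 45, 90), x = c(0, 3, 6), y = 0, z = 0)
#' instantaneous_speeds(tr)  # 4, 4 um/min
#' track_speed(tr)           # 4
#' meandering_index(tr)      # 1
#' @name motility_indices
NULL

track_coords <- function(track) {
  if (!is.data.frame(track) || !all(c("t", "x", "y") %in% names(track))) {
    stop_usage("`track` must be a data frame with columns t, x, y[, z].")
  }
  has_z <- "z" %in% names(track) && !all(is.na(track$z))
  m <- as.matrix(track[, c("x", "y", if (has_z) "z")])
  tt <- as.numeric(track$t)
  if (is.unsorted(tt, strictly = TRUE)) {
    o <- order(tt)
    if (anyDuplicated(tt)) stop_data("track has duplicate time points.")
    m <- m[o, , drop = FALSE]
    tt <- tt[o]
  }
  list(t = tt, xyz = m)
}

step_lengths <- function(track) {
  tc <- track_coords(track)
  if (length(tc$t) < 2L) {
    stop_undefined("track has a single position; step metrics are undefined.")
  }
  d <- diff(tc$xyz)
  list(len = sqrt(rowSums(d^2)), dt = diff(tc$t))
}

#' @rdname motility_indices
#' @export
instantaneous_speeds <- function(track) {
  s <- step_lengths(track)
  60 * s$len / s$dt
}

#' @rdname motility_indices
#' @export
track_speed <- function(track) {
  s <- step_lengths(track)
  60 * sum(s$len) / sum(s$dt)
}

#' @rdname motility_indices
#' @export
track_displacement <- function(track) {
  tc <- track_coords(track)
  if (length(tc$t) < 2L) {
    stop_undefined("track has a single position; displacement is undefined.")
  }
  n <- nrow(tc$xyz)
  sqrt(sum((tc$xyz[n, ] - tc$xyz[1, ])^2))
}

#' @rdname motility_indices
#' @export
path_length <- function(track) {
  sum(step_lengths(track)$len)
}

#' @rdname motility_indices
#' @export
meandering_index <- function(track) {
  pl <- path_length(track)
  if (pl <= 0) {
    stop_undefined("track never moved (zero path length); meandering index is undefined.")
  }
  track_displacement(track) / pl
}

#' @rdname motility_indices
#' @export
arrest_coefficient <- function(track, config = analysis_config()) {
  v <- instantaneous_speeds(track)
  100 * sum(v < config$arrest_threshold) / length(v)
}

#' Compute all motility indices for one track
#'
#' @inheritParams motility_indices
#' @return one-row tibble with `n_frames`, `duration_min`, `speed`,
#'   `displacement`, `path_length`, `meandering_index`,
#'   `arrest_coefficient`. The meandering index of a track with zero path
#'   length is reported as `NA` (undefined), not 0.
#' @export
track_metrics <- function(track, config = analysis_config()) {
  tc <- track_coords(track)
  n <- length(tc$t)
  if (n < 2L) stop_undefined("track has a single position; metrics are undefined.")
  s <- step_lengths(track)
  pl <- sum(s$len)
  disp <- sqrt(sum((tc$xyz[n, ] - tc$xyz[1, ])^2))
  tibble(
    n_frames = n,
    duration_min = (tc$t[n] - tc$t[1]) / 60,
    speed = 60 * pl / sum(s$dt),
    displacement = disp,
    path_length = pl,
    meandering_index = if (pl > 0) disp / pl else NA_real_,
    arrest_coefficient = 100 * sum(60 * s$len / s$dt < config$arrest_threshold) / (n - 1)
  )
}

MOTILITY_METRICS <- c("speed", "displacement", "meandering_index",
                      "arrest_coefficient")
CONTACT_METRICS <- c("contact_duration", "percent_long_contacts")

#' Summarize motility and contact indices across movies
#'
#' Computes per-track indices for every eligible T cell track (tumor tracks
#' are excluded from motility indices; tracks shorter than
#' `config$min_track_frames` positions are excluded and counted), detects
#' T cell-tumor contact episodes in each movie that contains tumor tracks,
#' and aggregates Mean / SEM / N per movie and per group. Motility indices
#' aggregate over tracks; contact duration aggregates over episodes; the
#' long-contact percentage is a per-movie scalar.
#'
#' Group aggregates pool tracks (and episodes) across the group's movies.
#'
#' @param movies an `ivm_movie` or a list of them.
#' @param config an [analysis_config()].
#' @return an `ivm_metrics_table`: list with tibbles `tracks` (per-track
#'   indices joined to movie metadata), `movie_summary` and `group_summary`
#'   (`metric`, `mean`, `sem`, `n`), `episodes` (all contact episodes) and
#'   `excluded` (per movie: single-position and short tracks excluded).
#' @examples
#' m <- simulate_tracks(preset_config("vehicle_early", seed = 1))$movie
#' mt <- summarize_movies(m)
#' mt$group_summary
#' @export
summarize_movies <- function(movies, config = analysis_config()) {
  if (inherits(movies, "ivm_movie")) movies <- list(movies)
  if (length(movies) == 0) stop_usage("no movies supplied.")

  track_rows <- list()
  episode_rows <- list()
  movie_sum <- list()
  excluded <- list()

  for (m in movies) {
    stopifnot(inherits(m, "ivm_movie"))
    trs <- movie_tracks(m, labels = T_CELL_LABELS)
    n_frames <- vapply(trs, nrow, integer(1))
    eligible <- trs[n_frames >= config$min_track_frames]
    excluded[[length(excluded) + 1L]] <- tibble(
      movie_id = m$movie_id,
      n_single_position = sum(n_frames == 1L),
      n_below_min_frames = sum(n_frames < config$min_track_frames)
    )
    if (length(eligible) == 0) {
      stop_usage(sprintf("movie %s has no eligible T cell track (>= %d frames).",
                         m$movie_id, as.integer(config$min_track_frames)))
    }
    per_track <- dplyr::bind_rows(lapply(eligible, track_metrics, config = config))
    per_track <- dplyr::bind_cols(
      tibble(movie_id = m$movie_id, group = m$group, timepoint_h = m$timepoint_h,
             track_id = vapply(eligible, attr, "", which = "track_id"),
             label = vapply(eligible, attr, "", which = "label")),
      per_track
    )
    track_rows[[length(track_rows) + 1L]] <- per_track

    has_tumor <- any(m$positions$label == "tumor")
    eps <- NULL
    if (has_tumor) {
      eps <- detect_contacts(m, config)
      if (nrow(eps) > 0) {
        eps <- dplyr::bind_cols(tibble(movie_id = m$movie_id, group = m$group,
                                       timepoint_h = m$timepoint_h), eps)
        episode_rows[[length(episode_rows) + 1L]] <- eps
      }
    }

    ms <- lapply(MOTILITY_METRICS, function(nm) {
      v <- per_track[[nm]]
      v <- v[is.finite(v)]
      tibble(metric = nm, mean = mean(v), sem = sem(v), n = length(v))
    })
    if (!is.null(eps) && nrow(eps) > 0) {
      d <- eps$duration_min
      ms <- c(ms, list(
        tibble(metric = "contact_duration", mean = mean(d), sem = sem(d),
               n = length(d)),
        tibble(metric = "percent_long_contacts",
               mean = percent_long_contacts(eps, config), sem = NA_real_,
               n = length(d))
      ))
    }
    movie_sum[[length(movie_sum) + 1L]] <- dplyr::bind_cols(
      tibble(movie_id = m$movie_id, group = m$group, timepoint_h = m$timepoint_h),
      dplyr::bind_rows(ms)
    )
  }

  tracks <- dplyr::bind_rows(track_rows)
  episodes <- if (length(episode_rows)) dplyr::bind_rows(episode_rows) else
    tibble(movie_id = character(), group = character(), timepoint_h = numeric(),
           tcell_id = character(), tumor_id = character(), start = numeric(),
           end = numeric(), duration_min = numeric(), n_frames = integer())

  group_sum <- dplyr::bind_rows(lapply(split(tracks, tracks$group), function(g) {
    dplyr::bind_rows(lapply(MOTILITY_METRICS, function(nm) {
      v <- g[[nm]]
      v <- v[is.finite(v)]
      tibble(group = g$group[1], metric = nm, mean = mean(v), sem = sem(v),
             n = length(v))
    }))
  }))
  if (nrow(episodes) > 0) {
    ge <- dplyr::bind_rows(lapply(split(episodes, episodes$group), function(g) {
      tibble(group = g$group[1],
             metric = CONTACT_METRICS,
             mean = c(mean(g$duration_min),
                      100 * mean(g$duration_min > config$long_contact_min)),
             sem = c(sem(g$duration_min), NA_real_),
             n = nrow(g))
    }))
    group_sum <- dplyr::bind_rows(group_sum, ge)
  }

  structure(
    list(tracks = tracks,
         movie_summary = dplyr::bind_rows(movie_sum),
         group_summary = group_sum,
         episodes = episodes,
         excluded = dplyr::bind_rows(excluded),
         config = config),
    class = "ivm_metrics_table"
  )
}

#' @export
print.ivm_metrics_table <- function(x, ...) {
  cat(sprintf("<ivm_metrics_table> %d tracks, %d movies\n",
              nrow(x$tracks), length(unique(x$tracks$movie_id))))
  if (!is.null(x$group_summary) && nrow(x$group_summary) > 0) {
    cat("group summary (mean +/- SEM, n):\n")
    print(as.data.frame(x$group_summary), row.names = FALSE)
  }
  invisible(x)
}
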