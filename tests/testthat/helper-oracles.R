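# Independent reference implementations (naive per-step loops) and random
# input generators used by the property and oracle-equivalence tests.

naive_track_metrics <- function(track, arrest_threshold = 2) {
  has_z <- "z" %in% names(track)
  n <- nrow(track)
  path <- 0
  speeds <- numeric(n - 1)
  for (i in 2:n) {
    dx <- track$x[i] - track$x[i - 1]
    dy <- track$y[i] - track$y[i - 1]
    dz <- if (has_z) track$z[i] - track$z[i - 1] else 0
    len <- sqrt(dx^2 + dy^2 + dz^2)
    dt <- track$t[i] - track$t[i - 1]
    path <- path + len
    speeds[i - 1] <- 60 * len / dt
  }
  dx <- track$x[n] - track$x[1]
  dy <- track$y[n] - track$y[1]
  dz <- if (has_z) track$z[n] - track$z[1] else 0
  disp <- sqrt(dx^2 + dy^2 + dz^2)
  list(
    speeds = speeds,
    speed = 60 * path / (track$t[n] - track$t[1]),
    displacement = disp,
    path_length = path,
    meandering_index = if (path > 0) disp / path else NA_real_,
    arrest_coefficient = 100 * sum(speeds < arrest_threshold) / length(speeds)
  )
}

# frame-by-frame all-pairs contact detection, then episode assembly by
# explicit iteration; mirrors the documented contract, not the implementation
naive_contacts <- function(movie, config = analysis_config()) {
  p <- movie$positions
  p$frame <- as.integer(round(p$t / movie$frame_interval))
  coord <- c("x", "y", if (movie$has_z) "z")
  tcells <- unique(p$track_id[p$label %in% c("t_cell_resident", "t_cell_peripheral")])
  tumors <- sort(unique(p$track_id[p$label == "tumor"]))
  hits <- list()
  for (tc in tcells) {
    a <- p[p$track_id == tc, ]
    for (fi in seq_len(nrow(a))) {
      f <- a$frame[fi]
      best_id <- NA_character_
      best_d <- Inf
      for (tu in tumors) {
        b <- p[p$track_id == tu & p$frame == f, ]
        if (nrow(b) == 0) next
        d <- 0
        for (cc in coord) d <- d + (a[[cc]][fi] - b[[cc]][1])^2
        d <- sqrt(d)
        if (d < best_d) {  # strict <: first (lowest) id wins ties
          best_d <- d
          best_id <- tu
        }
      }
      if (!is.na(best_id) && best_d <= config$contact_radius) {
        hits[[length(hits) + 1L]] <- data.frame(
          tcell_id = tc, tumor_id = best_id, frame = f, t = a$t[fi],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(tcell_id = character(), tumor_id = character(),
                          start = numeric(), end = numeric(),
                          duration_min = numeric(), n_frames = integer()))
  }
  hits <- do.call(rbind, hits)
  out <- list()
  for (tc in unique(hits$tcell_id)) {
    for (tu in unique(hits$tumor_id[hits$tcell_id == tc])) {
      h <- hits[hits$tcell_id == tc & hits$tumor_id == tu, ]
      h <- h[order(h$frame), ]
      start_i <- 1
      for (i in seq_len(nrow(h))) {
        last <- i == nrow(h)
        if (!last && h$frame[i + 1] - h$frame[i] - 1 <= config$contact_gap_tolerance) next
        s <- h$t[start_i]
        e <- h$t[i]
        if (e <= s) e <- s + movie$frame_interval
        out[[length(out) + 1L]] <- data.frame(
          tcell_id = tc, tumor_id = tu, start = s, end = e,
          duration_min = (e - s) / 60, n_frames = i - start_i + 1L,
          stringsAsFactors = FALSE)
        start_i <- i + 1
      }
    }
  }
  ep <- tibble::as_tibble(do.call(rbind, out))
  ep[order(ep$tcell_id, ep$start, ep$tumor_id), ]
}

random_track <- function(n = sample(4:30, 1), dt_range = c(30, 90)) {
  t <- cumsum(c(0, runif(n - 1, dt_range[1], dt_range[2])))
  data.frame(t = t,
             x = cumsum(rnorm(n, sd = 3)),
             y = cumsum(rnorm(n, sd = 3)),
             z = cumsum(rnorm(n, sd = 1)))
}

random_movie <- function(n_tcells = 4, n_tumor = 3, n_frames = 25,
                         field = 150, drop_frac = 0.15) {
  dt <- 45
  rows <- list()
  mk_walk <- function(id, label, step_sd) {
    start <- runif(3, c(20, 20, 5), c(field - 20, field - 20, 35))
    xyz <- sweep(apply(matrix(rnorm(3 * n_frames, sd = step_sd), ncol = 3), 2, cumsum),
                 2, start, `+`)
    keep <- runif(n_frames) > drop_frac
    if (!any(keep)) keep[sample(n_frames, 1)] <- TRUE
    data.frame(track_id = id, label = label, t = (which(keep) - 1) * dt,
               x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_tcells)) {
    rows[[length(rows) + 1L]] <- mk_walk(sprintf("tc%02d", i), "t_cell_resident", 2.5)
  }
  for (i in seq_len(n_tumor)) {
    rows[[length(rows) + 1L]] <- mk_walk(sprintf("tu%02d", i), "tumor", 0.3)
  }
  suppressWarnings(
    movie(do.call(rbind, rows), movie_id = "rnd", group = "random",
          frame_interval = dt, field_size_x = field, field_size_y = field,
          bounds_margin = field)
  )
}

straight_track <- function(n_steps = 3, step = 3, dt = 45) {
  data.frame(t = (0:n_steps) * dt, x = (0:n_steps) * step, y = 0, z = 0)
}

square_loop_track <- function(side = 10, dt = 45) {
  data.frame(t = (0:4) * dt,
             x = c(0, side, side, 0, 0),
             y = c(0, 0, side, side, 0),
             z = 0)
}
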