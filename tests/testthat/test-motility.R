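test_that("instantaneous speeds use true time gaps and report um/min", {
  tr <- data.frame(t = c(0, 45), x = c(0, 3), y = 0, z = 0)
  expect_equal(instantaneous_speeds(tr), 4)  # 3 um / 45 s
  tr0 <- data.frame(t = c(0, 45), x = 0, y = 0, z = 0)
  expect_equal(instantaneous_speeds(tr0), 0)
  # missing frame: true gaps of 45 and 90 s, no interpolation
  tr_gap <- data.frame(t = c(0, 45, 135), x = c(0, 3, 9), y = 0, z = 0)
  expect_equal(instantaneous_speeds(tr_gap), c(4, 4))
  expect_error(instantaneous_speeds(data.frame(t = 0, x = 0, y = 0, z = 0)),
               class = "ivm_metric_undefined")
})

test_that("track speed is the time-weighted mean of step speeds", {
  expect_equal(track_speed(straight_track(10)), 4)
  # steps at 2 and 6 um/min on equal gaps average to 4
  tr <- data.frame(t = c(0, 45, 90), x = c(0, 1.5, 6), y = 0, z = 0)
  expect_equal(instantaneous_speeds(tr), c(2, 6))
  expect_equal(track_speed(tr), 4)
  # unequal gaps: time-weighted, not the mean of step speeds
  tr2 <- data.frame(t = c(0, 45, 180), x = c(0, 1.5, 10.5), y = 0, z = 0)
  expect_equal(track_speed(tr2), 60 * 10.5 / 180)
  expect_false(isTRUE(all.equal(track_speed(tr2),
                                mean(instantaneous_speeds(tr2)))))
})

test_that("displacement is first-to-last Euclidean distance", {
  tr <- data.frame(t = c(0, 45), x = c(0, 3), y = c(0, 4), z = 0)
  expect_equal(track_displacement(tr), 5)
  expect_equal(track_displacement(square_loop_track()), 0)
  expect_equal(track_displacement(straight_track(10)), 30)
})

test_that("meandering index spans [0, 1] with its defining anchors", {
  expect_equal(meandering_index(straight_track()), 1)
  expect_equal(meandering_index(square_loop_track()), 0)
  # two equal orthogonal steps
  tr <- data.frame(t = c(0, 45, 90), x = c(0, 3, 3), y = c(0, 0, 3), z = 0)
  expect_equal(meandering_index(tr), sqrt(2) / 2)
  never_moved <- data.frame(t = c(0, 45), x = 0, y = 0, z = 0)
  expect_error(meandering_index(never_moved), class = "ivm_metric_undefined")
  # reported as missing (NA), not zero, in the bulk computation
  expect_true(is.na(track_metrics(never_moved)$meandering_index))
})

test_that("arrest coefficient counts steps strictly below the threshold", {
  slow <- data.frame(t = (0:4) * 45, x = (0:4) * 0.75, y = 0, z = 0)  # 1 um/min
  expect_equal(arrest_coefficient(slow), 100)
  fast <- data.frame(t = (0:4) * 45, x = (0:4) * 3.75, y = 0, z = 0)  # 5 um/min
  expect_equal(arrest_coefficient(fast), 0)
  # 4 steps below, 4 above
  step <- c(rep(0.5, 4), rep(3, 4))
  mixed <- data.frame(t = (0:8) * 45, x = cumsum(c(0, step)), y = 0, z = 0)
  expect_equal(arrest_coefficient(mixed), 50)
  # boundary: exactly 2 um/min is NOT arrested (strict <)
  at_thr <- data.frame(t = (0:2) * 45, x = (0:2) * 1.5, y = 0, z = 0)
  expect_equal(instantaneous_speeds(at_thr), c(2, 2))
  expect_equal(arrest_coefficient(at_thr), 0)
})

test_that("production metrics match the naive per-step oracle to 1e-9", {
  set.seed(101)
  for (i in 1:200) {
    tr <- random_track()
    ref <- naive_track_metrics(tr)
    expect_equal(instantaneous_speeds(tr), ref$speeds, tolerance = 1e-9)
    got <- track_metrics(tr)
    expect_equal(got$speed, ref$speed, tolerance = 1e-9)
    expect_equal(got$displacement, ref$displacement, tolerance = 1e-9)
    expect_equal(got$path_length, ref$path_length, tolerance = 1e-9)
    expect_equal(got$meandering_index, ref$meandering_index, tolerance = 1e-9)
    expect_equal(got$arrest_coefficient, ref$arrest_coefficient, tolerance = 1e-9)
  }
})

test_that("metrics obey geometric invariances", {
  set.seed(7)
  rot <- function(theta) matrix(c(cos(theta), sin(theta), 0,
                                  -sin(theta), cos(theta), 0,
                                  0, 0, 1), 3, 3)
  for (i in 1:25) {
    tr <- random_track()
    m0 <- track_metrics(tr)
    expect_lte(m0$displacement, m0$path_length + 1e-12)
    expect_true(m0$meandering_index >= 0 && m0$meandering_index <= 1)
    expect_true(m0$arrest_coefficient >= 0 && m0$arrest_coefficient <= 100)
    # rigid translation + rotation about z
    xyz <- as.matrix(tr[, c("x", "y", "z")]) %*% rot(runif(1, 0, 2 * pi))
    tr2 <- data.frame(t = tr$t, x = xyz[, 1] + 13, y = xyz[, 2] - 5, z = xyz[, 3] + 2)
    expect_equal(track_metrics(tr2), m0, tolerance = 1e-9)
    # time reversal preserves displacement, path length, MI
    tr3 <- data.frame(t = max(tr$t) - rev(tr$t),
                      x = rev(tr$x), y = rev(tr$y), z = rev(tr$z))
    m3 <- track_metrics(tr3)
    expect_equal(m3$displacement, m0$displacement, tolerance = 1e-9)
    expect_equal(m3$path_length, m0$path_length, tolerance = 1e-9)
    expect_equal(m3$meandering_index, m0$meandering_index, tolerance = 1e-9)
  }
})

test_that("downsampling behaves as geometry dictates", {
  # straight constant-speed track: dropping every other frame changes nothing
  tr <- straight_track(n_steps = 10)
  half <- tr[seq(1, 11, by = 2), ]
  expect_equal(track_speed(half), track_speed(tr))
  expect_equal(meandering_index(half), meandering_index(tr))
  # random walks: downsampling can only shorten the measured path
  set.seed(11)
  for (i in 1:20) {
    tr <- random_track(n = 21)
    half <- tr[seq(1, 21, by = 2), ]
    expect_lte(path_length(half), path_length(tr) + 1e-12)
  }
})

test_that("summarize_movies aggregates per movie and group with SEM and N", {
  pos <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(track_id = paste0("t", i), label = "t_cell_resident",
               t = (0:3) * 45, x = (0:3) * 3 + i, y = i, z = 0)
  }))
  m <- movie(pos, movie_id = "m1", group = "g", field_size_x = 50,
             field_size_y = 50)
  mt <- summarize_movies(m)
  gs <- mt$group_summary
  mi <- gs[gs$metric == "meandering_index", ]
  expect_equal(mi$mean, 1)
  expect_equal(mi$sem, 0)
  expect_equal(mi$n, 3)
  expect_setequal(unique(mt$movie_summary$metric),
                  c("speed", "displacement", "meandering_index",
                    "arrest_coefficient"))
  # tumor tracks are excluded from motility metrics; short tracks counted
  pos2 <- rbind(pos,
                data.frame(track_id = "u", label = "tumor", t = (0:3) * 45,
                           x = 5, y = 2, z = 0),
                data.frame(track_id = "short", label = "t_cell_resident",
                           t = c(0, 45), x = c(0, 1), y = 0, z = 0))
  m2 <- movie(pos2, movie_id = "m2", group = "g", field_size_x = 50,
              field_size_y = 50)
  mt2 <- summarize_movies(m2)
  expect_false("u" %in% mt2$tracks$track_id)
  expect_false("short" %in% mt2$tracks$track_id)
  expect_equal(mt2$excluded$n_below_min_frames, 1)
  # contact indices appear once tumor tracks exist
  expect_true(all(c("contact_duration", "percent_long_contacts") %in%
                    mt2$movie_summary$metric))
})

test_that("summarize_movies recovers programmed two-group speeds", {
  mk <- function(speed, group, seed) {
    cfg <- simulation_config(n_tcells = 15, n_tumor = 0, n_frames = 40,
                             free_speed_mean = speed, free_speed_sd = 0,
                             p_engage = 0, noise_sd = 0, seed = seed)
    m <- suppressWarnings(simulate_tracks(cfg)$movie)
    m$group <- group
    m
  }
  mt <- summarize_movies(list(mk(6, "fast", 1), mk(2.4, "slow", 2)))
  gs <- mt$group_summary
  expect_equal(gs$mean[gs$group == "fast" & gs$metric == "speed"], 6,
               tolerance = 1e-8)
  expect_equal(gs$mean[gs$group == "slow" & gs$metric == "speed"], 2.4,
               tolerance = 1e-8)
  expect_error(
    summarize_movies(movie(data.frame(track_id = "a", label = "t_cell_resident",
                                      t = 0, x = 1, y = 1, z = 0),
                           field_size_x = 10, field_size_y = 10)),
    class = "ivm_usage_error")
})
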