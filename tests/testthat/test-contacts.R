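two_cell_movie <- function(d, n_frames = 30, dt = 45) {
  pos <- rbind(
    data.frame(track_id = "t1", label = "t_cell_resident",
               t = (0:(n_frames - 1)) * dt, x = 0, y = 0, z = 0),
    data.frame(track_id = "u1", label = "tumor",
               t = (0:(n_frames - 1)) * dt, x = d, y = 0, z = 0)
  )
  movie(pos, frame_interval = dt, field_size_x = 100, field_size_y = 100)
}

test_that("contact episodes follow the radius criterion", {
  ep <- detect_contacts(two_cell_movie(10))  # 10 um apart, radius 12
  expect_equal(nrow(ep), 1)
  expect_equal(ep$n_frames, 30L)
  expect_equal(ep$duration_min, 29 * 45 / 60)
  # same geometry, radius 8: no contact
  ep8 <- detect_contacts(two_cell_movie(10), analysis_config(contact_radius = 8))
  expect_equal(nrow(ep8), 0)
  # a single-frame contact is credited one frame interval
  pos <- rbind(
    data.frame(track_id = "t1", label = "t_cell_resident", t = (0:4) * 45,
               x = c(50, 50, 5, 50, 50), y = 0, z = 0),
    data.frame(track_id = "u1", label = "tumor", t = (0:4) * 45,
               x = 0, y = 0, z = 0)
  )
  m <- movie(pos, field_size_x = 100, field_size_y = 100, split_gaps = FALSE)
  ep1 <- detect_contacts(m, analysis_config(contact_gap_tolerance = 0))
  expect_equal(nrow(ep1), 1)
  expect_equal(ep1$duration_min, 45 / 60)
  expect_equal(ep1$end - ep1$start, 45)
})

test_that("gap tolerance merges interrupted episodes", {
  # in contact at frames 1-10 and 12-20 (frame 11 away)
  xs <- c(rep(5, 10), 50, rep(5, 9))
  pos <- rbind(
    data.frame(track_id = "t1", label = "t_cell_resident", t = (0:19) * 45,
               x = xs, y = 0, z = 0),
    data.frame(track_id = "u1", label = "tumor", t = (0:19) * 45,
               x = 0, y = 0, z = 0)
  )
  m <- movie(pos, field_size_x = 100, field_size_y = 100)
  ep1 <- detect_contacts(m, analysis_config(contact_gap_tolerance = 1))
  expect_equal(nrow(ep1), 1)
  expect_equal(ep1$n_frames, 19L)
  ep0 <- detect_contacts(m, analysis_config(contact_gap_tolerance = 0))
  expect_equal(nrow(ep0), 2)
})

test_that("partner assignment is nearest-tumor with deterministic ties", {
  pos <- rbind(
    data.frame(track_id = "t1", label = "t_cell_resident", t = c(0, 45),
               x = 0, y = 0, z = 0),
    data.frame(track_id = "u2", label = "tumor", t = c(0, 45), x = 5, y = 0, z = 0),
    data.frame(track_id = "u1", label = "tumor", t = c(0, 45), x = -5, y = 0, z = 0),
    data.frame(track_id = "u3", label = "tumor", t = c(0, 45), x = 8, y = 0, z = 0)
  )
  m <- movie(pos, field_size_x = 30, field_size_y = 30, bounds_margin = 30)
  ep <- detect_contacts(m)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$tumor_id, "u1")  # tie between u1/u2 broken by lower id
})

test_that("contact detection needs both cell classes and an aligned grid", {
  no_tumor <- movie(data.frame(track_id = "t1", label = "t_cell_resident",
                               t = c(0, 45), x = 0, y = 0, z = 0),
                    field_size_x = 10, field_size_y = 10)
  expect_error(detect_contacts(no_tumor), class = "ivm_usage_error")
  off_grid <- movie(rbind(
    data.frame(track_id = "t1", label = "t_cell_resident", t = c(0, 45),
               x = 0, y = 0, z = 0),
    data.frame(track_id = "u1", label = "tumor", t = c(20, 65),
               x = 5, y = 0, z = 0)),
    field_size_x = 10, field_size_y = 10)
  expect_error(detect_contacts(off_grid), class = "ivm_data_error")
})

test_that("long-contact percentage uses a strict 20-minute cutoff", {
  ep <- tibble::tibble(duration_min = c(25, 25, 5, 5))
  expect_equal(percent_long_contacts(ep), 50)
  expect_equal(percent_long_contacts(tibble::tibble(duration_min = rep(21, 3))), 100)
  expect_equal(percent_long_contacts(tibble::tibble(duration_min = 20)), 0)
  expect_error(percent_long_contacts(tibble::tibble(duration_min = numeric())),
               class = "ivm_metric_undefined")
})

test_that("mean contact duration matches brute-force averaging", {
  expect_equal(mean_contact_duration(tibble::tibble(duration_min = c(3, 5))), 4)
  expect_equal(mean_contact_duration(tibble::tibble(duration_min = 7.74)), 7.74)
  set.seed(5)
  d <- runif(500, 0.5, 40)
  acc <- 0
  for (v in d) acc <- acc + v
  expect_equal(mean_contact_duration(tibble::tibble(duration_min = d)),
               acc / 500, tolerance = 1e-9)
  expect_error(mean_contact_duration(NULL), class = "ivm_metric_undefined")
})

test_that("episode invariants hold on random movies", {
  set.seed(21)
  cfg <- analysis_config()
  for (i in 1:20) {
    m <- random_movie()
    ep <- detect_contacts(m, cfg)
    if (nrow(ep) == 0) next
    expect_true(all(ep$end > ep$start))
    expect_equal(ep$duration_min, (ep$end - ep$start) / 60)
    # episodes of a (tcell, tumor) pair are disjoint and well separated
    for (key in unique(paste(ep$tcell_id, ep$tumor_id))) {
      e <- ep[paste(ep$tcell_id, ep$tumor_id) == key, ]
      if (nrow(e) < 2) next
      e <- e[order(e$start), ]
      gaps <- (e$start[-1] - e$end[-nrow(e)]) / m$frame_interval
      expect_true(all(gaps > cfg$contact_gap_tolerance))
    }
    # a cell's total contact time cannot exceed its track span + one frame
    for (tc in unique(ep$tcell_id)) {
      tt <- m$positions$t[m$positions$track_id == tc]
      span_min <- (max(tt) - min(tt) + m$frame_interval) / 60
      expect_lte(sum(ep$duration_min[ep$tcell_id == tc]), span_min + 1e-9)
    }
  }
})

test_that("widening the contact radius never loses in-contact frames", {
  set.seed(31)
  for (i in 1:10) {
    m <- random_movie()
    n_frames_at <- function(r) {
      ep <- detect_contacts(m, analysis_config(contact_radius = r))
      if (nrow(ep) == 0) 0L else sum(ep$n_frames)
    }
    counts <- vapply(c(6, 10, 14, 20), n_frames_at, integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("episode detection is stable under tumor id relabeling", {
  set.seed(41)
  m <- random_movie(n_tcells = 3, n_tumor = 3)
  p <- m$positions
  # swap tumor ids consistently (tu01 <-> tu03)
  relab <- c(tu01 = "tu03", tu03 = "tu01")
  hit <- p$track_id %in% names(relab)
  p$track_id[hit] <- relab[p$track_id[hit]]
  m2 <- suppressWarnings(movie(p, frame_interval = m$frame_interval,
                               field_size_x = m$field_size_x,
                               field_size_y = m$field_size_y,
                               bounds_margin = m$field_size_x))
  ep1 <- detect_contacts(m)
  ep2 <- detect_contacts(m2)
  ep1$tumor_id[ep1$tumor_id %in% names(relab)] <- relab[ep1$tumor_id[ep1$tumor_id %in% names(relab)]]
  o <- function(e) e[order(e$tcell_id, e$start, e$tumor_id), ]
  expect_equal(o(ep1)[c("tcell_id", "start", "end", "n_frames")],
               o(ep2)[c("tcell_id", "start", "end", "n_frames")])
})

test_that("cell density divides a frame count by the nominal field area", {
  pos <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(track_id = paste0("p", i), label = "t_cell_peripheral",
               t = c(0, 45), x = 100 * i, y = 100, z = 0)
  }))
  # 3 cells in a 707.1 x 707.1 um = 0.5 mm2 field -> 6 / mm2
  m <- movie(pos, field_size_x = sqrt(0.5) * 1000, field_size_y = sqrt(0.5) * 1000)
  d <- cell_density(m, "t_cell_peripheral", at_time = 45)
  expect_equal(d$density, 6, tolerance = 1e-9)
  expect_equal(d$n_cells, 3)
  # no cells of the class -> zero density
  expect_equal(cell_density(m, "tumor", at_time = 0)$density, 0)
  # doubling the field area halves the density
  m2 <- movie(pos, field_size_x = 1000, field_size_y = 1000)
  expect_equal(cell_density(m2, "t_cell_peripheral", at_time = 45)$density,
               3, tolerance = 1e-9)
  expect_error(cell_density(m, "stroma"), class = "ivm_usage_error")
  expect_error(cell_density(m, "tumor", at_time = 1e5), class = "ivm_usage_error")
})
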