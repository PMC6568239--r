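test_that("local minima require the depth threshold", {
  expect_equal(find_local_minima(c(5, 5, 3, 5, 5), 1), 3)
  expect_equal(find_local_minima(c(5, 5, 5, 5), 1), integer(0))
  expect_equal(find_local_minima(c(5, 4.5, 5), 1), integer(0)) # depth 0.5
  expect_equal(find_local_minima(c(5, 4.5, 5), 0.5), 2)
  expect_equal(find_local_minima(c(5, 3), 1), integer(0)) # too short
  # plateau minimum returns the whole plateau
  expect_equal(find_local_minima(c(5, 2, 2, 2, 5), 1), 2:4)
  # shallow internal bump does not split a deep valley
  expect_equal(find_local_minima(c(8, 8, 3, 3.5, 3, 8, 8), 1), c(3, 5))
})

test_that("similar-diameter extension reproduces the worked example", {
  p <- c(8, 8, 3, 3.5, 3, 8, 8)
  m <- find_local_minima(p, 1)
  expect_equal(extend_minima(p, m, 1), 3:5) # "three defined as contractions"
  expect_equal(extend_minima(c(8, 3, 8), 2, 1), 2)
  # zero tolerance joins only exact equals
  expect_equal(extend_minima(c(8, 3, 3.4, 3, 8), c(2, 4), 0), c(2, 4))
  expect_equal(extend_minima(c(8, 3, 3, 8), 2, 0), 2:3)
})

test_that("amplitude is the lower-flank delta, shared across the run", {
  expect_equal(cell_amplitude(c(8, 8, 3, 8, 8), 3, depth_threshold = 1), 5)
  expect_equal(cell_amplitude(c(6, 3, 8), 2, depth_threshold = 1), 3) # min(6, 8) - 3
  p <- c(8, 8, 3, 3.5, 3, 8, 8)
  expect_equal(cell_amplitude(p, 3, depth_threshold = 1, similarity_tol = 1), 5)
  expect_equal(cell_amplitude(p, 4, depth_threshold = 1, similarity_tol = 1), 5)
  expect_error(cell_amplitude(c(5, 5, 5), 2, depth_threshold = 1), "not part")
})

test_that("cell matrices fill amplitudes frame by frame", {
  # constant matrix: no contraction anywhere
  dm <- diameter_matrix(matrix(3, 10, 5), dx_mm = 0.5, dt_s = 1)
  expect_equal(sum(!is.na(build_cell_matrix(dm)$amplitude)), 0)

  # single-frame notch: cells only in that frame
  vals <- matrix(3, 10, 5)
  vals[5, 3] <- 2
  cm <- build_cell_matrix(diameter_matrix(vals, dx_mm = 0.5, dt_s = 1),
                          depth_threshold = 0.5)
  hit <- which(!is.na(cm$amplitude), arr.ind = TRUE)
  expect_equal(unname(hit), matrix(c(5L, 3L), 1))
  expect_equal(cm$amplitude[5, 3], 1)

  # missing stretches split the profile, never crash
  vals[c(1, 6), ] <- NA
  expect_silent(build_cell_matrix(diameter_matrix(vals, dx_mm = 0.5, dt_s = 1)))
})

test_that("detection is invariant under a constant diameter shift", {
  sim <- simulate_diameter_matrix(
    simulation_spec(length_mm = 30, n_frames = 60),
    ground_truth_event("ripple", onset_time_s = 5, duration_s = 30,
                       initiation_site_mm = 8, velocity_mm_per_s = 0.3,
                       amplitude_frac = 0.3)
  )
  cm1 <- build_cell_matrix(sim$dm)
  dm2 <- sim$dm
  dm2$values <- dm2$values + 1.7
  cm2 <- build_cell_matrix(dm2)
  expect_identical(is.na(cm1$amplitude), is.na(cm2$amplitude))
  expect_equal(cm1$amplitude[!is.na(cm1$amplitude)],
               cm2$amplitude[!is.na(cm2$amplitude)])
})

test_that("connected components follow the connectivity contract", {
  amp <- matrix(NA_real_, 10, 10)
  amp[2:3, 2:3] <- 1
  amp[7:8, 7:8] <- 1
  cm <- structure(list(amplitude = amp, dx_mm = 0.5, dt_s = 1,
                       total_length_mm = 5, depth_threshold = 0.1,
                       similarity_tol = 0.1), class = "contraction_cells")
  expect_equal(max(label_events(cm)$event_id), 2)

  diagonal <- matrix(NA_real_, 6, 6)
  diag(diagonal) <- 1
  cmd <- structure(list(amplitude = diagonal, dx_mm = 0.5, dt_s = 1,
                        total_length_mm = 3, depth_threshold = 0.1,
                        similarity_tol = 0.1), class = "contraction_cells")
  expect_equal(max(label_events(cmd, connectivity = 8)$event_id), 1)
  expect_equal(max(label_events(cmd, connectivity = 4)$event_id), 6)
})

test_that("labeling agrees with a flood-fill oracle and partitions cells", {
  set.seed(77)
  for (k in 1:60) {
    nr <- sample(3:20, 1)
    nc <- sample(3:20, 1)
    mask <- matrix(runif(nr * nc) < 0.35, nr, nc)
    amp <- ifelse(mask, 1, NA_real_)
    cm <- structure(list(amplitude = amp, dx_mm = 0.5, dt_s = 1,
                         total_length_mm = nr * 0.5, depth_threshold = 0.1,
                         similarity_tol = 0.1), class = "contraction_cells")
    conn <- sample(c(4, 8), 1)
    cells <- label_events(cm, connectivity = conn)
    oracle <- flood_fill_components(mask, conn)
    expect_equal(length(unique(cells$event_id)), oracle$n)
    # partition: each foreground cell appears exactly once
    expect_equal(nrow(cells), sum(mask))
    expect_equal(nrow(dplyr::distinct(cells, pos_idx, frame_idx)), sum(mask))
    # cells in one event share one oracle label and vice versa
    key <- oracle$labels[cbind(cells$pos_idx, cells$frame_idx)]
    expect_equal(length(unique(paste(key, cells$event_id))), oracle$n)
  }
})

test_that("the amplitude floor drops only sub-threshold events", {
  events <- tibble::tibble(
    event_id = 1:3,
    amplitude_pct = c(4.9, 5.0, 60),
    duration_s = c(5, 5, 0.4)
  )
  kept <- filter_events(events)
  expect_equal(kept$event_id, 2:3)
  expect_equal(filter_events(events, min_amplitude_frac = 0), events,
               ignore_attr = TRUE)
  expect_equal(filter_events(events, min_amplitude_frac = 0,
                             min_duration_s = 1)$event_id, 1:2)
})
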