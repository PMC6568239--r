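test_that("event features follow the defining formulas", {
  cells <- tibble::tibble(event_id = 1L, pos_mm = c(10, 10.5, 11),
                          time_s = c(0, 1, 2), amplitude_mm = 0.5)
  ev <- st_classify(cells, total_length_mm = 50)
  expect_equal(ev$initiation_site_mm, 10)
  expect_equal(ev$initiation_site_frac, 20)
  expect_equal(ev$distance_mm, 1)
  expect_equal(ev$distance_frac, 2)
  expect_equal(ev$duration_s, 2)
  expect_equal(ev$slope_mm_per_s, 0.5)
  expect_equal(ev$r2, 1)
  expect_equal(ev$velocity_mm_per_s, 0.5)
  expect_equal(ev$direction, "anterograde")

  mirror <- dplyr::mutate(cells, pos_mm = rev(pos_mm))
  evm <- st_classify(mirror, total_length_mm = 50)
  expect_equal(evm$slope_mm_per_s, -0.5)
  expect_equal(evm$direction, "retrograde")
})

test_that("initiation-site tie at the first frame picks the oral-most cell", {
  cells <- tibble::tibble(event_id = 1L,
                          pos_mm = c(12, 11, 13), time_s = c(0, 0, 1),
                          amplitude_mm = 1)
  ev <- st_classify(cells, total_length_mm = 50)
  expect_equal(ev$initiation_site_mm, 11)
})

test_that("single-cell and single-frame events have undefined regression", {
  one <- tibble::tibble(event_id = 1L, pos_mm = 5, time_s = 3, amplitude_mm = 1)
  ev <- st_classify(one, total_length_mm = 50)
  expect_equal(ev$distance_mm, 0)
  expect_equal(ev$duration_s, 0)
  expect_true(is.na(ev$r2))
  expect_true(is.na(ev$velocity_mm_per_s))
  expect_equal(ev$direction, "none")
  expect_equal(ev$type, "standing")

  # multi-cell single-frame event: spatial extent without time spread
  run <- tibble::tibble(event_id = 1L, pos_mm = c(5, 5.5, 6), time_s = 1,
                        amplitude_mm = 1)
  evr <- st_classify(run, total_length_mm = 50)
  expect_equal(evr$distance_mm, 1)
  expect_true(is.na(evr$r2))
  expect_equal(evr$type, "standing")
})

test_that("slope and r2 match the closed-form least-squares oracle", {
  set.seed(21)
  for (k in 1:50) {
    n <- sample(3:12, 1)
    cells <- tibble::tibble(
      event_id = 1L,
      pos_mm = runif(n, 0, 30),
      time_s = sample(seq(0, 20, by = 0.5), n),
      amplitude_mm = runif(n, 0.1, 1)
    )
    ev <- st_classify(cells, total_length_mm = 60)
    oracle <- ols_oracle(cells$time_s, cells$pos_mm)
    expect_equal(ev$slope_mm_per_s, oracle$slope, tolerance = 1e-9)
    expect_equal(ev$r2, oracle$r2, tolerance = 1e-9)
  }
})

test_that("the standing / ripple / slow rules apply in order", {
  expect_equal(classify_event(0.8, 0.99), "standing")
  expect_equal(classify_event(1.0, 0.99), "standing") # bound inclusive
  expect_equal(classify_event(2.0, 0.95), "ripple")
  expect_equal(classify_event(2.0, 0.80), "ripple") # bound inclusive
  expect_equal(classify_event(2.0, 0.50), "slow")
  expect_equal(classify_event(2.0, 0.799), "slow")
  expect_equal(classify_event(2.0, NA), "slow") # undefined r2 fallback
  expect_equal(classify_event(0.5, NA), "standing") # r2 irrelevant
})

test_that("segments are assigned by cumulative boundaries, right-inclusive", {
  sch <- segment_scheme()
  expect_equal(sch$boundary, c(0.39, 0.62, 0.85, 1.0))
  expect_equal(assign_segment(20, sch), 1L)
  expect_equal(assign_segment(50, sch), 2L)
  expect_equal(assign_segment(39, sch), 1L) # boundary belongs oral-side
  expect_equal(assign_segment(39.01, sch), 2L)
  expect_equal(assign_segment(0, sch), 1L)
  expect_equal(assign_segment(100, sch), 4L)
  expect_equal(assign_segment(c(10, 70, 90), sch), c(1L, 3L, 4L))
  expect_error(assign_segment(101, sch), "0, 100")
  expect_error(segment_scheme(c(0.5, 0.4)), "sum to 1")
})

test_that("summaries count cpm per segment and direction proportions", {
  # 12 standing events initiating in segment 2 of a 20-mm-long segment
  sch <- segment_scheme(c(0.2, 0.4, 0.4))
  events <- tibble::tibble(
    event_id = 1:22,
    initiation_time_s = rep(10, 22),
    initiation_site_frac = c(rep(30, 12), rep(70, 10)),
    type = c(rep("standing", 12), rep("ripple", 6), rep("slow", 4)),
    direction = c(rep("none", 12), rep("anterograde", 6), rep("retrograde", 4)),
    amplitude_pct = 20, distance_frac = 2, duration_s = 5,
    velocity_mm_per_s = c(rep(NA, 12), rep(0.3, 10))
  )
  s <- summarize_motility(events, sch, window = c(0, 600), total_length_mm = 50)
  freq <- s$frequency
  expect_equal(freq$cpm[freq$segment == 2 & freq$type == "standing"],
               12 / (10 * 20))
  # conservation: counts reconstruct from cpm
  total <- sum(freq$cpm * freq$segment_length_mm * 10)
  expect_equal(total, 22)
  dir <- s$direction
  ripple_ante <- dir$proportion[dir$type == "ripple" &
                                  dir$direction == "anterograde"]
  expect_equal(ripple_ante, 1)

  none <- summarize_motility(events[0, ], sch, window = c(0, 600),
                             total_length_mm = 50)
  expect_true(all(none$frequency$cpm == 0))
  expect_true(all(is.na(none$direction$proportion)))
  expect_error(summarize_motility(events, sch, window = c(10, 10),
                                  total_length_mm = 50), "positive")
})

test_that("anterograde/retrograde proportions split 60/40", {
  events <- tibble::tibble(
    event_id = 1:10, initiation_time_s = 5, initiation_site_frac = 50,
    type = "ripple",
    direction = c(rep("anterograde", 6), rep("retrograde", 4)),
    amplitude_pct = 20, distance_frac = 3, duration_s = 5,
    velocity_mm_per_s = 0.2
  )
  s <- summarize_motility(events, segment_scheme(), window = c(0, 60),
                          total_length_mm = 60)
  d <- s$direction
  expect_equal(d$proportion[d$type == "ripple" & d$direction == "anterograde"], 0.6)
  expect_equal(d$proportion[d$type == "ripple" & d$direction == "retrograde"], 0.4)
})

test_that("flipping the position axis swaps direction labels only", {
  sim <- simulate_diameter_matrix(
    simulation_spec(length_mm = 40, n_frames = 80),
    ground_truth_event("ripple", onset_time_s = 5, duration_s = 40,
                       initiation_site_mm = 10, velocity_mm_per_s = 0.25,
                       amplitude_frac = 0.4)
  )
  ev <- st_classify(st_detect(sim$dm), dm = sim$dm)
  flipped <- sim$dm
  flipped$values <- flipped$values[rev(seq_len(nrow(flipped$values))), ]
  evf <- st_classify(st_detect(flipped), dm = flipped)
  expect_equal(nrow(ev), nrow(evf))
  expect_equal(ev$type, evf$type)
  expect_equal(ev$velocity_mm_per_s, evf$velocity_mm_per_s, tolerance = 1e-9)
  expect_equal(ev$r2, evf$r2, tolerance = 1e-9)
  expect_equal(ev$direction, "anterograde")
  expect_equal(evf$direction, "retrograde")
})

test_that("summary objects expose tidy, glance and autoplot methods", {
  events <- tibble::tibble(
    event_id = 1:4, initiation_time_s = 2, initiation_site_frac = c(10, 45, 70, 95),
    type = c("standing", "ripple", "slow", "standing"),
    direction = c("none", "anterograde", "retrograde", "none"),
    amplitude_pct = 15, distance_frac = 2, duration_s = 4,
    velocity_mm_per_s = c(NA, 0.2, 0.05, NA)
  )
  s <- summarize_motility(events, segment_scheme(), window = c(0, 600),
                          total_length_mm = 60)
  expect_s3_class(tidy(s), "tbl_df")
  expect_equal(glance(s)$n_events, 4)
  expect_s3_class(autoplot(s), "ggplot")
})
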