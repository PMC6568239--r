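test_that("quartile categories use interpolated order statistics", {
  qc <- quartile_categories(1:8)
  expect_equal(qc$q1, 2.75)
  expect_equal(qc$q3, 6.25)
  expect_equal(which(qc$category == "low"), 1:2)
  expect_equal(which(qc$category == "high"), 7:8)
  expect_equal(which(qc$category == "medium"), 3:6)
  expect_equal(sum(qc$breakdown$proportion), 1)

  shuffled <- quartile_categories(sample(1:8))
  expect_equal(shuffled$q1, qc$q1)
  expect_equal(shuffled$q3, qc$q3)
  expect_equal(shuffled$breakdown, qc$breakdown)

  expect_error(quartile_categories(c(1, 2, 3)), "at least 4")
  expect_warning(deg <- quartile_categories(rep(2, 6)), "degenerate")
  expect_true(deg$degenerate)
})

test_that("log2 ratios exclude zero or missing pairs", {
  pr <- pre_post_log2(c(2, 3, 0, NA), c(4, 3, 5, 1))
  expect_equal(pr$log2_ratio[1], 1)
  expect_equal(pr$log2_ratio[2], 0)
  expect_true(all(is.na(pr$log2_ratio[3:4])))
  expect_equal(attr(pr, "n_excluded"), 2)
  expect_error(pre_post_log2(c(-1, 2), c(1, 2)), "nonnegative")
})

test_that("one-sample t matches the textbook formula and tiers", {
  res <- one_sample_t(c(0.5, 1, 1.5))
  expect_equal(res$statistic, 1 / (0.5 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$statistic, 3.4641016, tolerance = 1e-6)
  expect_equal(res$df, 2)

  sym <- one_sample_t(c(-1, 1))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  expect_equal(sym$tier, "")

  flat <- one_sample_t(c(0.3, 0.3, 0.3))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$p_value))
})

test_that("one-sample t agrees with the reference implementation", {
  set.seed(42)
  for (k in 1:100) {
    x <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    mine <- one_sample_t(x)
    ref <- t.test(x, mu = 0, conf.level = 0.90)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(c(mine$conf_low, mine$conf_high), as.numeric(ref$conf.int),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("significance tiers follow the two-level convention", {
  expect_equal(one_sample_t(c(0.01, -0.01, 0.02, 0.005))$tier, "")
  # construct p just below 0.1 and below 0.05 via known t quantiles
  make_ratios <- function(t_target, n = 5) {
    # mean m, sd 1 -> t = m sqrt(n)
    m <- t_target / sqrt(n)
    x <- scale(rnorm(n))[, 1] # mean 0, sd 1
    x + m
  }
  set.seed(1)
  mid <- one_sample_t(make_ratios(qt(0.96, df = 4))) # p = 0.08
  expect_equal(mid$tier, "*")
  hi <- one_sample_t(make_ratios(qt(0.995, df = 4))) # p = 0.01
  expect_equal(hi$tier, "**")
})

test_that("Kruskal-Wallis H matches the rank-formula oracle", {
  df <- tibble::tibble(
    value = c(1, 2, 3, 101, 102, 103, 201, 202, 203),
    type = rep(c("standing", "ripple", "slow"), each = 3)
  )
  res <- compare_types(df, value, type)
  expect_equal(res$kruskal$statistic, kw_oracle(df$value, df$type),
               tolerance = 1e-9)
  expect_equal(res$kruskal$statistic, 7.2, tolerance = 1e-9)
  expect_equal(res$kruskal$df, 2)
  # agreement with the reference implementation on tied data
  set.seed(13)
  df2 <- tibble::tibble(value = sample(1:6, 30, replace = TRUE),
                        g = sample(c("a", "b", "c"), 30, replace = TRUE))
  mine <- compare_types(df2, value, g)
  ref <- kruskal.test(df2$value, factor(df2$g))
  expect_equal(mine$kruskal$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("Dunn post-hoc z values follow the rank-sum formula", {
  df <- tibble::tibble(
    value = c(1, 2, 3, 101, 102, 103, 201, 202, 203),
    type = rep(c("a", "b", "c"), each = 3)
  )
  res <- compare_types(df, value, type)
  # mean ranks 2, 5, 8; SE = sqrt((N(N+1)/12)(1/3 + 1/3)) = sqrt(5)
  d <- res$dunn
  z_ab <- d$z[d$group1 == "a" & d$group2 == "b"]
  z_ac <- d$z[d$group1 == "a" & d$group2 == "c"]
  expect_equal(z_ab, -3 / sqrt(5), tolerance = 1e-9)
  expect_equal(z_ac, -6 / sqrt(5), tolerance = 1e-9)
  expect_equal(d$p_adj, p.adjust(d$p_value, "holm"))

  expect_error(compare_types(tibble::tibble(value = 1:3, g = "a"), value, g),
               "at least 2 groups")
  expect_warning(
    compare_types(tibble::tibble(value = c(1, 2, 3, 4, 9),
                                 g = c("a", "a", "b", "b", "c")), value, g),
    "< 2 values"
  )
})

test_that("ANOVA across segments matches the decomposition oracle", {
  df <- tibble::tibble(
    cpm = c(1, 2, 3, 2, 3, 4, 6, 7, 8),
    segment = rep(c("S1", "S2", "S3"), each = 3)
  )
  res <- compare_segments(df, cpm, segment)
  # SSB = 42, SSW = 6, F = (42/2)/(6/6) = 21
  expect_equal(res$anova$statistic, 21, tolerance = 1e-9)
  expect_equal(res$anova$df_between, 2)
  expect_equal(res$anova$df_within, 6)

  same <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_lt(compare_segments(same, v, g)$anova$statistic, 1e-10)
})

test_that("Tukey letters group non-different segments together", {
  set.seed(2)
  df <- tibble::tibble(
    cpm = c(rnorm(6, 1, 0.1), rnorm(6, 1.05, 0.1), rnorm(6, 8, 0.1)),
    segment = rep(c("S1", "S2", "S3"), each = 6)
  )
  res <- compare_segments(df, cpm, segment)
  lt <- setNames(res$letters$letters, res$letters$group)
  expect_equal(lt[["S1"]], lt[["S2"]]) # not separable
  expect_false(lt[["S3"]] == lt[["S1"]])
  # letter sharing mirrors the Tukey calls
  tk <- res$tukey
  for (k in seq_len(nrow(tk))) {
    shared <- any(strsplit(lt[[tk$group1[k]]], "")[[1]] %in%
                    strsplit(lt[[tk$group2[k]]], "")[[1]])
    expect_equal(shared, tk$p_adj[k] >= 0.05)
  }
})

test_that("length reduction compares pre-mean to post-minimum", {
  trace <- simulate_length_trace(n_frames = 1440, baseline_mm = 50,
                                 sustained_at_s = 600, sustained_frac = 0.2)$trace
  lr <- length_reduction(trace, event_time_s = 600)
  expect_equal(lr$percent_reduction, 20, tolerance = 0.01)

  flat <- simulate_length_trace(n_frames = 1440, baseline_mm = 50)$trace
  lr0 <- length_reduction(flat, event_time_s = 600)
  expect_equal(lr0$percent_reduction, 0)
  expect_equal(sum(lr0$events$n_events), 0)

  expect_error(length_reduction(flat, event_time_s = 5000), "cover")
})

test_that("shortening events above the prominence floor are counted", {
  dips <- tibble::tibble(time_s = c(650, 750, 850, 950, 1050),
                         prominence_frac = 0.05, duration_s = 20)
  sim <- simulate_length_trace(n_frames = 1440, baseline_mm = 50, dips = dips)
  lr <- length_reduction(sim$trace, event_time_s = 600)
  ev <- lr$events
  expect_equal(ev$n_events[ev$window == "after"], 5)
  expect_equal(ev$n_events[ev$window == "before"], 0)
  expect_equal(ev$per_min[ev$window == "after"], 0.5)
})
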