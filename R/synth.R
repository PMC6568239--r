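#' Specification for a synthetic motility recording
#'
#' Defines the geometry, calibration and noise of a simulated diameter
#' matrix. Defaults mirror the ex vivo recordings the method was built for: a
#' 60 mm juvenile intestine with a bulbous oral (foregut) region tapering
#' towards the anal end, 0.5 mm spatial bins, analyzed frames at 1.2 per
#' second, 10-minute windows (720 frames).
#'
#' @param length_mm Intestine length in mm.
#' @param diameter_oral_mm,diameter_anal_mm Baseline diameters at the two
#'   ends; the taper is a smooth oral bulge,
#'   `D0(x) = anal + (oral - anal) * exp(-(x / (0.35 * L))^2)`.
#' @param dx_mm,dt_s Grid calibration.
#' @param n_frames Number of analyzed frames.
#' @param noise_sd_mm Additive Gaussian measurement noise (mm).
#' @param seed Integer seed making simulation reproducible.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(length_mm = 60, diameter_oral_mm = 4,
                            diameter_anal_mm = 1.5, dx_mm = 0.5,
                            dt_s = 1 / 1.2, n_frames = 720,
                            noise_sd_mm = 0, seed = 1L) {
  if (length_mm <= 0 || dx_mm <= 0 || dt_s <= 0 || n_frames < 2) {
    abort("Invalid simulation geometry.")
  }
  if (noise_sd_mm < 0) abort("`noise_sd_mm` must be >= 0.")
  structure(
    list(length_mm = length_mm, diameter_oral_mm = diameter_oral_mm,
         diameter_anal_mm = diameter_anal_mm, dx_mm = dx_mm, dt_s = dt_s,
         n_frames = as.integer(n_frames), noise_sd_mm = noise_sd_mm,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

baseline_profile <- function(spec, positions) {
  spec$diameter_anal_mm + (spec$diameter_oral_mm - spec$diameter_anal_mm) *
    exp(-(positions / (0.35 * spec$length_mm))^2)
}

#' Ground-truth contraction event for simulation
#'
#' Describes one injected contraction. The event's centre path is
#' `c(t) = initiation_site_mm + dir * velocity * (t - onset)` plus, for
#' slow/irregular events, a sinusoidal waviness that degrades the linearity
#' of position versus time towards a target generative \eqn{r^2}. The local
#' narrowing is a Gaussian of width `spatial_sigma_mm` around the centre,
#' scaled by `amplitude_frac` of the baseline diameter and by a smooth
#' on/off envelope over `duration_s`.
#'
#' @param type `"standing"`, `"ripple"` or `"slow"`.
#' @param onset_time_s,duration_s Temporal extent (s); `duration_s > 0`.
#' @param initiation_site_mm Starting position (mm from the oral end).
#' @param velocity_mm_per_s Propagation speed (0 for standing).
#' @param direction `"anterograde"` (oral to anal) or `"retrograde"`.
#' @param amplitude_frac Depth as a fraction of the local baseline diameter,
#'   in (0, 1); the observed range spans roughly 0.05-0.85.
#' @param spatial_sigma_mm Spatial width (mm): the Gaussian sigma, or the
#'   half-width of the square kernel.
#' @param kernel `"gaussian"` (default; smooth, differentiable narrowing) or
#'   `"square"` (sharp-edged boxcar whose footprint width does not depend on
#'   amplitude — useful for threshold and footprint edge cases).
#' @param r2_target For slow events, the target generative \eqn{r^2} of
#'   position vs time (< 0.8); `NA` disables waviness.
#' @param waviness_cycles Number of full waviness cycles over the duration.
#' @return A one-row tibble (bind several with [dplyr::bind_rows()]).
#' @export
ground_truth_event <- function(type = c("standing", "ripple", "slow"),
                               onset_time_s, duration_s, initiation_site_mm,
                               velocity_mm_per_s = 0,
                               direction = c("anterograde", "retrograde"),
                               amplitude_frac = 0.3, spatial_sigma_mm = 0.8,
                               kernel = c("gaussian", "square"),
                               r2_target = NA_real_, waviness_cycles = 3) {
  type <- match.arg(type)
  direction <- match.arg(direction)
  kernel <- match.arg(kernel)
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  if (amplitude_frac <= 0 || amplitude_frac >= 1) {
    abort("`amplitude_frac` must be in (0, 1).")
  }
  if (velocity_mm_per_s < 0) abort("`velocity_mm_per_s` must be >= 0.")
  waviness_amp_mm <- 0
  if (!is.na(r2_target) && r2_target > 0 && r2_target < 1 && velocity_mm_per_s > 0) {
    # linear term variance over the duration is (vT)^2 / 12; a sinusoid of
    # amplitude A over whole cycles adds A^2 / 2 of unexplained variance, so
    # r2 ~ var_lin / (var_lin + A^2/2) inverts to the A below
    var_lin <- (velocity_mm_per_s * duration_s)^2 / 12
    waviness_amp_mm <- sqrt(2 * var_lin * (1 - r2_target) / r2_target)
  }
  tibble(
    type = type, onset_time_s = onset_time_s, duration_s = duration_s,
    initiation_site_mm = initiation_site_mm,
    velocity_mm_per_s = velocity_mm_per_s, direction = direction,
    amplitude_frac = amplitude_frac, spatial_sigma_mm = spatial_sigma_mm,
    kernel = kernel, r2_target = r2_target,
    waviness_amp_mm = waviness_amp_mm, waviness_cycles = waviness_cycles
  )
}

# smooth on/off envelope: raised-cosine ramps over a fifth of the duration
# (capped at 2 s), flat in between
event_envelope <- function(t, onset, duration) {
  ramp <- min(2, 0.2 * duration)
  u <- t - onset
  h <- numeric(length(t))
  inside <- u >= 0 & u <= duration
  h[inside] <- 1
  if (ramp > 0) {
    rise <- inside & u < ramp
    fall <- inside & u > duration - ramp
    h[rise] <- 0.5 * (1 - cos(pi * u[rise] / ramp))
    h[fall] <- 0.5 * (1 - cos(pi * (duration - u[fall]) / ramp))
  }
  h
}

#' Simulate a diameter matrix with known contraction events
#'
#' Builds the baseline tapered diameter profile, subtracts each event's
#' moving Gaussian narrowing, adds Gaussian measurement noise and clips at
#' zero. Identical spec + seed + events give bit-identical output. Events
#' whose space-time footprints overlap are allowed but flagged.
#'
#' @param spec A [simulation_spec()].
#' @param events Tibble of [ground_truth_event()] rows (may be empty).
#' @param seed Seed; defaults to `spec$seed`.
#' @return A list: `dm` (the [diameter_matrix()]) and `truth` (the event
#'   tibble with an added `event` index and expected footprint columns);
#'   `overlaps` attribute on `truth` flags footprint overlaps.
#' @export
simulate_diameter_matrix <- function(spec, events = NULL, seed = NULL) {
  events <- events %||% tibble()
  pos <- (seq_len(ceiling(spec$length_mm / spec$dx_mm)) - 0.5) * spec$dx_mm
  tim <- (seq_len(spec$n_frames) - 1) * spec$dt_s
  d0 <- baseline_profile(spec, pos)
  vals <- matrix(rep(d0, times = length(tim)), nrow = length(pos))
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      e <- events[k, ]
      s <- if (e$direction == "anterograde") 1 else -1
      u <- tim - e$onset_time_s
      centre <- e$initiation_site_mm + s * e$velocity_mm_per_s * u
      if (e$waviness_amp_mm > 0) {
        # cos - 1: zero displacement at onset and, over whole cycles,
        # orthogonal to the linear trend, so the path's regression slope
        # stays exactly +/- velocity (a sine term would leak a linear
        # component of size 6A/(pi*T) into the slope)
        centre <- centre + e$waviness_amp_mm *
          (cos(2 * pi * e$waviness_cycles * u / e$duration_s) - 1)
      }
      h <- event_envelope(tim, e$onset_time_s, e$duration_s)
      active <- which(h > 0)
      square <- identical(e$kernel, "square")
      for (j in active) {
        g <- if (square) {
          as.numeric(abs(pos - centre[j]) <= e$spatial_sigma_mm)
        } else {
          exp(-(pos - centre[j])^2 / (2 * e$spatial_sigma_mm^2))
        }
        vals[, j] <- vals[, j] - e$amplitude_frac * d0 * g * h[j]
      }
    }
  }
  if (spec$noise_sd_mm > 0) {
    set.seed(seed %||% spec$seed)
    vals <- vals + rnorm(length(vals), sd = spec$noise_sd_mm)
  }
  vals[vals < 0] <- 0
  dm <- diameter_matrix(vals, dx_mm = spec$dx_mm, dt_s = spec$dt_s,
                        total_length_mm = spec$length_mm)
  truth <- events
  if (nrow(truth)) {
    truth <- mutate(
      truth,
      event = dplyr::row_number(),
      end_time_s = .data$onset_time_s + .data$duration_s,
      end_site_mm = .data$initiation_site_mm +
        ifelse(.data$direction == "anterograde", 1, -1) *
          .data$velocity_mm_per_s * .data$duration_s,
      expected_distance_mm = .data$velocity_mm_per_s * .data$duration_s
    )
    attr(truth, "overlaps") <- footprint_overlaps(truth)
  }
  list(dm = dm, truth = truth)
}

footprint_overlaps <- function(truth) {
  if (nrow(truth) < 2) return(FALSE)
  lo <- pmin(truth$initiation_site_mm, truth$end_site_mm) - 2 * truth$spatial_sigma_mm
  hi <- pmax(truth$initiation_site_mm, truth$end_site_mm) + 2 * truth$spatial_sigma_mm
  t0 <- truth$onset_time_s
  t1 <- truth$end_time_s
  for (i in seq_len(nrow(truth) - 1)) {
    for (j in (i + 1):nrow(truth)) {
      if (t0[i] <= t1[j] && t0[j] <= t1[i] && lo[i] <= hi[j] && lo[j] <= hi[i]) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Rasterize a diameter matrix into a synthetic mask stack
#'
#' Renders each frame's diameter profile as a symmetric vertical tube: each
#' spatial bin becomes `dx_mm * px_per_mm` pixel rows whose foreground width
#' is the diameter rounded to whole pixels, centred in the image. Measuring
#' the result with [measure_diameters()] recovers the input within one
#' pixel-equivalent.
#'
#' @param dm A [diameter_matrix()].
#' @param px_per_mm Raster resolution; at least 10 px/mm recommended — a
#'   warning is given when one pixel exceeds the smallest nonzero amplitude
#'   the matrix could hold.
#' @return A [mask_stack()] with `fps = 1 / dt_s`.
#' @export
simulate_masks <- function(dm, px_per_mm = 10) {
  if (px_per_mm <= 0) abort("`px_per_mm` must be positive.")
  if (px_per_mm < 10) {
    warn("px_per_mm < 10: pixel quantization may hide small amplitudes.")
  }
  bin_px <- max(1L, round(dm$dx_mm * px_per_mm))
  n_rows <- nrow(dm$values) * bin_px
  width_px <- ceiling(max(dm$values, na.rm = TRUE) * px_per_mm) + 8L
  centre <- width_px / 2
  frames <- lapply(seq_len(ncol(dm$values)), function(j) {
    f <- matrix(FALSE, n_rows, width_px)
    for (i in seq_len(nrow(dm$values))) {
      d <- dm$values[i, j]
      if (is.na(d) || d <= 0) next
      w <- round(d * px_per_mm)
      if (w < 1) next
      c0 <- floor(centre - w / 2) + 1L
      f[((i - 1L) * bin_px + 1L):(i * bin_px), c0:(c0 + w - 1L)] <- TRUE
    }
    f
  })
  mask_stack(frames, px_per_mm = px_per_mm, fps = 1 / dm$dt_s)
}

#' Simulate a length trace with shortening events
#'
#' Baseline intestinal length with injected transient dips (discrete
#' shortening events of given prominence and duration) and an optional
#' sustained post-treatment reduction, for exercising [length_reduction()].
#'
#' @param n_frames,dt_s Trace calibration.
#' @param baseline_mm Resting length.
#' @param dips Tibble with columns `time_s`, `prominence_frac` (fraction of
#'   baseline) and `duration_s`; may be `NULL`.
#' @param sustained_at_s,sustained_frac Optional sustained reduction: from
#'   `sustained_at_s` onwards length decreases smoothly by `sustained_frac`
#'   of baseline (over ~30 s).
#' @param noise_sd_mm Additive Gaussian noise.
#' @param seed Seed for the noise.
#' @return A list: `trace` (length-trace tibble) and `truth` (the dip table).
#' @export
simulate_length_trace <- function(n_frames, dt_s = 1 / 1.2, baseline_mm = 50,
                                  dips = NULL, sustained_at_s = NULL,
                                  sustained_frac = 0, noise_sd_mm = 0,
                                  seed = 1L) {
  tim <- (seq_len(n_frames) - 1) * dt_s
  len <- rep(baseline_mm, n_frames)
  if (!is.null(sustained_at_s) && sustained_frac > 0) {
    ramp <- pmin(1, pmax(0, (tim - sustained_at_s) / 30))
    len <- len - baseline_mm * sustained_frac * 0.5 * (1 - cos(pi * ramp))
  }
  if (!is.null(dips) && nrow(dips)) {
    for (k in seq_len(nrow(dips))) {
      d <- dips[k, ]
      len <- len - baseline_mm * d$prominence_frac *
        event_envelope(tim, d$time_s - d$duration_s / 2, d$duration_s)
    }
  }
  if (noise_sd_mm > 0) {
    set.seed(seed)
    len <- len + rnorm(n_frames, sd = noise_sd_mm)
  }
  trace <- new_length_trace(pmax(len, 0), dt_s)
  list(trace = trace, truth = dips %||% tibble())
}

#' Sample ground-truth events across the observed parameter ranges
#'
#' Draws `n` events of the given types for parameter-recovery experiments,
#' using square spatial kernels so every event has an unambiguous,
#' amplitude-independent footprint. Relative amplitudes span 5-85% of the
#' local diameter, floored so the absolute depth stays resolvable
#' (`amplitude_frac * D0 >= 0.2` mm) over the event's path. Ripples are
#' perfectly linear with velocities log-uniform over 0.012-1.69 mm/s; slow
#' events follow a single-cycle sinusoidal path targeting a generative
#' \eqn{r^2} of 0.3-0.6, with velocities 0.012-0.12 mm/s so that the wavy
#' centre never jumps more than a grid step per frame (the bulk of observed
#' slow contractions move at or below 0.1 mm/s). Propagating distances
#' span 3.5-10 mm with durations capped at 300 s; the slowest printed
#' velocities (around 0.001-0.002 mm/s) cannot jointly satisfy a > 1 mm
#' distance within such durations and are not sampled. Standing events snap
#' to a bin centre (sub-bin placement is a raster artefact, not a property
#' of the detector).
#'
#' @param spec A [simulation_spec()].
#' @param n Number of events.
#' @param types Types to cycle through.
#' @param seed Seed.
#' @return A tibble of [ground_truth_event()] rows (all with
#'   `onset_time_s = 0`; stagger them before combining into one matrix).
#' @export
sample_ground_truth <- function(spec, n, types = c("standing", "ripple", "slow"),
                                seed = 1L) {
  set.seed(seed)
  pos_grid <- (seq_len(ceiling(spec$length_mm / spec$dx_mm)) - 0.5) * spec$dx_mm
  d0_at <- function(x) baseline_profile(spec, x)
  purrr::map(seq_len(n), function(k) {
    type <- types[((k - 1) %% length(types)) + 1]
    if (type == "standing") {
      site <- runif(1, 0.15, 0.85) * spec$length_mm
      site <- (round(site / spec$dx_mm - 0.5) + 0.5) * spec$dx_mm
      amp <- runif(1, max(0.05, 0.2 / d0_at(site)), 0.85)
      ground_truth_event(
        "standing", onset_time_s = 0, duration_s = runif(1, 3, 60),
        initiation_site_mm = site, amplitude_frac = amp,
        spatial_sigma_mm = 0.3 * spec$dx_mm, kernel = "square"
      )
    } else {
      dist <- runif(1, 4.5, 10)
      v <- if (type == "ripple") {
        exp(runif(1, log(0.012), log(1.69)))
      } else {
        exp(runif(1, log(0.012), log(0.12)))
      }
      # at least 12 s (~14 analyzed frames) so the position-time regression
      # is not dominated by grid quantization for fast waves; velocities near
      # one bin per analyzed frame (~0.6 mm/s) alias with the sampling grid,
      # so those waves run longer to average the quantization pattern out
      dur <- max(dist / v, 12)
      if (type == "ripple" && v >= 0.45 && v <= 0.75) dur <- max(dur, 20)
      dur <- min(dur, 300, 13.5 / v)
      dist <- v * dur
      dir <- sample(c("anterograde", "retrograde"), 1)
      r2t <- if (type == "slow") runif(1, 0.3, 0.6) else NA_real_
      # one-sided overshoot of the cos - 1 wavy path beyond the linear span
      over <- if (is.na(r2t)) 0 else 2 * dist * sqrt((1 - r2t) / (6 * r2t))
      # footprint wide enough that a fast wave's centre never outruns its
      # own footprint between two analyzed frames
      hw <- max(spec$dx_mm, 0.55 * v * spec$dt_s)
      margin <- (dist + 2 * over + 3) / spec$length_mm
      site <- if (dir == "anterograde") {
        runif(1, 0.03 + over / spec$length_mm, max(0.95 - margin, 0.06)) * spec$length_mm
      } else {
        runif(1, min(0.05 + margin, 0.92), 0.97 - over / spec$length_mm) * spec$length_mm
      }
      path <- sort(c(site, site + (if (dir == "anterograde") 1 else -1) * dist))
      d0_min <- min(d0_at(pos_grid[pos_grid >= path[1] - over - hw &
                                     pos_grid <= path[2] + over + hw]))
      amp <- runif(1, max(0.05, 0.2 / d0_min), 0.85)
      ground_truth_event(
        type, onset_time_s = 0, duration_s = dur,
        initiation_site_mm = site, velocity_mm_per_s = v,
        direction = dir, amplitude_frac = amp,
        spatial_sigma_mm = hw, kernel = "square",
        r2_target = r2t, waviness_cycles = 1
      )
    }
  }) |> bind_rows()
}
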