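#' Fractional segment scheme of the intestine
#'
#' Partitions the intestine into consecutive segments by length fractions.
#' The default is the four morphologically defined segments of the ballan
#' wrasse gut, with length ratios 0.39, 0.23, 0.23 and 0.15 of total length
#' (Segment 1 = anterior bulbous foregut, Segment 4 = hindgut).
#'
#' @param ratios Positive fractions summing to 1.
#' @return A `segment_scheme`: tibble with `segment`, `ratio`, `boundary`
#'   (cumulative fraction at the anal end of each segment).
#' @export
segment_scheme <- function(ratios = c(0.39, 0.23, 0.23, 0.15)) {
  if (any(ratios <= 0)) abort("Segment ratios must be positive.")
  if (abs(sum(ratios) - 1) > 1e-9) abort("Segment ratios must sum to 1.")
  out <- tibble(
    segment = seq_along(ratios),
    ratio = as.numeric(ratios),
    boundary = cumsum(as.numeric(ratios))
  )
  class(out) <- c("segment_scheme", class(out))
  out
}

#' Assign an initiation site to a segment
#'
#' @param initiation_site_frac Initiation site as percent (0-100) of total
#'   intestinal length from the oral end.
#' @param scheme A [segment_scheme()].
#' @return Integer segment index (vectorized). A site exactly on a boundary
#'   belongs to the earlier (more oral) segment; 0% belongs to Segment 1.
#' @export
assign_segment <- function(initiation_site_frac, scheme = segment_scheme()) {
  f <- initiation_site_frac / 100
  if (any(f < 0 | f > 1, na.rm = TRUE)) {
    abort("`initiation_site_frac` must lie in [0, 100].")
  }
  vapply(f, function(fi) {
    if (is.na(fi)) return(NA_integer_)
    which(fi <= scheme$boundary + 1e-12)[1]
  }, integer(1))
}

#' Classify a contraction event from its features
#'
#' An event propagating a distance of at most 1.0 mm is a standing
#' (non-propagating) contraction, whatever its regression linearity. Events
#' propagating further are ripples when the position-versus-time regression
#' has \eqn{r^2 \ge 0.8} and slow propagating contractions otherwise; an
#' undefined \eqn{r^2} with distance > 1 mm falls back to slow.
#'
#' @param distance_mm Propagating distance(s) in mm.
#' @param r2 Coefficient(s) of determination of position vs time.
#' @param standing_max_mm Standing-contraction distance bound (default 1.0).
#' @param ripple_min_r2 Ripple linearity bound (default 0.8).
#' @return Character vector: `"standing"`, `"ripple"` or `"slow"`.
#' @export
classify_event <- function(distance_mm, r2, standing_max_mm = 1.0,
                           ripple_min_r2 = 0.8) {
  ifelse(distance_mm <= standing_max_mm, "standing",
         ifelse(!is.na(r2) & r2 >= ripple_min_r2, "ripple", "slow"))
}

# simple OLS of position on time over event cells; r2 as squared Pearson r
ols_position_time <- function(pos, time) {
  n <- length(pos)
  if (n < 2 || length(unique(time)) < 2) {
    return(list(slope = NA_real_, r2 = NA_real_))
  }
  sxx <- sum((time - mean(time))^2)
  sxy <- sum((time - mean(time)) * (pos - mean(pos)))
  slope <- sxy / sxx
  syy <- sum((pos - mean(pos))^2)
  r2 <- if (syy == 0) NA_real_ else sxy^2 / (sxx * syy)
  list(slope = slope, r2 = r2)
}

#' Compute event features and classify contraction events
#'
#' For each event (connected cluster of contraction cells) computes the
#' defining features: initiation site (position of the earliest cell, oral-most
#' on ties), propagating distance (spatial extent of the cells), duration
#' (temporal extent), a linear regression of position (response) on time over
#' all cells giving slope and \eqn{r^2}, velocity as the absolute slope,
#' direction from the slope sign (positive slope = anterograde, oral to anal),
#' and relative amplitude: the event's largest percent decrease in diameter
#' relative to the maximum diameter (within the analysis window) of the
#' position where the contraction occurred. The
#' type label applies the standing / ripple / slow rules of
#' [classify_event()].
#'
#' @param cells Cell tibble from [st_detect()] / [label_events()] with
#'   columns `event_id`, `pos_mm`, `time_s`, `amplitude_mm` (grid indices
#'   optional).
#' @param dm The source [diameter_matrix()]; needed for `amplitude_pct`
#'   (omitted when `NULL`).
#' @param total_length_mm Intestinal length for fractional positions;
#'   defaults to the matrix calibration carried by `cells` or `dm`.
#' @param window Optional `c(start_s, end_s)` restricting the temporal
#'   maximum used for relative amplitude; default is the whole matrix.
#' @inheritParams classify_event
#' @return A tibble with one row per event: features, `direction`
#'   (`"anterograde"`, `"retrograde"` or `"none"`), `type`, `n_cells`.
#' @export
st_classify <- function(cells, dm = NULL, total_length_mm = NULL, window = NULL,
                        standing_max_mm = 1.0, ripple_min_r2 = 0.8) {
  total_length_mm <- total_length_mm %||% attr(cells, "total_length_mm") %||%
    (if (!is.null(dm)) dm$total_length_mm else NULL)
  if (is.null(total_length_mm)) {
    abort("`total_length_mm` is needed (argument or cell-table attribute).")
  }
  max_profile <- NULL
  if (!is.null(dm)) {
    vals <- dm$values
    if (!is.null(window)) {
      keep <- st_times(dm) >= window[1] & st_times(dm) <= window[2]
      vals <- vals[, keep, drop = FALSE]
    }
    max_profile <- apply(vals, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  }
  per_event <- function(df) {
    first <- df[df$time_s == min(df$time_s), ]
    init_mm <- min(first$pos_mm)
    distance_mm <- max(df$pos_mm) - min(df$pos_mm)
    duration_s <- max(df$time_s) - min(df$time_s)
    fit <- ols_position_time(df$pos_mm, df$time_s)
    amplitude_pct <- NA_real_
    if (!is.null(max_profile) && all(c("pos_idx", "frame_idx") %in% names(df))) {
      mx <- max_profile[df$pos_idx]
      d <- dm$values[cbind(df$pos_idx, df$frame_idx)]
      drop_pct <- 100 * (mx - d) / mx
      drop_pct <- drop_pct[!is.na(drop_pct) & mx > 0]
      if (length(drop_pct)) amplitude_pct <- max(drop_pct)
    }
    tibble(
      n_cells = nrow(df),
      initiation_time_s = min(df$time_s),
      initiation_site_mm = init_mm,
      initiation_site_frac = 100 * init_mm / total_length_mm,
      distance_mm = distance_mm,
      distance_frac = 100 * distance_mm / total_length_mm,
      duration_s = duration_s,
      amplitude_mm = max(df$amplitude_mm),
      amplitude_pct = amplitude_pct,
      slope_mm_per_s = fit$slope,
      r2 = fit$r2,
      velocity_mm_per_s = if (is.na(fit$slope)) NA_real_ else abs(fit$slope),
      direction = if (is.na(fit$slope) || fit$slope == 0) "none"
                  else if (fit$slope > 0) "anterograde" else "retrograde"
    )
  }
  events <- cells |>
    group_by(.data$event_id) |>
    dplyr::group_modify(~ per_event(.x)) |>
    ungroup()
  events <- mutate(
    events,
    type = classify_event(.data$distance_mm, .data$r2, standing_max_mm, ripple_min_r2)
  )
  attr(events, "total_length_mm") <- total_length_mm
  attr(events, "window") <- window
  events
}

#' Summarize motility per segment, type and direction
#'
#' Computes the windowed summary used for treatment comparisons: event
#' frequency in contractions per minute per mm of segment length (cpm),
#' binned by initiation-site segment and contraction type; direction
#' proportions per type over propagating events with a defined direction;
#' and pooled parameter distributions per type.
#'
#' @param events Classified event tibble from [st_classify()].
#' @param scheme A [segment_scheme()].
#' @param window `c(start_s, end_s)` analysis window; events initiating
#'   inside it (inclusive) are counted.
#' @param total_length_mm Intestinal length at window start, used both for
#'   fractional positions and segment lengths.
#' @return A `motility_summary` object: list with `frequency` (segment x
#'   type tibble: `n`, `cpm`), `direction` (per-type anterograde/retrograde
#'   proportions; `NA` when no propagating events), `distributions`
#'   (long tibble of per-type parameter values) and the window/scheme used.
#' @export
summarize_motility <- function(events, scheme = segment_scheme(), window,
                               total_length_mm = NULL) {
  total_length_mm <- total_length_mm %||% attr(events, "total_length_mm")
  if (is.null(total_length_mm)) abort("`total_length_mm` is needed.")
  if (diff(window) <= 0) abort("`window` must have positive duration.")
  win_min <- diff(window) / 60
  ev <- filter(events, .data$initiation_time_s >= window[1],
               .data$initiation_time_s <= window[2])
  ev <- mutate(ev, segment = assign_segment(.data$initiation_site_frac, scheme))
  types <- c("standing", "ripple", "slow")
  grid <- tidyr::expand_grid(segment = scheme$segment, type = types)
  freq <- ev |>
    count(.data$segment, .data$type, name = "n") |>
    dplyr::right_join(grid, by = c("segment", "type")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    left_join(select(scheme, "segment", "ratio"), by = "segment") |>
    mutate(
      segment_length_mm = .data$ratio * total_length_mm,
      cpm = .data$n / (win_min * .data$segment_length_mm)
    ) |>
    select("segment", "type", "n", "segment_length_mm", "cpm") |>
    arrange(.data$segment, match(.data$type, types))
  direction <- ev |>
    filter(.data$direction %in% c("anterograde", "retrograde")) |>
    count(.data$type, .data$direction) |>
    group_by(.data$type) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup() |>
    dplyr::right_join(
      tidyr::expand_grid(type = c("ripple", "slow"),
                         direction = c("anterograde", "retrograde")),
      by = c("type", "direction")
    ) |>
    arrange(match(.data$type, types), .data$direction)
  distributions <- ev |>
    select("event_id", "type", "amplitude_pct", "distance_frac",
           "duration_s", "velocity_mm_per_s") |>
    tidyr::pivot_longer(cols = c("amplitude_pct", "distance_frac",
                                 "duration_s", "velocity_mm_per_s"),
                        names_to = "parameter", values_to = "value")
  structure(
    list(frequency = freq, direction = direction, distributions = distributions,
         window = window, total_length_mm = total_length_mm, scheme = scheme,
         n_events = nrow(ev)),
    class = "motility_summary"
  )
}

#' @export
print.motility_summary <- function(x, ...) {
  cat(sprintf("<motility_summary> %d events in window [%g, %g] s\n",
              x$n_events, x$window[1], x$window[2]))
  print(x$frequency)
  invisible(x)
}

#' @rdname summarize_motility
#' @param x A `motility_summary`.
#' @param ... Unused.
#' @method tidy motility_summary
#' @export
tidy.motility_summary <- function(x, ...) x$frequency

#' @rdname summarize_motility
#' @method glance motility_summary
#' @export
glance.motility_summary <- function(x, ...) {
  tibble(
    n_events = x$n_events,
    window_start_s = x$window[1],
    window_end_s = x$window[2],
    total_length_mm = x$total_length_mm,
    n_segments = nrow(x$scheme)
  )
}

#' @method autoplot motility_summary
#' @export
autoplot.motility_summary <- function(object, ...) {
  ggplot2::ggplot(object$frequency,
                  ggplot2::aes(x = factor(.data$segment), y = .data$cpm,
                               fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Segment", y = "Contractions / min / mm (cpm)",
                  fill = "Type") +
    ggplot2::theme_minimal()
}
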