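#' Normalize a diameter matrix for ST-map rendering
#'
#' Subtracts, per position, the average diameter over the recorded (analyzed)
#' period, so the map shows diameter deviation rather than the tapering
#' baseline. A global-mean mode subtracts the single mean over the whole
#' matrix instead. Missing cells stay missing; all-missing rows are left
#' untouched with a warning.
#'
#' @param dm A [diameter_matrix()] with at least two frames.
#' @param mode `"per_position"` (default) or `"global"`.
#' @return A `normalized_matrix` (same structure and calibration; values are
#'   deviations in mm, per-position temporal mean ~ 0).
#' @export
st_normalize <- function(dm, mode = c("per_position", "global")) {
  mode <- match.arg(mode)
  vals <- dm$values
  if (ncol(vals) < 2) abort("Need at least two frames to normalize.")
  if (mode == "per_position") {
    all_na <- rowSums(!is.na(vals)) == 0
    if (any(all_na)) {
      warn(sprintf("%d all-missing position row(s) left unnormalized.", sum(all_na)))
    }
    means <- rowMeans(vals, na.rm = TRUE)
    means[all_na] <- 0
    vals <- vals - means
  } else {
    vals <- vals - mean(vals, na.rm = TRUE)
  }
  out <- dm
  out$values <- vals
  class(out) <- c("normalized_matrix", "diameter_matrix")
  out
}

#' Insert linear interpolants between adjacent positions
#'
#' Smooths an ST map spatially by inserting `n_insert` equally spaced linear
#' interpolants between each pair of adjacent positions in every frame (nine
#' by default). The original samples are preserved exactly; a pair with a
#' missing endpoint yields missing interpolants. Interpolation is for
#' rendering only — detection runs on the native grid.
#'
#' @param m A [diameter_matrix()] or `normalized_matrix` with >= 2 positions.
#' @param n_insert Number of inserted values per adjacent pair (>= 0).
#' @return Same class as `m`, with `(n - 1) * (n_insert + 1) + 1` positions
#'   and `dx_mm / (n_insert + 1)`.
#' @export
st_interpolate <- function(m, n_insert = 9L) {
  n_insert <- as.integer(n_insert)
  if (is.na(n_insert) || n_insert < 0L) abort("`n_insert` must be >= 0.")
  vals <- m$values
  n <- nrow(vals)
  if (n < 2) abort("Need at least two positions to interpolate.")
  if (n_insert == 0L) return(m)
  step <- n_insert + 1L
  out <- matrix(NA_real_, nrow = (n - 1L) * step + 1L, ncol = ncol(vals))
  lo <- vals[-n, , drop = FALSE]
  hi <- vals[-1, , drop = FALSE]
  # original samples are copied, not blended, so a missing neighbour cannot
  # poison them (0 * NA is NA)
  out[seq(1L, by = step, length.out = n - 1L), ] <- lo
  for (k in seq_len(n_insert)) {
    w <- k / step
    out[seq(1L, by = step, length.out = n - 1L) + k, ] <- (1 - w) * lo + w * hi
  }
  out[(n - 1L) * step + 1L, ] <- vals[n, ]
  res <- m
  res$values <- out
  res$dx_mm <- m$dx_mm / step
  res
}

#' Render a gray-scale ST map
#'
#' Maps values linearly to 8-bit gray with the minimum diameter (deepest
#' contraction) black and the maximum white, time running down the vertical
#' axis and position along the horizontal axis. Half-integers round to even
#' (banker's rounding), so the midpoint of a symmetric range renders as 128.
#' A constant matrix renders uniform mid-gray (128) with a warning. Missing
#' cells are `NA` in the returned matrix and drawn in a sentinel color
#' outside the gray ramp by [write_st_png()].
#'
#' @param m A [diameter_matrix()] or `normalized_matrix`.
#' @return A `gray_map`: integer matrix (frames x positions) in 0..255 with
#'   `NA` for missing, plus calibration attributes.
#' @export
render_gray_map <- function(m) {
  vals <- m$values
  if (!any(is.finite(vals))) abort("No finite values to render.")
  rng <- range(vals, na.rm = TRUE)
  if (diff(rng) == 0) {
    warn("Constant matrix: rendering uniform mid-gray (128).")
    gray <- matrix(128L, nrow(vals), ncol(vals))
    gray[is.na(vals)] <- NA_integer_
  } else {
    gray <- matrix(as.integer(round((vals - rng[1]) / diff(rng) * 255)),
                   nrow(vals), ncol(vals))
  }
  out <- t(gray) # rows = frames (time, vertical), cols = positions
  structure(out, class = "gray_map", dx_mm = m$dx_mm, dt_s = m$dt_s,
            range_mm = rng)
}

#' Render a binary (classified) ST map
#'
#' Draws classified contraction events on the native (non-interpolated) grid:
#' background white, standing contractions black, slow propagating green and
#' ripples red. Where events overlap, classes are drawn in the order
#' standing, slow, ripple, so the later-drawn ripple wins.
#'
#' @param cells Cell tibble from [st_detect()] (needs `pos_idx`,
#'   `frame_idx`, `event_id`).
#' @param events Classified event tibble from [st_classify()] supplying each
#'   event's `type`.
#' @param grid_dim `c(n_positions, n_frames)`; defaults to the grid recorded
#'   on `cells`.
#' @return A `binary_map`: character matrix (frames x positions) of
#'   `"background"`, `"standing"`, `"slow"`, `"ripple"`.
#' @export
render_binary_map <- function(cells, events, grid_dim = NULL) {
  grid_dim <- grid_dim %||% attr(cells, "grid_dim")
  if (is.null(grid_dim)) abort("`grid_dim` is needed (argument or cell-table attribute).")
  bad <- cells$pos_idx < 1 | cells$pos_idx > grid_dim[1] |
    cells$frame_idx < 1 | cells$frame_idx > grid_dim[2]
  if (any(bad)) {
    abort(sprintf("Cells of event %d fall outside the grid.",
                  cells$event_id[which(bad)[1]]))
  }
  map <- matrix("background", grid_dim[1], grid_dim[2])
  drawn <- left_join(cells, select(events, "event_id", "type"), by = "event_id")
  for (cls in c("standing", "slow", "ripple")) {
    sub <- filter(drawn, .data$type == cls)
    if (nrow(sub)) map[cbind(sub$pos_idx, sub$frame_idx)] <- cls
  }
  structure(t(map), class = "binary_map",
            dx_mm = attr(cells, "dx_mm"), dt_s = attr(cells, "dt_s"))
}

st_palette <- c(background = "#FFFFFF", standing = "#000000",
                ripple = "#CC0000", slow = "#008800")

#' Write a rendered ST map to PNG
#'
#' Gray maps are written on the 0..255 ramp with missing cells in light blue
#' (a sentinel outside the gray ramp); binary maps use white background,
#' black standing, red ripple and green slow pixels.
#'
#' @param map A `gray_map` or `binary_map`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_st_png <- function(map, path) {
  if (inherits(map, "gray_map")) {
    g <- unclass(map) / 255
    rgb <- array(0, c(nrow(g), ncol(g), 3))
    rgb[, , 1] <- rgb[, , 2] <- rgb[, , 3] <- ifelse(is.na(g), 0, g)
    na_idx <- which(is.na(g))
    if (length(na_idx)) {
      sentinel <- c(0.68, 0.85, 1.0)
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[na_idx] <- sentinel[ch]
        rgb[, , ch] <- plane
      }
    }
  } else if (inherits(map, "binary_map")) {
    cols <- grDevices::col2rgb(st_palette[unclass(map)]) / 255
    rgb <- array(0, c(nrow(map), ncol(map), 3))
    for (ch in 1:3) rgb[, , ch] <- matrix(cols[ch, ], nrow(map), ncol(map))
  } else {
    abort("`map` must be a gray_map or binary_map.")
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' @method autoplot gray_map
#' @export
autoplot.gray_map <- function(object, ...) {
  df <- tibble(
    time_s = rep((seq_len(nrow(object)) - 1) * attr(object, "dt_s"),
                 times = ncol(object)),
    pos_mm = rep((seq_len(ncol(object)) - 0.5) * attr(object, "dx_mm"),
                 each = nrow(object)),
    gray = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pos_mm, .data$time_s, fill = .data$gray)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "#AED9FF", name = "Gray") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Position (mm, oral to anal)", y = "Time (s)") +
    ggplot2::theme_minimal()
}

#' @method autoplot binary_map
#' @export
autoplot.binary_map <- function(object, ...) {
  df <- tibble(
    time_s = rep((seq_len(nrow(object)) - 1) * attr(object, "dt_s"),
                 times = ncol(object)),
    pos_mm = rep((seq_len(ncol(object)) - 0.5) * attr(object, "dx_mm"),
                 each = nrow(object)),
    class = factor(as.vector(unclass(object)),
                   levels = c("background", "standing", "ripple", "slow"))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pos_mm, .data$time_s, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = st_palette, name = "Contraction") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Position (mm, oral to anal)", y = "Time (s)") +
    ggplot2::theme_minimal()
}
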