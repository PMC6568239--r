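#' Local diameter minima of a single frame profile
#'
#' A contraction shows as a local minimum of the diameter profile along the
#' intestine. A candidate minimum (or plateau of equal values lower than both
#' neighbours) is kept when its depth — the lower of the two valley-bounding
#' flanking maxima minus the minimum value — is at least `depth_threshold`.
#' The flanking maximum on each side is the largest value encountered before
#' the profile drops below the minimum again (or the profile end), so shallow
#' wiggles inside a deep valley do not split it. Plateau minima return every
#' index of the plateau.
#'
#' @param profile Numeric vector of diameters along the gut for one frame
#'   (no `NA`s; split on missing stretches first).
#' @param depth_threshold Minimum depth (mm) for a minimum to count as a
#'   contraction. Default 0.1 mm, one pixel-equivalent at a 10 px/mm
#'   acquisition scale.
#' @return Integer indices of contraction minima (empty when the profile is
#'   shorter than 3 or flat).
#' @examples
#' find_local_minima(c(5, 5, 3, 5, 5), 1) # 3
#' find_local_minima(c(5, 4.5, 5), 1) # none: depth 0.5 < 1
#' @export
find_local_minima <- function(profile, depth_threshold = 0.1) {
  n <- length(profile)
  if (n < 3 || anyNA(profile)) {
    if (anyNA(profile)) abort("`profile` must not contain NA; split on missing runs.")
    return(integer(0))
  }
  runs <- candidate_min_runs(profile)
  out <- integer(0)
  for (r in runs) {
    if (min_depth(profile, r[1], r[2]) >= depth_threshold) {
      out <- c(out, r[1]:r[2])
    }
  }
  out
}

# maximal runs of equal values strictly lower than both neighbours (interior)
candidate_min_runs <- function(profile) {
  n <- length(profile)
  runs <- list()
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && profile[j + 1L] == profile[i]) j <- j + 1L
    if (profile[i - 1L] > profile[i] && j < n && profile[j + 1L] > profile[i]) {
      runs[[length(runs) + 1L]] <- c(i, j)
    }
    i <- j + 1L
  }
  runs
}

# depth of the valley holding run [a, b]: min(flanking maxima) - value; each
# flank is the running max until the profile falls below the run's value
min_depth <- function(profile, a, b) {
  v <- profile[a]
  flanks <- c()
  if (a > 1) {
    left <- profile[seq(a - 1, 1)]
    stop_at <- which(left < v)[1]
    if (!is.na(stop_at)) left <- left[seq_len(stop_at - 1)]
    if (length(left)) flanks <- c(flanks, max(left))
  }
  n <- length(profile)
  if (b < n) {
    right <- profile[seq(b + 1, n)]
    stop_at <- which(right < v)[1]
    if (!is.na(stop_at)) right <- right[seq_len(stop_at - 1)]
    if (length(right)) flanks <- c(flanks, max(right))
  }
  if (!length(flanks)) return(0)
  min(flanks) - v
}

#' Extend detected minima to similar-diameter neighbours
#'
#' Each minimum grows to the maximal contiguous run of neighbouring bins
#' whose diameter is within `similarity_tol` of the minimum's value; the
#' union of the runs is the frame's set of contraction cells. With the
#' worked profile `c(8, 8, 3, 3.5, 3, 8, 8)` and tolerance 1 the two minima
#' and the 3.5 bin between them merge into the three-cell contraction.
#'
#' @inheritParams find_local_minima
#' @param minima Indices from [find_local_minima()] on the same profile.
#' @param similarity_tol Diameter tolerance (mm); defaults to the depth
#'   threshold it is paired with.
#' @return Sorted integer indices of all contraction cells.
#' @export
extend_minima <- function(profile, minima, similarity_tol = 0.1) {
  if (!length(minima)) return(integer(0))
  n <- length(profile)
  cells <- logical(n)
  for (m in minima) {
    v <- profile[m]
    a <- m
    while (a > 1 && abs(profile[a - 1L] - v) <= similarity_tol) a <- a - 1L
    b <- m
    while (b < n && abs(profile[b + 1L] - v) <= similarity_tol) b <- b + 1L
    cells[a:b] <- TRUE
  }
  which(cells)
}

#' Amplitude of the contraction run containing a cell
#'
#' Amplitude is the delta between minimum and maximum: the run's minimum
#' diameter subtracted from the lower of its two valley-bounding flanking
#' maxima (the conservative flank convention). Every cell of one run carries
#' the same amplitude. A run touching the profile edge uses the single
#' available flank.
#'
#' @inheritParams extend_minima
#' @param cell Index of a cell inside a detected run.
#' @param cells Optional precomputed cell set (from [extend_minima()]);
#'   recomputed from the profile when absent.
#' @inheritParams find_local_minima
#' @return Amplitude in mm.
#' @export
cell_amplitude <- function(profile, cell, cells = NULL,
                           depth_threshold = 0.1, similarity_tol = depth_threshold) {
  if (is.null(cells)) {
    cells <- extend_minima(profile, find_local_minima(profile, depth_threshold),
                           similarity_tol)
  }
  if (!cell %in% cells) abort("`cell` is not part of a detected contraction run.")
  runs <- split_runs(cells)
  run <- runs[[which(vapply(runs, function(r) cell %in% r, logical(1)))[1]]]
  run_amplitude(profile, run)
}

split_runs <- function(idx) {
  if (!length(idx)) return(list())
  unname(split(idx, cumsum(c(1L, diff(idx) != 1L))))
}

run_amplitude <- function(profile, run) {
  a <- min(run)
  b <- max(run)
  v <- min(profile[run])
  n <- length(profile)
  flanks <- c()
  if (a > 1) {
    left <- profile[seq(a - 1, 1)]
    stop_at <- which(left < v)[1]
    if (!is.na(stop_at)) left <- left[seq_len(stop_at - 1)]
    if (length(left)) flanks <- c(flanks, max(left))
  }
  if (b < n) {
    right <- profile[seq(b + 1, n)]
    stop_at <- which(right < v)[1]
    if (!is.na(stop_at)) right <- right[seq_len(stop_at - 1)]
    if (length(right)) flanks <- c(flanks, max(right))
  }
  if (!length(flanks)) return(NA_real_)
  min(flanks) - v
}

#' Build the contraction-cell (amplitude/NA) matrix
#'
#' Applies minima extraction, similar-diameter extension and amplitude
#' computation independently to every frame of a diameter matrix. The result
#' is aligned with the source matrix and holds the contraction amplitude
#' (mm) where a cell was detected and `NA` elsewhere — the numerical form of
#' a binary ST map. Missing stretches of a frame's profile split it into
#' segments analyzed separately.
#'
#' @param dm A [diameter_matrix()].
#' @inheritParams find_local_minima
#' @param similarity_tol Diameter tolerance (mm) for extension; defaults to
#'   `depth_threshold` (the notion of "similar diameter" at detection scale).
#' @return An object of class `contraction_cells`: the amplitude matrix plus
#'   the detection parameters and source calibration.
#' @export
build_cell_matrix <- function(dm, depth_threshold = 0.1,
                              similarity_tol = depth_threshold) {
  vals <- dm$values
  amp <- matrix(NA_real_, nrow(vals), ncol(vals))
  for (j in seq_len(ncol(vals))) {
    col <- vals[, j]
    ok <- !is.na(col)
    if (!any(ok)) next
    for (seg in split_runs(which(ok))) {
      if (length(seg) < 3) next
      profile <- col[seg]
      minima <- find_local_minima(profile, depth_threshold)
      if (!length(minima)) next
      cells <- extend_minima(profile, minima, similarity_tol)
      for (run in split_runs(cells)) {
        a <- run_amplitude(profile, run)
        if (!is.na(a) && a > 0) amp[seg[run], j] <- a
      }
    }
  }
  structure(
    list(
      amplitude = amp, dx_mm = dm$dx_mm, dt_s = dm$dt_s,
      total_length_mm = dm$total_length_mm,
      depth_threshold = depth_threshold, similarity_tol = similarity_tol
    ),
    class = "contraction_cells"
  )
}

#' @export
print.contraction_cells <- function(x, ...) {
  cat(sprintf(
    "<contraction_cells> %d cells on a %d x %d grid (depth >= %g mm, tol %g mm)\n",
    sum(!is.na(x$amplitude)), nrow(x$amplitude), ncol(x$amplitude),
    x$depth_threshold, x$similarity_tol
  ))
  invisible(x)
}

#' Group contraction cells into events by connectivity
#'
#' Connected components of the non-missing cells become contraction events:
#' an isolated single-frame run is one event, a cluster of runs touching
#' across frames is one propagating event. Under 8-connectivity (default) a
#' diagonal step — the contraction advancing one bin in one frame — keeps an
#' event connected; 4-connectivity treats it as two events.
#'
#' @param cm A `contraction_cells` object from [build_cell_matrix()].
#' @param connectivity 8 (default) or 4.
#' @return A tibble of cells, one row per contraction cell: `event_id`,
#'   `pos_idx`, `frame_idx`, `pos_mm` (bin centre), `time_s`, `amplitude_mm`.
#'   Event ids are ordered by first frame then oral-most position.
#' @export
label_events <- function(cm, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  amp <- cm$amplitude
  nr <- nrow(amp)
  present <- which(!is.na(amp))
  cells <- tibble(
    event_id = integer(0), pos_idx = integer(0), frame_idx = integer(0),
    pos_mm = numeric(0), time_s = numeric(0), amplitude_mm = numeric(0)
  )
  if (length(present)) {
    rows <- ((present - 1L) %% nr) + 1L
    cols <- ((present - 1L) %/% nr) + 1L
    labels <- label_components(rows, cols, connectivity)
    # renumber by first occurrence in (frame, position) order
    ord <- order(cols, rows)
    labels <- match(labels, unique(labels[ord]))
    cells <- tibble(
      event_id = labels,
      pos_idx = rows,
      frame_idx = cols,
      pos_mm = (rows - 0.5) * cm$dx_mm,
      time_s = (cols - 1L) * cm$dt_s,
      amplitude_mm = amp[present]
    ) |>
      arrange(.data$event_id, .data$frame_idx, .data$pos_idx)
  }
  attr(cells, "connectivity") <- connectivity
  attr(cells, "grid_dim") <- dim(amp)
  attr(cells, "dx_mm") <- cm$dx_mm
  attr(cells, "dt_s") <- cm$dt_s
  attr(cells, "total_length_mm") <- cm$total_length_mm
  cells
}

# union-find connected components over sparse (row, col) cells
label_components <- function(rows, cols, connectivity) {
  n <- length(rows)
  key <- function(r, c) paste(r, c)
  index <- setNames(seq_len(n), key(rows, cols))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- if (connectivity == 8) {
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L))
  } else {
    list(c(-1L, 0L), c(0L, -1L))
  }
  for (off in offsets) {
    nb <- index[key(rows + off[1], cols + off[2])]
    hit <- which(!is.na(nb))
    for (i in hit) {
      ri <- find(i)
      rj <- find(nb[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Detect contraction cells and events in one call
#'
#' Convenience wrapper: [build_cell_matrix()] then [label_events()].
#'
#' @inheritParams build_cell_matrix
#' @inheritParams label_events
#' @return The cell tibble of [label_events()].
#' @export
st_detect <- function(dm, depth_threshold = 0.1, similarity_tol = depth_threshold,
                      connectivity = 8) {
  label_events(build_cell_matrix(dm, depth_threshold, similarity_tol), connectivity)
}

#' Drop events below an amplitude or duration floor
#'
#' Observed relative amplitudes start at about 5% of the local maximum
#' diameter, so the default floor drops events below 5%; whether such a floor
#' was part of the original analysis or 5% is simply the smallest amplitude
#' observed is unknowable from the description, so the floor is configurable
#' and `min_amplitude_frac = 0` disables it.
#'
#' @param events Classified event tibble from [st_classify()] (needs
#'   `amplitude_pct` when `min_amplitude_frac > 0`).
#' @param min_amplitude_frac Minimum relative amplitude (fraction of the
#'   local maximum diameter); default 0.05, 0 disables.
#' @param min_duration_s Minimum event duration in seconds; 0 disables.
#' @return The filtered event tibble; the thresholds used are recorded in
#'   the `filter` attribute.
#' @export
filter_events <- function(events, min_amplitude_frac = 0.05, min_duration_s = 0) {
  out <- events
  if (min_amplitude_frac > 0) {
    if (!"amplitude_pct" %in% names(out)) {
      abort("`events` lacks `amplitude_pct`; classify events first.")
    }
    out <- filter(out, is.na(.data$amplitude_pct) |
                    .data$amplitude_pct >= 100 * min_amplitude_frac)
  }
  if (min_duration_s > 0) out <- filter(out, .data$duration_s >= min_duration_s)
  attr(out, "filter") <- list(min_amplitude_frac = min_amplitude_frac,
                              min_duration_s = min_duration_s)
  out
}
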