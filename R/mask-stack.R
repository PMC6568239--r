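#' Calibrated stack of binary intestine masks
#'
#' One logical matrix per time-lapse frame with foreground = intestine. The
#' long axis of the organ runs along image rows with the oral end at row 1
#' (intestines are mounted vertically, oral end up); `orientation =
#' "anal_first"` flips that convention on ingest.
#'
#' @param frames List of logical (or 0/1) matrices of identical dimensions.
#' @param px_per_mm Pixels per millimetre (> 0).
#' @param fps Frames per second of the stack as provided (> 0).
#' @param orientation `"oral_first"` (default) or `"anal_first"`.
#' @return An object of class `mask_stack`. Frames with empty foreground are
#'   kept but flagged in the `degenerate` attribute.
#' @export
mask_stack <- function(frames, px_per_mm, fps, orientation = c("oral_first", "anal_first")) {
  orientation <- match.arg(orientation)
  if (px_per_mm <= 0 || fps <= 0) abort("`px_per_mm` and `fps` must be positive.")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    storage.mode(f) <- "logical"
    f
  })
  dims <- vapply(frames, dim, integer(2))
  if (length(frames) > 1 && any(dims != dims[, 1])) {
    abort("All frames must share identical dimensions.")
  }
  if (orientation == "anal_first") {
    frames <- lapply(frames, function(f) f[rev(seq_len(nrow(f))), , drop = FALSE])
  }
  degenerate <- which(!vapply(frames, any, logical(1)))
  structure(
    list(frames = frames, px_per_mm = as.numeric(px_per_mm), fps = as.numeric(fps)),
    degenerate = degenerate,
    class = "mask_stack"
  )
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<mask_stack> %d frames of %d x %d px (%.3g px/mm, %.3g fps)\n",
    length(x$frames), d[1], d[2], x$px_per_mm, x$fps
  ))
  invisible(x)
}

#' Read a mask stack from TIFF/PNG files
#'
#' Accepts a multi-page TIFF or a directory of single-page TIFF/PNG masks
#' (frames in lexical filename order). Pixels with intensity greater than
#' 0.5 are foreground. Calibration can be given directly or through a YAML or
#' JSON sidecar with fields `px_per_mm`, `fps` and optionally `orientation`.
#'
#' @param path Multi-page TIFF file or directory of masks.
#' @param px_per_mm,fps,orientation Calibration; each overrides the sidecar.
#' @param sidecar Optional sidecar file; defaults to `<path>.yaml` / `.json`
#'   if one exists.
#' @return A [mask_stack()].
#' @export
read_mask_stack <- function(path, px_per_mm = NULL, fps = NULL, orientation = NULL,
                            sidecar = NULL) {
  meta <- list()
  sidecar <- sidecar %||% {
    cands <- paste0(sub("/$", "", path), c(".yaml", ".yml", ".json"))
    cands[file.exists(cands)][1]
  }
  if (length(sidecar) == 1 && !is.na(sidecar) && file.exists(sidecar)) {
    meta <- if (grepl("\\.json$", sidecar)) {
      jsonlite::read_json(sidecar, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(sidecar)
    }
  }
  to_mask <- function(img) {
    if (length(dim(img)) == 3) img <- img[, , 1]
    img > 0.5
  }
  frames <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) abort(sprintf("No TIFF/PNG masks found under '%s'.", path))
    lapply(files, function(f) {
      to_mask(if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f) else tiff::readTIFF(f))
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, to_mask)
  } else {
    abort(sprintf("Mask input '%s' does not exist.", path))
  }
  mask_stack(
    frames,
    px_per_mm = px_per_mm %||% meta$px_per_mm %||% abort("`px_per_mm` missing (argument or sidecar)."),
    fps = fps %||% meta$fps %||% abort("`fps` missing (argument or sidecar)."),
    orientation = orientation %||% meta$orientation %||% "oral_first"
  )
}

#' Write a mask stack as a multi-page TIFF (plus YAML sidecar)
#' @param stack A [mask_stack()].
#' @param path Output TIFF path; a `<path>.yaml` sidecar records calibration.
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(stack, path) {
  imgs <- lapply(stack$frames, function(f) {
    m <- matrix(0, nrow(f), ncol(f))
    m[f] <- 1
    m
  })
  tiff::writeTIFF(imgs, path)
  yaml::write_yaml(
    list(px_per_mm = stack$px_per_mm, fps = stack$fps, orientation = "oral_first"),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' Keep every k-th frame of a stack
#'
#' Time-lapse series are acquired faster than needed for motility analysis;
#' keeping every third frame of a 3.5 fps recording gives the ~1.2 fps series
#' used for diameter measurement. Frames 1, 1+k, 1+2k, ... are kept and `fps`
#' is divided by `keep_every`.
#'
#' @param stack A [mask_stack()].
#' @param keep_every Positive integer stride.
#' @return A [mask_stack()] with the reduced frame set.
#' @export
downsample_frames <- function(stack, keep_every = 3L) {
  keep_every <- as.integer(keep_every)
  if (is.na(keep_every) || keep_every < 1L) {
    abort("`keep_every` must be a positive integer.")
  }
  idx <- seq(1L, length(stack$frames), by = keep_every)
  mask_stack(stack$frames[idx], px_per_mm = stack$px_per_mm,
             fps = stack$fps / keep_every)
}

# transverse extent (px) of foreground in each pixel row of one frame:
# distance between the outermost foreground pixels, 0 where the row is empty
row_extent_px <- function(frame) {
  apply(frame, 1, function(r) {
    w <- which(r)
    if (!length(w)) 0L else (w[length(w)] - w[1] + 1L)
  })
}

#' Measure intestinal diameters in transverse bins
#'
#' Stacks rectangular regions of interest of width `roi_width_mm` along the
#' long axis and records, per frame and bin, the transverse extent of the
#' foreground (the distance between the outermost foreground pixels
#' perpendicular to the long axis, i.e. between the upper and lower edge of
#' the white area). Bins are laid over the stack-wide foreground row range so
#' that a frame in which the (shortened) intestine no longer reaches a bin
#' yields `NA` there, not 0.
#'
#' @param stack A [mask_stack()].
#' @param roi_width_mm Bin (ROI) width in mm; default 0.5.
#' @param reducer How to reduce the per-pixel-row extents within a bin:
#'   `"max"` (default; the widest transverse cut) or `"mean"`.
#' @return A [diameter_matrix()] with `dx_mm = roi_width_mm` and
#'   `dt_s = 1 / fps`.
#' @export
measure_diameters <- function(stack, roi_width_mm = 0.5,
                              reducer = c("max", "mean")) {
  reducer <- match.arg(reducer)
  if (roi_width_mm <= 0) abort("`roi_width_mm` must be positive.")
  frames <- stack$frames
  if (!length(frames)) abort("Empty stack.")
  occupied <- lapply(frames, function(f) which(rowSums(f) > 0))
  all_rows <- unlist(occupied)
  if (!length(all_rows)) abort("No foreground in any frame; is the stack segmented?")
  row0 <- min(all_rows)
  row1 <- max(all_rows)
  bin_px <- roi_width_mm * stack$px_per_mm
  n_bins <- ceiling((row1 - row0 + 1L) / bin_px)
  bin_of <- function(rows) pmin(n_bins, floor((rows - row0) / bin_px) + 1L)
  vals <- matrix(NA_real_, nrow = n_bins, ncol = length(frames))
  red_fun <- if (reducer == "max") max else mean
  for (j in seq_along(frames)) {
    ext <- row_extent_px(frames[[j]])
    rows <- occupied[[j]]
    if (!length(rows)) next
    bins <- bin_of(rows)
    for (b in unique(bins)) {
      vals[b, j] <- red_fun(ext[rows[bins == b]]) / stack$px_per_mm
    }
  }
  if (all(is.na(vals))) abort("All bins empty; uncalibrated or degenerate stack.")
  dm <- diameter_matrix(vals, dx_mm = roi_width_mm, dt_s = 1 / stack$fps)
  first <- occupied[[1]]
  if (length(first)) {
    dm$total_length_mm <- (first[length(first)] - first[1] + 1L) / stack$px_per_mm
  }
  dm
}

#' Per-frame intestinal length
#'
#' Length is the longitudinal extent of the foreground: first to last image
#' row containing any foreground pixel, converted to mm. Frames with empty
#' foreground give `NA`.
#'
#' @param stack A [mask_stack()].
#' @return A tibble with columns `frame`, `time_s` and `length_mm`
#'   (class `length_trace`; `dt_s` is stored as an attribute).
#' @export
measure_length <- function(stack) {
  len <- vapply(stack$frames, function(f) {
    rows <- which(rowSums(f) > 0)
    if (!length(rows)) NA_real_ else (rows[length(rows)] - rows[1] + 1L) / stack$px_per_mm
  }, numeric(1))
  new_length_trace(len, dt_s = 1 / stack$fps)
}

new_length_trace <- function(length_mm, dt_s) {
  out <- tibble(
    frame = seq_along(length_mm),
    time_s = (seq_along(length_mm) - 1) * dt_s,
    length_mm = as.numeric(length_mm)
  )
  attr(out, "dt_s") <- dt_s
  class(out) <- c("length_trace", class(out))
  out
}

#' Threshold a grayscale stack into masks (convenience)
#'
#' A fixed-threshold segmentation helper for already clean recordings; the
#' analysis itself expects properly segmented masks.
#'
#' @param images List of numeric matrices in `[0, 1]`.
#' @param threshold Foreground if intensity > `threshold`.
#' @inheritParams mask_stack
#' @return A [mask_stack()].
#' @export
threshold_stack <- function(images, threshold, px_per_mm, fps,
                            orientation = "oral_first") {
  mask_stack(lapply(images, function(im) im > threshold),
             px_per_mm = px_per_mm, fps = fps, orientation = orientation)
}
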