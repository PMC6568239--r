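#' Calibrated diameter matrix (kymograph)
#'
#' A diameter matrix stores the intestinal diameter sampled in transverse
#' bins along the gut (rows, oral end first) over analyzed frames (columns).
#' It is the numerical form of a spatio-temporal (ST) map: contractions appear
#' as transient local decreases in diameter. Positions refer to bin centres,
#' `(i - 0.5) * dx_mm`; times to `(j - 1) * dt_s`. Missing measurements (for
#' example bins the shortened intestine no longer reaches) are `NA`, never 0,
#' so longitudinal shortening is not mistaken for contraction.
#'
#' @param values Numeric matrix, positions x frames; all finite values must be
#'   `>= 0`; `NA` marks missing measurements.
#' @param dx_mm Spatial sampling interval (bin width) in mm.
#' @param dt_s Time between analyzed frames in seconds.
#' @param total_length_mm Reference intestinal length in mm used when
#'   expressing positions and distances as percent of gut length; defaults to
#'   `nrow(values) * dx_mm`.
#' @return An object of class `diameter_matrix`.
#' @examples
#' dm <- diameter_matrix(matrix(2, 10, 6), dx_mm = 0.5, dt_s = 1 / 1.2)
#' dim(dm)
#' @export
diameter_matrix <- function(values, dx_mm = 0.5, dt_s = 1 / 1.2,
                            total_length_mm = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (dx_mm <= 0 || dt_s <= 0) {
    abort("`dx_mm` and `dt_s` must be positive.")
  }
  if (any(values < 0, na.rm = TRUE)) {
    abort("Diameters must be >= 0; use NA for missing measurements.")
  }
  structure(
    list(
      values = values,
      dx_mm = as.numeric(dx_mm),
      dt_s = as.numeric(dt_s),
      total_length_mm = as.numeric(total_length_mm %||% (nrow(values) * dx_mm))
    ),
    class = "diameter_matrix"
  )
}

#' @export
dim.diameter_matrix <- function(x) dim(x$values)

#' Bin-centre positions (mm) of a diameter matrix
#' @param dm A [diameter_matrix()].
#' @return Numeric vector of positions along the gut, oral end first.
#' @export
st_positions <- function(dm) (seq_len(nrow(dm$values)) - 0.5) * dm$dx_mm

#' Frame times (s) of a diameter matrix
#' @param dm A [diameter_matrix()].
#' @return Numeric vector of frame times starting at 0.
#' @export
st_times <- function(dm) (seq_len(ncol(dm$values)) - 1) * dm$dt_s

#' @export
print.diameter_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<diameter_matrix> %d positions x %d frames (dx = %g mm, dt = %g s, length = %g mm)\n",
    d[1], d[2], x$dx_mm, x$dt_s, x$total_length_mm
  ))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "  diameters %.3f-%.3f mm, %d missing cells\n",
    rng[1], rng[2], sum(is.na(x$values))
  ))
  invisible(x)
}

#' @method as_tibble diameter_matrix
#' @export
as_tibble.diameter_matrix <- function(x, ...) {
  pos <- st_positions(x)
  tim <- st_times(x)
  tibble(
    pos_mm = rep(pos, times = length(tim)),
    time_s = rep(tim, each = length(pos)),
    diameter_mm = as.vector(x$values)
  )
}

#' Write a diameter matrix to delimited text
#'
#' Rows are positions (oral first), columns frames; the first line is a
#' comment carrying the calibration so that [read_diameter_matrix()] round
#' trips losslessly. Missing cells use the token `NA`.
#'
#' @param dm A [diameter_matrix()].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_diameter_matrix <- function(dm, path, sep = ",") {
  header <- sprintf(
    "# stmapr diameter_matrix dx_mm=%.10g dt_s=%.10g total_length_mm=%.10g",
    dm$dx_mm, dm$dt_s, dm$total_length_mm
  )
  body <- apply(dm$values, 1, function(r) {
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = sep)
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a diameter matrix from delimited text
#'
#' Accepts files written by [write_diameter_matrix()] (calibration is taken
#' from the header comment) or plain delimited numeric matrices, in which
#' case `dx_mm` and `dt_s` must be given. Any cell other than a number or the
#' `NA` token is a parse error naming the offending row and column.
#'
#' @param path File to read.
#' @param dx_mm,dt_s,total_length_mm Calibration, overriding any header.
#' @param sep Field separator (default comma).
#' @return A [diameter_matrix()].
#' @export
read_diameter_matrix <- function(path, dx_mm = NULL, dt_s = NULL,
                                 total_length_mm = NULL, sep = ",") {
  lines <- readLines(path)
  meta <- list()
  if (length(lines) && startsWith(lines[1], "#")) {
    for (kv in regmatches(lines[1], gregexpr("[a-z_]+=[-0-9.eE+]+", lines[1]))[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      meta[[p[1]]] <- as.numeric(p[2])
    }
    lines <- lines[-1]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("No data rows in '%s'.", path))
  cells <- strsplit(lines, sep, fixed = TRUE)
  ncols <- length(cells[[1]])
  vals <- matrix(NA_real_, nrow = length(cells), ncol = ncols)
  for (i in seq_along(cells)) {
    row <- trimws(cells[[i]])
    if (length(row) != ncols) {
      abort(sprintf(
        "Ragged matrix in '%s': row %d has %d fields, expected %d.",
        path, i, length(row), ncols
      ))
    }
    num <- suppressWarnings(as.numeric(row))
    bad <- which(is.na(num) & row != "NA")
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric cell '%s' in '%s' at row %d, column %d.",
        row[bad[1]], path, i, bad[1]
      ))
    }
    vals[i, ] <- num
  }
  diameter_matrix(
    vals,
    dx_mm = dx_mm %||% meta$dx_mm %||% 0.5,
    dt_s = dt_s %||% meta$dt_s %||% (1 / 1.2),
    total_length_mm = total_length_mm %||% meta$total_length_mm
  )
}
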