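# Programmatic fixtures used across test files.

# a stack of frames each containing a solid axis-aligned rectangle:
# rows row0..row1 (long axis), width_px columns centred in a canvas
rect_stack <- function(n_frames = 1, rows = 1:40, width_px = 12,
                       canvas = c(60, 40), px_per_mm = 10, fps = 1.2,
                       col0 = 10) {
  frames <- replicate(n_frames, {
    f <- matrix(FALSE, canvas[1], canvas[2])
    f[rows, col0:(col0 + width_px - 1)] <- TRUE
    f
  }, simplify = FALSE)
  mask_stack(frames, px_per_mm = px_per_mm, fps = fps)
}

# collinear propagating cell set spanning `distance_mm` with r2 = 1
linear_cells <- function(distance_mm, n = 5, start_mm = 10, amplitude = 0.5) {
  tibble::tibble(
    event_id = 1L,
    pos_mm = seq(start_mm, start_mm + distance_mm, length.out = n),
    time_s = seq(0, n - 1),
    amplitude_mm = amplitude
  )
}

# one-row cell tables stacked into an event set with prescribed features,
# classified directly through the distance / r2 rules
classify_feature_grid <- function(distance_mm, r2) {
  classify_event(distance_mm, r2)
}
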