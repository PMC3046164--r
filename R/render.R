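#' Random texel background
#'
#' The background visible throughout a session: every texel is independently
#' gray or white with probability 1/2.  Frames are integer matrices with
#' `texels_y` rows and `texels_x` columns holding 8-bit luminance codes.
#'
#' @param geometry a [display_geometry()].
#' @param texture_seed integer seed for the texture.
#' @return Integer matrix of luminance codes (class `texel_frame`).
#' @export
make_background <- function(geometry = display_geometry(), texture_seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(texture_seed)
  lum <- geometry$luminance
  f <- matrix(sample(c(lum[["gray"]], lum[["white"]]),
                     geometry$texels_x * geometry$texels_y, replace = TRUE),
              nrow = geometry$texels_y, ncol = geometry$texels_x)
  storage.mode(f) <- "integer"
  class(f) <- c("texel_frame", class(f))
  f
}

#' Back-and-forth motion path
#'
#' Horizontal offsets for the visible epoch: 133 ms at the display refresh
#' rate (10 frames at 75 Hz).  Offsets start at zero, rise to the full
#' excursion over the first half of the epoch and return to zero over the
#' second half; each offset is snapped to a whole number of texels.
#'
#' @param geometry a [display_geometry()].
#' @param excursion_deg maximum rightward offset in degrees.
#' @param duration_s duration of the visible epoch in seconds.
#' @return Object of class `motion_path`: list with `offsets_deg` (nominal),
#'   `offsets_tex` (snapped), `duration_frames` and `excursion_deg`.
#' @export
motion_path <- function(geometry = display_geometry(),
                        excursion_deg = 1.84, duration_s = 0.133) {
  k <- as.integer(round(duration_s * geometry$refresh_hz))
  stopifnot(k >= 2)
  a <- as.integer(ceiling(k / 2))
  up <- seq(0, 1, length.out = a)
  down <- rev(seq(0, 1, length.out = k - a + 1L))[-1]
  frac <- c(up, down)
  max_tex <- deg_to_texels(excursion_deg, geometry)
  out <- list(offsets_deg = frac * excursion_deg,
              offsets_tex = as.integer(round(frac * max_tex)),
              duration_frames = k,
              excursion_deg = excursion_deg)
  class(out) <- "motion_path"
  out
}

#' Texel footprint of a layout at a horizontal offset
#'
#' Logical mask of the texels covered by the bars of `layout` when displaced
#' `offset_tex` texels to the right.
#'
#' @param layout a `bar_layout`.
#' @param offset_tex integer horizontal offset in texels.
#' @param geometry a [display_geometry()].
#' @return Logical matrix of the same shape as a frame.
#' @export
footprint_mask <- function(layout, offset_tex = 0L, geometry = display_geometry()) {
  m <- matrix(FALSE, nrow = geometry$texels_y, ncol = geometry$texels_x)
  b <- layout$bars
  for (i in seq_len(nrow(b))) {
    cols <- (b$x_tex[i] + offset_tex + 1L):(b$x_tex[i] + offset_tex + b$w_tex[i])
    rows <- (b$y_tex[i] + 1L):(b$y_tex[i] + b$h_tex[i])
    if (min(cols) < 1L || max(cols) > geometry$texels_x ||
        min(rows) < 1L || max(rows) > geometry$texels_y)
      stop(sprintf("bar %d pushed off screen at offset %d texels", i, offset_tex))
    m[rows, cols] <- TRUE
  }
  m
}

new_frame_sequence <- function(frames, condition, duration_frames, path) {
  out <- list(frames = frames, condition = condition,
              duration_frames = as.integer(duration_frames), path = path)
  class(out) <- "frame_sequence"
  out
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("Frame sequence: %s motion, %d visible frames (+%d after), %dx%d texels\n",
              x$condition, x$duration_frames,
              length(x$frames) - x$duration_frames,
              nrow(x$frames[[1]]), ncol(x$frames[[1]])))
  invisible(x)
}

#' Render a first-order (luminance-defined) motion sequence
#'
#' Each visible frame is the background with every bar footprint, displaced
#' along the motion path, painted black.  After the visible epoch the bars
#' disappear and the frames equal the background texel for texel.
#'
#' @param layout a `bar_layout` from [sample_layout()].
#' @param path a [motion_path()].
#' @param background background frame; generated from `texture_seed` if `NULL`.
#' @param geometry a [display_geometry()].
#' @param texture_seed seed used when `background` is `NULL`.
#' @param n_after number of post-epoch background frames to append.
#' @return A `frame_sequence` with `condition = "first_order"`.
#' @export
render_first_order <- function(layout, path = motion_path(geometry),
                               background = NULL,
                               geometry = display_geometry(),
                               texture_seed = 1L, n_after = 1L) {
  if (is.null(background)) background <- make_background(geometry, texture_seed)
  black <- geometry$luminance[["black"]]
  frames <- vector("list", path$duration_frames + n_after)
  for (t in seq_len(path$duration_frames)) {
    f <- background
    f[footprint_mask(layout, path$offsets_tex[t], geometry)] <- black
    frames[[t]] <- f
  }
  for (t in seq_len(n_after))
    frames[[path$duration_frames + t]] <- background
  new_frame_sequence(frames, "first_order", path$duration_frames, path)
}

#' Render a second-order (contrast-defined) motion sequence
#'
#' The bars consist of texels identical to the background: at each visible
#' frame the texels inside every bar's current footprint have their polarity
#' flipped (gray becomes white and vice versa) and the footprint then moves
#' to the next offset of the path.  No frame ever contains a black texel, and
#' because gray and white are exchangeable under the Bernoulli(1/2) texture,
#' no single frame carries any luminance signature of the bars --- the items
#' are defined only by the frame-to-frame contrast changes.
#'
#' With `invert_mode = "persistent"` the texture state evolves: a flip stays
#' until the footprint revisits the texel (the classic recipe).  With
#' `"fresh"` each frame flips relative to the untouched background instead.
#' After the visible epoch the untouched background reappears.
#'
#' @inheritParams render_first_order
#' @param invert_mode `"persistent"` (default) or `"fresh"`; see Details.
#' @return A `frame_sequence` with `condition = "second_order"`.
#' @export
render_second_order <- function(layout, path = motion_path(geometry),
                                background = NULL,
                                geometry = display_geometry(),
                                texture_seed = 1L,
                                invert_mode = c("persistent", "fresh"),
                                n_after = 1L) {
  invert_mode <- match.arg(invert_mode)
  if (is.null(background)) background <- make_background(geometry, texture_seed)
  gray <- geometry$luminance[["gray"]]
  white <- geometry$luminance[["white"]]
  flip_sum <- gray + white  # v -> flip_sum - v swaps the two polarities
  frames <- vector("list", path$duration_frames + n_after)
  state <- background
  for (t in seq_len(path$duration_frames)) {
    m <- footprint_mask(layout, path$offsets_tex[t], geometry)
    if (invert_mode == "persistent") {
      state[m] <- flip_sum - state[m]
      frames[[t]] <- state
    } else {
      f <- background
      f[m] <- flip_sum - f[m]
      frames[[t]] <- f
    }
  }
  for (t in seq_len(n_after))
    frames[[path$duration_frames + t]] <- background
  new_frame_sequence(frames, "second_order", path$duration_frames, path)
}
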