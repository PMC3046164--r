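#' Display geometry for stimulus generation
#'
#' Bundles the screen, texture and viewing parameters that every stimulus
#' routine needs, together with the degree-to-pixel conversion convention.
#' The defaults describe a 17-inch 4:3 monitor at 1024x768 viewed at 58 cm:
#' at that distance one degree of visual angle subtends about 30.77 pixels,
#' which makes the 0.13-degree bar width exactly one 4-pixel texel column.
#'
#' @param screen_px integer length-2 vector, screen width and height in
#'   pixels.  Both must be multiples of `texel_px`.
#' @param refresh_hz display refresh rate in frames per second.
#' @param texel_px side length in pixels of one background texture square
#'   ("texel").
#' @param px_per_deg pixels per degree of visual angle.
#' @param luminance named integer vector with the 8-bit codes used for
#'   `black`, `gray` and `white` texels.
#'
#' @return An object of class `display_geometry`: a list with the arguments
#'   above plus the derived texel-grid dimensions (`texels_x`, `texels_y`),
#'   the screen extent in degrees (`width_deg`, `height_deg`) and the angular
#'   size of one texel (`texel_deg`).
#' @examples
#' geom <- display_geometry()
#' geom$texels_x  # 256 texel columns
#' @export
display_geometry <- function(screen_px = c(1024L, 768L),
                             refresh_hz = 75,
                             texel_px = 4L,
                             px_per_deg = 30.77,
                             luminance = c(black = 0L, gray = 128L, white = 255L)) {
  stopifnot(length(screen_px) == 2, screen_px > 0,
            refresh_hz > 0, texel_px > 0, px_per_deg > 0)
  if (any(screen_px %% texel_px != 0))
    stop("screen dimensions must be integer multiples of texel_px")
  if (!all(c("black", "gray", "white") %in% names(luminance)))
    stop("luminance must name black, gray and white levels")
  g <- list(
    screen_px = as.integer(screen_px),
    refresh_hz = refresh_hz,
    texel_px = as.integer(texel_px),
    px_per_deg = px_per_deg,
    luminance = luminance,
    texels_x = as.integer(screen_px[1] %/% texel_px),
    texels_y = as.integer(screen_px[2] %/% texel_px),
    width_deg = screen_px[1] / px_per_deg,
    height_deg = screen_px[2] / px_per_deg,
    texel_deg = texel_px / px_per_deg
  )
  class(g) <- "display_geometry"
  g
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf("Display geometry: %dx%d px @ %g Hz, %d-px texels (%dx%d grid)\n",
              x$screen_px[1], x$screen_px[2], x$refresh_hz, x$texel_px,
              x$texels_x, x$texels_y))
  cat(sprintf("  %.2f px/deg; screen %.2f x %.2f deg; texel %.3f deg\n",
              x$px_per_deg, x$width_deg, x$height_deg, x$texel_deg))
  invisible(x)
}

#' Convert a visual angle to a whole number of texels
#'
#' @param deg non-negative angle in degrees of visual angle.
#' @param geometry a [display_geometry()].
#' @return Integer count of texels, `round(deg * px_per_deg / texel_px)`.
#' @examples
#' deg_to_texels(0.13)  # one texel column: the bar width
#' deg_to_texels(1.84)  # 14 texels: the motion excursion
#' @export
deg_to_texels <- function(deg, geometry = display_geometry()) {
  if (any(deg < 0)) stop("deg must be non-negative")
  as.integer(round(deg * geometry$px_per_deg / geometry$texel_px))
}

#' Convert degrees of visual angle to pixels
#'
#' @inheritParams deg_to_texels
#' @return Pixel count (not rounded).
#' @export
deg_to_px <- function(deg, geometry = display_geometry()) {
  if (any(deg < 0)) stop("deg must be non-negative")
  deg * geometry$px_per_deg
}
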