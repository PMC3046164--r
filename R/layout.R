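#' Sample a bar layout for one trial
#'
#' Places `n` vertical bars on the cells of a 17 x 12 imaginary grid covering
#' the screen.  Each bar is 0.13 deg wide and, with equal probability, either
#' 2.08 or 3.12 deg tall.  The grid pitch guarantees the spacing rule: any
#' two bars are at least 1.84 deg apart horizontally or at least 0.98 deg
#' apart vertically (centre-to-centre).  A margin equal to the rightward
#' motion excursion (1.84 deg) is reserved at the right screen edge so that
#' no bar leaves the screen while moving, and bars must fit vertically on the
#' screen.
#'
#' Placement is by rejection sampling: cells are drawn uniformly and a draw
#' is rejected if the cell is taken or the bar footprint (including motion
#' headroom) leaves the screen.  If no complete layout is found within
#' `max_attempts` draws, or `n` exceeds the number of grid cells, a capacity
#' error is raised.
#'
#' @param n number of bars (numerosity), a positive integer.
#' @param geometry a [display_geometry()].
#' @param seed integer seed; the layout is reproducible given the seed.
#' @param grid_dim integer length-2: columns and rows of the placement grid.
#' @param bar_width_deg bar width in degrees.
#' @param bar_heights_deg the two admissible bar heights in degrees.
#' @param min_dx_deg,min_dy_deg the horizontal / vertical spacing minima.
#' @param motion_margin_deg rightward headroom reserved for the motion.
#' @param max_attempts rejection-sampling budget.
#' @return An object of class `bar_layout`: a list with `numerosity`, a
#'   `bars` data frame (grid cell, position of the top-left corner in degrees
#'   and in texels, width and height in both units) and `mean_height_deg`,
#'   the trial's bar-height covariate.
#' @examples
#' lay <- sample_layout(30, seed = 1)
#' lay$mean_height_deg
#' @export
sample_layout <- function(n, geometry = display_geometry(), seed = 1L,
                          grid_dim = c(17L, 12L),
                          bar_width_deg = 0.13,
                          bar_heights_deg = c(2.08, 3.12),
                          min_dx_deg = 1.84, min_dy_deg = 0.98,
                          motion_margin_deg = 1.84,
                          max_attempts = 10000L) {
  if (n < 1) stop("n must be >= 1")
  n_cells <- prod(grid_dim)
  if (n > n_cells)
    stop(sprintf("capacity error: cannot place %d bars on a %dx%d grid (%d cells)",
                 n, grid_dim[1], grid_dim[2], n_cells))
  pitch_x <- geometry$width_deg / grid_dim[1]
  pitch_y <- geometry$height_deg / grid_dim[2]
  if (pitch_x < min_dx_deg || pitch_y < min_dy_deg)
    stop("grid pitch too small to guarantee the spacing constraints")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  taken <- matrix(FALSE, nrow = grid_dim[1], ncol = grid_dim[2])
  bars <- vector("list", n)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(
        "capacity error: placed only %d of %d bars on the %dx%d grid within %d attempts",
        placed, n, grid_dim[1], grid_dim[2], max_attempts))
    col <- sample.int(grid_dim[1], 1L)
    row <- sample.int(grid_dim[2], 1L)
    if (taken[col, row]) next
    h <- sample(bar_heights_deg, 1L)
    x <- (col - 1L) * pitch_x
    y <- (row - 1L) * pitch_y
    # on-screen including the rightward motion headroom
    if (x + bar_width_deg + motion_margin_deg > geometry$width_deg) next
    if (y + h > geometry$height_deg) next
    taken[col, row] <- TRUE
    placed <- placed + 1L
    bars[[placed]] <- data.frame(col = col, row = row,
                                 x_deg = x, y_deg = y,
                                 w_deg = bar_width_deg, h_deg = h)
  }
  bars <- do.call(rbind, bars)
  bars$x_tex <- as.integer(round(bars$x_deg * geometry$px_per_deg / geometry$texel_px))
  bars$y_tex <- as.integer(round(bars$y_deg * geometry$px_per_deg / geometry$texel_px))
  bars$w_tex <- pmax(1L, deg_to_texels(bars$w_deg, geometry))
  bars$h_tex <- deg_to_texels(bars$h_deg, geometry)
  out <- list(numerosity = as.integer(n), bars = bars,
              grid_dim = as.integer(grid_dim),
              mean_height_deg = mean(bars$h_deg),
              min_dx_deg = min_dx_deg, min_dy_deg = min_dy_deg,
              motion_margin_deg = motion_margin_deg)
  class(out) <- "bar_layout"
  out
}

#' @export
print.bar_layout <- function(x, ...) {
  cat(sprintf("Bar layout: %d bars on a %dx%d grid, mean height %.3f deg\n",
              x$numerosity, x$grid_dim[1], x$grid_dim[2], x$mean_height_deg))
  invisible(x)
}

#' Verify a layout against the spacing and screen constraints
#'
#' Independent brute-force checker: examines every bar pair and every bar
#' footprint directly, without relying on the sampler's grid bookkeeping.
#' For each pair the disjunctive spacing rule must hold: horizontal
#' centre-to-centre distance >= `min_dx_deg` OR vertical centre-to-centre
#' distance >= `min_dy_deg`.
#'
#' @param layout a `bar_layout`.
#' @param geometry a [display_geometry()].
#' @return `TRUE` if all constraints hold, otherwise a character vector
#'   describing each violation.
#' @export
verify_layout <- function(layout, geometry = display_geometry()) {
  b <- layout$bars
  bad <- character(0)
  if (nrow(b) != layout$numerosity)
    bad <- c(bad, sprintf("numerosity %d but %d bars", layout$numerosity, nrow(b)))
  for (i in seq_len(nrow(b))) {
    if (b$x_deg[i] < 0 || b$y_deg[i] < 0 ||
        b$x_deg[i] + b$w_deg[i] + layout$motion_margin_deg > geometry$width_deg + 1e-9 ||
        b$y_deg[i] + b$h_deg[i] > geometry$height_deg + 1e-9)
      bad <- c(bad, sprintf("bar %d off screen (with motion margin)", i))
  }
  cells <- paste(b$col, b$row)
  if (anyDuplicated(cells))
    bad <- c(bad, "duplicate grid cells")
  cx <- b$x_deg + b$w_deg / 2
  cy <- b$y_deg + b$h_deg / 2
  n <- nrow(b)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        dx <- abs(cx[i] - cx[j])
        dy <- abs(cy[i] - cy[j])
        if (dx < layout$min_dx_deg - 1e-9 && dy < layout$min_dy_deg - 1e-9)
          bad <- c(bad, sprintf("bars %d,%d too close (dx=%.3f, dy=%.3f)", i, j, dx, dy))
      }
    }
  }
  if (length(bad) == 0) TRUE else bad
}

#' Write / read a layout as JSON
#'
#' @param layout a `bar_layout`.
#' @param path file path.
#' @return `write_layout_json` returns `path` invisibly; `read_layout_json`
#'   returns a `bar_layout`.
#' @export
write_layout_json <- function(layout, path) {
  x <- unclass(layout)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$numerosity <- as.integer(x$numerosity)
  x$grid_dim <- as.integer(x$grid_dim)
  class(x) <- "bar_layout"
  x
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
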