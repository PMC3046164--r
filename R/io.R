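#' Export a texel frame as PGM or PNG
#'
#' PGM files use the plain-text P2 dialect; PNG files are written with the
#' png package.  Each texel becomes one image pixel (images are at texel
#' resolution, not screen-pixel resolution).
#'
#' @param frame integer luminance matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(frame, path) {
  f <- unclass(frame)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(f), nrow(f)), "255"), con)
  apply_rows <- apply(f, 1, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("only plain-text P2 PGM is supported")
  nx <- as.integer(toks[2]); ny <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
}

#' @rdname write_pgm
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(unclass(frame) / 255, path)
  invisible(path)
}

#' Export a frame sequence to a directory
#'
#' Writes one image per frame with a zero-padded index
#' (`frame001.pgm`, ...).
#'
#' @param fseq a `frame_sequence`.
#' @param dir output directory (created if needed).
#' @param format `"pgm"` (plain-text) or `"png"`.
#' @param prefix file-name prefix.
#' @param geometry unused placeholder for dialect options; kept for call
#'   symmetry with the renderers.
#' @return Character vector of the written paths, invisibly.
#' @export
write_frames <- function(fseq, dir, format = c("pgm", "png"),
                         prefix = "frame", geometry = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(fseq$frames))
  for (t in seq_along(fseq$frames)) {
    p <- file.path(dir, sprintf("%s%03d.%s", prefix, t, format))
    if (format == "pgm") write_pgm(fseq$frames[[t]], p)
    else write_frame_png(fseq$frames[[t]], p)
    paths[t] <- p
  }
  invisible(paths)
}
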