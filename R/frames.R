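#' Frame sequence container
#'
#' An ordered stack of 8-bit grayscale frames with a fixed frame rate,
#' the raw material for every image-domain stage.  Frames are stored as
#' an `height x width x n` integer array; frame index origin is 0 in
#' all user-facing coordinates (frame `i` covers time `i / fps`
#' seconds).
#'
#' @param frames a `h x w x n` array (or a single `h x w` matrix) of
#'   grayscale values in `[0, 255]`.
#' @param fps frame rate in Hz; must be positive.
#' @return An object of class `frame_seq`.
#' @examples
#' fs <- frame_sequence(array(0L, c(4, 6, 10)), fps = 30)
#' n_frames(fs)
#' @export
frame_sequence <- function(frames, fps) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stopf("`frames` must be a h x w x n array")
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0)
    stopf("`fps` must be a positive number")
  if (anyNA(frames) || min(frames) < 0 || max(frames) > 255)
    stopf("frame values must lie in [0, 255] with no NAs")
  storage.mode(frames) <- "integer"
  structure(list(frames = frames, fps = as.numeric(fps)),
            class = "frame_seq")
}

#' @export
print.frame_seq <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_seq> %d frames of %d x %d px @ %g Hz (%.2f s)\n",
              d[3], d[1], d[2], x$fps, d[3] / x$fps))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq a [frame_sequence()].
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[3]

#' Extract one frame as a matrix
#' @param seq a [frame_sequence()].
#' @param i 0-based frame index.
#' @return A `h x w` numeric matrix.
#' @export
get_frame <- function(seq, i) {
  n <- n_frames(seq)
  if (!is_count(i + 1) || i < 0 || i >= n)
    stopf("frame index %s out of range [0, %d)", format(i), n)
  seq$frames[, , i + 1L, drop = TRUE] + 0
}

#' Region of interest
#'
#' A pixel rectangle in frame coordinates.  Coordinates are 0-based and
#' half-open: the rectangle covers columns `[x, x + width)` and rows
#' `[y, y + height)`.  Two roles exist: `"chest"` (ROI 1, drives phase
#' detection) and `"mouth"` (ROI 2, plume counting; the clinical layout
#' uses 250 x 200 px in front of the mouth).
#'
#' @param x,y top-left corner, 0-based pixels.
#' @param width,height extent in pixels, both positive.
#' @param role `"chest"` or `"mouth"`.
#' @return An object of class `roi`.
#' @export
roi <- function(x, y, width, height, role = c("chest", "mouth")) {
  role <- match.arg(role)
  for (v in list(x = x, y = y)) if (!is.numeric(v) || v < 0 || v != floor(v))
    stopf("roi x/y must be non-negative integers")
  if (!is_count(width) || !is_count(height))
    stopf("roi width/height must be positive integers")
  structure(list(x = as.integer(x), y = as.integer(y),
                 width = as.integer(width), height = as.integer(height),
                 role = role), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi:%s> x=%d y=%d %dx%d px\n", x$role, x$x, x$y,
              x$width, x$height))
  invisible(x)
}

# Error unless `r` lies fully inside a frame of `dim_hw = c(h, w)`.
#' @noRd
check_roi_inside <- function(r, dim_hw) {
  if (r$x + r$width > dim_hw[2] || r$y + r$height > dim_hw[1])
    stopf("%s ROI [%d,%d %dx%d] exceeds frame %d x %d",
          r$role, r$x, r$y, r$width, r$height, dim_hw[1], dim_hw[2])
  invisible(r)
}

# Submatrix of `frame` covered by roi `r` (0-based half-open rect).
#' @noRd
roi_pixels <- function(frame, r) {
  frame[(r$y + 1L):(r$y + r$height), (r$x + 1L):(r$x + r$width), drop = FALSE]
}
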