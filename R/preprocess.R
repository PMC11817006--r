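#' Denoising chain configuration
#'
#' Parameters for the per-frame preprocessing chain applied before
#' respiration tracking: percentile intensity normalization, then a
#' median filter (salt-and-pepper / impulse noise), a Gaussian filter
#' (residual ambient-air speckle), and a bilateral filter (smooths
#' while keeping the plume/background edges).  Defaults follow the
#' clinical pipeline: 5x5 median, 5x5 Gaussian, 9x9 bilateral.  A
#' kernel of 1 disables that filter.
#'
#' @param median_kernel,gaussian_kernel,bilateral_kernel odd window
#'   sizes in pixels.
#' @param gaussian_sigma Gaussian standard deviation in pixels; `NULL`
#'   derives it from the kernel by the conventional
#'   `0.3 * ((k - 1)/2 - 1) + 0.8` rule.
#' @param bilateral_sigma_space,bilateral_sigma_range spatial (pixels)
#'   and range (grayscale units) standard deviations of the bilateral
#'   filter.
#' @param normalize apply percentile normalization first?
#' @param normalize_low,normalize_high percentile bounds mapped to
#'   0 and 255.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(median_kernel = 5, gaussian_kernel = 5,
                          gaussian_sigma = NULL, bilateral_kernel = 9,
                          bilateral_sigma_space = 2,
                          bilateral_sigma_range = 25,
                          normalize = TRUE,
                          normalize_low = 1, normalize_high = 99) {
  cfg <- list(
    median_kernel = check_odd_kernel(median_kernel, "median"),
    gaussian_kernel = check_odd_kernel(gaussian_kernel, "Gaussian"),
    gaussian_sigma = gaussian_sigma,
    bilateral_kernel = check_odd_kernel(bilateral_kernel, "bilateral"),
    bilateral_sigma_space = bilateral_sigma_space,
    bilateral_sigma_range = bilateral_sigma_range,
    normalize = isTRUE(normalize),
    normalize_low = normalize_low, normalize_high = normalize_high)
  if (!is.null(gaussian_sigma) && gaussian_sigma <= 0)
    stopf("gaussian_sigma must be positive (or NULL for auto)")
  if (bilateral_sigma_space <= 0 || bilateral_sigma_range <= 0)
    stopf("bilateral sigmas must be positive")
  if (!(normalize_low >= 0 && normalize_low < normalize_high &&
        normalize_high <= 100))
    stopf("need 0 <= normalize_low < normalize_high <= 100")
  structure(cfg, class = "filter_config")
}

#' @noRd
auto_sigma <- function(k) 0.3 * ((k - 1) / 2 - 1) + 0.8

#' Percentile intensity normalization
#'
#' Replaces the manual dynamic-range scaling done at acquisition time
#' with a deterministic rule: the sequence-global `low_pct` and
#' `high_pct` intensity percentiles map linearly to 0 and 255, values
#' outside are clipped.  Operating on the whole sequence (not per
#' frame) keeps frame-to-frame differences meaningful.
#'
#' @param seq a [frame_sequence()].
#' @param low_pct,high_pct percentile bounds, `0 <= low < high <= 100`.
#' @return A normalized [frame_sequence()].  A constant sequence (zero
#'   dynamic range) yields all-zero frames with a warning.
#' @export
normalize_sequence <- function(seq, low_pct = 1, high_pct = 99) {
  stopifnot(inherits(seq, "frame_seq"))
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100))
    stopf("need 0 <= low_pct < high_pct <= 100")
  qs <- quantile(seq$frames, c(low_pct, high_pct) / 100, names = FALSE)
  if (qs[2] <= qs[1]) {
    warnf("sequence has zero dynamic range between percentiles %g and %g; returning all-zero frames",
          low_pct, high_pct)
    return(frame_sequence(array(0L, dim(seq$frames)), seq$fps))
  }
  scaled <- round(clamp((seq$frames - qs[1]) / (qs[2] - qs[1]) * 255))
  frame_sequence(array(as.integer(scaled), dim(seq$frames)), seq$fps)
}

#' Median filter
#'
#' Each output pixel is the median of the `kernel x kernel` window
#' centered on it; borders use symmetric reflection.  The classic
#' remover of salt-and-pepper impulses.
#'
#' @param frame a numeric matrix.
#' @param kernel odd window size in pixels.
#' @return A filtered numeric matrix of the same shape.
#' @export
median_filter <- function(frame, kernel = 5) {
  kernel <- check_odd_kernel(kernel, "median")
  stopifnot(is.matrix(frame))
  if (kernel == 1L) return(frame + 0)
  median_filter_cpp(frame + 0, kernel)
}

#' Gaussian filter
#'
#' Convolution with a normalized, truncated Gaussian kernel (weights
#' sum to 1), symmetric-reflect borders.
#'
#' @inheritParams median_filter
#' @param sigma standard deviation in pixels; `NULL` derives it from
#'   the kernel size.
#' @return A filtered numeric matrix.
#' @export
gaussian_filter <- function(frame, kernel = 5, sigma = NULL) {
  kernel <- check_odd_kernel(kernel, "Gaussian")
  stopifnot(is.matrix(frame))
  if (is.null(sigma)) sigma <- auto_sigma(kernel)
  if (!is.numeric(sigma) || sigma <= 0) stopf("sigma must be positive")
  if (kernel == 1L) return(frame + 0)
  gaussian_filter_cpp(frame + 0, kernel, sigma)
}

#' Bilateral filter
#'
#' Edge-preserving smoother: each neighbor's weight is the product of a
#' spatial Gaussian in pixel distance and a range Gaussian in intensity
#' difference, normalized to sum to 1.  Neighbors across an edge get
#' negligible range weight, so plateaus are smoothed but the step
#' between them survives.
#'
#' @inheritParams median_filter
#' @param sigma_space spatial standard deviation, pixels.
#' @param sigma_range range standard deviation, grayscale units.
#' @return A filtered numeric matrix.
#' @export
bilateral_filter <- function(frame, kernel = 9, sigma_space = 2,
                             sigma_range = 25) {
  kernel <- check_odd_kernel(kernel, "bilateral")
  stopifnot(is.matrix(frame))
  if (sigma_space <= 0 || sigma_range <= 0) stopf("sigmas must be positive")
  if (kernel == 1L) return(frame + 0)
  bilateral_filter_cpp(frame + 0, kernel, sigma_space, sigma_range)
}

#' Apply the full denoising chain to a sequence
#'
#' Order is fixed: normalize, median, Gaussian, bilateral.  Each filter
#' output is rounded back to 8-bit before the next stage, mirroring an
#' integer-image pipeline.
#'
#' @param seq a [frame_sequence()].
#' @param cfg a [filter_config()].
#' @return The preprocessed [frame_sequence()].
#' @export
preprocess_sequence <- function(seq, cfg = filter_config()) {
  stopifnot(inherits(seq, "frame_seq"), inherits(cfg, "filter_config"))
  if (cfg$normalize)
    seq <- normalize_sequence(seq, cfg$normalize_low, cfg$normalize_high)
  sigma <- if (is.null(cfg$gaussian_sigma)) auto_sigma(cfg$gaussian_kernel)
           else cfg$gaussian_sigma
  d <- dim(seq$frames)
  out <- array(0L, d)
  for (i in seq_len(d[3])) {
    f <- seq$frames[, , i] + 0
    if (cfg$median_kernel > 1L)
      f <- median_filter_cpp(f, cfg$median_kernel)
    if (cfg$gaussian_kernel > 1L)
      f <- round(gaussian_filter_cpp(f, cfg$gaussian_kernel, sigma))
    if (cfg$bilateral_kernel > 1L)
      f <- round(bilateral_filter_cpp(f, cfg$bilateral_kernel,
                                      cfg$bilateral_sigma_space,
                                      cfg$bilateral_sigma_range))
    out[, , i] <- as.integer(clamp(f))
  }
  frame_sequence(out, seq$fps)
}
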