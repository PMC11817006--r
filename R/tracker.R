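#' Tracker configuration
#'
#' Thresholds and window for the dual-ROI respiration tracker.  The
#' flow threshold suppresses sub-threshold chest jitter (coughs,
#' vibration): the phase state machine only switches when the mean
#' vertical flow magnitude exceeds it.  The difference threshold is the
#' minimum per-pixel intensity rise counted as plume.  Analysis is
#' restricted to a window (default the first 40 s, when natural
#' breathing is most regular).
#'
#' @param flow_threshold pixels/frame; phase holds while
#'   `|flow| <= flow_threshold`.
#' @param diff_threshold grayscale units; a mouth-ROI pixel counts when
#'   `curr - prev >= diff_threshold`.
#' @param window_start,window_end analysis window in seconds,
#'   half-open `[start, end)`.
#' @param chest_sign_convention `TRUE` (default) means a rising chest
#'   (negative vertical flow, image y grows downward) is inspiration.
#' @param reset_on_inspiration `TRUE` (default): the difference
#'   reference simply tracks the previous frame, so entering
#'   inspiration discards any stale reference; `FALSE` freezes the
#'   reference over non-expiration frames instead.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(flow_threshold = 0.05, diff_threshold = 1,
                           window_start = 0, window_end = 40,
                           chest_sign_convention = TRUE,
                           reset_on_inspiration = TRUE) {
  if (flow_threshold < 0 || diff_threshold < 0)
    stopf("thresholds must be >= 0")
  if (!(window_end > window_start) || window_start < 0)
    stopf("need 0 <= window_start < window_end")
  structure(list(flow_threshold = flow_threshold,
                 diff_threshold = diff_threshold,
                 window_start = window_start, window_end = window_end,
                 chest_sign_convention = isTRUE(chest_sign_convention),
                 reset_on_inspiration = isTRUE(reset_on_inspiration)),
            class = "tracker_config")
}

#' Mean vertical optical flow over the chest ROI
#'
#' Dense two-frame Lucas-Kanade flow computed for every ROI pixel with
#' a usable structure tensor, averaged.  Positive values are downward
#' in image coordinates.
#'
#' @param prev_frame,curr_frame numeric matrices of identical shape.
#' @param roi a [roi()] fully inside the frame.
#' @return Mean vertical displacement in pixels/frame (scalar), with
#'   attributes `vx` (mean horizontal component) and `n_valid` (pixels
#'   that contributed).
#' @export
chest_flow <- function(prev_frame, curr_frame, roi) {
  stopifnot(is.matrix(prev_frame), is.matrix(curr_frame),
            inherits(roi, "roi"))
  if (!all(dim(prev_frame) == dim(curr_frame)))
    stopf("frames differ in shape")
  check_roi_inside(roi, dim(prev_frame))
  v <- lk_flow_cpp(prev_frame + 0, curr_frame + 0,
                   roi$x, roi$y, roi$width, roi$height)
  structure(v[2], vx = v[1], n_valid = as.integer(v[3]))
}

#' Phase state-machine update
#'
#' One step of the inspiration/expiration state machine: flow at or
#' below the threshold in magnitude holds the current state; stronger
#' flow sets the phase by its sign under the configured convention
#' (chest rising = negative vertical flow = inspiration by default).
#' The state before any supra-threshold flow is `"undetermined"`.
#'
#' @param state current phase, one of `"undetermined"`,
#'   `"inspiration"`, `"expiration"`.
#' @param flow mean vertical flow, pixels/frame.
#' @param cfg a [tracker_config()].
#' @return The new phase label.
#' @export
update_phase <- function(state, flow, cfg = tracker_config()) {
  state <- match.arg(state, c("undetermined", "inspiration", "expiration"))
  if (is.na(flow) || abs(flow) <= cfg$flow_threshold) return(state)
  up <- flow < 0
  if (cfg$chest_sign_convention) {
    if (up) "inspiration" else "expiration"
  } else {
    if (up) "expiration" else "inspiration"
  }
}

#' Count plume pixels by positive frame differencing
#'
#' Number of mouth-ROI pixels whose intensity rose by at least
#' `diff_threshold` between the two frames.  Negative changes (cooling)
#' never count.
#'
#' @inheritParams chest_flow
#' @param diff_threshold grayscale units.
#' @return Integer pixel count in `[0, roi area]`.
#' @export
count_plume_pixels <- function(prev_frame, curr_frame, roi,
                               diff_threshold = 1) {
  stopifnot(is.matrix(prev_frame), is.matrix(curr_frame),
            inherits(roi, "roi"))
  if (!all(dim(prev_frame) == dim(curr_frame)))
    stopf("frames differ in shape")
  check_roi_inside(roi, dim(prev_frame))
  sum(roi_pixels(curr_frame, roi) - roi_pixels(prev_frame, roi) >=
        diff_threshold)
}

#' Track respiration over a frame sequence
#'
#' Runs the dual-ROI procedure over the analysis window: per frame, the
#' chest-ROI flow updates the phase state machine; plume pixels are
#' counted in the mouth ROI only while the phase is expiration and are
#' 0 otherwise.  Phase-transition frames are recorded as expiration /
#' inspiration start indices.
#'
#' @param seq a [frame_sequence()] at least `window_end` seconds long.
#' @param chest_roi,mouth_roi [roi()] rectangles inside the frame.
#' @param cfg a [tracker_config()].
#' @return A `breath_trace`: a data.frame with columns `frame` (0-based
#'   index), `time_s`, `phase`, `plume_count`, carrying attributes
#'   `expiration_start_idx`, `inspiration_start_idx` (0-based frame
#'   indices), `fps` and `window`.
#' @export
track <- function(seq, chest_roi, mouth_roi, cfg = tracker_config()) {
  stopifnot(inherits(seq, "frame_seq"), inherits(cfg, "tracker_config"))
  check_roi_inside(chest_roi, dim(seq$frames)[1:2])
  check_roi_inside(mouth_roi, dim(seq$frames)[1:2])
  dur <- n_frames(seq) / seq$fps
  if (dur < cfg$window_end)
    stopf("video is %.2f s long but the analysis window requires %.2f s",
          dur, cfg$window_end)
  idx <- which((seq_len(n_frames(seq)) - 1) / seq$fps >= cfg$window_start &
               (seq_len(n_frames(seq)) - 1) / seq$fps < cfg$window_end)
  state <- "undetermined"
  phase <- character(length(idx))
  counts <- integer(length(idx))
  exp_start <- integer(0); insp_start <- integer(0)
  ref <- NULL    # difference reference frame
  for (k in seq_along(idx)) {
    i <- idx[k]                       # 1-based array index
    curr <- seq$frames[, , i] + 0
    if (i > 1L) {
      prev <- seq$frames[, , i - 1L] + 0
      fl <- chest_flow(prev, curr, chest_roi)
      new_state <- update_phase(state, fl, cfg)
    } else new_state <- state
    if (new_state != state) {
      if (new_state == "expiration") exp_start <- c(exp_start, i - 1L)
      if (new_state == "inspiration") insp_start <- c(insp_start, i - 1L)
    }
    state <- new_state
    phase[k] <- state
    if (state == "expiration" && !is.null(ref)) {
      counts[k] <- sum(roi_pixels(curr, mouth_roi) -
                         roi_pixels(ref, mouth_roi) >= cfg$diff_threshold)
      ref <- curr
    } else if (cfg$reset_on_inspiration || is.null(ref)) {
      ref <- curr                     # reference tracks previous frame
    }                                 # else: frozen until next expiration
  }
  out <- data.frame(frame = idx - 1L, time_s = (idx - 1L) / seq$fps,
                    phase = phase, plume_count = counts)
  structure(out, class = c("breath_trace", "data.frame"),
            expiration_start_idx = exp_start,
            inspiration_start_idx = insp_start,
            fps = seq$fps,
            window = c(cfg$window_start, cfg$window_end))
}

#' @export
print.breath_trace <- function(x, ...) {
  cat(sprintf("<breath_trace> %d frames @ %g Hz, window [%g, %g) s\n",
              nrow(x), attr(x, "fps"), attr(x, "window")[1],
              attr(x, "window")[2]))
  cat(sprintf("  %d expiration starts, %d inspiration starts, total plume %d px\n",
              length(attr(x, "expiration_start_idx")),
              length(attr(x, "inspiration_start_idx")),
              sum(x$plume_count)))
  invisible(x)
}

#' Plot a breath trace
#'
#' Upper panel: phase (0 = expiration, 1 = inspiration); lower panel:
#' per-frame plume pixel count, with dashed lines at expiration
#' (purple) and inspiration (yellow) starts.
#'
#' @param x a `breath_trace`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.breath_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  ph <- ifelse(x$phase == "inspiration", 1,
               ifelse(x$phase == "expiration", 0, NA))
  plot(x$time_s, ph, type = "s", ylab = "phase (0=exp, 1=insp)",
       xlab = "", yaxt = "n", ...)
  graphics::axis(2, at = c(0, 1))
  plot(x$time_s, x$plume_count, type = "l", ylab = "plume pixels",
       xlab = "time (s)")
  fps <- attr(x, "fps")
  graphics::abline(v = attr(x, "expiration_start_idx") / fps,
                   col = "purple", lty = 2)
  graphics::abline(v = attr(x, "inspiration_start_idx") / fps,
                   col = "goldenrod", lty = 2)
  invisible(x)
}
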