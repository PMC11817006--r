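#' Total respiratory volume (TRV)
#'
#' Sum of per-frame plume pixel counts over the analysis window: an
#' uncalibrated plume-area proxy for exhaled volume, accumulated across
#' all expiratory phases.
#'
#' @param trace a `breath_trace` from [track()].
#' @return Non-negative numeric scalar.
#' @export
total_volume <- function(trace) {
  stopifnot(inherits(trace, "breath_trace"), nrow(trace) > 0)
  sum(trace$plume_count)
}

#' Mean interval between phase starts
#'
#' Mean of consecutive differences of the start times of the chosen
#' phase (ADE for expirations, ADI for inspirations).  Fewer than two
#' starts leaves the interval undefined: the result is `NA` carrying
#' attribute `undefined = TRUE`, so callers can distinguish "no
#' information" from an interval of zero.
#'
#' @param start_times numeric vector of start times in seconds,
#'   strictly increasing.
#' @return Mean interval in seconds, or flagged `NA`.
#' @export
mean_interval <- function(start_times) {
  if (length(start_times) < 2)
    return(structure(NA_real_, undefined = TRUE))
  if (any(diff(start_times) <= 0))
    stopf("start times must be strictly increasing")
  mean(diff(start_times))
}

#' Total respiratory rate (TRR)
#'
#' Number of completed expiration-inspiration cycles in the window: a
#' cycle is counted at each expiration start that is followed by an
#' inspiration start inside the window.  Optionally rescaled to
#' cycles/minute by `60 / window length`.
#'
#' @param trace a `breath_trace`.
#' @param per_minute report cycles per minute instead of per window?
#' @return Non-negative numeric scalar.
#' @export
respiratory_rate <- function(trace, per_minute = FALSE) {
  stopifnot(inherits(trace, "breath_trace"), nrow(trace) > 0)
  es <- attr(trace, "expiration_start_idx")
  is_ <- attr(trace, "inspiration_start_idx")
  cycles <- sum(vapply(es, function(e) any(is_ > e), logical(1)))
  if (per_minute) {
    win <- attr(trace, "window")
    cycles * 60 / (win[2] - win[1])
  } else cycles
}

#' Extract the four breath features from a trace
#'
#' Bundles TRV, ADE, ADI and TRR into one feature vector.  Undefined
#' intervals (fewer than two starts of a phase) propagate as flagged
#' `NA`s and must be handled before model fitting.
#'
#' @param trace a `breath_trace`.
#' @param trr_per_minute passed to [respiratory_rate()].
#' @return An object of class `feature_vector`: named list with
#'   `trv`, `ade_s`, `adi_s`, `trr`, plus a logical `missing` vector.
#' @export
extract_features <- function(trace, trr_per_minute = FALSE) {
  stopifnot(inherits(trace, "breath_trace"))
  fps <- attr(trace, "fps")
  ade <- mean_interval(attr(trace, "expiration_start_idx") / fps)
  adi <- mean_interval(attr(trace, "inspiration_start_idx") / fps)
  fv <- list(trv = total_volume(trace), ade_s = as.numeric(ade),
             adi_s = as.numeric(adi),
             trr = respiratory_rate(trace, trr_per_minute))
  fv$missing <- c(trv = FALSE, ade_s = isTRUE(attr(ade, "undefined")),
                  adi_s = isTRUE(attr(adi, "undefined")), trr = FALSE)
  fv$trr_per_minute <- isTRUE(trr_per_minute)
  structure(fv, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> TRV=%g ADE=%gs ADI=%gs TRR=%g%s\n",
              x$trv, x$ade_s, x$adi_s, x$trr,
              if (x$trr_per_minute) "/min" else "/window"))
  if (any(x$missing)) cat("  undefined:",
                          paste(names(which(x$missing)), collapse = ", "),
                          "\n")
  invisible(x)
}
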