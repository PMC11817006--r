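# Synthetic thermal breathing videos with exact ground truth.
#
# No public thermal-video cohort exists, so every image-domain stage is
# validated against this generator: a high-contrast chest band that
# translates vertically with breathing phase, and a warm 2-D Gaussian
# exhalation plume in front of the mouth whose intensity follows a
# raised-cosine envelope over each expiration.  Noise emulates what a
# thermal camera actually shows: salt-and-pepper impulses, Gaussian
# sensor noise, and slow drifting warm blobs of ambient air.

#' Breathing program for the synthetic renderer
#'
#' Describes the breaths a synthetic subject takes.  The program is
#' cycled (or truncated) to cover the requested video duration.  Chest
#' displacement is piecewise linear -- the chest rises at constant
#' speed through an inspiration and sinks back through an expiration --
#' so the per-frame optical-flow signal has constant magnitude
#' `chest_amplitude / (duration * fps)` throughout a phase and the
#' phase boundary is sharp.  Resting breathing at ~15 cycles/min with a
#' visible but uncalibrated plume is the default.
#'
#' @param n_breaths number of breaths in the program.
#' @param expiration_durations,inspiration_durations seconds per phase;
#'   scalars are recycled to `n_breaths`.
#' @param plume_intensity grayscale units added at the plume peak
#'   (mid-expiration); 0 disables the plume.
#' @param chest_amplitude pixels of vertical chest travel per phase.
#' @param start_phase phase at t = 0; recordings conventionally start
#'   just before an expiration.
#' @return An object of class `breath_program`.
#' @export
breath_program <- function(n_breaths = 15,
                           expiration_durations = 2,
                           inspiration_durations = 2,
                           plume_intensity = 60,
                           chest_amplitude = 10,
                           start_phase = c("expiration", "inspiration")) {
  start_phase <- match.arg(start_phase)
  if (!is_count(n_breaths)) stopf("n_breaths must be a positive integer")
  ed <- rep_len(as.numeric(expiration_durations), n_breaths)
  id <- rep_len(as.numeric(inspiration_durations), n_breaths)
  if (any(ed <= 0) || any(id <= 0)) stopf("all phase durations must be > 0")
  if (plume_intensity < 0) stopf("plume_intensity must be >= 0")
  if (chest_amplitude < 0) stopf("chest_amplitude must be >= 0")
  structure(list(n_breaths = as.integer(n_breaths),
                 expiration_durations = ed, inspiration_durations = id,
                 plume_intensity = plume_intensity,
                 chest_amplitude = chest_amplitude,
                 start_phase = start_phase),
            class = "breath_program")
}

#' Noise model for the synthetic renderer
#'
#' @param salt_pepper_fraction proportion of pixels per frame replaced
#'   by 0 or 255 impulses.
#' @param gaussian_sigma additive Gaussian sensor noise, grayscale
#'   units.
#' @param ambient_blob_rate expected number of drifting warm ambient
#'   blobs appearing per second of video.
#' @param rng_seed integer seed; identical specs render bit-identical
#'   videos.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(salt_pepper_fraction = 0.002, gaussian_sigma = 1.5,
                       ambient_blob_rate = 0.1, rng_seed = 1) {
  if (salt_pepper_fraction < 0 || salt_pepper_fraction > 1)
    stopf("salt_pepper_fraction must be in [0, 1]")
  if (gaussian_sigma < 0) stopf("gaussian_sigma must be >= 0")
  if (ambient_blob_rate < 0) stopf("ambient_blob_rate must be >= 0")
  structure(list(salt_pepper_fraction = salt_pepper_fraction,
                 gaussian_sigma = gaussian_sigma,
                 ambient_blob_rate = ambient_blob_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_spec")
}

#' Zero-noise spec (deterministic clean rendering)
#' @param rng_seed kept for interface symmetry; unused when all noise
#'   terms are zero.
#' @return A [noise_spec()] with every noise source disabled.
#' @export
no_noise <- function(rng_seed = 1)
  noise_spec(0, 0, 0, rng_seed)

# Alternating phase schedule over [0, duration], cycling the program.
#' @noRd
breath_schedule <- function(program, duration) {
  phases <- character(0); t0 <- numeric(0); t1 <- numeric(0)
  t <- 0; b <- 1
  first <- program$start_phase
  second <- setdiff(c("expiration", "inspiration"), first)
  while (t < duration) {
    k <- ((b - 1) %% program$n_breaths) + 1
    d1 <- if (first == "expiration") program$expiration_durations[k]
          else program$inspiration_durations[k]
    d2 <- if (first == "expiration") program$inspiration_durations[k]
          else program$expiration_durations[k]
    phases <- c(phases, first, second)
    t0 <- c(t0, t, t + d1)
    t1 <- c(t1, t + d1, t + d1 + d2)
    t <- t + d1 + d2
    b <- b + 1
  }
  keep <- t0 < duration
  data.frame(phase = phases[keep], t_start = t0[keep],
             t_end = pmin(t1[keep], duration))
}

# Default scene geometry for a frame of `h x w` pixels: chest band in
# the lower-left, mouth ROI in the upper-right.  Returned ROIs are what
# the tracker should be given for this scene.
#' @noRd
scene_geometry <- function(h, w, amplitude) {
  band_sigma <- 3
  yc0 <- round(0.72 * h)                      # band center, at rest
  x0 <- round(0.05 * w); x1 <- round(0.55 * w)
  pad <- ceiling(amplitude + 4 * band_sigma)
  cy_top <- max(0L, yc0 - pad)
  chest <- roi(x0, cy_top, x1 - x0, min(h, yc0 + pad) - cy_top,
               role = "chest")
  mw <- round(0.30 * w); mh <- round(0.30 * h)
  mouth <- roi(round(0.62 * w), round(0.15 * h), mw, mh, role = "mouth")
  list(chest = chest, mouth = mouth, band_sigma = band_sigma, yc0 = yc0,
       band_x = c(x0, x1),
       plume_c = c(mouth$y + mh / 2, mouth$x + mw / 2),
       plume_sigma = 0.15 * min(mh, mw))
}

#' Render a synthetic thermal breathing video
#'
#' Produces an 8-bit grayscale [frame_sequence()] together with exact
#' ground truth.  The scene holds a bright horizontal chest band whose
#' vertical position follows the breathing program (rising through
#' inspiration, sinking through expiration) and a mouth-front plume
#' whose added intensity is `plume_intensity` times a raised-cosine
#' envelope over each expiration, with a 2-D Gaussian footprint.  The
#' band intensity is modulated along x so that 8-bit quantization
#' dithers rather than snapping whole rows, keeping sub-pixel motion
#' visible to optical flow.
#'
#' Ground-truth plume counts are computed from the clean quantized
#' frames by the same rule the tracker applies -- pixels of the mouth
#' ROI whose intensity rises by at least 1 between consecutive frames,
#' counted only on true expiration frames -- so in the noiseless case
#' the tracker must reproduce them exactly.
#'
#' @param program a [breath_program()].
#' @param noise a [noise_spec()]; [no_noise()] for clean output.
#' @param frame_shape `c(height, width)` in pixels; must be at least
#'   48 x 64 so the default scene ROIs fit.
#' @param fps frames per second.
#' @param duration video length in seconds.
#' @return A list of class `synthetic_video`: `seq` (noisy frames),
#'   `clean` (noise-free frames), `truth` (class `ground_truth`:
#'   per-frame `phase`, `plume_counts`, and `expiration_starts` /
#'   `inspiration_starts` in seconds), plus the scene's `chest_roi` and
#'   `mouth_roi`.
#' @export
render_thermal_video <- function(program = breath_program(),
                                 noise = noise_spec(),
                                 frame_shape = c(120, 160),
                                 fps = 30, duration = 40) {
  stopifnot(inherits(program, "breath_program"), inherits(noise, "noise_spec"))
  if (fps <= 0) stopf("fps must be positive")
  h <- as.integer(frame_shape[1]); w <- as.integer(frame_shape[2])
  if (h < 48 || w < 64)
    stopf("frame_shape %d x %d too small for the default ROI layout (need >= 48 x 64)",
          h, w)
  geo <- scene_geometry(h, w, program$chest_amplitude)
  check_roi_inside(geo$chest, c(h, w))
  check_roi_inside(geo$mouth, c(h, w))
  n <- round(duration * fps)
  sched <- breath_schedule(program, duration)
  times <- (seq_len(n) - 1) / fps
  seg_of <- findInterval(times, sched$t_start)   # segment index per frame
  phase <- sched$phase[seg_of]

  base <- 20
  contrast <- 170
  xs <- seq_len(w)
  band_mod <- 1 + 0.15 * sin(2 * pi * xs / 17)   # per-column dither
  band_cols <- xs >= geo$band_x[1] + 1 & xs <= geo$band_x[2]
  ys <- seq_len(h)

  clean <- array(0L, c(h, w, n))
  for (i in seq_len(n)) {
    s <- seg_of[i]
    u <- (times[i] - sched$t_start[s]) /
      (sched$t_end[s] - sched$t_start[s])
    # chest displacement in [0, A]: 0 = rest (end of expiration)
    d <- if (phase[i] == "inspiration") u * program$chest_amplitude
         else (1 - u) * program$chest_amplitude
    yc <- geo$yc0 - d
    prof <- contrast * exp(-(ys - yc)^2 / (2 * geo$band_sigma^2))
    fr <- matrix(base, h, w)
    fr[, band_cols] <- fr[, band_cols] +
      outer(prof, band_mod[band_cols])
    if (phase[i] == "expiration" && program$plume_intensity > 0) {
      env <- 0.5 * (1 - cos(2 * pi * u))
      g <- outer(exp(-(ys - geo$plume_c[1])^2 / (2 * geo$plume_sigma^2)),
                 exp(-(xs - geo$plume_c[2])^2 / (2 * geo$plume_sigma^2)))
      fr <- fr + program$plume_intensity * env * g
    }
    clean[, , i] <- as.integer(round(clamp(fr)))
  }

  # ground-truth plume counts on clean frames, gated by true phase
  counts <- integer(n)
  for (i in seq_len(n)) {
    if (i == 1L || phase[i] != "expiration") next
    dif <- roi_pixels(clean[, , i], geo$mouth) -
      roi_pixels(clean[, , i - 1], geo$mouth)
    counts[i] <- sum(dif >= 1)
  }

  frames <- clean
  if (noise$salt_pepper_fraction > 0 || noise$gaussian_sigma > 0 ||
      noise$ambient_blob_rate > 0) {
    frames <- with_seed(noise$rng_seed, {
      out <- clean + 0
      n_blob <- rpois(1, noise$ambient_blob_rate * duration)
      blobs <- if (n_blob > 0) data.frame(
        y = runif(n_blob, 1, h), x = runif(n_blob, 1, w),
        vy = rnorm(n_blob, 0, 3), vx = rnorm(n_blob, 0, 3),
        sig = runif(n_blob, 2, 4), amp = runif(n_blob, 10, 40),
        t0 = runif(n_blob, 0, duration)) else NULL
      npix <- round(noise$salt_pepper_fraction * h * w)
      for (i in seq_len(n)) {
        fr <- out[, , i]
        if (!is.null(blobs)) for (b in seq_len(n_blob)) {
          dt <- times[i] - blobs$t0[b]
          if (dt < 0) next
          by <- blobs$y[b] + blobs$vy[b] * dt
          bx <- blobs$x[b] + blobs$vx[b] * dt
          if (by < -8 || by > h + 8 || bx < -8 || bx > w + 8) next
          fr <- fr + blobs$amp[b] *
            outer(exp(-(ys - by)^2 / (2 * blobs$sig[b]^2)),
                  exp(-(xs - bx)^2 / (2 * blobs$sig[b]^2)))
        }
        if (noise$gaussian_sigma > 0)
          fr <- fr + rnorm(h * w, 0, noise$gaussian_sigma)
        if (npix > 0) {
          idx <- sample.int(h * w, npix)
          fr[idx] <- ifelse(runif(npix) < 0.5, 0, 255)
        }
        out[, , i] <- round(clamp(fr))
      }
      out
    })
  }

  truth <- structure(list(
    phase = phase,
    plume_counts = counts,
    expiration_starts = sched$t_start[sched$phase == "expiration"],
    inspiration_starts = sched$t_start[sched$phase == "inspiration"],
    fps = fps, duration = duration), class = "ground_truth")

  structure(list(
    seq = frame_sequence(array(as.integer(frames), c(h, w, n)), fps),
    clean = frame_sequence(clean, fps),
    truth = truth,
    chest_roi = geo$chest, mouth_roi = geo$mouth),
    class = "synthetic_video")
}

#' @export
print.synthetic_video <- function(x, ...) {
  cat("<synthetic_video>\n  ")
  print(x$seq)
  cat(sprintf("  %d expiration starts, %d inspiration starts\n",
              length(x$truth$expiration_starts),
              length(x$truth$inspiration_starts)))
  invisible(x)
}

# Defaults for the two-group feature sampler: group mean vectors from
# the clinical cohort summary, spreads calibrated so each feature's
# single-feature AUC under an equal-variance normal model matches the
# cohort's reported discriminative power (TRV 0.80, ADE 0.24, ADI 0.46,
# TRR 0.69; AUC = Phi(delta / (sqrt(2) sd))).
#' @noRd
cohort_defaults <- function() {
  mu_control <- c(trv = 292177, ade_s = 1.652137, adi_s = 1.260358,
                  trr = 15.75)
  mu_copd <- c(trv = 720140, ade_s = 1.007284, adi_s = 1.141885,
               trr = 20.825)
  auc <- c(trv = 0.80, ade_s = 0.24, adi_s = 0.46, trr = 0.69)
  sds <- abs(mu_copd - mu_control) / (sqrt(2) * abs(qnorm(auc)))
  list(mu_control = mu_control, mu_copd = mu_copd, sds = sds)
}

#' Sample a labelled two-group feature table
#'
#' Draws independent Gaussian feature vectors for a COPD group and a
#' control group.  Defaults reproduce the clinical cohort's group means
#' with spreads calibrated so each feature's standalone AUC matches the
#' cohort's (see the methods vignette).  Durations and counts are
#' floored at small non-negative values after sampling, which slightly
#' biases means when the spread is large relative to the mean.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param group_means list with numeric vectors `copd` and `control`,
#'   each named `trv, ade_s, adi_s, trr`.
#' @param group_sds like `group_means`; shared across groups if a
#'   single vector is given.
#' @param rng_seed integer seed.
#' @return A data.frame with columns `subject_id`, `trv`, `ade_s`,
#'   `adi_s`, `trr`, `label` (`"copd"` / `"control"`).
#' @export
sample_feature_table <- function(n_per_group = 20, group_means = NULL,
                                 group_sds = NULL, rng_seed = 1) {
  if (!is_count(n_per_group) || n_per_group < 2)
    stopf("n_per_group must be an integer >= 2")
  def <- cohort_defaults()
  if (is.null(group_means))
    group_means <- list(copd = def$mu_copd, control = def$mu_control)
  if (is.null(group_sds)) group_sds <- def$sds
  if (!is.list(group_sds)) group_sds <- list(copd = group_sds,
                                             control = group_sds)
  feats <- c("trv", "ade_s", "adi_s", "trr")
  floors <- c(trv = 0, ade_s = 0.05, adi_s = 0.05, trr = 0)
  for (g in c("copd", "control")) {
    if (!all(feats %in% names(group_means[[g]])) ||
        !all(feats %in% names(group_sds[[g]])))
      stopf("group_means/group_sds must name features %s",
            paste(feats, collapse = ", "))
    if (any(group_sds[[g]][feats] < 0)) stopf("sds must be >= 0")
  }
  with_seed(rng_seed, {
    draw <- function(g) {
      m <- vapply(feats, function(f)
        pmax(floors[[f]],
             rnorm(n_per_group, group_means[[g]][[f]],
                   group_sds[[g]][[f]])), numeric(n_per_group))
      as.data.frame(m)
    }
    copd <- draw("copd"); ctrl <- draw("control")
    out <- rbind(copd, ctrl)
    out$label <- rep(c("copd", "control"), each = n_per_group)
    out$subject_id <- sprintf("S%03d", seq_len(nrow(out)))
    out[, c("subject_id", feats, "label")]
  })
}
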