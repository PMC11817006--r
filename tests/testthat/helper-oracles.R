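# Independent brute-force oracles.  Each re-derives an operation from
# its mathematical definition with no shared code paths, so agreement
# with the implementation is evidence, not tautology.

reflect_idx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_median <- function(img, k) {
  r <- k %/% 2
  out <- img * 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    win <- numeric(0)
    for (di in -r:r) for (dj in -r:r)
      win <- c(win, img[reflect_idx(i + di, nrow(img)),
                        reflect_idx(j + dj, ncol(img))])
    out[i, j] <- median(win)
  }
  out
}

oracle_gaussian <- function(img, k, sigma) {
  r <- k %/% 2
  kern <- outer(-r:r, -r:r, function(x, y)
    exp(-(x^2 + y^2) / (2 * sigma^2)))
  kern <- kern / sum(kern)
  out <- img * 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + kern[di + r + 1, dj + r + 1] *
        img[reflect_idx(i + di, nrow(img)), reflect_idx(j + dj, ncol(img))]
    out[i, j] <- acc
  }
  out
}

oracle_bilateral <- function(img, k, ss, sr) {
  r <- k %/% 2
  out <- img * 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) {
      v <- img[reflect_idx(i + di, nrow(img)),
               reflect_idx(j + dj, ncol(img))]
      w <- exp(-(di^2 + dj^2) / (2 * ss^2)) *
        exp(-(v - img[i, j])^2 / (2 * sr^2))
      num <- num + w * v; den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# AUC as the exhaustive Mann-Whitney pairwise comparison.
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Best Youden J over every conceivable cut point, by direct
# classification (positive iff score >= t).
oracle_best_youden <- function(scores, pos) {
  cuts <- c(sort(unique(scores)), max(scores) + 1)
  best <- -Inf
  for (t in cuts) {
    pred <- scores >= t
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Small deterministic frame fixtures -----------------------------------

# A smooth horizontal band centered at row `yc` (fractional allowed).
band_frame <- function(h, w, yc, sigma = 2, contrast = 200, base = 20) {
  prof <- contrast * exp(-(seq_len(h) - yc)^2 / (2 * sigma^2))
  matrix(base, h, w) + prof %o% (1 + 0.1 * sin(seq_len(w) / 3))
}

# A smooth vertical edge at column `xc`.
vband_frame <- function(h, w, xc, sigma = 2, contrast = 200, base = 20) {
  prof <- contrast * exp(-(seq_len(w) - xc)^2 / (2 * sigma^2))
  matrix(base, h, w) + (1 + 0.1 * sin(seq_len(h) / 3)) %o% prof
}

make_clean_video <- function(bpm = 15, fps = 15, duration = 40,
                             plume = 60, amplitude = 10,
                             shape = c(96, 128)) {
  half <- 30 / bpm
  prog <- breath_program(n_breaths = ceiling(duration / (2 * half)),
                         expiration_durations = half,
                         inspiration_durations = half,
                         plume_intensity = plume,
                         chest_amplitude = amplitude)
  render_thermal_video(prog, no_noise(), frame_shape = shape,
                       fps = fps, duration = duration)
}

# First frame index belonging to a segment starting at time t: frame i
# covers time i / fps and belongs to the segment whose start <= i/fps.
gt_frame_idx <- function(t, fps) ceiling(t * fps - 1e-9)
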