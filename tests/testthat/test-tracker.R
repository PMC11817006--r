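test_that("chest_flow measures known shifts within tolerance", {
  r <- roi(10, 10, 60, 40, role = "chest")
  a <- band_frame(64, 80, yc = 30)
  expect_equal(as.numeric(chest_flow(a, a, r)), 0, tolerance = 1e-8)

  # band translated down by exactly 1 px -> vy in [0.8, 1.2]
  b <- band_frame(64, 80, yc = 31)
  vy <- as.numeric(chest_flow(a, b, r))
  expect_gte(vy, 0.8); expect_lte(vy, 1.2)
  # and upward motion flips the sign
  up <- band_frame(64, 80, yc = 29)
  expect_lt(as.numeric(chest_flow(a, up, r)), -0.8)

  # horizontal-only translation leaks almost nothing into vy
  va <- vband_frame(64, 80, xc = 40)
  vb <- vband_frame(64, 80, xc = 41)
  expect_lt(abs(as.numeric(chest_flow(va, vb, r))), 0.05)
  expect_gt(attr(chest_flow(va, vb, r), "vx"), 0.5)

  expect_error(chest_flow(a, b, roi(70, 50, 20, 20, role = "chest")),
               "exceeds frame")
  expect_error(chest_flow(a, b[1:32, ], r), "shape")
})

test_that("update_phase implements the thresholded sign rule exactly", {
  cfg <- tracker_config()
  states <- c("undetermined", "inspiration", "expiration")
  for (s in states) {
    expect_identical(update_phase(s, 0.01, cfg), s)    # hold
    expect_identical(update_phase(s, -0.05, cfg), s)   # boundary holds
    expect_identical(update_phase(s, -0.2, cfg), "inspiration")
    expect_identical(update_phase(s, 0.2, cfg), "expiration")
  }
  flipped <- tracker_config(chest_sign_convention = FALSE)
  expect_identical(update_phase("undetermined", -0.2, flipped),
                   "expiration")
  # alternating strong flows alternate phases with no holds
  st <- "undetermined"
  out <- character(6)
  for (i in 1:6) {
    st <- update_phase(st, c(-0.2, 0.2)[(i %% 2) + 1], cfg)
    out[i] <- st
  }
  expect_identical(out, rep(c("expiration", "inspiration"), 3))
})

test_that("count_plume_pixels counts exactly the risen pixels", {
  r <- roi(2, 2, 10, 8, role = "mouth")
  a <- matrix(100, 20, 20)
  expect_identical(count_plume_pixels(a, a, r), 0L)
  b <- a
  # raise exactly 7 pixels inside the ROI by +2, others elsewhere
  b[3:4, 3:5] <- 102; b[5, 3] <- 102   # 7 px in ROI
  b[15, 15] <- 200                     # outside ROI, must not count
  expect_identical(count_plume_pixels(a, b, r, 1), 7L)
  expect_identical(count_plume_pixels(a, b, r, 3), 0L)
  expect_identical(count_plume_pixels(b, a, r, 1), 0L)   # negative changes
  # monotone non-increasing in the threshold
  set.seed(4)
  d <- matrix(sample(0:255, 400, TRUE), 20, 20)
  counts <- vapply(0:6, function(t) count_plume_pixels(a, d, r, t),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("track recovers a clean synthetic recording", {
  v <- make_clean_video(bpm = 12, fps = 10, duration = 30)
  tr <- track(v$seq, v$chest_roi, v$mouth_roi,
              tracker_config(window_end = 30))
  es <- attr(tr, "expiration_start_idx")
  gt <- gt_frame_idx(v$truth$expiration_starts, 10)
  expect_length(es, length(gt))
  expect_true(all(abs(es - gt) <= 1))
  expect_identical(sum(tr$plume_count), sum(v$truth$plume_counts))
  # plume counts identically zero outside detected expiration frames
  expect_true(all(tr$plume_count[tr$phase != "expiration"] == 0))
})

test_that("the two ROIs are independent and null inputs stay null", {
  v0 <- make_clean_video(bpm = 12, fps = 10, duration = 20, plume = 0)
  tr <- track(v0$seq, v0$chest_roi, v0$mouth_roi,
              tracker_config(window_end = 20))
  expect_true(all(tr$plume_count == 0))
  expect_gt(length(attr(tr, "expiration_start_idx")), 0)

  static <- frame_sequence(array(50L, c(64, 80, 60)), fps = 10)
  tr0 <- track(static, roi(10, 10, 40, 30, role = "chest"),
               roi(55, 10, 20, 20, role = "mouth"),
               tracker_config(window_end = 5))
  expect_true(all(tr0$phase == "undetermined"))
  expect_true(all(tr0$plume_count == 0))
})

test_that("phase output is invariant to sub-threshold jitter", {
  v <- make_clean_video(bpm = 15, fps = 10, duration = 16)
  cfg <- tracker_config(window_end = 16)
  tr_ref <- track(v$seq, v$chest_roi, v$mouth_roi, cfg)
  # inject tiny intensity jitter into the chest band region: the
  # resulting flow perturbation stays under the 0.05 threshold
  set.seed(7)
  jit <- v$seq$frames
  cr <- v$chest_roi
  for (i in seq_len(dim(jit)[3])) {
    sub <- jit[(cr$y + 1):(cr$y + cr$height),
               (cr$x + 1):(cr$x + cr$width), i]
    jit[(cr$y + 1):(cr$y + cr$height),
        (cr$x + 1):(cr$x + cr$width), i] <-
      pmax(0L, pmin(255L, sub + sample(-1:1, length(sub), TRUE)))
  }
  tr_jit <- track(frame_sequence(jit, 10), v$chest_roi, v$mouth_roi, cfg)
  expect_identical(tr_jit$phase, tr_ref$phase)
})

test_that("track validates its window and total TRV is threshold-monotone", {
  v <- make_clean_video(bpm = 15, fps = 10, duration = 10)
  expect_error(track(v$seq, v$chest_roi, v$mouth_roi,
                     tracker_config(window_end = 40)),
               "requires 40")
  cfg <- function(t) tracker_config(window_end = 10, diff_threshold = t)
  tot <- vapply(c(1, 2, 4, 8), function(t)
    sum(track(v$seq, v$chest_roi, v$mouth_roi, cfg(t))$plume_count),
    numeric(1))
  expect_true(all(diff(tot) <= 0))
})

test_that("breath-count recovery holds across rates and moderate noise", {
  for (bpm in c(8, 15, 24)) {
    half <- 30 / bpm
    prog <- breath_program(n_breaths = ceiling(24 / (2 * half)),
                           expiration_durations = half,
                           inspiration_durations = half)
    v <- render_thermal_video(prog, noise_spec(0.002, 1.5, 0.1, 3),
                              frame_shape = c(96, 128), fps = 10,
                              duration = 24)
    pp <- preprocess_sequence(v$seq)
    tr <- track(pp, v$chest_roi, v$mouth_roi,
                tracker_config(window_end = 24))
    expect_length(attr(tr, "expiration_start_idx"),
                  length(v$truth$expiration_starts))
  }
})
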