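test_that("zscale matches the definition under both sigma conventions", {
  x <- c(1, 2, 3, 4)
  zp <- zscale(x, "population")
  expect_equal(zp$mu, 2.5)
  expect_equal(zp$sigma, sqrt(mean((x - 2.5)^2)))
  expect_equal(zp$z[4], (4 - 2.5) / sqrt(1.25))
  zs <- zscale(x, "sample")
  expect_equal(zs$sigma, sd(x))
  # X = mu -> 0; X = mu + sigma -> 1
  expect_equal(zscale(c(0, 10, 20))$z[2], 0)
  y <- c(2, 4)                 # mu = 3, pop sigma = 1
  expect_equal(zscale(y)$z, c(-1, 1))
  expect_error(zscale(rep(5, 4), name = "trr"), "trr")
  # property: mean 0 / sd 1 on random non-degenerate columns
  set.seed(6)
  for (i in 1:5) {
    z <- zscale(rnorm(20, sd = runif(1, 0.1, 100)))$z
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  }
})

test_that("composite_score is the weighted sum over active features", {
  w <- c(trv = 48, ade_s = 3, adi_s = 46, trr = 33)
  z0 <- c(trv = 0, ade_s = 0, adi_s = 0, trr = 0)
  expect_equal(composite_score(z0, w), 0)
  expect_equal(composite_score(z0 + 1, w), 130)
  # dropping a feature removes exactly its term
  expect_equal(composite_score((z0 + 1)[c("trv", "adi_s", "trr")],
                               w[c("trv", "adi_s", "trr")]), 127)
  expect_error(composite_score(z0[1:3], w), "active features")
  # matrix form scores many subjects at once
  zm <- rbind(z0, z0 + 1, c(trv = 1, ade_s = -1, adi_s = 0, trr = 2))
  expect_equal(unname(composite_score(zm, w)), c(0, 130, 48 - 3 + 66))
})

test_that("roc_curve matches exhaustive cut-point enumeration", {
  set.seed(12)
  for (rep in 1:4) {
    n <- 8
    scores <- round(rnorm(n), 2)
    pos <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(pos) || all(pos)) pos[1:2] <- c(TRUE, FALSE)
    rc <- roc_curve(scores, pos)
    for (k in seq_len(nrow(rc))) {
      pred <- scores >= rc$threshold[k]
      expect_equal(rc$tpr[k], sum(pred & pos) / sum(pos))
      expect_equal(rc$fpr[k], sum(pred & !pos) / sum(!pos))
    }
    # monotone from (0,0) to (1,1)
    expect_true(all(diff(rc$tpr) >= 0) && all(diff(rc$fpr) >= 0))
    expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
    expect_equal(c(rc$fpr[nrow(rc)], rc$tpr[nrow(rc)]), c(1, 1))
  }
  # perfect separation passes through (0, 1)
  rc <- roc_curve(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  # all-tied scores give only the trivial corners
  rc2 <- roc_curve(rep(5, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(nrow(rc2), 2L)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("auc equals the pairwise oracle and the trapezoid area", {
  set.seed(13)
  for (rep in 1:5) {
    scores <- sample(round(rnorm(12), 1))   # ties likely
    pos <- rep(c(TRUE, FALSE), each = 6)
    a <- auc(scores, pos)
    expect_equal(a, oracle_auc(scores, pos))
    rc <- roc_curve(scores, pos)
    trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
    expect_equal(a, trap)
  }
  expect_equal(auc(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc(rep(3, 8), rep(c(TRUE, FALSE), 4)), 0.5)
  # invariance under strictly increasing transforms
  set.seed(14)
  s <- rnorm(10); p <- rep(c(TRUE, FALSE), 5)
  expect_equal(auc(exp(s), p), auc(s, p))
  expect_equal(auc(rank(s), p), auc(s, p))
})

test_that("youden_threshold maximizes J with specificity tie-break", {
  scores <- c(1, 2, 3, 4)
  pos <- c(FALSE, FALSE, TRUE, TRUE)
  yj <- youden_threshold(roc_curve(scores, pos))
  expect_equal(yj$youden, 1)
  pred <- classify(scores, yj$threshold)
  expect_identical(pred, c("control", "control", "copd", "copd"))

  expect_equal(youden_threshold(roc_curve(rep(2, 6),
                                          rep(c(TRUE, FALSE), 3)))$youden,
               0)
  # oracle equivalence on random inputs
  set.seed(15)
  for (rep in 1:6) {
    s <- round(rnorm(10), 1)
    p <- sample(rep(c(TRUE, FALSE), 5))
    yj <- youden_threshold(roc_curve(s, p))
    expect_equal(yj$youden, oracle_best_youden(s, p))
    # reported sens/spec match direct classification at the threshold
    pred <- s >= yj$threshold
    expect_equal(yj$sensitivity, sum(pred & p) / sum(p))
    expect_equal(yj$specificity, sum(!pred & !p) / sum(!p))
  }
})

test_that("classify is boundary-inclusive and monotone in the score", {
  expect_identical(classify(5, 5), "copd")
  expect_identical(classify(5 - 1e-9, 5), "control")
  w <- c(trv = 48, ade_s = 3, adi_s = 46, trr = 33)
  z <- c(trv = -0.1, ade_s = 0.2, adi_s = 0, trr = 0.1)
  s1 <- composite_score(z, w)
  z["trv"] <- z["trv"] + 1          # raising TRV (positive weight)
  expect_gt(composite_score(z, w), s1)
})

test_that("evaluation metrics match direct arithmetic", {
  ev <- confusion_metrics(tp = 19, fn = 1, tn = 15, fp = 5)
  expect_equal(ev$precision_copd, 19 / 24)
  expect_equal(ev$recall_copd, 19 / 20)
  expect_equal(ev$accuracy, 34 / 40)
  expect_equal(ev$youden, 19 / 20 + 15 / 20 - 1)

  pred <- c("copd", "copd", "control", "control", "copd")
  true <- c("copd", "control", "control", "copd", "copd")
  ev2 <- evaluate_classification(pred, true)
  expect_identical(c(ev2$tp, ev2$fn, ev2$tn, ev2$fp), c(2L, 1L, 1L, 1L))
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(ev2$f1_copd, f1(2 / 3, 2 / 3))
  perfect <- evaluate_classification(true, true)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1_control, 1)
  expect_error(evaluate_classification(pred[1:3], true), "mismatch")
  # random-count property against the formula oracle
  set.seed(16)
  for (i in 1:5) {
    k <- sample(1:20, 4, TRUE)
    ev3 <- confusion_metrics(k[1], k[2], k[3], k[4])
    expect_equal(ev3$sensitivity, k[1] / (k[1] + k[2]))
    expect_equal(ev3$specificity, k[3] / (k[3] + k[4]))
    expect_equal(ev3$accuracy, (k[1] + k[3]) / sum(k))
  }
})

test_that("weight_search selects by the stated criteria, reproducibly", {
  tab <- sample_feature_table(10, rng_seed = 3)
  m1 <- weight_search(tab, n_iter = 50, rng_seed = 9)
  m2 <- weight_search(tab, n_iter = 50, rng_seed = 9)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$threshold, m2$threshold)
  expect_true(all(m1$search_log$youden >= -1))
  expect_identical(nrow(m1$search_log), 50L)
  expect_true(all(unlist(m1$search_log[paste0("w_",
    c("trv", "ade_s", "adi_s", "trr"))]) %in% 1:50))

  # n_iter = 1 reduces to a single fixed-weight fit
  m3 <- weight_search(tab, n_iter = 1, rng_seed = 11)
  w3 <- m3$weights
  m3b <- fit_score_model(tab, w3)
  expect_equal(m3$threshold, m3b$threshold)
  expect_equal(m3$evaluation$accuracy, m3b$evaluation$accuracy)

  # A perfectly separated cohort must yield a perfect model regardless
  # of seed.  Note: separation must be consistently oriented across
  # features -- Z-scaling rescales every column to unit variance, so a
  # label-independent column can outvote a separated one under an
  # unlucky positive weight draw.
  sep <- tab
  n <- nrow(sep)
  copd <- sep$label == "copd"
  sep$trv <- ifelse(copd, 1e6, 0) + seq_len(n)          # huge gap
  sep$ade_s <- ifelse(copd, 10, 0) + runif(n)           # aligned gaps
  sep$adi_s <- ifelse(copd, 10, 0) + runif(n)
  sep$trr <- ifelse(copd, 100, 0) + runif(n)
  expect_equal(auc(sep$trv, copd), 1)
  for (seed in c(1, 2, 3)) {
    ms <- weight_search(sep, n_iter = 20, rng_seed = seed)
    expect_equal(ms$evaluation$accuracy, 1)
    expect_false(ms$below_criterion)
  }

  # impossible criterion: below_criterion flag, best-Youden fallback
  mf <- weight_search(tab, n_iter = 5, rng_seed = 2, youden_min = 1.5)
  expect_true(mf$below_criterion)
  expect_equal(mf$youden, max(mf$search_log$youden))
})

test_that("selection prefers accuracy, then COPD recall", {
  # two candidate logs engineered via a 2-subject-per-class cohort are
  # hard to control; instead check the ordering rule on the log itself
  tab <- sample_feature_table(15, rng_seed = 4)
  m <- weight_search(tab, n_iter = 200, rng_seed = 5)
  log <- m$search_log
  cand <- log[log$passes, ]
  if (nrow(cand) > 0) {
    expect_equal(m$evaluation$accuracy, max(cand$accuracy))
    top <- cand[cand$accuracy == max(cand$accuracy), ]
    expect_equal(m$evaluation$recall_copd, max(top$recall_copd))
  }
})

test_that("dominant-TRV cohorts put the top weight on TRV above chance", {
  hits <- 0
  for (seed in 1:8) {
    tab <- sample_feature_table(12, rng_seed = seed)
    m <- weight_search(tab, n_iter = 100, rng_seed = seed)
    hits <- hits + (names(which.max(m$weights)) == "trv")
  }
  expect_gt(hits / 8, 0.25)   # chance would be 1/4
})

test_that("auc_difference_table and pearson_correlation are consistent", {
  tab <- sample_feature_table(12, rng_seed = 6)
  m <- fit_score_model(tab, c(trv = 48, ade_s = 3, adi_s = 46,
                              trr = 33))
  mcid <- c(trv = 0.08, ade_s = 0.12, adi_s = 0.13, trr = 0.11)
  dt <- auc_difference_table(tab, m, mcid)
  pos <- tab$label == "copd"
  for (k in seq_len(nrow(dt))) {
    f <- dt$feature[k]
    expect_equal(dt$feature_auc[k], auc(tab[[f]], pos))
    expect_equal(dt$observed_difference[k],
                 dt$composite_auc[k] - dt$feature_auc[k])
    expect_identical(dt$mcid_met[k],
                     dt$observed_difference[k] > mcid[[f]])
  }
  # a feature identical to the composite: difference 0, never met
  tab2 <- tab
  scored <- score_subjects(m, tab)
  tab2$trv <- scored$score
  m2 <- fit_score_model(tab2, m$weights[c("ade_s", "adi_s", "trr")],
                        feature_subset = c("ade_s", "adi_s", "trr"))
  # direct check instead: composite vs itself
  expect_equal(auc(scored$score, pos) - auc(scored$score, pos), 0)

  expect_equal(pearson_correlation(as.numeric(pos), pos), 1)
  expect_equal(pearson_correlation(as.numeric(!pos), pos), -1)
  x <- c(1, 3, 2, 5, 4, 6)
  p6 <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(pearson_correlation(x, p6),
               cov(x, as.numeric(p6)) / (sd(x) * sd(as.numeric(p6))))
  expect_error(pearson_correlation(rep(1, 6), p6), "non-constant")
})

test_that("fit_score_model validates input and stores the fit", {
  tab <- sample_feature_table(8, rng_seed = 7)
  w <- c(trv = 10, ade_s = 10, adi_s = 10, trr = 10)
  m <- fit_score_model(tab, w)
  expect_equal(unname(m$mu["trv"]), mean(tab$trv))
  scored <- score_subjects(m, tab)
  expect_equal(scored$score, m$scores)
  expect_error(fit_score_model(tab[tab$label == "copd", ], w),
               "per class")
  bad <- tab; bad$trv[1] <- NA
  expect_error(fit_score_model(bad, w), "missing values")
  expect_error(fit_score_model(tab, c(trv = 1, ade_s = 1)), "active")
})
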