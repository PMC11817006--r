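# Z-score weighted composite scoring and ROC/Youden classification.
#
# The four breath features live on wildly different scales (plume
# pixel counts in the hundreds of thousands, intervals of a couple of
# seconds), so each is Z-scaled on the cohort before a positive
# integer weight in [1, 50] multiplies it.  The weighted sum is the
# subject's score; the classification threshold is the Youden-index
# optimum of the score's ROC curve, and weights are chosen by a seeded
# random search with a Youden > 0.70 admission criterion.

FEATURES <- c("trv", "ade_s", "adi_s", "trr")

# TRUE where the label means the positive (COPD) class.
#' @noRd
positive_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  l <- tolower(as.character(labels))
  out <- l %in% c("copd", "patient", "positive", "1", "true")
  neg <- l %in% c("control", "non_patient", "non-patient", "negative",
                  "0", "false", "healthy")
  if (any(!out & !neg))
    stopf("unrecognized class labels: %s",
          paste(unique(l[!out & !neg]), collapse = ", "))
  out
}

#' @noRd
check_cohort <- function(cohort, feature_subset = FEATURES) {
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(c(feature_subset, "label"), names(cohort))
  if (length(miss))
    stopf("cohort table lacks columns: %s", paste(miss, collapse = ", "))
  if (anyNA(cohort[feature_subset]))
    stopf("cohort features contain missing values; drop or resolve flagged subjects before fitting")
  pos <- positive_labels(cohort$label)
  if (sum(pos) < 2 || sum(!pos) < 2)
    stopf("need at least 2 subjects per class, got %d positive / %d negative",
          sum(pos), sum(!pos))
  pos
}

#' Z-score a feature column
#'
#' `z = (x - mu) / sigma`.  The plain Z-score uses the population
#' standard deviation (divide by n); `sd_type = "sample"` switches to
#' the n-1 convention.
#'
#' @param x numeric vector, at least 2 values.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @param name feature name used in error messages.
#' @return List with `z` (mean 0, sd 1), `mu`, `sigma`.
#' @export
zscale <- function(x, sd_type = c("population", "sample"), name = "feature") {
  sd_type <- match.arg(sd_type)
  if (length(x) < 2 || anyNA(x)) stopf("need >= 2 non-missing values")
  mu <- mean(x)
  sigma <- if (sd_type == "population")
    sqrt(mean((x - mu)^2)) else sd(x)
  if (sigma == 0)
    stopf("feature '%s' is constant (sigma = 0); cannot Z-scale", name)
  list(z = (x - mu) / sigma, mu = mu, sigma = sigma)
}

#' Weighted composite score
#'
#' `score = sum(z_i * w_i)` over the active features.  `z` and `w`
#' must name the same features.
#'
#' @param z named numeric vector (or matrix with named columns) of
#'   z-values.
#' @param w named numeric vector of weights.
#' @return Numeric score (vector if `z` is a matrix).
#' @export
composite_score <- function(z, w) {
  if (is.matrix(z)) {
    if (!setequal(colnames(z), names(w)))
      stopf("z columns and weight names disagree")
    return(drop(z[, names(w), drop = FALSE] %*% w))
  }
  if (!setequal(names(z), names(w)))
    stopf("z and w must name the same active features")
  sum(z[names(w)] * w)
}

#' ROC curve
#'
#' Sweeps every distinct score as a cut point (plus an `Inf` sentinel)
#' under the rule "positive if score >= threshold", yielding a curve
#' monotone in both coordinates from (0,0) to (1,1).
#'
#' @param scores numeric vector.
#' @param labels class labels (positive = COPD); both classes must be
#'   present.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, ordered
#'   by descending threshold.
#' @export
roc_curve <- function(scores, labels) {
  pos <- positive_labels(labels)
  if (length(scores) != length(pos)) stopf("scores/labels length mismatch")
  if (!any(pos) || all(pos)) stopf("both classes must be present")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability
#' `P(score_pos > score_neg) + 0.5 P(tie)` via ranks; identical to the
#' trapezoidal area under [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  pos <- positive_labels(labels)
  if (!any(pos) || all(pos)) stopf("both classes must be present")
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index optimal threshold
#'
#' Returns the ROC cut point maximizing Youden's
#' `J = TPR - FPR = sensitivity + specificity - 1`.  Ties are broken
#' toward higher specificity (lower FPR), then toward the higher
#' threshold.
#'
#' @param roc a [roc_curve()] result (or `scores`/`labels` via `...`).
#' @return List with `threshold`, `youden`, `sensitivity`,
#'   `specificity`.
#' @export
youden_threshold <- function(roc) {
  stopifnot(is.data.frame(roc), all(c("threshold", "fpr", "tpr") %in%
                                      names(roc)))
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))
  best <- best[order(roc$fpr[best], -roc$threshold[best])][1]
  th <- roc$threshold[best]
  if (!is.finite(th)) th <- max(roc$threshold[is.finite(roc$threshold)],
                                na.rm = TRUE) + 1
  list(threshold = th, youden = j[best],
       sensitivity = roc$tpr[best], specificity = 1 - roc$fpr[best])
}

#' Classify scores against a threshold
#'
#' A subject is called COPD when the score meets or exceeds the
#' threshold (boundary inclusive).
#'
#' @param scores numeric vector.
#' @param threshold scalar score threshold.
#' @return Character vector of `"copd"` / `"control"`.
#' @export
classify <- function(scores, threshold) {
  ifelse(scores >= threshold, "copd", "control")
}

#' Confusion-matrix evaluation report
#'
#' All rates derived from the four confusion counts with COPD as the
#' positive class.  Values are kept at full precision; rounding (2
#' decimals, half-up) happens only in the print method.
#'
#' @param predicted predicted class labels.
#' @param truth true class labels (both classes present).
#' @return An object of class `evaluation_report`: confusion counts,
#'   per-class precision/recall/F1, sensitivity, specificity,
#'   accuracy, Youden's index.
#' @export
evaluate_classification <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stopf("predicted/truth length mismatch")
  p <- positive_labels(predicted); t <- positive_labels(truth)
  if (!any(t) || all(t)) stopf("both classes must be present in truth")
  confusion_metrics(tp = sum(p & t), fn = sum(!p & t),
                    tn = sum(!p & !t), fp = sum(p & !t))
}

#' Metrics from raw confusion counts
#'
#' @param tp,fn,tn,fp confusion counts with COPD positive.
#' @return An `evaluation_report`; see [evaluate_classification()].
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  n <- tp + fn + tn + fp
  prec_pos <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec_pos <- tp / (tp + fn)
  prec_neg <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  rec_neg <- tn / (tn + fp)
  f1 <- function(p, r) if (is.na(p) || p + r == 0) NA_real_ else
    2 * p * r / (p + r)
  structure(list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    precision_copd = prec_pos, recall_copd = rec_pos,
    f1_copd = f1(prec_pos, rec_pos),
    precision_control = prec_neg, recall_control = rec_neg,
    f1_control = f1(prec_neg, rec_neg),
    sensitivity = rec_pos, specificity = rec_neg,
    accuracy = (tp + tn) / n,
    youden = rec_pos + rec_neg - 1), class = "evaluation_report")
}

# Round half up at `digits` (R's round() is half-to-even).
#' @noRd
round_half_up <- function(x, digits = 2) {
  floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}

#' @export
print.evaluation_report <- function(x, digits = 2, ...) {
  r <- function(v) format(round_half_up(v, digits), nsmall = digits)
  cat("<evaluation_report>  (COPD = positive class)\n")
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n", x$tp, x$fn,
              x$tn, x$fp))
  cat(sprintf("  COPD:     precision %s  recall %s  F1 %s\n",
              r(x$precision_copd), r(x$recall_copd), r(x$f1_copd)))
  cat(sprintf("  control:  precision %s  recall %s  F1 %s\n",
              r(x$precision_control), r(x$recall_control),
              r(x$f1_control)))
  cat(sprintf("  sensitivity %s  specificity %s  accuracy %s  Youden %s\n",
              r(x$sensitivity), r(x$specificity), r(x$accuracy),
              r(x$youden)))
  cat("  note: fitted and evaluated in-sample (no held-out data)\n")
  invisible(x)
}

# Z-matrix of the active features, fit on the cohort.
#' @noRd
fit_zmatrix <- function(cohort, feature_subset, sd_type) {
  zs <- lapply(feature_subset, function(f)
    zscale(cohort[[f]], sd_type, name = f))
  names(zs) <- feature_subset
  z <- vapply(zs, `[[`, numeric(nrow(cohort)), "z")
  if (is.null(dim(z))) z <- matrix(z, nrow = 1,
                                   dimnames = list(NULL, feature_subset))
  list(z = z, mu = vapply(zs, `[[`, numeric(1), "mu"),
       sigma = vapply(zs, `[[`, numeric(1), "sigma"))
}

#' Fit a score model with fixed weights
#'
#' Z-scales the active features on the full cohort (in-sample, as the
#' screening procedure does), scores every subject, and sets the
#' classification threshold at the Youden optimum of the score's ROC
#' curve.
#'
#' @param cohort data.frame with feature columns and a `label` column
#'   (COPD positive).
#' @param weights named positive weights for the active features.
#' @param feature_subset which features are active (default all four;
#'   a 3-feature subset reproduces the reduced-model comparison).
#' @param sd_type passed to [zscale()].
#' @return An object of class `score_model`: `mu`, `sigma`, `weights`,
#'   `threshold`, `feature_subset`, `sd_type`, plus in-sample `scores`
#'   and `evaluation`.
#' @export
fit_score_model <- function(cohort, weights,
                            feature_subset = FEATURES,
                            sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  feature_subset <- match.arg(feature_subset, FEATURES,
                              several.ok = TRUE)
  pos <- check_cohort(cohort, feature_subset)
  if (!setequal(names(weights), feature_subset))
    stopf("weights must name exactly the active features")
  if (any(weights <= 0)) stopf("weights must be positive")
  fz <- fit_zmatrix(cohort, feature_subset, sd_type)
  scores <- composite_score(fz$z, weights[feature_subset])
  yj <- youden_threshold(roc_curve(scores, pos))
  ev <- evaluate_classification(classify(scores, yj$threshold), pos)
  structure(list(mu = fz$mu, sigma = fz$sigma,
                 weights = weights[feature_subset],
                 threshold = yj$threshold,
                 feature_subset = feature_subset, sd_type = sd_type,
                 youden = yj$youden, scores = scores, evaluation = ev),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat("<score_model>\n  features:", paste(x$feature_subset,
                                          collapse = ", "), "\n")
  cat("  weights: ", paste(sprintf("%s=%g", names(x$weights), x$weights),
                           collapse = "  "), "\n")
  cat(sprintf("  threshold %.4f (Youden %.3f), sigma convention: %s\n",
              x$threshold, x$youden, x$sd_type))
  if (isTRUE(x$below_criterion))
    cat("  WARNING: no weight draw reached the Youden admission criterion\n")
  invisible(x)
}

#' Score new subjects with a fitted model
#'
#' Applies the stored Z-scaling and weights, then the stored
#' threshold.
#'
#' @param model a [fit_score_model()] / [weight_search()] result.
#' @param table data.frame with the model's feature columns.
#' @return data.frame with `score` and `predicted` columns appended.
#' @export
score_subjects <- function(model, table) {
  stopifnot(inherits(model, "score_model"))
  fs <- model$feature_subset
  miss <- setdiff(fs, names(table))
  if (length(miss)) stopf("table lacks feature columns: %s",
                          paste(miss, collapse = ", "))
  z <- vapply(fs, function(f)
    (table[[f]] - model$mu[[f]]) / model$sigma[[f]],
    numeric(nrow(table)))
  if (is.null(dim(z))) z <- matrix(z, 1, dimnames = list(NULL, fs))
  table$score <- drop(z %*% model$weights[fs])
  table$predicted <- classify(table$score, model$threshold)
  table
}

#' Randomized weight search
#'
#' Draws `n_iter` integer weight vectors uniformly from
#' `weight_range`, fits the Z-scaled composite score and its Youden
#' threshold for each, and keeps candidates whose Youden index exceeds
#' `youden_min` with specificity at least `min_specificity` (the
#' "balanced tendency" admission rule).  Among candidates, selection
#' is by maximal accuracy, ties broken by higher COPD recall, then
#' higher Youden index, then earliest draw.  If nothing passes, the
#' best-Youden model is returned flagged `below_criterion`.
#'
#' @inheritParams fit_score_model
#' @param n_iter number of weight draws (default 1000).
#' @param weight_range inclusive integer range weights are drawn from.
#' @param rng_seed integer seed; identical seeds give identical
#'   searches.
#' @param youden_min admission criterion on Youden's index (strict
#'   inequality).
#' @param min_specificity admission criterion on specificity; set to 0
#'   to disable the balance filter.
#' @return The selected `score_model`, with the full `search_log`
#'   data.frame attached.
#' @export
weight_search <- function(cohort, n_iter = 1000, weight_range = c(1, 50),
                          rng_seed = 1, youden_min = 0.70,
                          min_specificity = 0.5,
                          feature_subset = FEATURES,
                          sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  feature_subset <- match.arg(feature_subset, FEATURES, several.ok = TRUE)
  if (!is_count(n_iter)) stopf("n_iter must be a positive integer")
  pos <- check_cohort(cohort, feature_subset)
  fz <- fit_zmatrix(cohort, feature_subset, sd_type)
  k <- length(feature_subset)
  wmat <- with_seed(rng_seed, matrix(
    sample(seq.int(weight_range[1], weight_range[2]), n_iter * k,
           replace = TRUE), n_iter, k,
    dimnames = list(NULL, feature_subset)))
  log <- data.frame(iter = seq_len(n_iter))
  for (f in feature_subset) log[[paste0("w_", f)]] <- wmat[, f]
  met <- matrix(NA_real_, n_iter, 5,
                dimnames = list(NULL, c("threshold", "youden", "accuracy",
                                        "recall_copd", "specificity")))
  for (i in seq_len(n_iter)) {
    scores <- drop(fz$z %*% wmat[i, ])
    yj <- youden_threshold(roc_curve(scores, pos))
    ev <- evaluate_classification(classify(scores, yj$threshold), pos)
    met[i, ] <- c(yj$threshold, yj$youden, ev$accuracy, ev$recall_copd,
                  ev$specificity)
  }
  log <- cbind(log, as.data.frame(met))
  log$passes <- log$youden > youden_min & log$specificity >= min_specificity
  cand <- which(log$passes)
  below <- length(cand) == 0
  pool <- if (below) seq_len(n_iter) else cand
  sel <- pool[order(-log$accuracy[pool], -log$recall_copd[pool],
                    -log$youden[pool], log$iter[pool])][1]
  if (below)   # nothing admitted: fall back to best Youden
    sel <- pool[order(-log$youden[pool], -log$accuracy[pool],
                      log$iter[pool])][1]
  model <- fit_score_model(cohort, wmat[sel, ], feature_subset, sd_type)
  model$below_criterion <- below
  model$selected_iter <- sel
  model$search_log <- log
  model$rng_seed <- as.integer(rng_seed)
  model$criteria <- list(youden_min = youden_min,
                         min_specificity = min_specificity,
                         n_iter = n_iter, weight_range = weight_range)
  model
}

#' Composite-vs-single-feature AUC comparison
#'
#' For each active feature: its standalone AUC, the composite score's
#' AUC, the observed difference (composite minus feature), and whether
#' that difference exceeds the user-supplied minimal clinically
#' important difference (MCID) threshold.  MCID thresholds are inputs;
#' their derivation is out of scope.
#'
#' @inheritParams fit_score_model
#' @param model a fitted `score_model`.
#' @param mcid_thresholds named numeric vector of per-feature MCID
#'   upper thresholds.
#' @return data.frame with one row per feature.
#' @export
auc_difference_table <- function(cohort, model, mcid_thresholds) {
  stopifnot(inherits(model, "score_model"))
  pos <- check_cohort(cohort, model$feature_subset)
  scored <- score_subjects(model, cohort)
  comp <- auc(scored$score, pos)
  rows <- lapply(model$feature_subset, function(f) {
    a <- auc(cohort[[f]], pos)
    d <- comp - a
    thr <- if (f %in% names(mcid_thresholds)) mcid_thresholds[[f]]
           else NA_real_
    data.frame(feature = f, feature_auc = a, composite_auc = comp,
               observed_difference = d, mcid_threshold = thr,
               mcid_met = if (is.na(thr)) NA else d > thr)
  })
  do.call(rbind, rows)
}

#' Point-biserial correlation of a feature with the class label
#'
#' Pearson correlation between a feature column and the binary label
#' (COPD = 1).
#'
#' @param x numeric feature column (>= 3 values, non-constant).
#' @param labels class labels.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, labels) {
  pos <- positive_labels(labels)
  if (length(x) < 3) stopf("need >= 3 subjects")
  if (length(unique(x)) < 2 || (!any(pos) || all(pos)))
    stopf("feature and labels must both be non-constant")
  cor(x, as.numeric(pos))
}
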