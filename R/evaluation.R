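# Comparing paired experimental and predicted scores: correlation and error
# metrics with percentile-bootstrap CIs, ROC/AUC, precision-recall, binned
# recall versus effect strength, and the regression line for plots.

#' Align experimental and predicted scores on their common variants
#'
#' Predictors fail on some residues and experiments probe only a subset of
#' all possible SAVs, so every comparison runs on the largest common subset
#' of variant keys. Restricted to SAVs (synonymous records never enter the
#' pairing) on one effect side, ordered deterministically by position then
#' substituted residue.
#'
#' @param normalized a `dms_normalized` data frame from
#'   [normalize_dataset()].
#' @param pred a [prediction_set()] with `unit_score` filled (run
#'   [rescale_to_unit()] first).
#' @param side `"deleterious"` or `"beneficial"`.
#' @param scheme optional classification scheme (`"syn90"`, `"syn95"`,
#'   `"syn99"`) whose labels to carry along.
#' @return Object of class `paired_scores` with fields `x` (experimental
#'   normalized scores), `p` (predicted unit scores), `labels` (or `NULL`),
#'   `keys`, `side`, `n`. `n == 0` signals an empty intersection; metric
#'   functions refuse such input.
#' @export
pair_scores <- function(normalized, pred, side = c("deleterious", "beneficial"),
                        scheme = NULL) {
  side <- match.arg(side)
  stopifnot(inherits(pred, "prediction_set"))
  ex <- as.data.frame(normalized)
  ex <- ex[!ex$is_synonymous & ex$effect_side == side, ]
  ps <- pred$scores[!is.na(pred$scores$unit_score), ]
  if (nrow(ps) == 0 && nrow(pred$scores) > 0)
    stop_dmsbench("prediction set has no unit scores; run rescale_to_unit()",
                  class = "dmsbench_config_error")
  ex_key <- variant_key(ex)
  p_key <- variant_key(ps)
  common <- intersect(ex_key, p_key)
  ex <- ex[match(common, ex_key), ]
  ord <- order(ex$position, ex$mut_aa)
  ex <- ex[ord, ]
  common <- common[ord]
  labels <- NULL
  if (!is.null(scheme)) {
    col <- paste0("label_", scheme)
    if (!col %in% names(ex))
      stop_dmsbench("no ", col, " column in normalized data",
                    class = "dmsbench_config_error")
    labels <- ex[[col]]
  }
  structure(list(x = ex$normalized_score,
                 p = ps$unit_score[match(common, p_key)],
                 labels = labels, keys = common, side = side,
                 n = length(common)),
            class = "paired_scores")
}

#' @export
print.paired_scores <- function(x, ...) {
  cat("<paired_scores> n = ", x$n, " (", x$side, " side)\n", sep = "")
  invisible(x)
}

metric_result <- function(metric, estimate, ci, n, reps, seed,
                          status = "ok") {
  structure(list(metric = metric, estimate = estimate,
                 ci_low = ci[1], ci_high = ci[2], n = n,
                 bootstrap_reps = reps, seed = seed, status = status),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat("<metric_result> ", x$metric, " = ", signif(x$estimate, 4),
      " [", signif(x$ci_low, 4), ", ", signif(x$ci_high, 4),
      "] (n = ", x$n, ", ", x$bootstrap_reps, " bootstrap reps, status ",
      x$status, ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.metric_result <- function(x, ...) {
  data.frame(metric = x$metric, estimate = x$estimate, ci_low = x$ci_low,
             ci_high = x$ci_high, n = x$n, reps = x$bootstrap_reps,
             seed = x$seed, status = x$status, stringsAsFactors = FALSE)
}

spearman_stat <- function(x, p) {
  if (length(unique(x)) < 2 || length(unique(p)) < 2) return(NA_real_)
  stats::cor(x, p, method = "spearman")  # average ranks for ties
}

pearson_stat <- function(x, p) {
  if (length(unique(x)) < 2 || length(unique(p)) < 2) return(NA_real_)
  stats::cor(x, p, method = "pearson")
}

mse_stat <- function(x, p) mean((x - p)^2)

#' Percentile bootstrap confidence interval for a paired statistic
#'
#' Resamples index pairs with replacement `reps` times, recomputes the
#' statistic on each resample, and returns its 2.5th and 97.5th empirical
#' percentiles. Seeded and reproducible. Fails when the statistic is
#' undefined (e.g. a constant resample for a correlation) on more than half
#' of the resamples.
#'
#' @param stat function of two aligned numeric vectors returning a scalar
#'   (may return `NA` when undefined).
#' @param x,p aligned numeric vectors.
#' @param reps number of bootstrap resamples (>= 2; 1000 by default).
#' @param seed integer RNG seed.
#' @param conf confidence level (0.95).
#' @return Numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(stat, x, p, reps = 1000, seed = 1, conf = 0.95) {
  n <- length(x)
  stopifnot(length(p) == n, reps >= 2, n >= 3)
  set.seed(seed)
  boot <- vapply(seq_len(reps), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    stat(x[idx], p[idx])
  }, numeric(1))
  if (mean(is.na(boot)) > 0.5)
    stop_dmsbench("statistic undefined on more than half of the resamples",
                  class = "dmsbench_refusal_error")
  alpha <- (1 - conf) / 2
  stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, type = 7,
                  names = FALSE)
}

paired_metric <- function(paired, metric, stat, min_n, reps, seed) {
  stopifnot(inherits(paired, "paired_scores"))
  if (paired$n < min_n)
    stop_dmsbench("need n >= ", min_n, " paired scores, have ", paired$n,
                  class = "dmsbench_refusal_error")
  est <- stat(paired$x, paired$p)
  if (is.na(est))
    return(metric_result(metric, NA_real_, c(NA_real_, NA_real_), paired$n,
                         0L, seed, status = "undefined"))
  ci <- if (reps >= 2 && paired$n >= 3)
    bootstrap_ci(stat, paired$x, paired$p, reps = reps, seed = seed)
  else c(NA_real_, NA_real_)
  metric_result(metric, est, ci, paired$n, if (paired$n >= 3) reps else 0L,
                seed)
}

#' Spearman rank correlation with bootstrap CI
#'
#' Rank correlation (average ranks for ties) between experimental and
#' predicted scores; the primary comparison measure, robust to the monotone
#' rescalings both score types undergo. Constant input yields an
#' *undefined* result (reported as missing, never as 0).
#'
#' @param paired a [pair_scores()] result with `n >= 3`.
#' @param reps bootstrap resamples (0 skips the CI).
#' @param seed integer RNG seed.
#' @return A `metric_result`.
#' @export
spearman_rho <- function(paired, reps = 1000, seed = 1) {
  paired_metric(paired, "spearman_rho", spearman_stat, 3, reps, seed)
}

#' Pearson correlation with bootstrap CI
#'
#' Product-moment correlation, reported for comparability with other
#' studies; DMS score distributions are typically skewed with outliers, so
#' interpretation should rest on [spearman_rho()].
#'
#' @inheritParams spearman_rho
#' @return A `metric_result`.
#' @export
pearson_r <- function(paired, reps = 1000, seed = 1) {
  paired_metric(paired, "pearson_r", pearson_stat, 3, reps, seed)
}

#' Mean squared error with bootstrap CI
#'
#' Mean of squared differences between experimental and predicted unit
#' scores. Low MSE alone does not imply variant-specific signal: a
#' prediction that merely mimics the experimental score distribution (see
#' [shuffle_baseline()]) can score just as well.
#'
#' @inheritParams spearman_rho
#' @return A `metric_result`.
#' @export
mse <- function(paired, reps = 1000, seed = 1) {
  paired_metric(paired, "mse", mse_stat, 1, reps, seed)
}

roc_points <- function(pos, scores) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- pos[ord]
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)  # one point per distinct threshold
  data.frame(fpr = c(0, cumsum(!y)[last_of_group] / sum(!pos)),
             tpr = c(0, cumsum(y)[last_of_group] / sum(pos)))
}

trapezoid_auc <- function(pts) {
  sum(diff(pts$fpr) * (pts$tpr[-nrow(pts)] + pts$tpr[-1]) / 2)
}

auc_stat_factory <- function() {
  function(labels_num, scores) {
    pos <- labels_num > 0
    if (all(pos) || !any(pos)) return(NA_real_)
    trapezoid_auc(roc_points(pos, scores))
  }
}

#' ROC curve and AUC with bootstrap CI
#'
#' Sweeps every distinct score threshold (positive class *effect*, higher
#' score = more effect), giving one ROC point per threshold; tied scores
#' collapse into a single point, so the trapezoidal AUC equals the
#' probability that a random effect variant outscores a random neutral one,
#' counting ties as one half. CIs come from the same percentile bootstrap
#' as the other metrics.
#'
#' @param labels vector with values `"effect"`/`"neutral"` (or logical,
#'   `TRUE` = effect); both classes must be present.
#' @param scores numeric unit scores aligned with `labels`.
#' @param reps bootstrap resamples (0 skips the CI).
#' @param seed integer RNG seed.
#' @return Object of class `roc_result` with fields `points` (data frame
#'   `fpr`, `tpr`), `auc`, `ci_low`, `ci_high`, `n`.
#' @export
roc_and_auc <- function(labels, scores, reps = 1000, seed = 1) {
  pos <- if (is.logical(labels)) labels else labels == "effect"
  keep <- !is.na(pos) & !is.na(scores)
  pos <- pos[keep]
  scores <- scores[keep]
  if (all(pos) || !any(pos))
    stop_dmsbench("both classes must be present for ROC analysis",
                  class = "dmsbench_refusal_error")
  pts <- roc_points(pos, scores)
  auc <- trapezoid_auc(pts)
  ci <- if (reps >= 2 && length(pos) >= 3)
    bootstrap_ci(auc_stat_factory(), as.numeric(pos), scores,
                 reps = reps, seed = seed)
  else c(NA_real_, NA_real_)
  structure(list(points = pts, auc = auc, ci_low = ci[1], ci_high = ci[2],
                 n = length(pos), bootstrap_reps = reps, seed = seed),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", signif(x$auc, 4), " [", signif(x$ci_low, 4),
      ", ", signif(x$ci_high, 4), "] (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Confusion counts at fixed binary calls
#'
#' @param labels reference labels (`"effect"`/`"neutral"` or logical).
#' @param calls predicted labels in the same encoding.
#' @return Named integer vector `tp, fp, fn, tn`.
#' @export
confusion_counts <- function(labels, calls) {
  pos <- if (is.logical(labels)) labels else labels == "effect"
  called <- if (is.logical(calls)) calls else calls == "effect"
  c(tp = sum(pos & called), fp = sum(!pos & called),
    fn = sum(pos & !called), tn = sum(!pos & !called))
}

#' Operating point of a binary classifier on the ROC plane
#'
#' @inheritParams confusion_counts
#' @return Named numeric `c(fpr, tpr)`.
#' @export
operating_point <- function(labels, calls) {
  cc <- confusion_counts(labels, calls)
  c(fpr = unname(cc["fp"] / (cc["fp"] + cc["tn"])),
    tpr = unname(cc["tp"] / (cc["tp"] + cc["fn"])))
}

#' Precision-recall curve
#'
#' Precision `TP/(TP+FP)` and recall `TP/(TP+FN)` at every distinct score
#' threshold (variants scoring at or above the threshold are called
#' effect). Thresholds where no variant is called positive would leave
#' precision undefined and are omitted; by construction the highest score
#' always yields at least one call, so the curve is never empty.
#'
#' @inheritParams roc_and_auc
#' @return Data frame with columns `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(labels, scores) {
  pos <- if (is.logical(labels)) labels else labels == "effect"
  if (!any(pos))
    stop_dmsbench("at least one effect-labeled variant required",
                  class = "dmsbench_refusal_error")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  out <- lapply(thresholds, function(t) {
    called <- scores >= t
    tp <- sum(pos & called)
    fp <- sum(!pos & called)
    if (tp + fp == 0) return(NULL)
    data.frame(threshold = t, recall = tp / sum(pos),
               precision = tp / (tp + fp))
  })
  do.call(rbind, out)
}

#' Recall binned by experimental effect strength
#'
#' Sorts the paired SAVs by experimental normalized score (ascending; ties
#' keep the deterministic key order) and splits them into `n_bins`
#' contiguous bins of (near-)equal count, spreading any remainder over the
#' lowest bins. Per bin it reports the mean experimental score, the count,
#' the recall (fraction of SAVs the classifier calls effect), and the
#' recall adjusted by subtracting the first bin's recall — the first bin
#' holds the weakest effects, so its recall approximates a method's
#' base calling rate.
#'
#' @param paired a [pair_scores()] result.
#' @param binary_calls vector of `"effect"`/`"neutral"` calls (or logical)
#'   aligned with `paired`.
#' @param n_bins number of bins (20 by default); requires `n >= n_bins`.
#' @return Data frame of class `binned_recall` with columns `bin`,
#'   `mean_score`, `count`, `recall`, `adjusted_recall`.
#' @export
binned_recall <- function(paired, binary_calls, n_bins = 20) {
  stopifnot(inherits(paired, "paired_scores"))
  called <- if (is.logical(binary_calls)) binary_calls else
    binary_calls == "effect"
  stopifnot(length(called) == paired$n)
  if (paired$n < n_bins)
    stop_dmsbench("need at least n_bins = ", n_bins, " paired scores, have ",
                  paired$n, class = "dmsbench_refusal_error")
  ord <- order(paired$x)  # stable: ties stay in key order
  x <- paired$x[ord]
  called <- called[ord]
  base <- paired$n %/% n_bins
  sizes <- rep(base, n_bins)
  rem <- paired$n %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- base + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  recall <- as.numeric(tapply(called, bin, mean))
  out <- data.frame(bin = seq_len(n_bins),
                    mean_score = as.numeric(tapply(x, bin, mean)),
                    count = sizes, recall = recall,
                    adjusted_recall = recall - recall[1])
  structure(out, class = c("binned_recall", "data.frame"))
}

#' Least-squares regression line for correlation plots
#'
#' Ordinary least squares of the predicted on the experimental scores;
#' purely descriptive, drawn on scatter plots alongside the correlation
#' estimates.
#'
#' @param paired a [pair_scores()] result with `n >= 2` and nonconstant
#'   experimental scores.
#' @return Named numeric `c(slope, intercept)`.
#' @export
regression_line <- function(paired) {
  stopifnot(inherits(paired, "paired_scores"))
  if (paired$n < 2 || length(unique(paired$x)) < 2)
    stop_dmsbench("need >= 2 paired scores with nonconstant x",
                  class = "dmsbench_refusal_error")
  fit <- stats::lm(p ~ x, data = data.frame(x = paired$x, p = paired$p))
  c(slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]))
}
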