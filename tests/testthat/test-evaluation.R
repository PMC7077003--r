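# Paired-score metrics, bootstrap CIs, ROC/PR, binned recall, regression.

test_that("pair_scores intersects variant keys on one effect side", {
  ds <- dataset_from_signed(c(-1, -2, -3), syn_signed = rnorm(15, 0, 0.1))
  norm <- normalize_dataset(ds)
  keys <- data.frame(protein_id = "P1", position = c(1, 3, 4), wt_aa = "A",
                     mut_aa = "V", stringsAsFactors = FALSE)
  pred <- pred_from_unit(keys, c(0.1, 0.9, 0.5))
  paired <- pair_scores(norm, pred, "deleterious")
  expect_equal(paired$n, 2)
  expect_equal(paired$keys, c("P1|1|A|V", "P1|3|A|V"))
  expect_equal(paired$p, c(0.1, 0.9))

  disjoint <- pred_from_unit(data.frame(protein_id = "P2", position = 1,
                                        wt_aa = "A", mut_aa = "V"), 0.5)
  expect_equal(pair_scores(norm, disjoint, "deleterious")$n, 0)

  full <- pred_from_unit(as.data.frame(norm)[!norm$is_synonymous, ],
                         c(0.2, 0.4, 0.6))
  expect_equal(pair_scores(norm, full, "deleterious")$n, 3)
})

test_that("spearman matches the rank-difference formula and flags constants", {
  paired <- make_paired(c(1, 2, 3, 4) / 4, c(1, 3, 2, 4) / 4)
  expect_equal(spearman_rho(paired, reps = 0)$estimate, 0.8)
  expect_equal(spearman_rho(make_paired(1:5 / 5, 1:5 / 5), reps = 0)$estimate, 1)
  expect_equal(spearman_rho(make_paired(1:5 / 5, 5:1 / 5), reps = 0)$estimate, -1)
  res <- spearman_rho(make_paired(1:5 / 5, rep(0.5, 5)), reps = 100)
  expect_equal(res$status, "undefined")
  expect_true(is.na(res$estimate))
  expect_error(spearman_rho(make_paired(c(0, 1), c(0, 1))),
               class = "dmsbench_refusal_error")
})

test_that("pearson and mse match their closed forms", {
  x <- c(0.1, 0.4, 0.7, 0.9)
  expect_equal(pearson_r(make_paired(x, 0.3 * x + 0.1), reps = 0)$estimate, 1)
  expect_equal(pearson_r(make_paired(c(0, 0.5, 1), c(1, 0.5, 0)),
                         reps = 0)$estimate, -1)
  expect_equal(mse(make_paired(x, x), reps = 0)$estimate, 0)
  expect_equal(mse(make_paired(x, x + 0.05), reps = 0)$estimate, 0.0025)
  expect_equal(mse(make_paired(c(0, 1), c(1, 1)), reps = 0)$estimate, 0.5)
})

test_that("the percentile bootstrap is seeded and degenerate-safe", {
  x <- seq(0.01, 1, length.out = 50)
  ci1 <- bootstrap_ci(function(a, b) cor(a, b, method = "spearman"),
                      x, x, reps = 200, seed = 7)
  ci2 <- bootstrap_ci(function(a, b) cor(a, b, method = "spearman"),
                      x, x, reps = 200, seed = 7)
  expect_identical(ci1, ci2)
  expect_equal(ci1, c(1, 1))  # perfectly correlated resamples
  expect_error(bootstrap_ci(function(a, b) NA_real_, x, x, reps = 10,
                            seed = 1),
               class = "dmsbench_refusal_error")
})

test_that("trapezoidal AUC equals the pairwise probability statistic", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(pos) || !any(pos)) pos[1:2] <- c(TRUE, FALSE)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # plenty of ties
    rr <- roc_and_auc(pos, scores, reps = 0)
    expect_equal(rr$auc, auc_oracle(pos, scores), tolerance = 1e-12)
    # complement symmetry needs tie-free scores
    tf <- sample(seq_len(n)) / n
    expect_equal(roc_and_auc(pos, tf, reps = 0)$auc +
                   roc_and_auc(pos, -tf, reps = 0)$auc, 1,
                 tolerance = 1e-12)
  }
  expect_equal(roc_and_auc(c(TRUE, TRUE, FALSE, FALSE),
                           c(0.9, 0.8, 0.2, 0.1), reps = 0)$auc, 1)
  expect_equal(roc_and_auc(c(TRUE, FALSE, TRUE), rep(0.5, 3), reps = 0)$auc,
               0.5)
  expect_error(roc_and_auc(c(TRUE, TRUE), c(0.1, 0.2), reps = 0),
               class = "dmsbench_refusal_error")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(29)
  for (i in 1:10) {
    n <- sample(30:120, 1)
    pos <- runif(n) < 0.4
    if (all(pos) || !any(pos)) pos[1:2] <- c(TRUE, FALSE)
    scores <- round(runif(n), 2)  # ties included
    ref <- as.numeric(pROC::auc(pROC::roc(response = pos,
                                          predictor = scores,
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_and_auc(pos, scores, reps = 0)$auc, ref,
                 tolerance = 1e-12)
  }
})

test_that("ROC points rise monotonically from (0,0) to (1,1)", {
  set.seed(19)
  pos <- runif(100) < 0.4
  scores <- runif(100)
  pts <- roc_and_auc(pos, scores, reps = 0)$points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("precision-recall points match hand counts", {
  labels <- c(TRUE, FALSE, TRUE, FALSE)
  scores <- c(0.9, 0.8, 0.7, 0.1)
  pr <- pr_curve(labels, scores)
  # at the 0.7 threshold: tp=2, fp=1, fn=0, tn=1
  at <- pr[pr$threshold == 0.7, ]
  expect_equal(at$precision, 2 / 3)
  expect_equal(at$recall, 1)
  expect_equal(confusion_counts(labels, scores >= 0.65),
               c(tp = 2L, fp = 1L, fn = 0L, tn = 1L))
  expect_equal(operating_point(labels, scores >= 0.65),
               c(fpr = 0.5, tpr = 1))

  perfect <- pr_curve(c(TRUE, TRUE, FALSE), c(0.9, 0.8, 0.1))
  expect_true(any(perfect$recall == 1 & perfect$precision == 1))
  all_eff <- pr_curve(rep(TRUE, 4), c(0.1, 0.5, 0.5, 0.9))
  expect_true(all(all_eff$precision == 1))
  expect_error(pr_curve(rep(FALSE, 3), c(0.1, 0.2, 0.3)),
               class = "dmsbench_refusal_error")
})

test_that("binned recall uses near-equal counts with the remainder in low bins", {
  paired <- make_paired(seq(0, 1, length.out = 41), runif(41))
  br <- binned_recall(paired, rep("effect", 41), n_bins = 20)
  expect_equal(sum(br$count), 41)
  expect_equal(br$count[1], 3)          # remainder goes to the lowest bin
  expect_true(all(diff(br$count) <= 0))
  expect_equal(br$recall, rep(1, 20))
  expect_equal(br$adjusted_recall, rep(0, 20))

  # calls only in the top experimental half give a clean step
  x <- seq(0.001, 1, length.out = 40)
  paired2 <- make_paired(x, x)
  calls <- ifelse(x > 0.5, "effect", "neutral")
  br2 <- binned_recall(paired2, calls, n_bins = 20)
  expect_equal(br2$recall, c(rep(0, 10), rep(1, 10)))
  expect_equal(br2$adjusted_recall[1], 0)

  expect_error(binned_recall(make_paired(1:5 / 5, 1:5 / 5), rep("effect", 5),
                             n_bins = 20),
               class = "dmsbench_refusal_error")
})

test_that("the regression line is ordinary least squares of p on x", {
  x <- seq(0, 1, length.out = 10)
  expect_equal(regression_line(make_paired(x, x)),
               c(slope = 1, intercept = 0))
  expect_equal(regression_line(make_paired(x, rep(0.5, 10))),
               c(slope = 0, intercept = 0.5))
  expect_equal(regression_line(make_paired(c(0, 1), c(0.2, 0.8))),
               c(slope = 0.6, intercept = 0.2))
  expect_error(regression_line(make_paired(rep(0.5, 5), x[1:5])),
               class = "dmsbench_refusal_error")
})
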