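# Harmonized predictors: conservation baseline, rescaling, binary calls
# and the null baselines.

test_that("naive conservation flips PSSM signs and emits 19 scores per position", {
  lo <- matrix(0L, 2, 20, dimnames = list(NULL, AA_ALPHABET))
  seqq <- "AC"
  lo[1, "V"] <- 5L    # favored substitution -> low effect
  lo[1, "W"] <- -5L   # disfavored -> high effect
  lo[2, "G"] <- 2L
  lo[2, "Y"] <- -3L
  nc <- naive_conservation(pssm_profile("P1", seqq, lo))
  expect_equal(nrow(nc$scores), 19 * 2)
  expect_false(any(variant_key(nc$scores) %in% c("P1|1|A|A", "P1|2|C|C")))
  sc <- function(pos, mut)
    nc$scores$raw_score[nc$scores$position == pos & nc$scores$mut_aa == mut]
  expect_equal(sc(1, "V"), -5)
  expect_equal(sc(1, "W"), 5)
  # order reversal: log-odds 2 vs -3 at one position
  expect_gt(sc(2, "Y"), sc(2, "G"))
})

test_that("rescale_to_unit maps the theoretical range linearly, with reversal", {
  keys <- data.frame(protein_id = "P1", position = 1:3, wt_aa = "A",
                     mut_aa = c("V", "G", "W"), stringsAsFactors = FALSE)
  fwd <- prediction_set(method_spec("m", -100, 100),
                        data.frame(keys, raw_score = c(100, 0, -100)))
  expect_equal(rescale_to_unit(fwd)$scores$unit_score, c(1, 0.5, 0))
  rev <- prediction_set(method_spec("sift", 0, 1, reversed = TRUE,
                                    default_threshold = 0.05),
                        data.frame(keys, raw_score = c(0, 0.5, 1)))
  expect_equal(rescale_to_unit(rev)$scores$unit_score, c(1, 0.5, 0))
  expect_error(prediction_set(method_spec("bad", 1, 1), NULL),
               class = "dmsbench_config_error")
})

test_that("binary calls are strict at the oriented default threshold", {
  keys <- data.frame(protein_id = "P1", position = 1:3, wt_aa = "A",
                     mut_aa = c("V", "G", "W"), stringsAsFactors = FALSE)
  nc_spec <- method_spec("naive_conservation", -17, 17,
                         default_threshold = 0)
  nc <- prediction_set(nc_spec, data.frame(keys, raw_score = c(0, 1, -1)))
  expect_equal(unname(binary_call(nc)), c("neutral", "effect", "neutral"))

  # SIFT-style: raw 0.04 with default cutoff 0.05 on the reversed scale
  # orients to 0.96 > 0.95, hence effect; raw 0.06 orients below, neutral
  sift <- prediction_set(method_spec("sift", 0, 1, reversed = TRUE,
                                     default_threshold = 0.05),
                         data.frame(keys, raw_score = c(0.04, 0.06, 0.05)))
  expect_equal(unname(binary_call(sift)), c("effect", "neutral", "neutral"))
})

test_that("beneficial-range mapping is a rank-preserving min-max map", {
  keys <- data.frame(protein_id = "P1", position = 1:3, wt_aa = "A",
                     mut_aa = c("V", "G", "W"), stringsAsFactors = FALSE)
  spec <- method_spec("envision_like", 0, 5, beneficial_range = c(0, 0.2))
  ben <- prediction_set(spec, data.frame(keys, raw_score = c(1, 1.5, 2)))
  mapped <- map_beneficial_range(ben)
  expect_equal(mapped$scores$unit_score, c(0, 0.1, 0.2))
  ref <- c(3, 1, 2)
  expect_equal(cor(mapped$scores$unit_score, ref, method = "spearman"),
               cor(ben$scores$raw_score, ref, method = "spearman"))
  flat <- map_beneficial_range(
    prediction_set(spec, data.frame(keys, raw_score = rep(1.2, 3))))
  expect_equal(flat$scores$unit_score, rep(0.1, 3))
  no_range <- prediction_set(method_spec("m", 0, 1),
                             data.frame(keys, raw_score = c(0.1, 0.2, 0.3)))
  expect_error(map_beneficial_range(no_range),
               class = "dmsbench_config_error")
})

test_that("shuffle baseline permutes scores reproducibly, preserving the multiset", {
  set.seed(3)
  sim <- generate_dms(sim_config(protein_length = 20, n_synonymous = 10,
                                 seed = 9))
  pred <- generate_predictor(sim$truth, 0.8, seed = 4)
  sh1 <- shuffle_baseline(pred, seed = 99)
  sh2 <- shuffle_baseline(pred, seed = 99)
  expect_identical(sh1$scores$unit_score, sh2$scores$unit_score)
  expect_equal(sort(sh1$scores$unit_score), sort(pred$scores$unit_score))
  expect_false(identical(sh1$scores$unit_score, pred$scores$unit_score))

  single <- pred
  single$scores <- single$scores[1, ]
  expect_equal(shuffle_baseline(single, 1)$scores$unit_score,
               single$scores$unit_score)

  # rank correlation with the experiment vanishes on average over seeds
  truth_mag <- abs(sim$truth$true_effect)
  rhos <- vapply(1:60, function(s)
    cor(shuffle_baseline(pred, s)$scores$unit_score, truth_mag,
        method = "spearman"), numeric(1))
  expect_lt(abs(mean(rhos)), 0.03)
})

test_that("gaussian baseline reproduces the experimental mean and sd", {
  expect_equal(gaussian_baseline(rep(0.3, 50), seed = 1)$scores$unit_score,
               rep(0.3, 50))
  set.seed(5)
  x <- rnorm(20000, 0.5, 0.05)  # well inside [0,1]: clamping inert
  g <- gaussian_baseline(x, seed = 2)
  expect_equal(mean(g$scores$unit_score), mean(x), tolerance = 0.01)
  # E[(X - Y)^2] = 2 sigma^2 for independent draws with equal means
  expect_equal(mean((x - g$scores$unit_score)^2), 2 * var(x),
               tolerance = 0.05)
  expect_error(gaussian_baseline(0.5, seed = 1),
               class = "dmsbench_validation_error")
})

test_that("the bundled method registry harmonizes the supported methods", {
  reg <- load_method_registry()
  expect_true(all(c("naive_conservation", "snap2", "sift", "polyphen2",
                    "envision") %in% names(reg)))
  expect_true(reg$sift$reversed)
  expect_equal(reg$sift$default_threshold, 0.05)
  expect_equal(reg$envision$beneficial_range, c(0, 0.2))
  expect_equal(reg$naive_conservation$default_threshold, 0)
  expect_equal(reg$naive_conservation$raw_max, 17)
})
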