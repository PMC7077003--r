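# Harmonizing predictor scores onto the unit effect scale: method metadata,
# the naive conservation baseline from a PSSM, and the two null baselines.

#' Describe a prediction method
#'
#' Method metadata needed to harmonize its scores: the theoretical score
#' range, whether the raw scale is reversed (lower score = more effect, as
#' for SIFT), the default threshold for binary effect calls, and, for
#' methods that score beneficial variants on a separate footing
#' (Envision-style), the target interval their beneficial-side scores are
#' mapped onto.
#'
#' @param name method name.
#' @param raw_min,raw_max theoretical minimum and maximum raw score.
#' @param reversed `TRUE` when lower raw scores mean more effect.
#' @param default_threshold raw-units threshold for binary calls (a variant
#'   is called *effect* when its oriented score strictly exceeds the
#'   oriented threshold).
#' @param beneficial_range optional length-2 numeric, the unit-scale target
#'   interval for beneficial-side scores (e.g. `c(0, 0.2)`).
#' @return Object of class `method_spec`.
#' @export
method_spec <- function(name, raw_min, raw_max, reversed = FALSE,
                        default_threshold = (raw_min + raw_max) / 2,
                        beneficial_range = NULL) {
  if (!is.numeric(raw_min) || !is.numeric(raw_max) || raw_min >= raw_max)
    stop_dmsbench("raw_min must be < raw_max",
                  class = "dmsbench_config_error")
  if (default_threshold < raw_min || default_threshold > raw_max)
    stop_dmsbench("default_threshold must lie within [raw_min, raw_max]",
                  class = "dmsbench_config_error")
  structure(list(name = name, raw_min = raw_min, raw_max = raw_max,
                 reversed = isTRUE(reversed),
                 default_threshold = default_threshold,
                 beneficial_range = beneficial_range),
            class = "method_spec")
}

#' Load the bundled method registry
#'
#' Per-method harmonization settings (theoretical bounds, reversal, default
#' thresholds, beneficial-range mapping) are data, not logic: they live in
#' an editable YAML registry. The bundled registry covers SNAP2-, SIFT-,
#' PolyPhen-2- and Envision-style score files plus the naive conservation
#' baseline.
#'
#' @param path registry file; defaults to the bundled one.
#' @return Named list of [method_spec()] objects.
#' @export
load_method_registry <- function(path = system.file("extdata",
                                                    "method_registry.yaml",
                                                    package = "dmsbench")) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(m) {
    method_spec(name = m$name, raw_min = m$raw_min, raw_max = m$raw_max,
                reversed = isTRUE(m$reversed),
                default_threshold = m$default_threshold %||%
                  ((m$raw_min + m$raw_max) / 2),
                beneficial_range = if (!is.null(m$beneficial_range))
                  as.numeric(m$beneficial_range))
  })
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Construct a prediction set
#'
#' One method's per-variant scores: raw scores as read from the method's
#' output, and, once [rescale_to_unit()] has run, harmonized `unit_score`
#' values on `[0, 1]` (0 = no effect, 1 = highest effect).
#'
#' @param method a [method_spec()].
#' @param scores data frame with columns `protein_id`, `position`, `wt_aa`,
#'   `mut_aa`, `raw_score` and optionally `unit_score`.
#' @return Object of class `prediction_set`.
#' @export
prediction_set <- function(method, scores) {
  stopifnot(inherits(method, "method_spec"))
  required <- c("protein_id", "position", "wt_aa", "mut_aa", "raw_score")
  missing_cols <- setdiff(required, names(scores))
  if (length(missing_cols) > 0)
    stop_dmsbench("scores is missing column(s): ",
                  paste(missing_cols, collapse = ", "),
                  class = "dmsbench_config_error")
  out_of_range <- scores$raw_score < method$raw_min |
    scores$raw_score > method$raw_max
  if (any(out_of_range))
    stop_dmsbench(sum(out_of_range), " score(s) outside the declared range [",
                  method$raw_min, ", ", method$raw_max, "] for method ",
                  method$name, " (first offender: ",
                  variant_key(scores[which(out_of_range)[1], ]), ")",
                  class = "dmsbench_validation_error")
  scores <- as.data.frame(scores)
  if (!"unit_score" %in% names(scores))
    scores$unit_score <- rep(NA_real_, nrow(scores))
  bad_unit <- !is.na(scores$unit_score) &
    (scores$unit_score < 0 | scores$unit_score > 1)
  if (any(bad_unit))
    stop_dmsbench("unit_score values outside [0, 1]",
                  class = "dmsbench_validation_error")
  rownames(scores) <- NULL
  structure(list(method = method, scores = scores), class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set> ", x$method$name, ": ", nrow(x$scores),
      " variant scores (", sum(!is.na(x$scores$unit_score)),
      " harmonized)\n", sep = "")
  invisible(x)
}

#' Naive conservation baseline from a PSSM
#'
#' The baseline predictor reads effect straight off a PSI-BLAST profile:
#' for every position and every non-native amino acid (19 per position) the
#' raw score is the sign-flipped log-odds value, so less frequent
#' substitutions score as higher effect. It is deliberately simple — profile
#' search output feeds, in some form, into every sophisticated method — and
#' serves as the conservation floor those methods must beat.
#'
#' @param pssm a [pssm_profile()].
#' @param method a [method_spec()] for the flipped scale; defaults to the
#'   bundled `naive_conservation` entry (bounds (-17, 17), binary calls
#'   *effect* when the flipped score is above 0).
#' @return A [prediction_set()] with 19 scores per profile position.
#' @export
naive_conservation <- function(pssm, method = NULL) {
  stopifnot(inherits(pssm, "pssm_profile"))
  if (is.null(method)) method <- load_method_registry()[["naive_conservation"]]
  n <- nchar(pssm$sequence)
  seq_aa <- strsplit(pssm$sequence, "")[[1]]
  pos <- rep(seq_len(n), each = 20)
  mut <- rep(AA_ALPHABET, times = n)
  keep <- mut != seq_aa[pos]
  raw <- -as.numeric(t(pssm$log_odds))[keep]  # sign flip: rarer => more effect
  scores <- data.frame(protein_id = pssm$protein_id, position = pos[keep],
                       wt_aa = seq_aa[pos[keep]], mut_aa = mut[keep],
                       raw_score = pmin(method$raw_max,
                                        pmax(method$raw_min, raw)),
                       stringsAsFactors = FALSE)
  prediction_set(method, scores)
}

orient_raw <- function(x, method) {
  if (method$reversed) method$raw_max + method$raw_min - x else x
}

#' Harmonize raw scores onto the unit interval
#'
#' Orients reversed methods (`s' = raw_max + raw_min - s`) and linearly maps
#' the oriented score from the method's theoretical range onto `[0, 1]`
#' (0 = no effect, 1 = highest effect). Values falling outside after
#' orientation are clamped with a message. Strictly monotone on the
#' oriented scale, so rank-based metrics downstream are unchanged.
#'
#' @param pred a [prediction_set()].
#' @return The prediction set with `unit_score` filled.
#' @export
rescale_to_unit <- function(pred) {
  m <- pred$method
  if (m$raw_max == m$raw_min)
    stop_dmsbench("degenerate score range for method ", m$name,
                  class = "dmsbench_config_error")
  unit <- (orient_raw(pred$scores$raw_score, m) - m$raw_min) /
    (m$raw_max - m$raw_min)
  n_clamped <- sum(unit < 0 | unit > 1)
  if (n_clamped > 0)
    message("rescale_to_unit: clamped ", n_clamped, " score(s) for ", m$name)
  pred$scores$unit_score <- clamp01(unit)
  pred
}

#' Map beneficial-side predictions onto a target interval
#'
#' For methods that score beneficial variants on their own footing
#' (Envision-style), the beneficial-side scores are min–max mapped onto the
#' method's `beneficial_range` (e.g. `[0, 0.2]`), preserving rank order.
#' When all scores are identical they map to the interval midpoint.
#'
#' @param pred a [prediction_set()] restricted to beneficial-side
#'   predictions of a method with `beneficial_range` set.
#' @param target optional length-2 numeric overriding the method's range.
#' @return The prediction set with `unit_score` set to the mapped values.
#' @export
map_beneficial_range <- function(pred, target = NULL) {
  target <- target %||% pred$method$beneficial_range
  if (is.null(target))
    stop_dmsbench("method ", pred$method$name, " has no beneficial_range",
                  class = "dmsbench_config_error")
  s <- orient_raw(pred$scores$raw_score, pred$method)
  rng <- range(s)
  pred$scores$unit_score <- if (rng[1] == rng[2])
    rep(mean(target), length(s))
  else
    target[1] + (s - rng[1]) / (rng[2] - rng[1]) * (target[2] - target[1])
  pred
}

#' Binary effect calls at the method's default threshold
#'
#' A variant is called *effect* when its oriented raw score strictly
#' exceeds the method's oriented default threshold (for the naive
#' conservation baseline: flipped score above 0), else *neutral*.
#'
#' @param pred a [prediction_set()].
#' @return Named character vector (`"effect"`/`"neutral"`) keyed by
#'   [variant_key()].
#' @export
binary_call <- function(pred) {
  m <- pred$method
  oriented <- orient_raw(pred$scores$raw_score, m)
  thr <- orient_raw(m$default_threshold, m)
  calls <- ifelse(oriented > thr, "effect", "neutral")
  stats::setNames(calls, variant_key(pred$scores))
}

#' Shuffled-score null baseline
#'
#' Permutes a method's harmonized scores uniformly at random across variant
#' keys. The score multiset — hence every marginal property — is unchanged;
#' only the assignment to variants is destroyed. Matching this baseline's
#' MSE reveals a method that mimics the experimental score distribution
#' without ranking variants.
#'
#' @param pred a [prediction_set()] with `unit_score` filled.
#' @param seed integer RNG seed; same seed, same permutation.
#' @return A new [prediction_set()] (method name suffixed `_shuffled`).
#' @export
shuffle_baseline <- function(pred, seed) {
  if (nrow(pred$scores) == 0)
    stop_dmsbench("empty prediction set", class = "dmsbench_validation_error")
  set.seed(seed)
  perm <- sample.int(nrow(pred$scores))
  pred$scores$raw_score <- pred$scores$raw_score[perm]
  pred$scores$unit_score <- pred$scores$unit_score[perm]
  pred$method$name <- paste0(pred$method$name, "_shuffled")
  pred
}

#' Gaussian null baseline around the experimental mean
#'
#' Predicts, for every variant, an independent draw from a normal
#' distribution with the mean and standard deviation of the experimental
#' score vector, clamped to the unit interval. A method must beat this to
#' demonstrate any variant-specific signal beyond the score distribution.
#'
#' @param experimental_scores numeric vector of experimental unit scores;
#'   may be named by variant key (names are carried over).
#' @param seed integer RNG seed.
#' @param keys optional data frame with variant key columns
#'   (`protein_id`, `position`, `wt_aa`, `mut_aa`) aligned with
#'   `experimental_scores`; when absent, placeholder keys are used.
#' @return A [prediction_set()] named `gaussian`.
#' @export
gaussian_baseline <- function(experimental_scores, seed, keys = NULL) {
  n <- length(experimental_scores)
  if (n < 2)
    stop_dmsbench("need at least 2 experimental scores",
                  class = "dmsbench_validation_error")
  mu <- mean(experimental_scores)
  sdev <- stats::sd(experimental_scores)
  set.seed(seed)
  draws <- clamp01(stats::rnorm(n, mu, sdev))
  if (is.null(keys))
    keys <- data.frame(protein_id = "x", position = seq_len(n),
                       wt_aa = "A", mut_aa = "V", stringsAsFactors = FALSE)
  prediction_set(method_spec("gaussian", 0, 1, default_threshold = 0.5),
                 data.frame(keys, raw_score = draws, unit_score = draws,
                            stringsAsFactors = FALSE))
}
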