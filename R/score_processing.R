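# Raw DMS scores -> wild-type-anchored signed scale -> per-side unit
# interpolation, plus the synonymous-variant classification schemes.

#' Anchor scores at wild type and orient the effect scale
#'
#' Subtracts the wild-type score and flips the sign if needed so that, on
#' the resulting signed scale, 0 is wild-type-like, negative values are
#' reduced fitness (deleterious) and positive values increased fitness
#' (beneficial). Assays are not symmetrical around wild type, so the two
#' sides are analyzed separately downstream.
#'
#' @param dataset a [dms_dataset()] with `wt_score` and `orientation` set.
#' @return The variants data frame with added columns `signed_score` and
#'   `effect_side` (`"deleterious"`, `"zero"`, `"beneficial"`), class
#'   `dms_anchored`.
#' @export
anchor_and_orient <- function(dataset) {
  stopifnot(inherits(dataset, "dms_dataset"))
  v <- dataset$variants
  v$signed_score <- if (dataset$orientation == "higher_is_fitter")
    v$raw_score - dataset$wt_score else dataset$wt_score - v$raw_score
  v$effect_side <- ifelse(v$signed_score < 0, "deleterious",
                          ifelse(v$signed_score > 0, "beneficial", "zero"))
  v$dataset_id <- dataset$dataset_id
  structure(v, class = c("dms_anchored", "data.frame"),
            dataset_id = dataset$dataset_id)
}

#' Interpolate effect magnitudes onto the unit interval, per side
#'
#' Within one dataset and one effect side, maps `|signed_score|` linearly
#' onto `[0, 1]` by dividing by the side's maximum magnitude, so 0 is
#' wild-type-like and 1 the strongest observed effect on that side. Rank
#' order within the side is untouched, hence Spearman correlations against
#' any fixed predictor are invariant to this step.
#'
#' @param anchored a `dms_anchored` data frame from [anchor_and_orient()].
#' @param side `"deleterious"` or `"beneficial"`.
#' @return Numeric vector of normalized scores for the rows of `anchored`
#'   on the requested side (non-synonymous and synonymous alike), named by
#'   row index; empty (with a warning) when the side has no variants.
#' @export
interpolate_unit <- function(anchored, side = c("deleterious", "beneficial")) {
  side <- match.arg(side)
  idx <- which(anchored$effect_side == side)
  if (length(idx) == 0) {
    warning("no variants on the ", side, " side")
    return(stats::setNames(numeric(0), character(0)))
  }
  mags <- abs(anchored$signed_score[idx])
  stats::setNames(mags / max(mags), idx)
}

#' Synonymous-variant neutrality interval
#'
#' Synonymous nucleotide variants leave the protein unchanged, so their
#' score spread proxies experimental noise around wild type. The interval
#' covering the middle `coverage` fraction of synonymous signed scores
#' (empirical quantiles, linear interpolation between order statistics)
#' defines what counts as neutral; variants outside it are *effect*.
#' `coverage` of 0.90/0.95/0.99 gives the `syn90`/`syn95`/`syn99` schemes.
#'
#' @param dataset a [dms_dataset()] or `dms_anchored` data frame.
#' @param coverage fraction of the synonymous distribution called neutral.
#' @param min_synonymous minimum number of synonymous records required;
#'   datasets below it are refused (excluded from classification analyses).
#' @return Object of class `syn_threshold` with fields `coverage`,
#'   `lower_bound`, `upper_bound` (signed-score units) and `n_syn`.
#' @export
synonymous_threshold <- function(dataset, coverage = 0.95,
                                 min_synonymous = 10) {
  stopifnot(coverage > 0, coverage < 1)
  anchored <- if (inherits(dataset, "dms_dataset"))
    anchor_and_orient(dataset) else dataset
  syn <- anchored$signed_score[anchored$is_synonymous]
  if (length(syn) < min_synonymous)
    stop_dmsbench("only ", length(syn), " synonymous variant(s); at least ",
                  min_synonymous, " required for thresholding",
                  class = "dmsbench_refusal_error")
  alpha <- (1 - coverage) / 2
  bounds <- stats::quantile(syn, probs = c(alpha, 1 - alpha), type = 7,
                            names = FALSE)
  structure(list(coverage = coverage, lower_bound = bounds[1],
                 upper_bound = bounds[2], n_syn = length(syn)),
            class = "syn_threshold")
}

#' @export
print.syn_threshold <- function(x, ...) {
  cat("<syn_threshold> syn", round(100 * x$coverage),
      ": neutral in [", signif(x$lower_bound, 4), ", ",
      signif(x$upper_bound, 4), "] (", x$n_syn, " synonymous)\n", sep = "")
  invisible(x)
}

#' Classify variants as neutral or effect
#'
#' A SAV is *neutral* iff its signed score lies inside the synonymous
#' interval, bounds included (the synonymous variants defining the bounds
#' must themselves be neutral), else *effect*. Deleterious and beneficial
#' effect SAVs stay distinguishable through `effect_side`. Synonymous rows
#' are not labeled.
#'
#' @param anchored a `dms_anchored` data frame.
#' @param threshold a [synonymous_threshold()] from the same dataset.
#' @return Character vector (`"neutral"`/`"effect"`, `NA` for synonymous
#'   rows) aligned with `anchored`.
#' @export
classify_variants <- function(anchored, threshold) {
  stopifnot(inherits(threshold, "syn_threshold"))
  s <- anchored$signed_score
  lab <- ifelse(s >= threshold$lower_bound & s <= threshold$upper_bound,
                "neutral", "effect")
  lab[anchored$is_synonymous] <- NA_character_
  lab
}

#' Normalize a DMS dataset and derive classification labels
#'
#' Runs the full per-measurement processing: anchoring and orientation,
#' per-side unit interpolation, and, when enough synonymous variants are
#' present, the requested synonymous classification schemes.
#'
#' @param dataset a [dms_dataset()].
#' @param schemes subset of `c("syn90", "syn95", "syn99")`.
#' @param min_synonymous passed to [synonymous_threshold()].
#' @return A data frame of class `dms_normalized` with columns
#'   `dataset_id`, `protein_id`, `position`, `wt_aa`, `mut_aa`,
#'   `is_synonymous`, `raw_score`, `signed_score`, `effect_side`,
#'   `normalized_score` and one `label_*` column per scheme (all `NA`, with
#'   attribute `classification_refused = TRUE`, when the dataset has too
#'   few synonymous variants). Thresholds used are stored in attribute
#'   `syn_thresholds`.
#' @export
normalize_dataset <- function(dataset, schemes = c("syn90", "syn95", "syn99"),
                              min_synonymous = 10) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  anchored <- anchor_and_orient(dataset)
  anchored$normalized_score <- 0
  for (side in c("deleterious", "beneficial")) {
    if (any(anchored$effect_side == side)) {
      u <- suppressWarnings(interpolate_unit(anchored, side))
      anchored$normalized_score[as.integer(names(u))] <- unname(u)
    }
  }
  thresholds <- list()
  refused <- FALSE
  for (sch in schemes) {
    cov <- as.numeric(sub("syn", "", sch)) / 100
    lab <- tryCatch({
      thr <- synonymous_threshold(anchored, coverage = cov,
                                  min_synonymous = min_synonymous)
      thresholds[[sch]] <- thr
      classify_variants(anchored, thr)
    }, dmsbench_refusal_error = function(e) {
      refused <<- TRUE
      rep(NA_character_, nrow(anchored))
    })
    anchored[[paste0("label_", sch)]] <- lab
  }
  keep <- c("dataset_id", "protein_id", "position", "wt_aa", "mut_aa",
            "is_synonymous", "raw_score", "signed_score", "effect_side",
            "normalized_score", paste0("label_", schemes))
  out <- as.data.frame(anchored)[keep]
  structure(out, class = c("dms_normalized", "data.frame"),
            dataset_id = dataset$dataset_id, protein_id = dataset$protein_id,
            provenance = dataset$provenance, syn_thresholds = thresholds,
            classification_refused = refused)
}

#' Write a normalized score set as TSV
#'
#' Fixed column order as produced by [normalize_dataset()].
#'
#' @param normalized a `dms_normalized` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(normalized, path) {
  utils::write.table(as.data.frame(normalized), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
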