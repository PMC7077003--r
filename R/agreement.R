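# Inter-experiment agreement: how much two DMS measurements of the same
# protein agree with each other versus with a prediction method.

#' Align two experiments and a prediction on their common variants
#'
#' Takes the largest possible set of SAVs shared, on the requested effect
#' side, by both experiments and the prediction. Both experiments' own
#' normalized scores and the predictor's unit scores are returned on that
#' one key set (the same harmonized predictor serves both pairings, so
#' `p1` and `p2` coincide).
#'
#' @param exp1,exp2 `dms_normalized` data frames for two measurements of
#'   the same protein.
#' @param pred a [prediction_set()] with `unit_score` filled.
#' @param side `"deleterious"` or `"beneficial"`.
#' @param min_n minimum common-subset size (3: below that the correlations
#'   are meaningless).
#' @return Object of class `experiment_pair` with fields `x1`, `x2`, `p1`,
#'   `p2`, `keys`, `n`, `side`.
#' @export
common_pair <- function(exp1, exp2, pred,
                        side = c("deleterious", "beneficial"), min_n = 3) {
  side <- match.arg(side)
  if (!identical(attr(exp1, "protein_id"), attr(exp2, "protein_id")))
    stop_dmsbench("experiments target different proteins",
                  class = "dmsbench_config_error")
  pick <- function(ex) {
    ex <- as.data.frame(ex)
    ex[!ex$is_synonymous & ex$effect_side == side, ]
  }
  e1 <- pick(exp1)
  e2 <- pick(exp2)
  ps <- pred$scores[!is.na(pred$scores$unit_score), ]
  k1 <- variant_key(e1)
  k2 <- variant_key(e2)
  kp <- variant_key(ps)
  common <- Reduce(intersect, list(k1, k2, kp))
  if (length(common) < min_n)
    stop_dmsbench("common subset has only ", length(common),
                  " SAV(s); at least ", min_n, " required",
                  class = "dmsbench_refusal_error")
  i1 <- match(common, k1)
  ord <- order(e1$position[i1], e1$mut_aa[i1])
  common <- common[ord]
  structure(list(x1 = e1$normalized_score[match(common, k1)],
                 x2 = e2$normalized_score[match(common, k2)],
                 p1 = ps$unit_score[match(common, kp)],
                 p2 = ps$unit_score[match(common, kp)],
                 keys = common, n = length(common), side = side),
            class = "experiment_pair")
}

#' @export
print.experiment_pair <- function(x, ...) {
  cat("<experiment_pair> n = ", x$n, " common SAVs (", x$side, " side)\n",
      sep = "")
  invisible(x)
}

#' Rank-correlation agreement difference
#'
#' Contrasts prediction-experiment with experiment-experiment rank
#' agreement: the mean of the predictor's Spearman correlation with each
#' experiment, minus the correlation between the experiments themselves.
#' Negative values mean the two experiments agree more with each other than
#' either does with the prediction.
#'
#' @param pair an [common_pair()] result.
#' @return Scalar difference, or `NA` when any correlation is undefined.
#' @export
delta_rho <- function(pair) {
  stopifnot(inherits(pair, "experiment_pair"))
  r1 <- spearman_stat(pair$x1, pair$p1)
  r2 <- spearman_stat(pair$x2, pair$p2)
  r12 <- spearman_stat(pair$x1, pair$x2)
  if (anyNA(c(r1, r2, r12))) return(NA_real_)
  (r1 + r2) / 2 - r12
}

#' Squared-error agreement difference
#'
#' The MSE between the two experiments minus the mean MSE between the
#' prediction and each experiment, all on the unit score scale. Negative
#' values mean the experiments are numerically closer to each other than
#' to the predictions.
#'
#' @param pair an [common_pair()] result.
#' @return Scalar difference.
#' @export
delta_mse <- function(pair) {
  stopifnot(inherits(pair, "experiment_pair"))
  mse_stat(pair$x1, pair$x2) -
    (mse_stat(pair$x1, pair$p1) + mse_stat(pair$x2, pair$p2)) / 2
}

#' Pairwise agreement table across same-protein datasets
#'
#' Builds the per-pair agreement statistics for every unordered pair of
#' normalized datasets sharing a protein, crossed with every predictor.
#' Pairs whose datasets share a provenance tag (same publication) are
#' skipped; beneficial-side pairs below `low_n` common SAVs are kept but
#' flagged, since small beneficial subsets make the statistics fragile.
#'
#' @param normalized_list list of `dms_normalized` data frames.
#' @param predictions named list of [prediction_set()] objects.
#' @param sides effect sides to analyze.
#' @param low_n flag threshold for small common subsets.
#' @return Data frame with columns `protein_id`, `dataset_1`, `dataset_2`,
#'   `method`, `side`, `n`, `rho_x1x2`, `delta_rho`, `mse_x1x2`,
#'   `delta_mse`, `status`.
#' @export
agreement_table <- function(normalized_list, predictions,
                            sides = c("deleterious", "beneficial"),
                            low_n = 10) {
  rows <- list()
  ids <- vapply(normalized_list, attr, character(1), "dataset_id")
  prots <- vapply(normalized_list, attr, character(1), "protein_id")
  provs <- vapply(normalized_list, function(x)
    as.character(attr(x, "provenance") %||% NA_character_), character(1))
  idx_pairs <- if (length(normalized_list) >= 2)
    utils::combn(seq_along(normalized_list), 2, simplify = FALSE) else list()
  for (ij in idx_pairs) {
    i <- ij[1]; j <- ij[2]
    if (prots[i] != prots[j]) next
    if (!is.na(provs[i]) && !is.na(provs[j]) && provs[i] == provs[j]) next
    for (mname in names(predictions)) {
      for (side in sides) {
        row <- data.frame(protein_id = prots[i], dataset_1 = ids[i],
                          dataset_2 = ids[j], method = mname, side = side,
                          n = 0L, rho_x1x2 = NA_real_, delta_rho = NA_real_,
                          mse_x1x2 = NA_real_, delta_mse = NA_real_,
                          status = "ok", stringsAsFactors = FALSE)
        res <- tryCatch({
          pair <- common_pair(normalized_list[[i]], normalized_list[[j]],
                              predictions[[mname]], side = side)
          row$n <- pair$n
          row$rho_x1x2 <- spearman_stat(pair$x1, pair$x2)
          row$delta_rho <- delta_rho(pair)
          row$mse_x1x2 <- mse_stat(pair$x1, pair$x2)
          row$delta_mse <- delta_mse(pair)
          if (pair$n < low_n) row$status <- "low_n"
          row
        }, dmsbench_error = function(e) {
          row$status <- "refused"
          row
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(protein_id = character(0), dataset_1 = character(0),
                      dataset_2 = character(0), method = character(0),
                      side = character(0), n = integer(0),
                      rho_x1x2 = numeric(0), delta_rho = numeric(0),
                      mse_x1x2 = numeric(0), delta_mse = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
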