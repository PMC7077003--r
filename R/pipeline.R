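# End-to-end benchmark: normalize -> classify -> harmonize predictors ->
# evaluate -> agreement, from in-memory objects or a YAML run config.

empty_df <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(t) vector(t, 0)),
                stringsAsFactors = FALSE)
}

#' Run the full benchmark
#'
#' For every dataset x predictor x effect side: pairs the scores on the
#' largest common SAV subset, computes Spearman, Pearson and MSE with
#' percentile-bootstrap CIs, and, for every classification scheme that
#' yields both classes, ROC/AUC (with the method's default-threshold
#' operating point), the precision-recall curve, and recall binned by
#' effect strength. Same-protein dataset pairs (differing provenance) are
#' compared through the agreement statistics. Any stage refusal (empty
#' intersection, single-class labels, undefined correlation, too few
#' synonymous variants) is recorded as a status row for that combination
#' and never aborts the others.
#'
#' All randomness derives from the single `seed` through a fixed hash of
#' (stage, dataset, method, ...), so reruns with an identical configuration
#' are byte-identical.
#'
#' @param datasets named list of [dms_dataset()] objects.
#' @param predictions named list of [prediction_set()] objects
#'   ([rescale_to_unit()] is applied to any set still lacking unit scores).
#' @param schemes classification schemes to apply.
#' @param sides effect sides to analyze.
#' @param reps bootstrap resamples (default 1000).
#' @param n_bins bins for the binned-recall analysis (default 20).
#' @param seed global integer seed.
#' @param out_dir optional directory; when given, all tables are written as
#'   TSV plus a JSON manifest.
#' @param add_shuffle also evaluate a shuffled-score null per predictor.
#' @param add_gaussian also evaluate the Gaussian-around-the-experimental-
#'   mean null per dataset.
#' @param min_synonymous passed to [normalize_dataset()].
#' @return Object of class `dmsbench_run`: list of data frames `metrics`,
#'   `roc`, `roc_points`, `pr_points`, `binned`, `agreement`, `refusals`,
#'   plus the `manifest` list.
#' @export
run_benchmark <- function(datasets, predictions,
                          schemes = c("syn90", "syn95", "syn99"),
                          sides = c("deleterious", "beneficial"),
                          reps = 1000, n_bins = 20, seed = 1,
                          out_dir = NULL, add_shuffle = FALSE,
                          add_gaussian = FALSE, min_synonymous = 10) {
  stopifnot(length(datasets) >= 1, length(predictions) >= 1, reps >= 2)
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, `[[`, character(1), "dataset_id")
  if (is.null(names(predictions)))
    names(predictions) <- vapply(predictions, function(p) p$method$name,
                                 character(1))
  normalized <- lapply(datasets, normalize_dataset, schemes = schemes,
                       min_synonymous = min_synonymous)
  predictions <- lapply(predictions, function(p) {
    if (all(is.na(p$scores$unit_score)) && nrow(p$scores) > 0)
      rescale_to_unit(p) else p
  })
  if (add_shuffle) {
    for (mname in names(predictions)) {
      sh <- shuffle_baseline(predictions[[mname]],
                             seed = derive_seed(seed, "shuffle", mname))
      predictions[[sh$method$name]] <- sh
    }
  }

  metrics <- list(); roc <- list(); roc_pts <- list(); pr_pts <- list()
  binned <- list(); refusals <- list()
  refuse <- function(stage, dataset_id, method, side, scheme, msg) {
    refusals[[length(refusals) + 1L]] <<- data.frame(
      stage = stage, dataset_id = dataset_id, method = method, side = side,
      scheme = scheme, reason = conditionMessage(msg) %||% as.character(msg),
      stringsAsFactors = FALSE)
  }

  for (did in names(normalized)) {
    norm <- normalized[[did]]
    preds_here <- predictions
    if (add_gaussian) {
      sav <- as.data.frame(norm)
      sav <- sav[!sav$is_synonymous, ]
      preds_here[["gaussian"]] <- gaussian_baseline(
        sav$normalized_score, seed = derive_seed(seed, "gaussian", did),
        keys = sav[c("protein_id", "position", "wt_aa", "mut_aa")])
    }
    for (mname in names(preds_here)) {
      pred <- preds_here[[mname]]
      calls <- binary_call(pred)
      for (side in sides) {
        paired <- pair_scores(norm, pred, side = side)
        if (paired$n == 0) {
          refuse("pairing", did, mname, side, NA_character_,
                 simpleError("empty intersection"))
          next
        }
        for (mfun in list(spearman_rho, pearson_r, mse)) {
          row <- tryCatch({
            res <- mfun(paired, reps = reps,
                        seed = derive_seed(seed, "metric", did, mname, side))
            cbind(data.frame(dataset_id = did, method = mname, side = side,
                             stringsAsFactors = FALSE),
                  as.data.frame(res))
          }, dmsbench_error = function(e) {
            refuse("metric", did, mname, side, NA_character_, e)
            NULL
          })
          if (!is.null(row)) metrics[[length(metrics) + 1L]] <- row
        }
        for (sch in schemes) {
          paired_l <- pair_scores(norm, pred, side = side, scheme = sch)
          lab <- paired_l$labels
          if (all(is.na(lab))) {
            refuse("classification", did, mname, side, sch,
                   simpleError("no labels (too few synonymous variants)"))
            next
          }
          res <- tryCatch({
            rr <- roc_and_auc(lab, paired_l$p, reps = reps,
                              seed = derive_seed(seed, "auc", did, mname,
                                                 side, sch))
            op <- operating_point(lab[!is.na(lab)],
                                  calls[paired_l$keys][!is.na(lab)])
            roc[[length(roc) + 1L]] <- data.frame(
              dataset_id = did, method = mname, side = side, scheme = sch,
              auc = rr$auc, ci_low = rr$ci_low, ci_high = rr$ci_high,
              n = rr$n, op_fpr = op["fpr"], op_tpr = op["tpr"],
              stringsAsFactors = FALSE)
            roc_pts[[length(roc_pts) + 1L]] <- data.frame(
              dataset_id = did, method = mname, side = side, scheme = sch,
              rr$points, stringsAsFactors = FALSE)
            keep <- !is.na(lab)
            pr_pts[[length(pr_pts) + 1L]] <- data.frame(
              dataset_id = did, method = mname, side = side, scheme = sch,
              pr_curve(lab[keep], paired_l$p[keep]),
              stringsAsFactors = FALSE)
            TRUE
          }, dmsbench_error = function(e) {
            refuse("roc", did, mname, side, sch, e)
            FALSE
          })
          res
        }
        binned_row <- tryCatch({
          br <- binned_recall(paired, calls[paired$keys], n_bins = n_bins)
          data.frame(dataset_id = did, method = mname, side = side,
                     as.data.frame(br), stringsAsFactors = FALSE)
        }, dmsbench_error = function(e) {
          refuse("binned_recall", did, mname, side, NA_character_, e)
          NULL
        })
        if (!is.null(binned_row)) binned[[length(binned) + 1L]] <- binned_row
      }
    }
  }

  agreement <- agreement_table(normalized, predictions, sides = sides)

  bind <- function(rows, proto) if (length(rows)) do.call(rbind, rows) else proto
  out <- list(
    metrics = bind(metrics, empty_df(dataset_id = "character",
                                     method = "character", side = "character",
                                     metric = "character",
                                     estimate = "numeric", ci_low = "numeric",
                                     ci_high = "numeric", n = "integer",
                                     reps = "integer", seed = "integer",
                                     status = "character")),
    roc = bind(roc, empty_df(dataset_id = "character", method = "character",
                             side = "character", scheme = "character",
                             auc = "numeric", ci_low = "numeric",
                             ci_high = "numeric", n = "integer",
                             op_fpr = "numeric", op_tpr = "numeric")),
    roc_points = bind(roc_pts, empty_df(dataset_id = "character",
                                        method = "character",
                                        side = "character",
                                        scheme = "character",
                                        fpr = "numeric", tpr = "numeric")),
    pr_points = bind(pr_pts, empty_df(dataset_id = "character",
                                      method = "character",
                                      side = "character", scheme = "character",
                                      threshold = "numeric",
                                      recall = "numeric",
                                      precision = "numeric")),
    binned = bind(binned, empty_df(dataset_id = "character",
                                   method = "character", side = "character",
                                   bin = "integer", mean_score = "numeric",
                                   count = "integer", recall = "numeric",
                                   adjusted_recall = "numeric")),
    agreement = agreement,
    refusals = bind(refusals, empty_df(stage = "character",
                                       dataset_id = "character",
                                       method = "character",
                                       side = "character",
                                       scheme = "character",
                                       reason = "character"))
  )
  rownames(out$metrics) <- NULL

  out$manifest <- list(
    package = "dmsbench",
    package_version = as.character(utils::packageVersion("dmsbench")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, reps = reps, n_bins = n_bins, schemes = schemes,
    sides = sides, min_synonymous = min_synonymous,
    add_shuffle = add_shuffle, add_gaussian = add_gaussian,
    datasets = lapply(normalized, function(nd) {
      list(dataset_id = attr(nd, "dataset_id"),
           protein_id = attr(nd, "protein_id"),
           provenance = attr(nd, "provenance"),
           n_sav = sum(!nd$is_synonymous),
           n_synonymous = sum(nd$is_synonymous),
           classification_refused = isTRUE(attr(nd, "classification_refused")))
    }),
    methods = names(predictions),
    row_counts = lapply(out[c("metrics", "roc", "binned", "agreement",
                              "refusals")], nrow)
  )
  class(out) <- "dmsbench_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tab in c("metrics", "roc", "roc_points", "pr_points", "binned",
                  "agreement", "refusals")) {
      utils::write.table(out[[tab]], file.path(out_dir, paste0(tab, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.dmsbench_run <- function(x, ...) {
  cat("<dmsbench_run> ", length(x$manifest$datasets), " dataset(s) x ",
      length(x$manifest$methods), " method(s); ", nrow(x$metrics),
      " metric rows, ", nrow(x$roc), " ROC rows, ", nrow(x$agreement),
      " agreement rows, ", nrow(x$refusals), " refusal(s)\n", sep = "")
  invisible(x)
}

#' Run the benchmark from a YAML configuration file
#'
#' File-based front end over [run_benchmark()]: reads score sets, FASTA
#' sequences, PSSM files and predictor tables named in the config, checks
#' sequence consistency where a sequence is given, harmonizes each
#' predictor through the method registry, and runs the benchmark.
#'
#' Config layout (YAML):
#' \preformatted{
#' datasets:
#'   - id: bla1
#'     scoreset: scores.tsv       # delimited score table
#'     sequence: protein.fasta    # optional FASTA
#'     wt_score: 0
#'     orientation: higher_is_fitter
#'     provenance: study_A        # optional
#' predictors:
#'   - name: snap2
#'     path: snap2.tsv            # method looked up in the registry
#'   - name: naive_conservation
#'     pssm: profile.pssm         # conservation baseline from a PSSM
#' schemes: [syn95]
#' reps: 1000
#' bins: 20
#' seed: 1
#' add_shuffle: false
#' add_gaussian: false
#' out_dir: results/
#' }
#'
#' @param config path to a YAML file, or an equivalent nested list.
#' @param registry method registry (see [load_method_registry()]).
#' @param ... overrides passed to [run_benchmark()] (e.g. `seed`, `reps`).
#' @return A `dmsbench_run`.
#' @export
run_benchmark_config <- function(config, registry = load_method_registry(),
                                 ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  datasets <- list()
  for (d in config$datasets) {
    ds <- read_scoreset(d$scoreset, column_map = d$column_map,
                        orientation = d$orientation %||% "higher_is_fitter",
                        wt_score = d$wt_score %||% 0, dataset_id = d$id,
                        protein_id = d$protein_id,
                        provenance = d$provenance %||% NA_character_,
                        sep = d$sep %||% "\t")
    if (!is.null(d$sequence))
      ds <- check_sequence_consistency(ds, read_fasta_sequence(d$sequence))
    datasets[[d$id]] <- ds
  }
  predictions <- list()
  for (p in config$predictors) {
    predictions[[p$name]] <- if (!is.null(p$pssm)) {
      naive_conservation(read_pssm(p$pssm, protein_id = p$protein_id),
                         method = registry[[p$name]] %||% NULL)
    } else {
      spec <- registry[[p$method %||% p$name]]
      if (is.null(spec))
        stop_dmsbench("method '", p$method %||% p$name,
                      "' not in the registry", class = "dmsbench_config_error")
      rescale_to_unit(read_prediction_table(p$path, spec,
                                            sep = p$sep %||% "\t"))
    }
  }
  args <- list(datasets = datasets, predictions = predictions,
               schemes = config$schemes %||% c("syn90", "syn95", "syn99"),
               reps = config$reps %||% 1000,
               n_bins = config$bins %||% 20,
               seed = config$seed %||% 1,
               out_dir = config$out_dir,
               add_shuffle = isTRUE(config$add_shuffle),
               add_gaussian = isTRUE(config$add_gaussian))
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_benchmark, args)
}
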