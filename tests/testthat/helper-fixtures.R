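# In-code fixtures and independent oracles shared across test files.

# Dataset with one SAV per position (wt A -> V) at the given signed scores,
# plus synonymous records at the given signed scores. Sequence is poly-A,
# orientation higher_is_fitter, wt_score 0, so raw == signed.
dataset_from_signed <- function(sav_signed, syn_signed = numeric(0),
                                dataset_id = "d1", protein_id = "P1",
                                wt_score = 0,
                                orientation = "higher_is_fitter") {
  n <- length(sav_signed)
  sgn <- if (orientation == "higher_is_fitter") 1 else -1
  sav <- data.frame(protein_id = protein_id, position = seq_len(n),
                    wt_aa = "A", mut_aa = "V",
                    raw_score = wt_score + sgn * sav_signed,
                    is_synonymous = FALSE, stringsAsFactors = FALSE)
  syn <- if (length(syn_signed) > 0)
    data.frame(protein_id = protein_id,
               position = rep_len(seq_len(max(n, 1)), length(syn_signed)),
               wt_aa = "A", mut_aa = "A",
               raw_score = wt_score + sgn * syn_signed,
               is_synonymous = TRUE, stringsAsFactors = FALSE)
  else NULL
  dms_dataset(dataset_id, protein_id, rbind(sav, syn), wt_score = wt_score,
              orientation = orientation,
              sequence = strrep("A", max(n, 1)))
}

# Prediction set whose unit scores are given per key row of `keys`.
pred_from_unit <- function(keys, unit, name = "toy") {
  prediction_set(method_spec(name, 0, 1, default_threshold = 0.5),
                 data.frame(keys[c("protein_id", "position", "wt_aa",
                                   "mut_aa")],
                            raw_score = unit, unit_score = unit,
                            stringsAsFactors = FALSE))
}

# Brute-force Spearman for tie-free vectors: 1 - 6*sum(d^2)/(n(n^2-1)).
spearman_oracle <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exhaustive pairwise AUC: P(effect score > neutral score) + 0.5 P(tie).
auc_oracle <- function(pos, scores) {
  se <- scores[pos]
  sn <- scores[!pos]
  cmp <- outer(se, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Expected MSE of a uniformly random pairing of x against p: the grand
# mean of all pairwise squared differences.
random_pairing_mse <- function(x, p) {
  mean(outer(x, p, function(a, b) (a - b)^2))
}

# Minimal paired_scores object for direct metric tests.
make_paired <- function(x, p, labels = NULL, side = "deleterious") {
  structure(list(x = x, p = p, labels = labels,
                 keys = sprintf("P1|%d|A|V", seq_along(x)), side = side,
                 n = length(x)),
            class = "paired_scores")
}
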