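# Synthetic DMS-like data with controlled statistical structure: score
# sets, replicate experiments, predictors at a target rank correlation,
# and matching PSSM profiles.

#' Simulation configuration
#'
#' Parameters of the synthetic DMS generator. Defaults emulate a typical
#' published scan: a few thousand SAVs dominated by deleterious effects
#' (deleterious outnumbering beneficial about 3:1, within the 1.5-22.5
#' range seen across published scans), heavy-tailed per-side effect-size
#' distributions with the deleterious tail the longer one, on the order of
#' a hundred synonymous variants clustered tightly around wild type, and
#' predictors/replicates at moderate/high rank correlation with the truth.
#'
#' @param protein_length N, number of residues (>= 5); up to `19 * N`
#'   non-native SAVs are generated.
#' @param fraction_deleterious,fraction_beneficial fractions of SAVs drawn
#'   with a true deleterious/beneficial effect; the remainder are
#'   near-neutral. Must sum to at most 1.
#' @param n_synonymous number of synonymous records.
#' @param syn_noise_sd standard deviation of the wild-type-anchored noise
#'   for synonymous and near-neutral variants (signed-score units).
#' @param deleterious_shape,deleterious_scale,beneficial_shape,beneficial_scale
#'   Gamma parameters of the per-side effect magnitude distributions
#'   (strictly positive, heavy-tailed; deleterious scale larger).
#' @param predictor_target_rho,replicate_target_rho default Spearman
#'   targets for [generate_predictor()] and [generate_replicate()].
#' @param missingness fraction of SAVs without predictions.
#' @param wt_score raw score assigned to wild type.
#' @param orientation assay score direction.
#' @param seed integer RNG seed; everything downstream is reproducible
#'   from (config, seed).
#' @param dataset_id,protein_id identifiers.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(protein_length = 200, fraction_deleterious = 0.6,
                       fraction_beneficial = 0.2, n_synonymous = 100,
                       syn_noise_sd = 0.1,
                       deleterious_shape = 2, deleterious_scale = 1,
                       beneficial_shape = 2, beneficial_scale = 0.4,
                       predictor_target_rho = 0.4,
                       replicate_target_rho = 0.9,
                       missingness = 0, wt_score = 0,
                       orientation = c("higher_is_fitter", "lower_is_fitter"),
                       seed = 42, dataset_id = "synth1",
                       protein_id = "SYNP1") {
  orientation <- match.arg(orientation)
  if (protein_length < 5)
    stop_dmsbench("protein_length must be >= 5",
                  class = "dmsbench_config_error")
  fr <- c(fraction_deleterious, fraction_beneficial)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop_dmsbench("side fractions must be in [0,1] and sum to at most 1",
                  class = "dmsbench_config_error")
  if (missingness < 0 || missingness >= 1)
    stop_dmsbench("missingness must be in [0, 1)",
                  class = "dmsbench_config_error")
  structure(list(protein_length = as.integer(protein_length),
                 fraction_deleterious = fraction_deleterious,
                 fraction_beneficial = fraction_beneficial,
                 n_synonymous = as.integer(n_synonymous),
                 syn_noise_sd = syn_noise_sd,
                 deleterious_shape = deleterious_shape,
                 deleterious_scale = deleterious_scale,
                 beneficial_shape = beneficial_shape,
                 beneficial_scale = beneficial_scale,
                 predictor_target_rho = predictor_target_rho,
                 replicate_target_rho = replicate_target_rho,
                 missingness = missingness, wt_score = wt_score,
                 orientation = orientation, seed = as.integer(seed),
                 dataset_id = dataset_id, protein_id = protein_id),
            class = "sim_config")
}

# Latent Pearson correlation giving a bivariate-normal population Spearman
# equal to target: inverse of rho_s = (6/pi) * asin(r/2).
copula_weight <- function(target_rho) {
  if (abs(target_rho) >= 1 - 1e-12) return(sign(target_rho))
  2 * sin(pi * target_rho / 6)
}

#' Generate a synthetic DMS dataset with known ground truth
#'
#' Draws a random protein sequence, assigns each of the `19 * N` possible
#' non-native SAVs to the deleterious, beneficial or near-neutral class
#' according to the configured fractions, and samples true signed effects:
#' negative Gamma-distributed magnitudes for deleterious, positive for
#' beneficial, and tight Gaussian noise around 0 for near-neutral SAVs and
#' all synonymous records. Raw scores place the true effect on the
#' configured assay scale (`wt_score`, orientation).
#'
#' @param config a [sim_config()].
#' @return List of class `dms_simulation`: `dataset` (a [dms_dataset()])
#'   and `truth` (data frame with the variant key columns and
#'   `true_effect`, the signed ground-truth effect).
#' @export
generate_dms <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pos <- config$protein_length
  seq_aa <- sample(AA_ALPHABET, n_pos, replace = TRUE)
  pos <- rep(seq_len(n_pos), each = 19)
  wt <- rep(seq_aa, each = 19)
  mut <- unlist(lapply(seq_aa, function(a) setdiff(AA_ALPHABET, a)),
                use.names = FALSE)
  n_sav <- length(pos)
  cls <- sample(c("deleterious", "beneficial", "neutral"), n_sav,
                replace = TRUE,
                prob = c(config$fraction_deleterious,
                         config$fraction_beneficial,
                         1 - config$fraction_deleterious -
                           config$fraction_beneficial))
  true_effect <- numeric(n_sav)
  i_del <- cls == "deleterious"
  i_ben <- cls == "beneficial"
  i_neu <- cls == "neutral"
  true_effect[i_del] <- -stats::rgamma(sum(i_del), config$deleterious_shape,
                                       scale = config$deleterious_scale)
  true_effect[i_ben] <- stats::rgamma(sum(i_ben), config$beneficial_shape,
                                      scale = config$beneficial_scale)
  true_effect[i_neu] <- stats::rnorm(sum(i_neu), 0, config$syn_noise_sd)

  sgn <- if (config$orientation == "higher_is_fitter") 1 else -1
  sav <- data.frame(protein_id = config$protein_id, position = pos,
                    wt_aa = wt, mut_aa = mut,
                    raw_score = config$wt_score + sgn * true_effect,
                    is_synonymous = FALSE, stringsAsFactors = FALSE)
  syn_pos <- sample.int(n_pos, config$n_synonymous, replace = TRUE)
  syn_noise <- stats::rnorm(config$n_synonymous, 0, config$syn_noise_sd)
  syn <- data.frame(protein_id = config$protein_id, position = syn_pos,
                    wt_aa = seq_aa[syn_pos], mut_aa = seq_aa[syn_pos],
                    raw_score = config$wt_score + sgn * syn_noise,
                    is_synonymous = TRUE, stringsAsFactors = FALSE)
  dataset <- dms_dataset(dataset_id = config$dataset_id,
                         protein_id = config$protein_id,
                         variants = rbind(sav, syn),
                         wt_score = config$wt_score,
                         orientation = config$orientation,
                         sequence = paste(seq_aa, collapse = ""),
                         provenance = paste0("sim:", config$dataset_id))
  truth <- data.frame(protein_id = config$protein_id, position = pos,
                      wt_aa = wt, mut_aa = mut, true_effect = true_effect,
                      stringsAsFactors = FALSE)
  structure(list(dataset = dataset, truth = truth, config = config),
            class = "dms_simulation")
}

#' Generate a predictor at a target rank correlation with the truth
#'
#' Builds a synthetic predictor whose unit scores achieve a chosen Spearman
#' correlation with the true effect magnitude: the truth's normal scores
#' are mixed with independent Gaussian noise at the latent weight that
#' gives the requested population Spearman under a Gaussian copula
#' (`r = 2 sin(pi * rho / 6)`), then pushed through the normal CDF onto
#' `[0, 1]`. The realized sample correlation is stored in attribute
#' `realized_rho`; a warning reports it when it misses the target by more
#' than 0.05 (small-n fluctuation).
#'
#' @param truth truth data frame from [generate_dms()] (key columns plus
#'   `true_effect`).
#' @param target_rho target Spearman correlation, `|target_rho| < 1`
#'   (exactly 1 reproduces the truth ranks).
#' @param seed integer RNG seed.
#' @param method_name name for the resulting method.
#' @param missingness fraction of SAVs left without a prediction.
#' @return A [prediction_set()] with `unit_score` filled.
#' @export
generate_predictor <- function(truth, target_rho, seed,
                               method_name = "synthetic_predictor",
                               missingness = 0) {
  n <- nrow(truth)
  magnitude <- abs(truth$true_effect)
  z_t <- stats::qnorm((rank(magnitude, ties.method = "average") - 0.5) / n)
  r <- copula_weight(target_rho)
  set.seed(seed)
  z <- r * z_t + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  unit <- stats::pnorm(z)
  scores <- data.frame(truth[c("protein_id", "position", "wt_aa", "mut_aa")],
                       raw_score = unit, unit_score = unit,
                       stringsAsFactors = FALSE)
  if (missingness > 0)
    scores <- scores[stats::runif(n) >= missingness, ]
  realized <- spearman_stat(scores$unit_score,
                            abs(truth$true_effect)[match(
                              variant_key(scores), variant_key(truth))])
  if (!is.na(realized) &&
      abs(realized - target_rho) > max(0.05, 4 / sqrt(nrow(scores))))
    warning("realized Spearman ", signif(realized, 3),
            " misses target ", target_rho)
  out <- prediction_set(method_spec(method_name, 0, 1,
                                    default_threshold = 0.5), scores)
  attr(out, "realized_rho") <- realized
  out
}

#' Generate a replicate experiment at a target inter-experiment correlation
#'
#' Produces a second measurement of the same protein sharing the original's
#' score distribution but with fresh noise: the original SAV signed scores
#' are rank-transformed to normal scores, mixed with independent noise at
#' the copula weight for the target Spearman, and the resulting ranks are
#' mapped back onto the original score values (identical marginal, new
#' ordering). Synonymous records are redrawn around wild type at the
#' original synonymous spread. A target of 1 reproduces the rank order
#' exactly.
#'
#' @param dataset a [dms_dataset()].
#' @param target_rho target Spearman correlation between the two
#'   experiments' SAV scores.
#' @param seed integer RNG seed.
#' @param dataset_id identifier for the replicate (default: original id
#'   suffixed `_rep`).
#' @return A [dms_dataset()] with provenance distinct from the original.
#' @export
generate_replicate <- function(dataset, target_rho, seed,
                               dataset_id = paste0(dataset$dataset_id, "_rep")) {
  stopifnot(inherits(dataset, "dms_dataset"))
  anchored <- anchor_and_orient(dataset)
  sav <- anchored[!anchored$is_synonymous, ]
  syn <- anchored[anchored$is_synonymous, ]
  s <- sav$signed_score
  n <- length(s)
  z1 <- stats::qnorm((rank(s, ties.method = "average") - 0.5) / n)
  r <- copula_weight(target_rho)
  set.seed(seed)
  z2 <- if (r == 1) z1 else r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  new_s <- sort(s)[rank(z2, ties.method = "first")]
  sgn <- if (dataset$orientation == "higher_is_fitter") 1 else -1
  v <- dataset$variants
  is_syn <- v$is_synonymous
  key_v <- variant_key(v[!is_syn, ])
  key_s <- variant_key(sav)
  v$raw_score[!is_syn] <- dataset$wt_score +
    sgn * new_s[match(key_v, key_s)]
  if (nrow(syn) > 0) {
    syn_sd <- stats::sd(syn$signed_score)
    if (is.na(syn_sd)) syn_sd <- 0
    v$raw_score[is_syn] <- dataset$wt_score +
      sgn * stats::rnorm(sum(is_syn), 0, syn_sd)
  }
  dms_dataset(dataset_id = dataset_id, protein_id = dataset$protein_id,
              variants = v, wt_score = dataset$wt_score,
              orientation = dataset$orientation,
              sequence = dataset$sequence,
              provenance = paste0("sim:", dataset_id))
}

#' Generate a PSSM profile anti-correlated with deleterious effect
#'
#' Builds an integer log-odds profile in which substitutions with stronger
#' true deleterious effect get more negative log-odds (rarer in the implied
#' alignment), the wild-type residue gets a positive value, and optional
#' Gaussian noise perturbs the values before rounding. With zero noise the
#' naive conservation baseline recovers the deleterious effect ranking up
#' to integer-quantization ties. Profiles round-trip through
#' [write_pssm()] / [read_pssm()].
#'
#' @param truth truth data frame from [generate_dms()].
#' @param sequence the protein sequence the truth refers to.
#' @param seed integer RNG seed (used only when `noise_sd > 0`).
#' @param noise_sd standard deviation of the pre-rounding noise, in
#'   log-odds units.
#' @param lo_span magnitude of the most deleterious substitution's
#'   log-odds (values span about `[-lo_span, 0]` before noise).
#' @param wt_value log-odds assigned to the wild-type residue.
#' @param protein_id identifier for the profile.
#' @return A [pssm_profile()].
#' @export
generate_pssm <- function(truth, sequence, seed = 1, noise_sd = 0,
                          lo_span = 12, wt_value = 7,
                          protein_id = truth$protein_id[1]) {
  n_pos <- nchar(sequence)
  seq_aa <- strsplit(sequence, "")[[1]]
  mat <- matrix(0L, n_pos, 20, dimnames = list(NULL, AA_ALPHABET))
  m <- pmax(-truth$true_effect, 0)  # deleterious magnitude
  m_max <- max(m, 1e-9)
  set.seed(seed)
  noise <- if (noise_sd > 0) stats::rnorm(nrow(truth), 0, noise_sd) else 0
  vals <- as.integer(round(-(lo_span * m / m_max + noise)))
  mat[cbind(truth$position, match(truth$mut_aa, AA_ALPHABET))] <- vals
  mat[cbind(seq_len(n_pos), match(seq_aa, AA_ALPHABET))] <- as.integer(wt_value)
  pssm_profile(protein_id = protein_id, sequence = sequence, log_odds = mat)
}

#' Write all artifacts of one simulation to a directory
#'
#' Emits the score set, ground truth, a predictor table, the PSSM file and
#' a JSON snapshot of the configuration, so a generated study can be fed
#' back through the file-based interfaces.
#'
#' @param sim a `dms_simulation` from [generate_dms()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "dms_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  paths <- c(scoreset = file.path(dir, "scoreset.tsv"),
             truth = file.path(dir, "truth.tsv"),
             predictor = file.path(dir, "predictor.tsv"),
             pssm = file.path(dir, "profile.pssm"),
             fasta = file.path(dir, "protein.fasta"),
             config = file.path(dir, "config.json"))
  write_scoreset(sim$dataset, paths["scoreset"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pred <- generate_predictor(sim$truth, cfg$predictor_target_rho,
                             seed = derive_seed(cfg$seed, "predictor"),
                             missingness = cfg$missingness)
  write_predictions(pred, paths["predictor"])
  pssm <- generate_pssm(sim$truth, sim$dataset$sequence,
                        seed = derive_seed(cfg$seed, "pssm"), noise_sd = 2)
  write_pssm(pssm, paths["pssm"])
  writeLines(c(paste0(">", cfg$protein_id), sim$dataset$sequence),
             paths["fasta"])
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
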