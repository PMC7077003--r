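# Reading and validating DMS score sets, sequences, PSI-BLAST PSSMs and
# predictor score tables; writing result tables.

#' Construct a DMS dataset
#'
#' A `dms_dataset` bundles one DMS measurement: the protein, its sequence,
#' the per-variant raw scores (single amino-acid variants plus synonymous
#' records), the raw score the assay assigns to the unmutated protein, and
#' the direction of the assay scale.
#'
#' @param dataset_id character identifier for the measurement.
#' @param protein_id character protein identifier.
#' @param variants data frame with columns `protein_id`, `position` (1-based
#'   integer), `wt_aa`, `mut_aa` (one-letter codes), `raw_score` (numeric,
#'   assay units) and `is_synonymous` (logical). Synonymous records have
#'   `mut_aa == wt_aa`.
#' @param wt_score raw score of the wild-type protein (0 when the assay
#'   reports log ratios versus wild type).
#' @param orientation `"higher_is_fitter"` when larger raw scores mean a
#'   fitter protein, `"lower_is_fitter"` otherwise.
#' @param sequence optional amino-acid sequence string (length N); checked
#'   against variant `wt_aa` by [check_sequence_consistency()].
#' @param provenance optional tag marking the originating study; experiment
#'   pairs sharing a provenance tag are excluded from agreement analyses.
#' @return Object of class `dms_dataset`.
#' @export
dms_dataset <- function(dataset_id, protein_id, variants, wt_score = 0,
                        orientation = c("higher_is_fitter", "lower_is_fitter"),
                        sequence = NULL, provenance = NA_character_) {
  orientation <- match.arg(orientation)
  required <- c("protein_id", "position", "wt_aa", "mut_aa", "raw_score",
                "is_synonymous")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0)
    stop_dmsbench("variants is missing column(s): ",
                  paste(missing_cols, collapse = ", "),
                  class = "dmsbench_config_error")
  variants <- as.data.frame(variants)[required]
  variants$position <- as.integer(variants$position)
  if (any(variants$position < 1L))
    stop_dmsbench("positions must be >= 1 (1-based residue index)",
                  class = "dmsbench_validation_error")
  bad_aa <- !(variants$wt_aa %in% AA_ALPHABET) |
    !(variants$mut_aa %in% AA_ALPHABET)
  if (any(bad_aa))
    stop_dmsbench("amino acid(s) outside the 20-letter alphabet in row(s) ",
                  paste(utils::head(which(bad_aa), 5), collapse = ", "),
                  class = "dmsbench_validation_error")
  syn_mismatch <- variants$is_synonymous != (variants$wt_aa == variants$mut_aa)
  if (any(syn_mismatch))
    stop_dmsbench("synonymous flag inconsistent with wt_aa/mut_aa in row(s) ",
                  paste(utils::head(which(syn_mismatch), 5), collapse = ", "),
                  class = "dmsbench_validation_error")

  # Supplements often repeat rows: deduplicate exact duplicates silently,
  # refuse conflicting scores for one variant.  Synonymous records at one
  # position are distinct nucleotide variants, so several may share a key.
  sav <- variants[!variants$is_synonymous, ]
  key <- variant_key(sav)
  dup <- duplicated(paste(key, sav$raw_score))
  sav <- sav[!dup, ]
  key <- key[!dup]
  if (anyDuplicated(key)) {
    offender <- key[duplicated(key)][1]
    stop_dmsbench("conflicting duplicate scores for variant ", offender,
                  class = "dmsbench_validation_error")
  }
  variants <- rbind(sav, variants[variants$is_synonymous, ])
  rownames(variants) <- NULL
  if (!is.null(sequence) && nzchar(sequence)) {
    n_sav_max <- 19L * nchar(sequence)
    if (nrow(sav) > n_sav_max)
      stop_dmsbench("more non-synonymous variants (", nrow(sav),
                    ") than the 19*N possible for N = ", nchar(sequence),
                    class = "dmsbench_validation_error")
  }
  structure(list(dataset_id = dataset_id, protein_id = protein_id,
                 sequence = sequence, variants = variants,
                 wt_score = wt_score, orientation = orientation,
                 provenance = provenance),
            class = "dms_dataset")
}

#' @export
print.dms_dataset <- function(x, ...) {
  n_syn <- sum(x$variants$is_synonymous)
  cat("<dms_dataset> ", x$dataset_id, " (protein ", x$protein_id, ")\n",
      "  ", nrow(x$variants) - n_syn, " SAVs, ", n_syn,
      " synonymous records; wt_score = ", x$wt_score,
      "; orientation = ", x$orientation, "\n", sep = "")
  invisible(x)
}

#' Read a DMS score set from delimited text
#'
#' Parses one measurement's per-variant scores from a delimited text file
#' with a header row. Column names are resolved through `column_map`, so
#' heterogeneous supplements (e.g. a position column called `aa_pos`) map
#' onto the required fields without editing the file. Rows whose score does
#' not parse as a number are dropped with a message; a file where no score
#' parses (categorical scores) is rejected.
#'
#' @param path file path.
#' @param column_map named character vector mapping any of `protein_id`,
#'   `position`, `wt_aa`, `mut_aa`, `raw_score`, `is_synonymous` to the
#'   column names used in the file. Fields not mentioned use their own name.
#'   An absent `is_synonymous` column is inferred from `wt_aa == mut_aa`; an
#'   absent `protein_id` column uses the `protein_id` argument.
#' @param orientation,wt_score,dataset_id,protein_id,sequence,provenance
#'   passed to [dms_dataset()].
#' @param sep field separator (tab by default, `","` for CSV).
#' @return A [dms_dataset()].
#' @export
read_scoreset <- function(path, column_map = NULL,
                          orientation = c("higher_is_fitter", "lower_is_fitter"),
                          wt_score = 0, dataset_id = NULL, protein_id = NULL,
                          sequence = NULL, provenance = NA_character_,
                          sep = "\t") {
  orientation <- match.arg(orientation)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  fields <- c("protein_id", "position", "wt_aa", "mut_aa", "raw_score",
              "is_synonymous")
  cmap <- stats::setNames(fields, fields)
  if (!is.null(column_map)) cmap[names(column_map)] <- unlist(column_map)

  pick <- function(field, required = TRUE) {
    col <- cmap[[field]]
    if (!col %in% names(tab)) {
      if (required)
        stop_dmsbench("required column '", col, "' (field ", field,
                      ") not found in ", path,
                      class = "dmsbench_config_error")
      return(NULL)
    }
    tab[[col]]
  }

  df <- data.frame(
    protein_id = pick("protein_id", required = is.null(protein_id)) %||%
      rep(protein_id, nrow(tab)),
    position = suppressWarnings(as.integer(pick("position"))),
    wt_aa = toupper(pick("wt_aa")),
    mut_aa = toupper(pick("mut_aa")),
    raw_score_chr = pick("raw_score"),
    stringsAsFactors = FALSE
  )
  syn <- pick("is_synonymous", required = FALSE)
  df$is_synonymous <- if (is.null(syn)) df$wt_aa == df$mut_aa else
    as.logical(toupper(syn) %in% c("TRUE", "T", "1", "YES")) |
      (suppressWarnings(as.numeric(syn)) %in% 1)

  df$raw_score <- suppressWarnings(as.numeric(df$raw_score_chr))
  n_bad <- sum(is.na(df$raw_score))
  if (n_bad == nrow(df) && nrow(df) > 0)
    stop_dmsbench("no numeric scores in ", path,
                  " -- categorical score sets are not supported",
                  class = "dmsbench_validation_error")
  if (n_bad > 0) {
    message("read_scoreset: dropped ", n_bad,
            " row(s) with unparseable scores from ", path)
    df <- df[!is.na(df$raw_score), ]
  }
  df$raw_score_chr <- NULL
  dms_dataset(dataset_id = dataset_id %||% basename(path),
              protein_id = protein_id %||% df$protein_id[1],
              variants = df, wt_score = wt_score, orientation = orientation,
              sequence = sequence, provenance = provenance)
}

#' Write a DMS score set as TSV
#'
#' Fixed column order `protein_id, position, wt_aa, mut_aa, raw_score,
#' is_synonymous`; round-trips through [read_scoreset()].
#'
#' @param dataset a [dms_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scoreset <- function(dataset, path) {
  utils::write.table(dataset$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read one amino-acid sequence from a FASTA file
#'
#' @param path FASTA file path.
#' @param which index or name of the record to return (first by default).
#' @return Character scalar sequence.
#' @export
read_fasta_sequence <- function(path, which = 1) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0)
    stop_dmsbench("no sequences in ", path, class = "dmsbench_format_error")
  as.character(seqs[[which]])
}

#' Check variant wild-type residues against a protein sequence
#'
#' Compares each variant's `wt_aa` with the sequence residue at its
#' position. Measurements may have been made on a close homolog of the
#' sequence the predictors saw, so a small number of mismatching positions
#' is tolerated: the dataset is accepted iff the number of mismatching
#' positions is at most `max_mismatch` and the implied pairwise identity
#' `1 - mismatches / N` is at least `min_identity` (defaults: up to five
#' substitutions, identity >= 98%). Accepted datasets carry a per-variant
#' `wt_mismatch` flag; the check is idempotent.
#'
#' @param dataset a [dms_dataset()].
#' @param sequence amino-acid string; defaults to `dataset$sequence`.
#' @param max_mismatch maximum number of mismatching positions tolerated.
#' @param min_identity minimum implied pairwise sequence identity.
#' @return The dataset with `sequence` set and variants flagged.
#' @export
check_sequence_consistency <- function(dataset, sequence = NULL,
                                       max_mismatch = 5, min_identity = 0.98) {
  sequence <- sequence %||% dataset$sequence
  if (is.null(sequence) || !nzchar(sequence))
    stop_dmsbench("no sequence to check against",
                  class = "dmsbench_config_error")
  n <- nchar(sequence)
  v <- dataset$variants
  if (any(v$position > n))
    stop_dmsbench("variant position(s) beyond sequence length ", n,
                  class = "dmsbench_validation_error")
  seq_aa <- strsplit(sequence, "")[[1]]
  mism <- v$wt_aa != seq_aa[v$position]
  bad_pos <- sort(unique(v$position[mism]))
  identity <- 1 - length(bad_pos) / n
  if (length(bad_pos) > max_mismatch || identity < min_identity)
    stop_dmsbench("sequence inconsistency: ", length(bad_pos),
                  " mismatching position(s) [",
                  paste(utils::head(bad_pos, 10), collapse = ", "),
                  "], identity ", signif(identity, 4), " < required",
                  class = "dmsbench_rejection_error")
  v$wt_mismatch <- mism
  dataset$variants <- v
  dataset$sequence <- sequence
  dataset
}

#' Construct a PSSM profile
#'
#' Per-position log-odds of observing each of the 20 amino acids, as
#' produced by iterative profile search (PSI-BLAST).
#'
#' @param protein_id protein identifier.
#' @param sequence query sequence (length N).
#' @param log_odds N x 20 integer matrix, columns named by [AA_ALPHABET].
#' @return Object of class `pssm_profile`.
#' @export
pssm_profile <- function(protein_id, sequence, log_odds) {
  log_odds <- as.matrix(log_odds)
  if (ncol(log_odds) != 20 || !setequal(colnames(log_odds), AA_ALPHABET))
    stop_dmsbench("log_odds must have 20 columns named by the amino-acid alphabet",
                  class = "dmsbench_validation_error")
  if (nrow(log_odds) != nchar(sequence))
    stop_dmsbench("log_odds rows (", nrow(log_odds),
                  ") != sequence length (", nchar(sequence), ")",
                  class = "dmsbench_validation_error")
  log_odds <- log_odds[, AA_ALPHABET, drop = FALSE]
  structure(list(protein_id = protein_id, sequence = sequence,
                 log_odds = log_odds),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("<pssm_profile> ", x$protein_id, ", ", nchar(x$sequence),
      " positions x 20 amino acids\n", sep = "")
  invisible(x)
}

# Column order PSI-BLAST prints log-odds in (differs from alphabetical).
PSIBLAST_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the ASCII matrix PSI-BLAST writes with `-out_ascii_pssm`: header
#' lines, a column-header row of amino-acid letters, then one row per query
#' position holding the position index, the query residue, 20 integer
#' log-odds, and optionally 20 weighted-percentage columns plus two trailing
#' reals (information content, relative weight). Only the first (log-odds)
#' block is kept; the query sequence is reconstructed from the residue
#' column. Whitespace between columns may vary.
#'
#' @param path PSSM file path.
#' @param protein_id protein identifier for the profile; defaults to the
#'   file name without extension.
#' @return A [pssm_profile()].
#' @export
read_pssm <- function(path, protein_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  aa_order <- PSIBLAST_AA_ORDER
  body_idx <- integer(0)
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) == 0) next
    if (length(toks) >= 20 && all(toks[1:20] %in% AA_ALPHABET)) {
      aa_order <- toks[1:20]  # column-header row fixes the letter order
    } else if (grepl("^[0-9]+$", toks[1]) && length(toks) >= 2 &&
               toks[2] %in% AA_ALPHABET) {
      body_idx <- c(body_idx, i)
    }
  }
  if (length(body_idx) == 0)
    stop_dmsbench("no PSSM body rows found in ", path,
                  class = "dmsbench_format_error")
  residues <- character(length(body_idx))
  mat <- matrix(NA_integer_, length(body_idx), 20,
                dimnames = list(NULL, aa_order))
  for (j in seq_along(body_idx)) {
    i <- body_idx[j]
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.integer(toks[3:length(toks)]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 20)
      stop_dmsbench("line ", i, " of ", path, ": expected 20 log-odds values, found ",
                    length(vals), class = "dmsbench_format_error")
    residues[j] <- toks[2]
    mat[j, ] <- vals[1:20]  # first block = log-odds; percentages ignored
  }
  pssm_profile(protein_id = protein_id %||%
                 sub("\\.[^.]*$", "", basename(path)),
               sequence = paste(residues, collapse = ""),
               log_odds = mat)
}

#' Write a PSSM profile in the PSI-BLAST ASCII dialect
#'
#' Writes a file that [read_pssm()] parses back to an identical profile;
#' useful for exporting synthetic profiles.
#'
#' @param profile a [pssm_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  mat <- profile$log_odds[, PSIBLAST_AA_ORDER, drop = FALSE]
  res <- strsplit(profile$sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("            ", paste(sprintf("%3s", PSIBLAST_AA_ORDER),
                                           collapse = " "))), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste0(sprintf("%5d %s  ", i, res[i]),
                      paste(sprintf("%3d", mat[i, ]), collapse = " ")), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read a predictor score table
#'
#' Parses one method's per-variant scores from delimited text keyed by
#' `(protein_id, position, wt_aa, mut_aa)` with a numeric score column.
#' Variants the method failed on are simply absent (never imputed); the
#' downstream pairing takes the largest common subset. Scores outside the
#' method's declared theoretical range are an error.
#'
#' @param path file path.
#' @param method a [method_spec()] carrying the theoretical score range,
#'   orientation and default binary threshold.
#' @param column_map optional named vector as in [read_scoreset()] (fields
#'   `protein_id`, `position`, `wt_aa`, `mut_aa`, `raw_score`).
#' @param sep field separator.
#' @return A [prediction_set()].
#' @export
read_prediction_table <- function(path, method, column_map = NULL, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  fields <- c("protein_id", "position", "wt_aa", "mut_aa", "raw_score")
  cmap <- stats::setNames(fields, fields)
  if (!is.null(column_map)) cmap[names(column_map)] <- unlist(column_map)
  for (f in fields) {
    if (!cmap[[f]] %in% names(tab))
      stop_dmsbench("required column '", cmap[[f]], "' not found in ", path,
                    class = "dmsbench_config_error")
  }
  scores <- data.frame(protein_id = as.character(tab[[cmap["protein_id"]]]),
                       position = as.integer(tab[[cmap["position"]]]),
                       wt_aa = toupper(tab[[cmap["wt_aa"]]]),
                       mut_aa = toupper(tab[[cmap["mut_aa"]]]),
                       raw_score = as.numeric(tab[[cmap["raw_score"]]]),
                       stringsAsFactors = FALSE)
  scores <- scores[!is.na(scores$raw_score), ]
  prediction_set(method, scores)
}

#' Write harmonized predictions as TSV
#'
#' @param pred a [prediction_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(pred$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
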