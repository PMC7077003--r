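# Reading and validating score sets, PSSMs and prediction tables.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_scoreset parses variants, synonymous flags and column maps", {
  path <- write_tsv_lines(c(
    "protein_id\tposition\twt_aa\tmut_aa\traw_score",
    "P1\t1\tA\tV\t0.2",
    "P1\t1\tA\tG\t-1.3",
    "P1\t1\tA\tA\t0.01",
    "P1\t2\tL\tP\t-2.0"))
  ds <- read_scoreset(path, wt_score = 0, dataset_id = "toy")
  expect_s3_class(ds, "dms_dataset")
  expect_equal(sum(!ds$variants$is_synonymous), 3)
  expect_equal(sum(ds$variants$is_synonymous), 1)
  expect_equal(ds$variants$raw_score[ds$variants$mut_aa == "G"], -1.3)

  # a renamed position column maps onto the same dataset
  path2 <- write_tsv_lines(c(
    "protein_id\taa_pos\twt_aa\tmut_aa\traw_score",
    "P1\t1\tA\tV\t0.2",
    "P1\t1\tA\tG\t-1.3",
    "P1\t1\tA\tA\t0.01",
    "P1\t2\tL\tP\t-2.0"))
  ds2 <- read_scoreset(path2, column_map = c(position = "aa_pos"),
                       wt_score = 0, dataset_id = "toy")
  expect_equal(ds2$variants, ds$variants)
})

test_that("read_scoreset rejects bad alphabets, conflicts and categorical scores", {
  bad_aa <- write_tsv_lines(c("protein_id\tposition\twt_aa\tmut_aa\traw_score",
                              "P1\t1\tA\tX\t0.5"))
  expect_error(read_scoreset(bad_aa), class = "dmsbench_validation_error")

  conflict <- write_tsv_lines(c("protein_id\tposition\twt_aa\tmut_aa\traw_score",
                                "P1\t1\tA\tV\t0.5",
                                "P1\t1\tA\tV\t0.7"))
  expect_error(read_scoreset(conflict), regexp = "P1\\|1\\|A\\|V",
               class = "dmsbench_validation_error")

  # exact duplicate rows are deduplicated silently
  dup <- write_tsv_lines(c("protein_id\tposition\twt_aa\tmut_aa\traw_score",
                           "P1\t1\tA\tV\t0.5",
                           "P1\t1\tA\tV\t0.5"))
  expect_equal(nrow(read_scoreset(dup)$variants), 1)

  categorical <- write_tsv_lines(c("protein_id\tposition\twt_aa\tmut_aa\traw_score",
                                   "P1\t1\tA\tV\tstrong",
                                   "P1\t2\tA\tV\tweak"))
  expect_error(read_scoreset(categorical), regexp = "categorical",
               class = "dmsbench_validation_error")

  # unparseable rows among numeric ones are dropped with a message
  mixed <- write_tsv_lines(c("protein_id\tposition\twt_aa\tmut_aa\traw_score",
                             "P1\t1\tA\tV\t0.5",
                             "P1\t2\tA\tV\tn/a"))
  expect_message(ds <- read_scoreset(mixed), "dropped 1")
  expect_equal(nrow(ds$variants), 1)

  missing_col <- write_tsv_lines(c("protein_id\tposition\twt_aa\traw_score",
                                   "P1\t1\tA\t0.5"))
  expect_error(read_scoreset(missing_col), class = "dmsbench_config_error")
})

test_that("scoresets round-trip through write_scoreset", {
  ds <- dataset_from_signed(c(-2, -0.5, 0.3, 1.1), syn_signed = c(0.01, -0.02))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scoreset(ds, path)
  back <- read_scoreset(path, dataset_id = ds$dataset_id,
                        sequence = ds$sequence)
  expect_equal(back$variants, ds$variants)
})

test_that("sequence consistency tolerates few mismatches and rejects many", {
  sig <- seq(-1, 1, length.out = 100)
  ds <- dataset_from_signed(sig)   # 100 positions, sequence all A

  ok <- check_sequence_consistency(ds)
  expect_equal(sum(ok$variants$wt_mismatch), 0)

  # two disagreeing positions of 100: identity 0.98, accepted with flags
  seq2 <- ds$sequence
  substr(seq2, 3, 3) <- "W"
  substr(seq2, 7, 7) <- "W"
  flagged <- check_sequence_consistency(ds, seq2)
  expect_equal(sum(flagged$variants$wt_mismatch), 2)
  # idempotent
  expect_equal(check_sequence_consistency(flagged)$variants,
               flagged$variants)

  # six disagreeing positions: beyond both defaults
  seq6 <- ds$sequence
  for (i in 1:6) substr(seq6, i * 10, i * 10) <- "W"
  expect_error(check_sequence_consistency(ds, seq6),
               class = "dmsbench_rejection_error")
})

test_that("read_pssm parses the PSI-BLAST ASCII dialect", {
  lo <- matrix(0L, 3, 20, dimnames = list(NULL, AA_ALPHABET))
  lo[1, ] <- as.integer(seq(-9, 10))
  lo[2, "K"] <- 7L
  lo[3, "V"] <- -5L
  prof <- pssm_profile("toy", "MKV", lo)
  path <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(prof, path)
  back <- read_pssm(path)
  expect_equal(back$sequence, "MKV")
  expect_equal(unname(back$log_odds), unname(prof$log_odds))

  # variable whitespace and absent percentage block are tolerated
  hand <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed",
    paste0("     ", paste(PSIBLAST <- c("A","R","N","D","C","Q","E","G","H",
                                        "I","L","K","M","F","P","S","T","W",
                                        "Y","V"), collapse = "   ")),
    paste("1  M ", paste(1:20, collapse = "  ")),
    paste("2    K   ", paste(rep(-2L, 20), collapse = " "))), hand)
  p2 <- read_pssm(hand)
  expect_equal(p2$sequence, "MK")
  expect_equal(unname(p2$log_odds[1, PSIBLAST]), 1:20)
  expect_equal(unname(p2$log_odds[2, ]), rep(-2L, 20))

  # a body row with too few values names its line
  broken <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c("  A R N D C Q E G H I L K M F P S T W Y V",
               paste("1 M", paste(1:7, collapse = " "))), broken)
  expect_error(read_pssm(broken), regexp = "line 2",
               class = "dmsbench_format_error")
  empty <- withr::local_tempfile(fileext = ".pssm")
  writeLines("no body here", empty)
  expect_error(read_pssm(empty), class = "dmsbench_format_error")
})

test_that("read_prediction_table validates scores against the declared range", {
  spec <- method_spec("snap2", -100, 100, default_threshold = 0)
  path <- write_tsv_lines(c("protein_id\tposition\twt_aa\tmut_aa\traw_score",
                            "P1\t1\tA\tV\t-95.5",
                            "P1\t2\tA\tG\t88"))
  ps <- read_prediction_table(path, spec)
  expect_s3_class(ps, "prediction_set")
  expect_equal(nrow(ps$scores), 2)

  out_of_range <- write_tsv_lines(
    c("protein_id\tposition\twt_aa\tmut_aa\traw_score",
      "P1\t1\tA\tV\t1.2"))
  expect_error(read_prediction_table(out_of_range,
                                     method_spec("unitm", 0, 1)),
               class = "dmsbench_validation_error")

  empty <- write_tsv_lines("protein_id\tposition\twt_aa\tmut_aa\traw_score")
  expect_equal(nrow(read_prediction_table(empty, spec)$scores), 0)
})

test_that("FASTA sequences are read back verbatim", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 toy", "MKVLAA", "WYC"), path)
  expect_equal(read_fasta_sequence(path), "MKVLAAWYC")
})
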