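# Shared helpers: amino-acid alphabet, variant keys, seed derivation.

#' The 20-letter amino-acid alphabet
#'
#' One-letter codes for the 20 proteinogenic amino acids, alphabetical.
#' Every variant record's `wt_aa` and `mut_aa` must come from this set, and
#' PSSM profiles carry one log-odds value per position for each of them.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Variant keys
#'
#' Builds the canonical variant key `protein|position|wt|mut` used to align
#' experimental and predicted scores. Synonymous records share the scheme
#' with `mut_aa == wt_aa`.
#'
#' @param df data frame with columns `protein_id`, `position`, `wt_aa`,
#'   `mut_aa`.
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(df) {
  paste(df$protein_id, df$position, df$wt_aa, df$mut_aa, sep = "|")
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps a global seed plus any number of string/numeric
#' labels (stage name, dataset id, method name, ...) to a 31-bit integer
#' seed, so that pipeline stages get distinct, reproducible RNG streams
#' without seed collisions.
#'
#' @param global_seed integer global seed.
#' @param ... labels identifying the stage (coerced to character).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(global_seed, ...) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps arithmetic exact in doubles
  parts <- paste(vapply(list(...), function(x) paste(x, collapse = ","),
                        character(1)), collapse = "/")
  h <- (as.numeric(global_seed) %% m) * 48271 %% m
  for (code in utf8ToInt(parts)) h <- (h * 31 + code) %% m
  as.integer(h)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dmsbench <- function(..., class) {
  stop(structure(class = c(class, "dmsbench_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
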