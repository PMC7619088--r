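# The 19 x L mutational landscape: ingestion of external score matrices, a
# documented baseline log-odds scorer, and the per-residue sensitivity
# profile.
#
# Scores are dimensionless raw evolutionary scores; more negative means
# stronger predicted impact. Internally the landscape is a 20 x L numeric
# matrix (rows = AA_ALPHABET, columns = positions); the wild-type cell of
# each column is NA so exactly 19 substitution cells per position carry
# values.

new_landscape <- function(wild_type, scores, scorer = "external") {
  L <- nchar(wild_type)
  stopifnot(is.matrix(scores), nrow(scores) == 20L, ncol(scores) == L)
  rownames(scores) <- AA_ALPHABET
  wt <- strsplit(wild_type, "")[[1L]]
  scores[cbind(match(wt, AA_ALPHABET), seq_len(L))] <- NA_real_
  structure(list(L = L, wild_type = wild_type, scores = scores,
                 scorer = scorer),
            class = "mutational_landscape")
}

#' @export
print.mutational_landscape <- function(x, ...) {
  cat(sprintf("Mutational landscape: 19 x %d variants (scorer: %s), %d unscored cells\n",
              x$L, x$scorer, sum(is.na(x$scores)) - x$L))
  invisible(x)
}

#' Load an externally computed score matrix
#'
#' Ingests a 19 x L matrix of raw evolutionary scores produced by an upstream
#' variant-effect predictor, either in long form (CSV with header
#' \code{position,wt,mut,score}) or as a 20 x L grid (20 rows in the fixed
#' alphabetical amino-acid order of [AA_ALPHABET], one column per position,
#' optionally with a leading column of amino-acid letters). Wild-type cells
#' are masked to \code{NA}; missing substitution cells are allowed and are
#' reported downstream as unscored variants.
#'
#' @param path CSV file path.
#' @param query_seq Query protein sequence (wild type), length L.
#' @return A \code{"mutational_landscape"} object.
#' @export
load_score_matrix <- function(path, query_seq) {
  if (!file.exists(path))
    ml_error("mutland_io_error", sprintf("score matrix not found: %s", path))
  L <- nchar(query_seq)
  wt <- strsplit(query_seq, "")[[1L]]
  first <- tolower(readLines(path, n = 1L))
  long_form <- grepl("position", first) && grepl("mut", first)
  scores <- matrix(NA_real_, 20L, L, dimnames = list(AA_ALPHABET, NULL))

  if (long_form) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("position", "wt", "mut", "score")
    if (!all(need %in% names(df)))
      ml_error("mutland_bad_matrix", "long-form CSV must have columns position,wt,mut,score")
    if (!is.numeric(df$score))
      ml_error("mutland_bad_matrix", "non-numeric values in score column")
    if (any(df$position < 1 | df$position > L | df$position != round(df$position)))
      ml_error("mutland_bad_matrix",
               sprintf("position out of range [1, %d]", L))
    mism <- df$wt != wt[df$position]
    if (any(mism))
      ml_error("mutland_wt_mismatch",
               sprintf("wt letter does not match query at position(s): %s",
                       paste(unique(df$position[mism]), collapse = ", ")))
    if (any(df$mut == df$wt))
      ml_error("mutland_bad_matrix", "wild-type cells must not be scored")
    if (!all(df$mut %in% AA_ALPHABET))
      ml_error("mutland_bad_matrix", "mut letters outside the 20-letter alphabet")
    key <- paste(df$position, df$mut)
    if (anyDuplicated(key))
      ml_error("mutland_duplicate_entry",
               sprintf("duplicate (position, mut) entries: %s",
                       paste(unique(key[duplicated(key)]), collapse = "; ")))
    scores[cbind(match(df$mut, AA_ALPHABET), df$position)] <- df$score
  } else {
    df <- read.csv(path, header = FALSE, stringsAsFactors = FALSE)
    if (is.character(df[[1L]]) && all(df[[1L]] %in% AA_ALPHABET)) {
      if (!identical(df[[1L]], AA_ALPHABET))
        ml_error("mutland_bad_matrix",
                 "grid rows must be in fixed alphabetical amino-acid order")
      df <- df[, -1L, drop = FALSE]
    }
    if (nrow(df) != 20L || ncol(df) != L)
      ml_error("mutland_bad_matrix",
               sprintf("grid must be 20 x %d (got %d x %d)", L, nrow(df), ncol(df)))
    g <- as.matrix(df)
    gn <- suppressWarnings(matrix(as.numeric(g), nrow(g), ncol(g)))
    was_value <- !is.na(g) & !(trimws(as.character(g)) %in% c("", "NA", "NaN"))
    if (any(was_value & is.na(gn)))
      ml_error("mutland_bad_matrix", "non-numeric score in grid")
    scores[] <- gn
  }
  new_landscape(query_seq, scores, scorer = "external")
}

#' Baseline column log-odds scorer
#'
#' A deliberately simple, column-independent evolutionary scorer used when no
#' external score matrix is supplied:
#' \deqn{score(i, a) = \log\frac{c_i(a) + p}{c_i(wt_i) + p}}
#' where \eqn{c_i} counts non-gap occurrences of each amino acid in MSA
#' column \eqn{i} and \eqn{p} is a pseudocount. It captures column
#' conservation only (no phylogeny, no epistasis) and is labelled
#' \code{"baseline"} in all outputs so it cannot be mistaken for an upstream
#' predictor's scores.
#'
#' @param msa An \code{"msa"} object.
#' @param pseudocount Positive pseudocount, default 1.
#' @return A \code{"mutational_landscape"} object.
#' @export
baseline_scores <- function(msa, pseudocount = 1) {
  stopifnot(inherits(msa, "msa"), pseudocount > 0)
  mat <- msa_char_matrix(msa)
  wt <- strsplit(msa$query_seq, "")[[1L]]
  counts <- vapply(seq_len(msa$L), function(i) {
    col <- mat[, i]
    tabulate(match(col, AA_ALPHABET), nbins = 20L)
  }, numeric(20L))
  wt_counts <- counts[cbind(match(wt, AA_ALPHABET), seq_len(msa$L))]
  scores <- log(sweep(counts + pseudocount, 2L, wt_counts + pseudocount, "/"))
  new_landscape(msa$query_seq, scores, scorer = "baseline")
}

#' Per-residue mutational sensitivity profile
#'
#' The mutational sensitivity of a residue is the arithmetic mean of the raw
#' evolutionary scores of its 19 substitutions. Positions with missing
#' substitution scores use the mean over the available cells; a fully
#' unscored position yields \code{NaN}.
#'
#' @param landscape A \code{"mutational_landscape"} (or structure-aware)
#'   object.
#' @return A \code{"sensitivity_profile"} object: list with \code{values}
#'   (numeric length L) and \code{n} (the signal length).
#' @export
sensitivity_profile <- function(landscape) {
  stopifnot(inherits(landscape, c("mutational_landscape",
                                  "structure_aware_landscape")))
  vals <- colMeans(landscape$scores, na.rm = TRUE)
  vals[!is.finite(vals)] <- NaN
  structure(list(values = as.numeric(vals), n = landscape$L),
            class = "sensitivity_profile")
}

# per-position standard deviation of the 19 substitution scores
landscape_dispersion <- function(landscape) {
  apply(landscape$scores, 2L, function(s) {
    s <- s[is.finite(s)]
    if (length(s) < 2L) return(NA_real_)
    sd(s)
  })
}

#' Export a landscape in long CSV form
#'
#' One row per substitution with header \code{position,wt,mut,score};
#' wild-type cells are omitted.
#'
#' @param landscape A \code{"mutational_landscape"} object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_landscape_csv <- function(landscape, path) {
  wt <- strsplit(landscape$wild_type, "")[[1L]]
  df <- data.frame(position = rep(seq_len(landscape$L), each = 20L),
                   wt = rep(wt, each = 20L),
                   mut = rep(AA_ALPHABET, landscape$L),
                   score = as.vector(landscape$scores))
  df <- df[df$mut != df$wt, ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
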