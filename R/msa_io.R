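# MSA input/output and per-column / per-sequence summaries.
#
# Conventions: the first record is the query and must be gap-free after
# dialect normalisation; all positions are 1-based; internally rows are kept
# as uppercase strings of identical length L with '-' as the only gap
# character.

#' Read a multiple sequence alignment
#'
#' Parses an MSA in A2M, A3M or aligned FASTA and normalises it to a
#' rectangular alignment of length \code{L = nchar(query)}. In A2M/A3M,
#' lowercase letters and dots mark insertions relative to the query and are
#' removed; in aligned FASTA all rows must already share one length. Gap
#' characters are normalised to \code{'-'}. The first record is taken as the
#' query and must contain no gaps after normalisation.
#'
#' @param path Path to the alignment file.
#' @param dialect One of \code{"auto"}, \code{"a2m"}, \code{"a3m"},
#'   \code{"fasta"}. With \code{"auto"}, the presence of lowercase letters or
#'   dots selects A2M/A3M-style insertion removal, otherwise aligned FASTA.
#' @return An object of class \code{"msa"}: a list with \code{query_id},
#'   \code{query_seq}, \code{ids}, \code{rows} (character vector, query
#'   first), \code{L} and \code{n_sequences}.
#' @details Errors are signalled with distinct condition classes:
#'   \code{mutland_empty_file}, \code{mutland_gapped_query},
#'   \code{mutland_ragged_alignment}, \code{mutland_bad_character}.
#' @export
read_msa <- function(path, dialect = c("auto", "a2m", "a3m", "fasta")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    ml_error("mutland_io_error", sprintf("MSA file not found: %s", path))
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE, set.attributes = FALSE),
    error = function(e) ml_error("mutland_empty_file",
      sprintf("no FASTA records could be read from %s", path)))
  if (length(recs) == 0L)
    ml_error("mutland_empty_file", sprintf("no sequences in %s", path))
  ids <- names(recs)
  rows <- vapply(recs, as.character, character(1))

  bad <- grepl("[^A-Za-z.\\-]", rows)
  if (any(bad))
    ml_error("mutland_bad_character",
             sprintf("unknown alignment characters in record(s): %s",
                     paste(ids[bad], collapse = ", ")))

  insertion_style <- switch(dialect,
    a2m = TRUE, a3m = TRUE, fasta = FALSE,
    auto = any(grepl("[a-z.]", rows)))
  if (insertion_style) {
    rows <- gsub("[a-z.]", "", rows)
  } else {
    rows <- gsub("\\.", "-", toupper(rows))
  }

  query <- rows[[1L]]
  if (grepl("[-.]", query))
    ml_error("mutland_gapped_query",
             "first record (the query) contains gaps after normalisation")
  L <- nchar(query)
  if (any(nchar(rows) != L))
    ml_error("mutland_ragged_alignment",
             sprintf("rows of inconsistent length after normalisation (query L=%d)", L))

  structure(list(query_id = ids[[1L]], query_seq = query, ids = ids,
                 rows = unname(rows), L = L, n_sequences = length(rows)),
            class = "msa")
}

#' Write a normalised alignment as aligned FASTA
#'
#' @param msa An \code{"msa"} object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  seqinr::write.fasta(as.list(msa$rows), names = msa$ids, file.out = path,
                      as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d positions (query: %s)\n",
              x$n_sequences, x$L, x$query_id))
  invisible(x)
}

msa_char_matrix <- function(msa) {
  matrix(unlist(strsplit(msa$rows, "", fixed = TRUE), use.names = FALSE),
         nrow = msa$n_sequences, ncol = msa$L, byrow = TRUE)
}

#' Per-column alignment statistics
#'
#' For each query position, the gap fraction, the number of distinct
#' substituting amino acids observed, and a conservation proxy (frequency of
#' the modal non-gap amino acid among non-gap letters). \code{'X'} and other
#' non-standard letters are counted as gap-like: they carry no substitution
#' identity.
#'
#' @param msa An \code{"msa"} object.
#' @param conservation_fun Optional replacement conservation statistic:
#'   a function of a character vector of standard-residue letters in the
#'   column returning a scalar in \code{[0, 1]}. Defaults to the modal
#'   frequency.
#' @return A data frame with columns \code{position}, \code{gap_fraction},
#'   \code{n_substitutions_sampled}, \code{conservation}.
#' @export
column_stats <- function(msa, conservation_fun = NULL) {
  stopifnot(inherits(msa, "msa"))
  mat <- msa_char_matrix(msa)
  wt <- strsplit(msa$query_seq, "")[[1L]]
  n <- msa$n_sequences
  out <- data.frame(position = seq_len(msa$L), gap_fraction = 0,
                    n_substitutions_sampled = 0L, conservation = 0)
  for (i in seq_len(msa$L)) {
    col <- mat[, i]
    std <- col[col %in% AA_ALPHABET]
    out$gap_fraction[i] <- 1 - length(std) / n
    if (length(std)) {
      tab <- table(std)
      out$conservation[i] <- if (is.null(conservation_fun))
        max(tab) / length(std) else conservation_fun(std)
      out$n_substitutions_sampled[i] <- sum(names(tab) != wt[i])
    }
  }
  out
}

#' Per-sequence identity to the query
#'
#' Identity is computed over query positions (the query is ungapped, so over
#' all L columns); a gap in a homolog never matches. Row 1 (the query) has
#' identity 1 by construction.
#'
#' @param msa An \code{"msa"} object.
#' @return A data frame with columns \code{row_index}, \code{id},
#'   \code{identity_to_query}.
#' @export
similarity_to_query <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  mat <- msa_char_matrix(msa)
  wt <- strsplit(msa$query_seq, "")[[1L]]
  ident <- apply(mat, 1L, function(r) mean(r == wt))
  data.frame(row_index = seq_len(msa$n_sequences), id = msa$ids,
             identity_to_query = as.numeric(ident))
}

#' Export per-column statistics to CSV
#'
#' @param stats Data frame from [column_stats()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_column_stats <- function(stats, path) {
  write.csv(stats, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
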