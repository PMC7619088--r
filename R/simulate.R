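# Synthetic fixture generators: alignments with conserved motifs in a
# divergent background, score landscapes with a planted three-class mixture
# and segment-level mean shifts, piecewise-constant noisy signals, and toy
# PDB structures. Each generator returns its generating truth so recovery
# can be checked against it.

#' Generate a synthetic MSA with conserved motifs
#'
#' Columns inside motif windows are sampled from low-entropy profiles
#' (probability \code{conservation} on a consensus letter, the remainder
#' spread over the other 19), background columns from high-entropy profiles.
#' The query (first row) is the ungapped consensus. Homolog rows may carry
#' gaps at the background gap rate; motif columns are gap-free.
#'
#' @param L Query length.
#' @param n_sequences Number of rows including the query.
#' @param motifs List of \code{list(start, end, conservation)} windows;
#'   windows must not overlap.
#' @param background_conservation Consensus probability outside motifs,
#'   default 0.2.
#' @param gap_prob Per-cell gap probability outside motifs, default 0.05.
#' @param seed Integer seed.
#' @return List with \code{msa} (an \code{"msa"} object), \code{profiles}
#'   (20 x L generating profile matrix, gap mass excluded) and
#'   \code{consensus}.
#' @export
generate_synthetic_msa <- function(L, n_sequences,
                                   motifs = list(),
                                   background_conservation = 0.2,
                                   gap_prob = 0.05, seed = 0L) {
  stopifnot(L >= 1L, n_sequences >= 1L)
  if (length(motifs) > 1L) {
    iv <- do.call(rbind, lapply(motifs, function(m) c(m$start, m$end)))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
      ml_error("mutland_overlapping_motifs", "motif windows overlap")
  }
  withr::with_seed(as.integer(seed), {
    cons_level <- rep(background_conservation, L)
    in_motif <- rep(FALSE, L)
    for (m in motifs) {
      stopifnot(m$start >= 1L, m$end <= L, m$start <= m$end)
      cons_level[m$start:m$end] <- m$conservation
      in_motif[m$start:m$end] <- TRUE
    }
    consensus <- sample(AA_ALPHABET, L, replace = TRUE)
    profiles <- matrix(0, 20L, L, dimnames = list(AA_ALPHABET, NULL))
    for (i in seq_len(L)) {
      p <- rep((1 - cons_level[i]) / 19, 20L)
      p[match(consensus[i], AA_ALPHABET)] <- cons_level[i]
      profiles[, i] <- p
    }
    rows <- character(n_sequences)
    rows[1L] <- paste(consensus, collapse = "")
    if (n_sequences > 1L) {
      for (s in 2:n_sequences) {
        letters_s <- vapply(seq_len(L), function(i) {
          if (!in_motif[i] && runif(1) < gap_prob) return("-")
          sample(AA_ALPHABET, 1L, prob = profiles[, i])
        }, character(1))
        rows[s] <- paste(letters_s, collapse = "")
      }
    }
    msa <- structure(list(query_id = "query",
                          query_seq = rows[1L],
                          ids = c("query", if (n_sequences > 1L)
                            sprintf("homolog_%03d", seq_len(n_sequences - 1L))),
                          rows = rows, L = L, n_sequences = n_sequences),
                     class = "msa")
    list(msa = msa, profiles = profiles, consensus = rows[1L])
  })
}

#' Generate a synthetic mutational landscape with known truth
#'
#' Each substitution cell draws its component from a three-class mixture
#' (impactful / mild / neutral) and its score from the corresponding
#' Gaussian; an optional segment plan adds position-level mean shifts so the
#' sensitivity profile carries planted changepoints.
#'
#' @param L Protein length.
#' @param class_means Ascending means of the three score classes, default
#'   \code{c(-8, -4, 0)}.
#' @param class_sds Standard deviations, default \code{c(0.5, 0.5, 0.5)}.
#' @param class_weights Mixing proportions, default \code{c(0.3, 0.3, 0.4)}.
#' @param segment_plan Optional data frame \code{start, end, shift}; windows
#'   must tile or partially cover \code{1..L} without overlap.
#' @param seed Integer seed.
#' @return List with \code{landscape}, \code{wild_type}, \code{truth}
#'   (component matrix 20 x L, generating thresholds = weighted-density
#'   crossovers of the generating mixture, planted changepoints, shifts).
#' @export
generate_synthetic_landscape <- function(L, class_means = c(-8, -4, 0),
                                         class_sds = c(0.5, 0.5, 0.5),
                                         class_weights = c(0.3, 0.3, 0.4),
                                         segment_plan = NULL, seed = 0L) {
  stopifnot(length(class_means) == 3L, !is.unsorted(class_means),
            all(class_sds > 0), all(class_weights > 0))
  class_weights <- class_weights / sum(class_weights)
  if (!is.null(segment_plan)) {
    sp <- segment_plan[order(segment_plan$start), , drop = FALSE]
    if (any(sp$start < 1L) || any(sp$end > L) || any(sp$start > sp$end) ||
        (nrow(sp) > 1L && any(sp$start[-1L] <= sp$end[-nrow(sp)])))
      ml_error("mutland_bad_plan", "malformed segment plan")
  }
  withr::with_seed(as.integer(seed), {
    wt <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    comp <- matrix(sample(1:3, 20L * L, replace = TRUE, prob = class_weights),
                   20L, L)
    scores <- matrix(rnorm(20L * L, class_means[comp], class_sds[comp]),
                     20L, L)
    shift <- rep(0, L)
    if (!is.null(segment_plan)) {
      for (r in seq_len(nrow(segment_plan)))
        shift[segment_plan$start[r]:segment_plan$end[r]] <-
          segment_plan$shift[r]
    }
    scores <- sweep(scores, 2L, shift, "+")
    landscape <- new_landscape(wt, scores, scorer = "synthetic")
    true_cp <- if (is.null(segment_plan)) integer(0) else {
      ends <- sort(unique(c(segment_plan$end, segment_plan$start - 1L)))
      ends[ends >= 1L & ends < L]
    }
    tl <- density_crossover(class_weights[1], class_means[1], class_sds[1]^2,
                            class_weights[2], class_means[2], class_sds[2]^2)
    th <- density_crossover(class_weights[2], class_means[2], class_sds[2]^2,
                            class_weights[3], class_means[3], class_sds[3]^2)
    list(landscape = landscape, wild_type = wt,
         truth = list(components = comp,
                      threshold_low = tl, threshold_high = th,
                      changepoints = true_cp, shift = shift))
  })
}

#' Generate a noisy piecewise-constant signal
#'
#' Convenience generator for changepoint-recovery experiments.
#'
#' @param n Signal length.
#' @param changepoints Last index of each segment except the final one
#'   (sorted, in \code{1..n-1}).
#' @param means Segment means, length \code{length(changepoints) + 1}.
#' @param sigma Noise standard deviation.
#' @param seed Integer seed.
#' @return List with \code{y}, \code{mean} (noise-free signal),
#'   \code{changepoints}.
#' @export
generate_piecewise_signal <- function(n, changepoints, means, sigma,
                                      seed = 0L) {
  stopifnot(length(means) == length(changepoints) + 1L,
            all(diff(c(0L, changepoints, n)) > 0L))
  withr::with_seed(as.integer(seed), {
    ends <- c(changepoints, n)
    starts <- c(1L, head(ends, -1L) + 1L)
    mu <- numeric(n)
    for (j in seq_along(ends)) mu[starts[j]:ends[j]] <- means[j]
    list(y = mu + rnorm(n, 0, sigma), mean = mu, changepoints = changepoints)
  })
}

#' Generate a toy PDB structure
#'
#' Builds an idealised backbone (N, CA, C, O plus a CB placeholder for
#' non-glycine residues) along a helical or extended trace, with one or two
#' chains; the two-chain mode places the second chain in contact so that
#' interface residues are buried in the complexed context. Optionally writes
#' synthetic pLDDT values into the B-factor column. Geometry is deliberately
#' simple: it is meant for exercising parsing, alignment, accessibility and
#' export code, not for physical realism.
#'
#' @param seq Amino-acid sequence (length at most 50).
#' @param conformation \code{"helix"} or \code{"extended"}.
#' @param n_chains 1 or 2.
#' @param plddt Optional numeric vector (length \code{nchar(seq)}) written to
#'   the B-factor column of every chain.
#' @param path Optional output file; when \code{NULL} the PDB text is only
#'   returned.
#' @return Character vector of PDB lines, invisibly when \code{path} is
#'   given.
#' @export
generate_toy_structure <- function(seq, conformation = c("helix", "extended"),
                                   n_chains = 1L, plddt = NULL, path = NULL) {
  conformation <- match.arg(conformation)
  L <- nchar(seq)
  stopifnot(L >= 1L, L <= 50L, n_chains %in% 1:2,
            is.null(plddt) || length(plddt) == L)
  letters1 <- strsplit(seq, "")[[1L]]
  if (!all(letters1 %in% AA_ALPHABET))
    ml_error("mutland_bad_residue",
             "sequence contains letters outside the 20-residue alphabet")
  aa3 <- names(STANDARD_AA3)[match(letters1, STANDARD_AA3)]

  ca <- matrix(0, L, 3L)
  radial <- matrix(0, L, 3L)
  if (conformation == "helix") {
    theta <- (seq_len(L) - 1L) * 100 * pi / 180
    ca[, 1L] <- 2.3 * cos(theta)
    ca[, 2L] <- 2.3 * sin(theta)
    ca[, 3L] <- 1.5 * (seq_len(L) - 1L)
    radial[, 1L] <- cos(theta)
    radial[, 2L] <- sin(theta)
  } else {
    ca[, 1L] <- 3.8 * (seq_len(L) - 1L)
    radial[, 2L] <- 1
  }
  unit <- function(v) v / sqrt(sum(v^2))
  atoms <- list()
  for (i in seq_len(L)) {
    back <- if (i > 1L) unit(ca[i - 1L, ] - ca[i, ]) else
      -unit(ca[min(i + 1L, L), ] - ca[i, ])
    fwd <- if (i < L) unit(ca[i + 1L, ] - ca[i, ]) else
      -unit(ca[i - 1L, ] - ca[i, ])
    res <- list(N = ca[i, ] + 1.45 * back, CA = ca[i, ],
                C = ca[i, ] + 1.52 * fwd,
                O = ca[i, ] + 1.52 * fwd + 1.23 * radial[i, ])
    if (letters1[i] != "G") res$CB <- ca[i, ] + 1.53 * radial[i, ]
    atoms[[i]] <- res
  }

  offset <- if (conformation == "helix") c(0, 8.0, 0) else c(0, 5.5, 0)
  # fixed-column PDB ATOM record (name in 13-16, resName 18-20, chain 22,
  # resSeq 23-26, xyz 31-54, occ 55-60, B 61-66, element 77-78)
  fmt_atom <- function(serial, name, res3, chain, resno, xyz, b, elem) {
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, res3, chain, resno, xyz[1], xyz[2], xyz[3], 1.00, b,
            elem)
  }
  lines <- character(0)
  serial <- 0L
  for (c_i in seq_len(n_chains)) {
    chain <- c("A", "B")[c_i]
    shift <- if (c_i == 2L) offset else c(0, 0, 0)
    for (i in seq_len(L)) {
      b <- if (is.null(plddt)) 0 else plddt[i]
      for (nm in names(atoms[[i]])) {
        serial <- serial + 1L
        lines <- c(lines, fmt_atom(serial, nm, aa3[i], chain, i,
                                   atoms[[i]][[nm]] + shift, b,
                                   substr(nm, 1L, 1L)))
      }
    }
    lines <- c(lines, sprintf("TER   %5d      %3s %s%4d", serial + 1L,
                              aa3[L], chain, L))
    serial <- serial + 1L
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
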