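# Structural context: PDB chain parsing, query-to-chain sequence alignment,
# Shrake-Rupley solvent accessibility (free and complexed), structure-aware
# score modulation, and per-residue B-factor exports for 3D colouring.

# curated non-standard -> standard residue mapping (modified and substituted
# residues commonly found in experimental structures)
NONSTANDARD_AA <- c(MSE = "M", SEP = "S", TPO = "T", PTR = "Y", MLY = "K",
                    M3L = "K", HYP = "P", CSO = "C", CME = "C", KCX = "K",
                    PCA = "Q", SEC = "C", PYL = "K", FME = "M")

STANDARD_AA3 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
                  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
                  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
                  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

# van der Waals radii by element (Angstrom); unknown elements fall back to
# carbon
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# theoretical maximum ASA per residue type (Tien et al. 2013), Angstrom^2
MAX_ASA_TIEN2013 <- c(A = 129, C = 167, D = 193, E = 223, F = 240, G = 104,
                      H = 224, I = 197, K = 236, L = 201, M = 224, N = 195,
                      P = 159, Q = 225, R = 274, S = 155, T = 172, V = 174,
                      W = 285, Y = 263)

element_radius <- function(elements) {
  r <- VDW_RADII[toupper(trimws(elements))]
  r[is.na(r)] <- VDW_RADII[["C"]]
  as.numeric(r)
}

#' Read one chain of a PDB structure
#'
#' Parses the first model of a PDB file with \pkg{bio3d}, keeps the requested
#' chain, drops waters, resolves alternate locations to the highest-occupancy
#' copy, maps non-standard residues to their standard equivalents via a
#' curated dictionary (MSE, SEP, TPO, PTR, MLY, M3L, HYP, ...) and drops
#' residues with no mapping. Atoms of all other chains are retained
#' separately as occluders for complexed-context solvent accessibility.
#'
#' @param path PDB file path.
#' @param chain_id Chain identifier, default \code{"A"}.
#' @param source \code{"pdb_experimental"} or \code{"alphafold_model"}; only
#'   in the latter case is the B-factor column interpreted as pLDDT.
#' @return A \code{"chain_structure"} object with \code{residues} (data
#'   frame: \code{chain_idx, resno, insert, resid3, code1, bfactor}),
#'   \code{atoms} (coordinates, elements, radii, residue index),
#'   \code{other_atoms}, \code{sequence}, \code{plddt} (per-residue, only
#'   for AlphaFold models), and the source \pkg{bio3d} object for export.
#' @export
read_chain <- function(path, chain_id = "A",
                       source = c("pdb_experimental", "alphafold_model")) {
  source <- match.arg(source)
  if (!file.exists(path))
    ml_error("mutland_io_error", sprintf("structure file not found: %s", path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$row <- seq_len(nrow(at))
  at <- at[!(at$resid %in% WATER_RESID), , drop = FALSE]
  if (!chain_id %in% unique(at$chain))
    ml_error("mutland_missing_chain",
             sprintf("chain '%s' not present (available: %s)", chain_id,
                     paste(sort(unique(at$chain)), collapse = ", ")))

  # altloc: keep the highest-occupancy alternative of each atom
  resolve_alt <- function(df) {
    key <- paste(df$chain, df$resno, df$insert, df$elety)
    keep <- rep(TRUE, nrow(df))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      o <- df$o[idx]
      o[is.na(o)] <- 1
      keep[idx] <- FALSE
      keep[idx[which.max(o)]] <- TRUE
    }
    df[keep, , drop = FALSE]
  }
  at <- resolve_alt(at)

  ch <- at[at$chain == chain_id, , drop = FALSE]
  other <- at[at$chain != chain_id, , drop = FALSE]

  code <- unname(STANDARD_AA3[ch$resid])
  code[is.na(code)] <- unname(NONSTANDARD_AA[ch$resid[is.na(code)]])
  ch <- ch[!is.na(code), , drop = FALSE]
  code <- code[!is.na(code)]
  if (nrow(ch) == 0L)
    ml_error("mutland_no_standard_residues",
             sprintf("chain '%s' has no standard (or mappable) residues", chain_id))

  rkey <- paste(ch$resno, ch$insert %||% "")
  rkey <- factor(rkey, levels = unique(rkey))  # file order
  ridx <- as.integer(rkey)
  residues <- data.frame(
    chain_idx = seq_along(levels(rkey)),
    resno = ch$resno[!duplicated(ridx)],
    insert = ifelse(is.na(ch$insert[!duplicated(ridx)]), "",
                    ch$insert[!duplicated(ridx)]),
    resid3 = ch$resid[!duplicated(ridx)],
    code1 = code[!duplicated(ridx)],
    bfactor = as.numeric(tapply(ch$b, ridx, mean)))

  atoms <- data.frame(x = ch$x, y = ch$y, z = ch$z,
                      element = ch$elesy, radius = element_radius(ch$elesy),
                      residue_idx = ridx, pdb_row = ch$row)
  other_atoms <- data.frame(x = other$x, y = other$y, z = other$z,
                            element = other$elesy,
                            radius = element_radius(other$elesy))

  structure(list(chain_id = chain_id, source = source, residues = residues,
                 atoms = atoms, other_atoms = other_atoms,
                 sequence = paste(residues$code1, collapse = ""),
                 n_residues = nrow(residues),
                 plddt = if (source == "alphafold_model") residues$bfactor,
                 pdb = pdb),
            class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("Chain %s: %d residues, %d atoms (%s), %d occluder atoms\n",
              x$chain_id, x$n_residues, nrow(x$atoms), x$source,
              nrow(x$other_atoms)))
  invisible(x)
}

#' Globally align the query sequence to a chain sequence
#'
#' Global affine-gap alignment with match 1.0, mismatch -3.0, gap opening
#' -2.5, and gap extension and terminal gaps -2.0 per position (terminal gap
#' runs are scored entirely at the extension rate). Ties are resolved
#' deterministically by preferring diagonal over up over left moves.
#'
#' @param query_seq Query protein sequence.
#' @param chain_seq One-letter sequence of the structure chain.
#' @return A \code{"seqstruct_mapping"} object: \code{pairs} (data frame
#'   \code{query_pos, chain_idx} of aligned, strictly monotone position
#'   pairs), \code{unaligned_query_positions}, \code{alignment_score},
#'   \code{identity} (fraction of aligned pairs that match), and the two
#'   aligned strings.
#' @export
align_query_to_chain <- function(query_seq, chain_seq) {
  stopifnot(nchar(query_seq) > 0L, nchar(chain_seq) > 0L)
  res <- gotoh_align_cpp(query_seq, chain_seq, 1.0, -3.0, -2.5, -2.0, -2.0)
  ax <- strsplit(res$aligned_x, "")[[1L]]
  ay <- strsplit(res$aligned_y, "")[[1L]]
  qi <- cumsum(ax != "-")
  ci <- cumsum(ay != "-")
  both <- ax != "-" & ay != "-"
  pairs <- data.frame(query_pos = qi[both], chain_idx = ci[both])
  identity <- if (nrow(pairs)) mean(ax[both] == ay[both]) else 0
  structure(list(pairs = pairs,
                 unaligned_query_positions =
                   setdiff(seq_len(nchar(query_seq)), pairs$query_pos),
                 alignment_score = res$score, identity = identity,
                 aligned_query = res$aligned_x, aligned_chain = res$aligned_y),
            class = "seqstruct_mapping")
}

#' @export
print.seqstruct_mapping <- function(x, ...) {
  cat(sprintf("Sequence-structure mapping: %d aligned pairs, score %.1f, identity %.1f%%\n",
              nrow(x$pairs), x$alignment_score, 100 * x$identity))
  invisible(x)
}

#' Per-residue relative solvent accessibility (Shrake-Rupley)
#'
#' Accessible surface area is computed per atom by Shrake-Rupley sphere
#' sampling (probe radius 1.4 A, 100 points per atom sphere by default) and
#' summed per residue. RSA is the residue ASA as a percentage of the
#' theoretical maximum ASA for its residue type (Tien et al. 2013 table by
#' default). In the \code{"complexed"} context the atoms of all other chains
#' occlude solvent; in the \code{"free"} context the chain is evaluated in
#' isolation.
#'
#' @param chain A \code{"chain_structure"} object.
#' @param context \code{"free"} or \code{"complexed"}.
#' @param probe Probe radius in Angstrom, default 1.4.
#' @param n_points Sampling points per atom sphere, default 100.
#' @param max_asa Named vector of maximum ASA per one-letter residue type;
#'   default [MAX_ASA_TIEN2013].
#' @return Data frame \code{chain_idx, code1, asa, rsa} with attributes
#'   \code{context} and \code{max_asa_table}.
#' @export
compute_rsa <- function(chain, context = c("free", "complexed"), probe = 1.4,
                        n_points = 100L, max_asa = MAX_ASA_TIEN2013) {
  stopifnot(inherits(chain, "chain_structure"))
  context <- match.arg(context)
  a <- chain$atoms
  if (nrow(a) == 0L)
    ml_error("mutland_no_atoms", "chain has no atoms")
  occ <- if (context == "complexed" && nrow(chain$other_atoms)) {
    chain$other_atoms
  } else {
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               radius = numeric(0))
  }
  asa_atom <- shrake_rupley_cpp(as.matrix(a[, c("x", "y", "z")]), a$radius,
                                as.matrix(occ[, c("x", "y", "z")]),
                                occ$radius, probe, as.integer(n_points))
  asa <- as.numeric(tapply(asa_atom, a$residue_idx, sum))
  out <- data.frame(chain_idx = chain$residues$chain_idx,
                    code1 = chain$residues$code1, asa = asa,
                    rsa = 100 * asa / as.numeric(max_asa[chain$residues$code1]))
  attr(out, "context") <- context
  attr(out, "max_asa_table") <- "tien2013_theoretical"
  out
}

#' Free and complexed RSA in one table
#'
#' For multimeric inputs both contexts are computed; for a monomer the two
#' columns coincide.
#'
#' @inheritParams compute_rsa
#' @return Data frame \code{chain_idx, code1, asa_free, rsa_free,
#'   asa_complexed, rsa_complexed}.
#' @export
rsa_profile <- function(chain, probe = 1.4, n_points = 100L,
                        max_asa = MAX_ASA_TIEN2013) {
  free <- compute_rsa(chain, "free", probe, n_points, max_asa)
  cplx <- if (nrow(chain$other_atoms)) {
    compute_rsa(chain, "complexed", probe, n_points, max_asa)
  } else {
    free
  }
  data.frame(chain_idx = free$chain_idx, code1 = free$code1,
             asa_free = free$asa, rsa_free = free$rsa,
             asa_complexed = cplx$asa, rsa_complexed = cplx$rsa)
}

#' Structure-aware variant scores
#'
#' Modulates the raw evolutionary score of each variant by the solvent
#' exposure of its wild-type residue:
#' \deqn{pred^{RSA}_{evol} = pred_{evol} \times (1 - \min(RSA, 100)/100)}
#' so fully buried residues keep their score and fully exposed residues are
#' zeroed; RSA is capped at 100\% to absorb accessibilities above the
#' theoretical maximum. Query positions not aligned to the structure get
#' \code{NaN} in all 19 cells.
#'
#' @param landscape A \code{"mutational_landscape"} object.
#' @param rsa Data frame from [rsa_profile()].
#' @param mapping A \code{"seqstruct_mapping"} from [align_query_to_chain()].
#' @param context Which RSA feeds the modulation: \code{"complexed"}
#'   (default, meaningful for multimeric inputs) or \code{"free"}.
#' @return A \code{"structure_aware_landscape"}: \code{scores} (20 x L, NaN
#'   columns at unaligned positions), \code{aligned} (logical length L),
#'   \code{rsa_used} (per-position RSA, NA when unaligned), \code{context}.
#' @export
structure_aware_scores <- function(landscape, rsa, mapping,
                                   context = c("complexed", "free")) {
  stopifnot(inherits(landscape, "mutational_landscape"),
            inherits(mapping, "seqstruct_mapping"))
  context <- match.arg(context)
  L <- landscape$L
  col <- if (context == "complexed") "rsa_complexed" else "rsa_free"
  rsa_q <- rep(NA_real_, L)
  m <- match(mapping$pairs$chain_idx, rsa$chain_idx)
  rsa_q[mapping$pairs$query_pos] <- rsa[[col]][m]
  mult <- 1 - pmin(pmax(rsa_q, 0), 100) / 100
  scores <- sweep(landscape$scores, 2L, mult, "*")
  scores[, is.na(rsa_q)] <- NaN
  wtcells <- cbind(match(strsplit(landscape$wild_type, "")[[1L]], AA_ALPHABET),
                   seq_len(L))
  scores[wtcells] <- NA_real_
  structure(list(L = L, wild_type = landscape$wild_type, scores = scores,
                 aligned = !is.na(rsa_q), rsa_used = rsa_q,
                 context = context, scorer = landscape$scorer),
            class = "structure_aware_landscape")
}

#' Write per-residue values into the B-factor column of a PDB file
#'
#' Replaces every atom's B-factor with its residue's value so the structure
#' can be coloured in any molecular viewer (sensitivity, residue class code,
#' or structure-aware sensitivity). Residues without a value get a sentinel.
#'
#' @param chain A \code{"chain_structure"} object.
#' @param values Numeric vector, one value per chain residue
#'   (\code{chain_idx} order); \code{NA} entries are replaced by \code{fill}.
#' @param path Output PDB path.
#' @param fill Sentinel for residues without a value, default \code{-99}.
#' @return The path, invisibly.
#' @export
export_bfactor_pdb <- function(chain, values, path, fill = -99) {
  stopifnot(inherits(chain, "chain_structure"),
            length(values) == chain$n_residues)
  values <- ifelse(is.na(values), fill, values)
  inds <- bio3d::as.select(chain$atoms$pdb_row)
  sub <- bio3d::trim.pdb(chain$pdb, inds)
  b <- values[chain$atoms$residue_idx]
  bio3d::write.pdb(sub, file = path, b = b)
  invisible(path)
}
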