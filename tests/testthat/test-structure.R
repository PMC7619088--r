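toy_pdb <- function(seq = "ACDEFGHIKL", conformation = "helix",
                    n_chains = 1, plddt = NULL) {
  f <- tempfile(fileext = ".pdb")
  generate_toy_structure(seq, conformation, n_chains, plddt, path = f)
  f
}

test_that("toy structures round-trip through the chain parser", {
  f <- toy_pdb("AAAAA")
  ch <- read_chain(f)
  expect_equal(ch$n_residues, 5)
  expect_equal(ch$sequence, "AAAAA")
  expect_equal(nrow(ch$other_atoms), 0)

  f2 <- toy_pdb("ACDEF", n_chains = 2, plddt = c(90, 90, 40, 40, 40))
  chA <- read_chain(f2, "A", source = "alphafold_model")
  expect_equal(chA$sequence, "ACDEF")
  expect_gt(nrow(chA$other_atoms), 0)
  expect_equal(chA$plddt, c(90, 90, 40, 40, 40))
  chB <- read_chain(f2, "B")
  expect_equal(chB$sequence, "ACDEF")
  expect_null(chB$plddt)  # experimental B-factors are not pLDDT
})

test_that("non-standard residues map to standard equivalents; waters drop", {
  # hand-built file: MSE (selenomethionine) as HETATM, a water, and a GLY
  lines <- c(
    "HETATM    1  CA  MSE A   1       0.000   0.000   0.000  1.00 10.00           C",
    "HETATM    2  SE  MSE A   1       1.800   0.000   0.000  1.00 10.00          SE",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00 20.00           C",
    "HETATM    4  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb"); writeLines(lines, f)
  ch <- read_chain(f)
  expect_equal(ch$sequence, "MG")
  expect_equal(ch$residues$bfactor, c(10, 20))
  expect_equal(nrow(ch$atoms), 3)  # water excluded

  expect_error(read_chain(f, "B"), class = "mutland_missing_chain")
})

test_that("altloc atoms resolve to the highest-occupancy copy", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30 11.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.70 22.00           C",
    "END")
  f <- tempfile(fileext = ".pdb"); writeLines(lines, f)
  ch <- read_chain(f)
  expect_equal(nrow(ch$atoms), 1)
  expect_equal(ch$atoms$x, 5.0)
  expect_equal(ch$residues$bfactor, 22)
})

test_that("query-chain alignment reproduces worked examples", {
  # identical sequences: identity mapping, score = k
  a <- align_query_to_chain("ACDEFG", "ACDEFG")
  expect_equal(a$alignment_score, 6)
  expect_equal(a$pairs$query_pos, 1:6)
  expect_equal(a$pairs$chain_idx, 1:6)
  expect_equal(a$identity, 1)

  # one internal deletion: 5 matches - 2.5 open
  b <- align_query_to_chain("ACDEFG", "ACEFG")
  expect_equal(b$alignment_score, 5 - 2.5)
  expect_equal(b$unaligned_query_positions, 3)
  expect_equal(b$pairs$chain_idx, 1:5)

  # disjoint sequences still align (terminal gaps at -2/position beat
  # four mismatches)
  d <- align_query_to_chain("AAAA", "WWWW")
  expect_equal(d$alignment_score,
               oracle_align_score("AAAA", "WWWW"))
  expect_lt(d$identity, 0.3)
})

test_that("alignment score matches the reference affine-gap DP on random pairs", {
  alphabet <- c("A", "C", "D", "E", "F", "G")
  for (k in 1:120) {
    pair <- withr::with_seed(3000 + k, {
      n1 <- sample(1:20, 1); n2 <- sample(1:20, 1)
      c(paste(sample(alphabet, n1, TRUE), collapse = ""),
        paste(sample(alphabet, n2, TRUE), collapse = ""))
    })
    got <- align_query_to_chain(pair[1], pair[2])
    expect_equal(got$alignment_score, oracle_align_score(pair[1], pair[2]))
    # mapping strictly monotone in both coordinates
    expect_true(all(diff(got$pairs$query_pos) > 0))
    expect_true(all(diff(got$pairs$chain_idx) > 0))
    # every query position in exactly one of pairs / unaligned
    expect_setequal(c(got$pairs$query_pos, got$unaligned_query_positions),
                    seq_len(nchar(pair[1])))
  }
})

test_that("Shrake-Rupley matches sphere geometry", {
  sr <- mutland:::shrake_rupley_cpp
  empty <- matrix(numeric(0), 0, 3)
  # isolated atom: ASA = 4*pi*(r+probe)^2
  for (r in c(1.2, 1.52, 1.7, 1.9)) {
    asa <- sr(matrix(0, 1, 3), r, empty, numeric(0), 1.4, 100)
    expect_equal(asa, 4 * pi * (r + 1.4)^2, tolerance = 0.02)
  }
  # fully caged atom: zero accessibility
  dirs <- vapply(0:59, function(k) {
    z <- 1 - 2 * (k + 0.5) / 60
    phi <- pi * (3 - sqrt(5)) * k
    c(cos(phi) * sqrt(1 - z^2), sin(phi) * sqrt(1 - z^2), z)
  }, numeric(3))
  cage <- t(dirs) * 3.0
  asa_caged <- sr(matrix(0, 1, 3), 1.7, cage, rep(1.7, 60), 1.4, 100)
  expect_equal(asa_caged, 0)
  # convergence: doubling the sampling density moves per-residue RSA by
  # < 2 points (checked at base 200; at 100 points each sample is a full 1%
  # of an atom sphere, so small residues can still move ~3 points)
  ch <- read_chain(toy_pdb("ACDEFGHIKL"), "A")
  r200 <- compute_rsa(ch, "free", n_points = 200)
  r400 <- compute_rsa(ch, "free", n_points = 400)
  expect_lt(max(abs(r200$rsa - r400$rsa)), 2)
})

test_that("complex context only reduces accessibility; interfaces are buried", {
  f <- toy_pdb("ACDEFGHIKLMNPQRSTVWY", "extended", n_chains = 2)
  ch <- read_chain(f, "A")
  rp <- rsa_profile(ch)
  expect_true(all(rp$rsa_free >= rp$rsa_complexed - 1e-9))
  expect_gt(max(rp$rsa_free - rp$rsa_complexed), 10)
  # monomer: contexts coincide
  ch1 <- read_chain(toy_pdb("ACDEF"), "A")
  rp1 <- rsa_profile(ch1)
  expect_identical(rp1$rsa_free, rp1$rsa_complexed)
})

within_scale <- function(ls, k) { ls$scores <- ls$scores * k; ls }

test_that("structure-aware scores implement the RSA modulation contract", {
  sim <- generate_synthetic_landscape(6, seed = 41)
  ls <- sim$landscape
  rsa <- data.frame(chain_idx = 1:5, code1 = strsplit(sim$wild_type, "")[[1]][1:5],
                    asa_free = 0, rsa_free = c(25, 0, 150, 100, 50),
                    asa_complexed = 0, rsa_complexed = c(25, 0, 150, 100, 50))
  mapping <- structure(list(
    pairs = data.frame(query_pos = 1:5, chain_idx = 1:5),
    unaligned_query_positions = 6L, alignment_score = 5, identity = 1),
    class = "seqstruct_mapping")
  sa <- structure_aware_scores(ls, rsa, mapping, "free")

  # worked value: raw -4, RSA 25 -> -3
  ls2 <- ls; ls2$scores[!is.na(ls2$scores)] <- -4
  sa2 <- structure_aware_scores(ls2, rsa, mapping, "free")
  ok <- !is.na(sa2$scores[, 1])
  expect_equal(unique(sa2$scores[ok, 1]), -3)
  # RSA 0: unchanged; RSA >= 100: zero
  expect_equal(sa$scores[, 2], ls$scores[, 2])
  expect_equal(unique(sa2$scores[!is.na(sa2$scores[, 3]), 3]), 0)
  expect_equal(unique(sa2$scores[!is.na(sa2$scores[, 4]), 4]), 0)
  # multiplier in [0,1]: same sign, never larger in magnitude
  expect_true(all(abs(sa$scores) <= abs(ls$scores) + 1e-12, na.rm = TRUE))
  expect_true(all(sign(sa$scores) == sign(ls$scores) | sa$scores == 0,
                  na.rm = TRUE))
  # unmapped position: all 19 substitution cells NaN (the wild-type cell
  # stays masked as NA)
  expect_equal(sum(is.nan(sa$scores[, 6])), 19)
  expect_true(all(is.nan(sa$scores[, 6]) | is.na(sa$scores[, 6])))
  expect_false(sa$aligned[6])
  # linear in the raw score
  sa_half <- structure_aware_scores(
    within_scale(ls, 0.5), rsa, mapping, "free")
  expect_equal(sa_half$scores[, 1], 0.5 * sa$scores[, 1])
})

test_that("B-factor export writes per-residue values readable to 2 decimals", {
  f <- toy_pdb("ACDEFG")
  ch <- read_chain(f)
  out <- tempfile(fileext = ".pdb")
  vals <- c(1.25, -0.5, 3.14159, NA, 0, 2)
  export_bfactor_pdb(ch, vals, out)
  back <- read_chain(out)
  expect_equal(back$residues$bfactor,
               round(ifelse(is.na(vals), -99, vals), 2), tolerance = 1e-9)
  # constant export
  export_bfactor_pdb(ch, rep(1, 6), out)
  expect_true(all(read_chain(out)$residues$bfactor == 1))
})
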