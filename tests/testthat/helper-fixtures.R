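# shared fixture builder: MSA with two conserved motifs + a toy AlphaFold-
# style structure covering the first 50 residues
build_fixture <- function(dir, seed = 7, with_structure = TRUE,
                          with_mutations = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_synthetic_msa(
    L = 120, n_sequences = 200,
    motifs = list(list(start = 41, end = 55, conservation = 0.95),
                  list(start = 86, end = 95, conservation = 0.9)),
    seed = seed)
  write_msa(sim$msa, file.path(dir, "msa.fasta"))
  paths <- list(msa = file.path(dir, "msa.fasta"), query = sim$msa$query_seq)
  if (with_structure) {
    paths$structure <- file.path(dir, "structure.pdb")
    generate_toy_structure(substr(sim$msa$query_seq, 1, 50), "helix",
                           n_chains = 1,
                           plddt = c(rep(90, 40), rep(45, 10)),
                           path = paths$structure)
  }
  if (with_mutations) {
    wt <- strsplit(sim$msa$query_seq, "")[[1]]
    mut <- vapply(c(5, 45), function(p) setdiff(AA_ALPHABET, wt[p])[1],
                  character(1))
    write.csv(data.frame(wt = wt[c(5, 45)], position = c(5, 45), mut = mut,
                         label = c("benign", "pathogenic")),
              file.path(dir, "mutations.csv"), row.names = FALSE,
              quote = FALSE)
    paths$mutations <- file.path(dir, "mutations.csv")
  }
  paths
}
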