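# Full-run orchestration: MSA -> landscape -> classification -> segmentation
# -> (optional) structure, plus annotated-mutation ingestion and all file
# exports. All positions in exported tables are 1-based closed intervals;
# the BED export is 0-based half-open.

#' Load annotated mutations
#'
#' CSV with header \code{wt,position,mut,label}. Each row is validated
#' against the query sequence; duplicate (position, mut) pairs with
#' conflicting labels are rejected.
#'
#' @param path CSV path.
#' @param query_seq Query protein sequence.
#' @return Data frame \code{wt, position, mut, label} (possibly 0 rows).
#' @export
load_mutations <- function(path, query_seq) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("wt", "position", "mut", "label")
  if ("label" %in% names(df)) df$label <- as.character(df$label)
  if (!all(need %in% names(df)))
    ml_error("mutland_bad_mutations", "mutation CSV must have columns wt,position,mut,label")
  if (nrow(df) == 0L) return(df[, need])
  wt <- strsplit(query_seq, "")[[1L]]
  if (any(df$position < 1L | df$position > length(wt)))
    ml_error("mutland_bad_mutations", "mutation position out of range")
  mism <- df$wt != wt[df$position]
  if (any(mism))
    ml_error("mutland_wt_mismatch",
             sprintf("annotated wt letter does not match query at position(s): %s",
                     paste(unique(df$position[mism]), collapse = ", ")))
  if (any(df$mut == df$wt))
    ml_error("mutland_bad_mutations", "mut equals wt")
  key <- paste(df$position, df$mut)
  for (k in unique(key[duplicated(key)])) {
    if (length(unique(df$label[key == k])) > 1L)
      ml_error("mutland_conflicting_labels",
               sprintf("conflicting labels for (position, mut) = (%s)", k))
  }
  df[!duplicated(key), need]
}

#' Run configuration
#'
#' @param msa Path to the MSA (required).
#' @param scores Optional path to an external score-matrix CSV; when absent
#'   the baseline column log-odds scorer is used.
#' @param structure Optional PDB path.
#' @param chain Chain of interest, default \code{"A"}.
#' @param alphafold_model Logical; when \code{TRUE} the structure's B-factors
#'   are interpreted as pLDDT and used for segmentation weights and IDR
#'   flags. Experimental B-factors are never used as weights.
#' @param mutations Optional annotated-mutation CSV path.
#' @param alpha Segmentation penalty multiplier, default 1.4.
#' @param w_high,plddt_cutoff See [segmentation_config()].
#' @param pseudocount Baseline-scorer pseudocount, default 1.
#' @param d_min,c_min,g_max,s_min Confidence cut-offs, see
#'   [residue_confidence()].
#' @param rsa_context \code{"auto"} (complexed when the input has more than
#'   one chain, else free), \code{"complexed"} or \code{"free"}.
#' @param seed Integer seed, recorded in all outputs.
#' @param out_dir Output directory (created if needed).
#' @param bed Also write a BED export of the segments.
#' @param plots Also write static PNG plots.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(msa, scores = NULL, structure = NULL, chain = "A",
                       alphafold_model = FALSE, mutations = NULL,
                       alpha = 1.4, w_high = 0.1, plddt_cutoff = 70,
                       pseudocount = 1, d_min = 0.2, c_min = 0.3,
                       g_max = 0.5, s_min = 5,
                       rsa_context = c("auto", "complexed", "free"),
                       seed = 0L, out_dir = tempfile("mutland_run_"),
                       bed = FALSE, plots = FALSE) {
  structure(list(msa = msa, scores = scores, structure = structure,
                 chain = chain, alphafold_model = alphafold_model,
                 mutations = mutations, alpha = alpha, w_high = w_high,
                 plddt_cutoff = plddt_cutoff, pseudocount = pseudocount,
                 d_min = d_min, c_min = c_min, g_max = g_max, s_min = s_min,
                 rsa_context = match.arg(rsa_context),
                 seed = as.integer(seed), out_dir = out_dir,
                 bed = isTRUE(bed), plots = isTRUE(plots)),
            class = "run_config")
}

# write.csv folds NaN into the `na` string; NaN marks unaligned-to-structure
# cells and must survive the round trip, so such columns are pre-rendered
write_csv_file <- function(df, path) {
  for (cn in names(df)) {
    x <- df[[cn]]
    if (is.double(x) && any(is.nan(x))) {
      xc <- as.character(x)          # same rendering write.csv would use
      xc[is.na(x) & !is.nan(x)] <- NA
      df[[cn]] <- xc
    }
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  path
}

#' Run the full analysis pipeline
#'
#' Executes MSA parsing and QC, landscape ingestion (or the baseline
#' scorer), mixture-based variant and residue classification, confidence
#' flagging, sensitivity-profile segmentation and, when a structure is
#' given, sequence-structure mapping, free/complexed RSA, structure-aware
#' scores and B-factor PDB exports. All randomness is controlled by
#' \code{config$seed}; two runs with the same configuration and seed produce
#' byte-identical CSV outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of class \code{"run_result"} with the variants,
#'   residues and segments tables, the mixture fit, the QC summary and the
#'   output manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  manifest <- character(0)
  out <- function(name) file.path(config$out_dir, name)

  msa <- read_msa(config$msa)
  stats <- column_stats(msa)
  sims <- similarity_to_query(msa)
  if (msa$n_sequences < 50L)
    warnings_log <- c(warnings_log,
                      sprintf("low MSA depth: %d sequences", msa$n_sequences))

  landscape <- if (!is.null(config$scores)) {
    load_score_matrix(config$scores, msa$query_seq)
  } else {
    baseline_scores(msa, config$pseudocount)
  }
  profile <- sensitivity_profile(landscape)
  dispersion <- landscape_dispersion(landscape)

  fit <- fit_gmm3(landscape$scores, seed = config$seed)
  if (any(fit$threshold_fallback))
    warnings_log <- c(warnings_log, "GMM threshold fallback (midpoint) used")
  variants <- classify_variants(landscape, fit)
  residues <- classify_residues(variants)
  conf <- residue_confidence(stats, dispersion, config$d_min, config$c_min,
                             config$g_max, config$s_min)

  # structural context (optional)
  chain <- NULL; mapping <- NULL; rsa <- NULL; sa <- NULL
  plddt_q <- NULL
  if (!is.null(config$structure)) {
    chain <- read_chain(config$structure, config$chain,
                        if (config$alphafold_model) "alphafold_model"
                        else "pdb_experimental")
    mapping <- align_query_to_chain(msa$query_seq, chain$sequence)
    if (mapping$identity < 0.3)
      warnings_log <- c(warnings_log,
                        sprintf("low sequence-structure identity: %.1f%%",
                                100 * mapping$identity))
    rsa <- rsa_profile(chain)
    context <- if (config$rsa_context == "auto") {
      if (nrow(chain$other_atoms)) "complexed" else "free"
    } else config$rsa_context
    sa <- structure_aware_scores(landscape, rsa, mapping, context)
    if (config$alphafold_model) {
      plddt_q <- rep(NA_real_, msa$L)
      plddt_q[mapping$pairs$query_pos] <- chain$plddt[mapping$pairs$chain_idx]
    }
  }

  seg_cfg <- segmentation_config(config$alpha, config$w_high,
                                 config$plddt_cutoff)
  seg <- segment_profile(profile, plddt_q, seg_cfg)
  segments <- flag_idr_segments(seg, plddt_q, seg_cfg)

  # assemble tables
  variants$confident <- conf$confident[variants$position]
  if (!is.null(config$mutations)) {
    muts <- load_mutations(config$mutations, msa$query_seq)
    variants$label <- muts$label[match(paste(variants$position, variants$mut),
                                       paste(muts$position, muts$mut))]
  }
  if (!is.null(sa)) {
    variants$structure_aware_score <-
      sa$scores[cbind(match(variants$mut, AA_ALPHABET), variants$position)]
    variants$aligned <- sa$aligned[variants$position]
  }

  res_tab <- data.frame(position = seq_len(msa$L),
                        wt = strsplit(msa$query_seq, "")[[1L]],
                        gap_fraction = stats$gap_fraction,
                        n_substitutions_sampled = stats$n_substitutions_sampled,
                        conservation = stats$conservation,
                        sensitivity = profile$values,
                        n_neutral = residues$n_neutral,
                        residue_class = residues$residue_class,
                        score_dispersion = conf$score_dispersion,
                        confident = conf$confident,
                        reasons = conf$reasons)
  if (!is.null(chain)) {
    cn <- match(seq_len(msa$L), mapping$pairs$query_pos)
    ci <- mapping$pairs$chain_idx[cn]
    res_tab$chain_resnum <- chain$residues$resno[ci]
    res_tab$rsa_free <- rsa$rsa_free[ci]
    res_tab$rsa_complexed <- rsa$rsa_complexed[ci]
    res_tab$plddt <- if (config$alphafold_model) plddt_q else NA_real_
    res_tab$aligned <- !is.na(ci)
  }

  manifest <- c(manifest,
                write_csv_file(variants, out("variants.csv")),
                write_csv_file(res_tab, out("residues.csv")),
                write_csv_file(segments, out("segments.csv")),
                write_gmm_json(fit, out("gmm.json")))
  if (config$bed)
    manifest <- c(manifest,
                  write_segments_bed(segments, msa$query_id, out("segments.bed")))

  if (!is.null(chain)) {
    sens_chain <- rep(NA_real_, chain$n_residues)
    sens_chain[mapping$pairs$chain_idx] <- profile$values[mapping$pairs$query_pos]
    class_chain <- rep(NA_real_, chain$n_residues)
    class_chain[mapping$pairs$chain_idx] <-
      as.numeric(residues$residue_class[mapping$pairs$query_pos] == "sensitive")
    sa_prof <- sensitivity_profile(sa)
    sa_chain <- rep(NA_real_, chain$n_residues)
    sa_chain[mapping$pairs$chain_idx] <- sa_prof$values[mapping$pairs$query_pos]
    manifest <- c(manifest,
                  export_bfactor_pdb(chain, sens_chain, out("sensitivity.pdb")),
                  export_bfactor_pdb(chain, class_chain, out("class.pdb")),
                  export_bfactor_pdb(chain, sa_chain, out("structure_aware.pdb")))
  }

  if (config$plots) {
    grDevices::png(out("sensitivity_profile.png"), 900, 400)
    plot_sensitivity(profile, seg)
    grDevices::dev.off()
    grDevices::png(out("score_distribution.png"), 600, 400)
    plot_score_distribution(landscape, fit)
    grDevices::dev.off()
    manifest <- c(manifest, out("sensitivity_profile.png"),
                  out("score_distribution.png"))
  }

  qc <- list(n_sequences = msa$n_sequences, L = msa$L,
             mean_identity_to_query = mean(sims$identity_to_query),
             fraction_confident = mean(conf$confident),
             fraction_unscored = mean(variants$class == "unscored"),
             warnings = warnings_log)
  summary_json <- list(
    seed = config$seed, scorer = landscape$scorer, qc = qc,
    segmentation = list(alpha = seg$alpha, sigma2 = seg$sigma2,
                        sigma2_method = seg$sigma2_method,
                        penalty = seg$penalty,
                        n_segments = length(seg$changepoints),
                        hall_coefficients = c(0.1942, 0.2809, 0.3832, -0.8582)),
    structure = if (!is.null(chain)) list(
      chain = chain$chain_id, source = chain$source,
      n_residues = chain$n_residues,
      alignment_score = mapping$alignment_score,
      alignment_identity = mapping$identity,
      rsa_context = sa$context,
      max_asa_table = "tien2013_theoretical"),
    config = unclass(config))
  jsonlite::write_json(summary_json, out("run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- c(manifest, out("run_summary.json"))
  manifest <- c(manifest, out("manifest.json"))
  jsonlite::write_json(list(files = basename(manifest)),
                       out("manifest.json"), auto_unbox = FALSE)

  invisible(structure(list(variants = variants, residues = res_tab,
                           segments = segments, fit = fit,
                           segmentation = seg, landscape = landscape,
                           profile = profile, mapping = mapping, rsa = rsa,
                           structure_aware = sa, qc = qc,
                           manifest = manifest, config = config),
                      class = "run_result"))
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(paste0("Run: L = %d, %d sequences, %d variants ",
                     "(%d impactful / %d mild / %d neutral / %d unscored)\n",
                     "%d segment(s); %.0f%% of residues confident\n"),
              x$qc$L, x$qc$n_sequences, nrow(x$variants),
              sum(x$variants$class == "impactful"),
              sum(x$variants$class == "mild"),
              sum(x$variants$class == "neutral"),
              sum(x$variants$class == "unscored"),
              nrow(x$segments), 100 * x$qc$fraction_confident))
  invisible(x)
}

#' Plot the sensitivity profile with its segmentation
#'
#' @param profile A \code{"sensitivity_profile"}.
#' @param seg A scored \code{"segmentation"}.
#' @export
plot_sensitivity <- function(profile, seg) {
  y <- profile$values
  plot(seq_along(y), y, type = "l", col = "grey40",
       xlab = "position", ylab = "mean substitution score",
       main = "Mutational sensitivity profile")
  cols <- c("black", "red", "purple")
  for (j in seq_along(seg$changepoints)) {
    graphics::segments(seg$starts[j], seg$segment_means[j],
                       seg$changepoints[j], seg$segment_means[j],
                       col = cols[seg$segment_scores[j] + 1L], lwd = 3)
  }
}

#' Plot the raw-score distribution with the fitted mixture
#'
#' @param landscape A \code{"mutational_landscape"}.
#' @param fit A \code{"gmm_fit"}.
#' @export
plot_score_distribution <- function(landscape, fit) {
  x <- landscape$scores[is.finite(landscape$scores)]
  graphics::hist(x, breaks = 60, freq = FALSE, col = "grey85",
                 border = NA, xlab = "raw evolutionary score",
                 main = "Score distribution and 3-component mixture")
  xs <- seq(min(x), max(x), length.out = 400)
  cols <- c("red", "purple", "blue")
  for (j in 1:3)
    graphics::lines(xs, fit$weights[j] * dnorm(xs, fit$means[j],
                                               sqrt(fit$variances[j])),
                    col = cols[j], lwd = 2)
  graphics::abline(v = c(fit$threshold_low, fit$threshold_high),
                   lty = 2, col = c("purple", "pink3"))
}
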