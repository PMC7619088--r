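# Three-tier variant classification.
#
# The pooled raw-score distribution of a protein is modelled as a mixture of
# three Gaussians (impactful / mild / neutral, means sorted ascending, most
# negative = impactful). The two classification thresholds are the points
# between adjacent component means where the weighted component densities
# cross; variants are labelled by which of the three score intervals they
# fall in, residues by how many of their 19 substitutions are neutral.

#' Fit a three-component Gaussian mixture to raw scores
#'
#' Expectation-maximisation with component-specific variances, multiple
#' restarts and a deterministic quantile initialisation, so the fit is
#' reproducible given \code{seed}. Components are returned sorted by mean
#' ascending and the two classification thresholds (weighted-density
#' crossovers, see [derive_thresholds()]) are attached.
#'
#' @param scores Numeric vector of raw scores; non-finite values are dropped.
#' @param seed Integer seed controlling the (jittered) restarts.
#' @param n_restarts Number of EM restarts (the first is deterministic
#'   quantile initialisation), default 10.
#' @param tol Convergence tolerance on the log-likelihood, default 1e-6.
#' @param max_iter Maximum EM iterations per restart, default 500.
#' @param var_floor Lower bound on component variances, default 1e-8.
#' @return A \code{"gmm_fit"} object: \code{weights}, \code{means},
#'   \code{variances} (each length 3, sorted by mean), \code{threshold_low},
#'   \code{threshold_high}, \code{threshold_fallback} (logical length 2),
#'   \code{seed}, \code{log_likelihood}, \code{n}.
#' @export
fit_gmm3 <- function(scores, seed = 0L, n_restarts = 10L, tol = 1e-6,
                     max_iter = 500L, var_floor = 1e-8) {
  x <- scores[is.finite(scores)]
  n <- length(x)
  if (n < 30L)
    ml_error("mutland_insufficient_data",
             sprintf("need at least 30 finite scores for a 3-component fit (got %d)", n))

  em_once <- function(mu0) {
    k <- 3L
    mu <- as.numeric(mu0)
    sg2 <- rep(max(var(x) / 9, var_floor), k)
    pi_ <- rep(1 / k, k)
    ll_old <- -Inf
    ll <- -Inf
    for (it in seq_len(max_iter)) {
      logd <- vapply(1:k, function(j)
        dnorm(x, mu[j], sqrt(sg2[j]), log = TRUE) + log(pi_[j]), numeric(n))
      mx <- apply(logd, 1L, max)
      lse <- mx + log(rowSums(exp(logd - mx)))
      ll <- sum(lse)
      r <- exp(logd - lse)
      nk <- colSums(r)
      if (any(nk < 1e-6)) return(NULL)  # collapsed component
      pi_ <- nk / n
      mu <- colSums(r * x) / nk
      sg2 <- pmax(vapply(1:k, function(j)
        sum(r[, j] * (x - mu[j])^2) / nk[j], numeric(1)), var_floor)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (any(sg2 <= var_floor * 1.0001 & pi_ < 1e-3)) return(NULL)
    list(weights = pi_, means = mu, variances = sg2, log_likelihood = ll)
  }

  fits <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_restarts), function(r) {
      mu0 <- if (r == 1L) {
        quantile(x, c(1, 3, 5) / 6, names = FALSE, type = 7)
      } else {
        sort(quantile(x, sort(runif(3, 0.02, 0.98)), names = FALSE))
      }
      em_once(mu0)
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    ml_error("mutland_gmm_degenerate",
             "EM collapsed on every restart (variance floor reached)")
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "log_likelihood"))]]

  ord <- order(best$means)
  fit <- structure(list(weights = best$weights[ord], means = best$means[ord],
                        variances = best$variances[ord],
                        threshold_low = NA_real_, threshold_high = NA_real_,
                        threshold_fallback = c(low = FALSE, high = FALSE),
                        seed = as.integer(seed),
                        log_likelihood = best$log_likelihood, n = n),
                   class = "gmm_fit")
  derive_thresholds(fit)
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(paste0("3-component Gaussian mixture (n = %d, logLik = %.2f)\n",
                     "  means: %s  weights: %s\n",
                     "  thresholds: impactful < %.4f <= mild < %.4f <= neutral\n"),
              x$n, x$log_likelihood,
              paste(sprintf("%.3f", x$means), collapse = ", "),
              paste(sprintf("%.3f", x$weights), collapse = ", "),
              x$threshold_low, x$threshold_high))
  invisible(x)
}

# crossover of two weighted Gaussian densities inside the open interval
# (m1, m2); NA when no root lies in the interval
density_crossover <- function(w1, m1, v1, w2, m2, v2) {
  a <- 1 / (2 * v2) - 1 / (2 * v1)
  b <- m1 / v1 - m2 / v2
  cc <- m2^2 / (2 * v2) - m1^2 / (2 * v1) +
    log(w1 / w2) + 0.5 * log(v2 / v1)
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (!length(inside)) return(NA_real_)
  # with two admissible roots keep the one nearest the midpoint
  inside[which.min(abs(inside - (m1 + m2) / 2))]
}

#' Derive the two classification thresholds from a mixture fit
#'
#' Each threshold is the score between two adjacent component means at which
#' the weighted component densities are equal (the posterior crossover). If
#' no crossing exists in the open interval, the midpoint of the two means is
#' used and flagged in \code{threshold_fallback}.
#'
#' @param fit A \code{"gmm_fit"} object.
#' @return The fit with \code{threshold_low} and \code{threshold_high} set.
#' @export
derive_thresholds <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  w <- fit$weights; m <- fit$means; v <- fit$variances
  tl <- density_crossover(w[1], m[1], v[1], w[2], m[2], v[2])
  th <- density_crossover(w[2], m[2], v[2], w[3], m[3], v[3])
  fit$threshold_fallback <- c(low = is.na(tl), high = is.na(th))
  fit$threshold_low <- if (is.na(tl)) (m[1] + m[2]) / 2 else tl
  fit$threshold_high <- if (is.na(th)) (m[2] + m[3]) / 2 else th
  fit
}

score_to_class <- function(score, threshold_low, threshold_high) {
  cls <- rep("unscored", length(score))
  fin <- is.finite(score)
  cls[fin & score < threshold_low] <- "impactful"
  cls[fin & score >= threshold_low & score < threshold_high] <- "mild"
  cls[fin & score >= threshold_high] <- "neutral"
  cls
}

#' Classify all variants of a landscape
#'
#' Scores below \code{threshold_low} are impactful, scores in
#' \code{[threshold_low, threshold_high)} mild, scores at or above
#' \code{threshold_high} neutral; a score equal to a threshold belongs to the
#' milder class (conservative tie-break). Missing scores give class
#' \code{"unscored"}.
#'
#' @param landscape A \code{"mutational_landscape"} object.
#' @param fit A \code{"gmm_fit"} with thresholds set.
#' @return Data frame \code{position, wt, mut, raw_score, class}, 19 rows per
#'   position (wild-type cells excluded), ordered by position then mutant
#'   letter.
#' @export
classify_variants <- function(landscape, fit) {
  stopifnot(inherits(landscape, "mutational_landscape"),
            inherits(fit, "gmm_fit"), is.finite(fit$threshold_low))
  wt <- strsplit(landscape$wild_type, "")[[1L]]
  df <- data.frame(position = rep(seq_len(landscape$L), each = 20L),
                   wt = rep(wt, each = 20L),
                   mut = rep(AA_ALPHABET, landscape$L),
                   raw_score = as.vector(landscape$scores))
  df <- df[df$mut != df$wt, ]
  df$class <- score_to_class(df$raw_score, fit$threshold_low, fit$threshold_high)
  rownames(df) <- NULL
  df
}

#' Classify residues as sensitive or tolerant
#'
#' A residue is tolerant when more than half of its 19 possible substitutions
#' are neutral, i.e. at least 10; otherwise sensitive. Unscored substitutions
#' count as non-neutral (absence of evidence does not manufacture tolerance).
#'
#' @param variants Data frame from [classify_variants()].
#' @return Data frame \code{position, n_neutral, residue_class}.
#' @export
classify_residues <- function(variants) {
  n_neutral <- tapply(variants$class == "neutral", variants$position, sum)
  pos <- as.integer(names(n_neutral))
  data.frame(position = pos, n_neutral = as.integer(n_neutral),
             residue_class = ifelse(n_neutral >= 10L, "tolerant", "sensitive"))[order(pos), ]
}

#' Flag positions with insufficient evolutionary information
#'
#' A position is non-confident when its 19 scores show low dispersion AND the
#' column is poorly conserved AND (the column is highly gapped OR few of the
#' 19 substitutions are sampled in the MSA). The clause cut-offs are
#' configuration, not constants.
#'
#' @param stats Data frame from [column_stats()].
#' @param dispersion Numeric vector of per-position standard deviations of
#'   the 19 scores (positions align with \code{stats$position}). \code{NA}
#'   dispersion (fully unscored position) is treated as 0.
#' @param d_min Dispersion cut-off, default 0.2.
#' @param c_min Conservation cut-off, default 0.3.
#' @param g_max Gap-fraction cut-off, default 0.5.
#' @param s_min Minimum substitutions sampled, default 5.
#' @return Data frame \code{position, score_dispersion, confident, reasons}
#'   (\code{reasons} is a comma-joined subset of \code{low_dispersion},
#'   \code{poorly_conserved}, \code{highly_gapped}, \code{few_substitutions},
#'   empty when confident).
#' @export
residue_confidence <- function(stats, dispersion, d_min = 0.2, c_min = 0.3,
                               g_max = 0.5, s_min = 5) {
  stopifnot(nrow(stats) == length(dispersion))
  disp <- ifelse(is.na(dispersion), 0, dispersion)
  low_disp <- disp < d_min
  poor_cons <- stats$conservation < c_min
  gapped <- stats$gap_fraction > g_max
  few_sub <- stats$n_substitutions_sampled < s_min
  non_conf <- low_disp & poor_cons & (gapped | few_sub)
  reasons <- character(nrow(stats))
  for (i in which(non_conf)) {
    r <- c("low_dispersion", "poorly_conserved",
           if (gapped[i]) "highly_gapped", if (few_sub[i]) "few_substitutions")
    reasons[i] <- paste(r, collapse = ",")
  }
  data.frame(position = stats$position, score_dispersion = disp,
             confident = !non_conf, reasons = reasons)
}

#' Export a mixture fit as JSON
#'
#' @param fit A \code{"gmm_fit"} object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmm_json <- function(fit, path) {
  jsonlite::write_json(list(
    weights = fit$weights, means = fit$means, variances = fit$variances,
    threshold_low = fit$threshold_low, threshold_high = fit$threshold_high,
    threshold_rule = "weighted-density crossover, midpoint fallback",
    threshold_fallback = as.list(fit$threshold_fallback),
    seed = fit$seed, log_likelihood = fit$log_likelihood, n = fit$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
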