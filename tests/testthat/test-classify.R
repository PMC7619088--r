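test_that("the mixture fit recovers well-separated generating components", {
  x <- withr::with_seed(101, c(rnorm(1000, -8, 0.5), rnorm(1000, -4, 0.5),
                               rnorm(1000, 0, 0.5)))
  fit <- fit_gmm3(x, seed = 0)
  expect_equal(fit$means, c(-8, -4, 0), tolerance = 0.1 / 8)
  expect_equal(fit$weights, rep(1 / 3, 3), tolerance = 0.1)
  expect_lt(fit$threshold_low, fit$threshold_high)
  expect_true(fit$means[1] <= fit$threshold_low &&
                fit$threshold_low <= fit$means[2])
  expect_true(fit$means[2] <= fit$threshold_high &&
                fit$threshold_high <= fit$means[3])

  # independent cross-check of the EM against mclust on the same data
  withr::local_package("mclust")
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(as.numeric(mc$parameters$mean)), fit$means,
               tolerance = 0.02)
})

test_that("the fit is deterministic and seed changes do not move a clear optimum", {
  x <- withr::with_seed(102, c(rnorm(500, -6, 0.4), rnorm(500, -3, 0.4),
                               rnorm(500, 0.5, 0.4)))
  f1 <- fit_gmm3(x, seed = 0)
  f2 <- fit_gmm3(x, seed = 0)
  f3 <- fit_gmm3(x, seed = 42)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$threshold_low, f2$threshold_low)
  expect_equal(f1$means, f3$means, tolerance = 1e-6)
  expect_equal(f1$weights, f3$weights, tolerance = 1e-6)
  expect_equal(f1$variances, f3$variances, tolerance = 1e-6)
})

test_that("unimodal data fits without collapse and tiny samples error", {
  x <- withr::with_seed(103, rnorm(400, -2, 1))
  fit <- fit_gmm3(x, seed = 0)
  expect_true(all(diff(fit$means) < 2 * sd(x)))
  expect_lt(fit$threshold_low, fit$threshold_high)
  expect_error(fit_gmm3(rnorm(10), seed = 0),
               class = "mutland_insufficient_data")
})

test_that("thresholds are weighted-density crossovers with midpoint fallback", {
  # equal weights/variances: crossover is the midpoint
  fit <- structure(list(weights = c(0.5, 0.3, 0.2), means = c(-6, -2, 3),
                        variances = c(1, 1, 4),
                        threshold_fallback = c(low = FALSE, high = FALSE)),
                   class = "gmm_fit")
  fit$weights <- c(1, 1, 1) / 3; fit$variances <- c(1, 1, 1)
  fit <- derive_thresholds(fit)
  expect_equal(fit$threshold_low, -4)
  expect_equal(fit$threshold_high, 0.5)

  # unequal weights shift the crossover toward the lighter component;
  # validated against a dense grid search of the density-equality point
  for (pars in list(c(0.9, 0.1), c(0.25, 0.75), c(0.5, 0.5))) {
    w1 <- pars[1]; w2 <- pars[2]
    got <- mutland:::density_crossover(w1, -5, 1, w2, 0, 1)
    grid <- oracle_crossover_grid(w1, -5, 1, w2, 0, 1)
    expect_equal(got, grid, tolerance = 1e-3)
    if (w1 > w2) expect_gt(got, -2.5)
    if (w1 < w2) expect_lt(got, -2.5)
  }
  # unequal variances, verified against the grid too
  got <- mutland:::density_crossover(0.4, -5, 0.5, 0.6, 0, 2)
  expect_equal(got, oracle_crossover_grid(0.4, -5, 0.5, 0.6, 0, 2),
               tolerance = 1e-3)

  # pathological overlap: no crossing in the open interval -> midpoint
  fit2 <- structure(list(weights = c(1e-6, 1 - 2e-6, 1e-6),
                         means = c(-1, -0.999, -0.998),
                         variances = c(10, 10, 10),
                         threshold_fallback = c(low = FALSE, high = FALSE)),
                    class = "gmm_fit")
  fit2 <- derive_thresholds(fit2)
  expect_true(any(fit2$threshold_fallback))
  expect_equal(fit2$threshold_low, mean(c(-1, -0.999)))
})

test_that("variant classes partition the score axis with the stated tie-break", {
  fit <- fit_gmm3(withr::with_seed(1, c(rnorm(100, -8, .5), rnorm(100, -4, .5),
                                        rnorm(100, 0, .5))), seed = 0)
  tl <- fit$threshold_low; th <- fit$threshold_high
  cls <- mutland:::score_to_class(c(tl - 1e-9, tl, th - 1e-9, th, -100, 100,
                                    NA), tl, th)
  expect_identical(cls, c("impactful", "mild", "mild", "neutral", "impactful",
                          "neutral", "unscored"))

  # full-landscape classification equals per-cell recomputation
  sim <- generate_synthetic_landscape(30, seed = 8)
  v <- classify_variants(sim$landscape, fit)
  expect_equal(nrow(v), 19 * 30)
  brute <- vapply(seq_len(nrow(v)), function(k) {
    s <- v$raw_score[k]
    if (!is.finite(s)) "unscored"
    else if (s < tl) "impactful" else if (s < th) "mild" else "neutral"
  }, character(1))
  expect_identical(v$class, brute)
  # classes are monotone in score
  ord <- order(v$raw_score)
  lev <- match(v$class[ord], c("impactful", "mild", "neutral"))
  expect_true(all(diff(lev[!is.na(lev)]) >= 0))
  expect_equal(sum(v$class != "unscored"), sum(is.finite(v$raw_score)))
})

test_that("residues are tolerant iff at least 10 of 19 substitutions are neutral", {
  for (k in 0:19) {
    v <- data.frame(position = 1L, wt = "A", mut = AA_ALPHABET[-1],
                    raw_score = 0,
                    class = c(rep("neutral", k), rep("impactful", 19 - k)))
    r <- classify_residues(v)
    expect_identical(r$residue_class,
                     if (k >= 10) "tolerant" else "sensitive")
    expect_equal(r$n_neutral, k)
  }
  # unscored counts as non-neutral
  v <- data.frame(position = 1L, wt = "A", mut = AA_ALPHABET[-1],
                  raw_score = NA,
                  class = c(rep("neutral", 9), rep("unscored", 10)))
  expect_identical(classify_residues(v)$residue_class, "sensitive")
})

test_that("the confidence rule is the stated conjunction/disjunction", {
  base <- data.frame(position = 1L, gap_fraction = 0,
                     n_substitutions_sampled = 12L, conservation = 1)
  case <- function(disp, cons, gap, nsub) {
    st <- base
    st$conservation <- cons; st$gap_fraction <- gap
    st$n_substitutions_sampled <- nsub
    residue_confidence(st, disp)
  }
  # all clauses fire
  r <- case(0.05, 0.1, 0.9, 12L)
  expect_false(r$confident)
  expect_identical(r$reasons, "low_dispersion,poorly_conserved,highly_gapped")
  # neither OR clause fires -> confident despite low dispersion/conservation
  expect_true(case(0.05, 0.1, 0.0, 12L)$confident)
  # high dispersion -> always confident
  expect_true(case(5, 0.1, 0.9, 0L)$confident)
  # few substitutions alone can complete the conjunction
  r2 <- case(0.05, 0.1, 0.0, 2L)
  expect_false(r2$confident)
  expect_identical(r2$reasons,
                   "low_dispersion,poorly_conserved,few_substitutions")
  # reasons empty exactly when confident
  expect_identical(case(5, 0.1, 0.9, 0L)$reasons, "")
})

test_that("tightening confidence cut-offs never gains confidence", {
  sim <- generate_synthetic_msa(60, 80, gap_prob = 0.3,
                                background_conservation = 0.15, seed = 9)
  ls <- baseline_scores(sim$msa)
  st <- column_stats(sim$msa)
  disp <- mutland:::landscape_dispersion(ls)
  f0 <- mean(residue_confidence(st, disp)$confident)
  f_gmax <- mean(residue_confidence(st, disp, g_max = 0.2)$confident)
  f_cmin <- mean(residue_confidence(st, disp, c_min = 0.6)$confident)
  expect_lte(f_gmax, f0)
  expect_lte(f_cmin, f0)
})
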