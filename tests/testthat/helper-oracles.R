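# Independent reference implementations used to validate the fast paths.

# Exhaustive O(n^2) optimal-partitioning dynamic program for the weighted
# Gaussian changepoint model. Same objective and tie-break (most recent
# changepoint wins among equal-cost optima) as fpop_segment(), but computed
# from cumulative sums rather than functional pruning.
oracle_partition <- function(y, w, penalty) {
  n <- length(y)
  w <- rep_len(w, n)
  cw <- cumsum(w); cwy <- cumsum(w * y); cwy2 <- cumsum(w * y^2)
  seg_cost <- function(a, t) {
    W <- cw[t] - if (a > 1) cw[a - 1] else 0
    S <- cwy[t] - if (a > 1) cwy[a - 1] else 0
    Q <- cwy2[t] - if (a > 1) cwy2[a - 1] else 0
    Q - S^2 / W
  }
  Fv <- c(-penalty, rep(NA_real_, n))
  last <- integer(n)
  for (t in 1:n) {
    taus <- 0:(t - 1)
    costs <- vapply(taus, function(tau) seg_cost(tau + 1, t), numeric(1))
    vals <- Fv[taus + 1] + costs + penalty
    best <- max(which(vals == min(vals)))
    Fv[t + 1] <- vals[best]
    last[t] <- taus[best]
  }
  ends <- integer(0)
  t <- n
  while (t > 0) { ends <- c(t, ends); t <- last[t] }
  list(changepoints = ends, total_cost = Fv[n + 1])
}

# Reference global affine-gap alignment score: three-state DP written
# directly from the cost definition (internal gap: open on the first
# position then extend; terminal gaps: term per position). Scores only.
oracle_align_score <- function(x, y, match = 1, mismatch = -3,
                               open = -2.5, extend = -2, term = -2) {
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  n <- length(xs); m <- length(ys)
  NI <- -Inf
  M <- matrix(NI, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 0:n) for (j in 0:m) {
    if (i > 0) {
      o <- if (j == 0 || j == m) term else open
      e <- if (j == 0 || j == m) term else extend
      X[i + 1, j + 1] <- max(M[i, j + 1] + o, X[i, j + 1] + e,
                             Y[i, j + 1] + o)
    }
    if (j > 0) {
      o <- if (i == 0 || i == n) term else open
      e <- if (i == 0 || i == n) term else extend
      Y[i + 1, j + 1] <- max(M[i + 1, j] + o, X[i + 1, j] + o,
                             Y[i + 1, j] + e)
    }
    if (i > 0 && j > 0) {
      s <- if (xs[i] == ys[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# dense grid search for the point in (m1, m2) where two weighted Gaussian
# densities are equal
oracle_crossover_grid <- function(w1, m1, v1, w2, m2, v2, k = 200001) {
  xs <- seq(m1, m2, length.out = k)[-c(1, k)]
  d <- w1 * dnorm(xs, m1, sqrt(v1)) - w2 * dnorm(xs, m2, sqrt(v2))
  sg <- which(diff(sign(d)) != 0)
  if (!length(sg)) return(NA_real_)
  xs[sg[1]]
}

tmp_write <- function(lines, ext = ".fasta") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
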