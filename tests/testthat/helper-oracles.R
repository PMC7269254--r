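# Independent brute-force oracles used to check the analytic implementations.

# Otsu: exhaustive search of the between-class variance over all histogram
# cut points, computed directly from the pixel values.
oracle_otsu <- function(values, bins = 256L) {
  b <- pmin(floor(pmin(pmax(values, 0), 1) * bins), bins - 1L) + 1L
  h <- tabulate(b, nbins = bins)
  n <- sum(h)
  mids <- (seq_len(bins) - 0.5) / bins
  best <- -Inf
  best_t <- NA_real_
  for (t in seq_len(bins - 1L)) {
    w0 <- sum(h[1:t]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * mids[1:t]) / w0
    mu1 <- sum(h[(t + 1):bins] * mids[(t + 1):bins]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t / bins }
  }
  best_t
}

# Binary erosion/dilation/opening by direct double loop with zero padding.
oracle_erode <- function(m, se) {
  ctr <- (dim(se) + 1) %/% 2
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    keep <- TRUE
    for (a in seq_len(nrow(se))) for (b in seq_len(ncol(se))) {
      if (se[a, b] > 0) {
        ii <- i + a - ctr[1]; jj <- j + b - ctr[2]
        v <- if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m))
          m[ii, jj] else 0
        if (v == 0) { keep <- FALSE; break }
      }
    }
    out[i, j] <- as.integer(keep)
  }
  out
}

oracle_dilate <- function(m, se) {
  ctr <- (dim(se) + 1) %/% 2
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    hit <- FALSE
    for (a in seq_len(nrow(se))) for (b in seq_len(ncol(se))) {
      if (se[a, b] > 0) {
        ii <- i - (a - ctr[1]); jj <- j - (b - ctr[2])
        if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
            m[ii, jj] > 0) { hit <- TRUE; break }
      }
    }
    out[i, j] <- as.integer(hit)
  }
  out
}

oracle_tophat <- function(m, se) {
  opened <- oracle_dilate(oracle_erode(m, se), se)
  out <- (m > 0) & !(opened > 0)
  storage.mode(out) <- "integer"
  out
}

# Youden: enumerate a threshold strictly between every pair of consecutive
# sorted scores (plus the two extremes) and take the best J.
oracle_best_j <- function(scores, labels) {
  lab <- labels == 1 | labels == TRUE
  ss <- sort(unique(scores))
  cands <- c(min(ss) - 1, ss[-length(ss)] + diff(ss) / 2, max(ss) + 1)
  best <- -Inf
  for (ct in cands) {
    sens <- mean(scores[lab] > ct)
    spec <- mean(scores[!lab] <= ct)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Pearson chi-squared by the textbook double loop.
oracle_chisq <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  stat
}

# Small phantom used by unit tests (fast; the acceptance suite uses the
# default grid).
small_phantom_spec <- function(seed = 1L, n_left = 8, n_right = 8, ...) {
  phantom_spec(dim = c(48, 56, 40), n_veins_left = n_left,
               n_veins_right = n_right, seed = seed, ...)
}
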