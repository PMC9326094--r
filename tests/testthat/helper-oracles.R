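# Independent brute-force oracles used across test files. These stay
# deliberately naive (explicit loops, closed forms) so they share no code
# path with the implementation they check.

# pixel-enumeration intersection area
bf_coloc_area <- function(a, b) {
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] && b[i, j]) n <- n + 1L
    }
  }
  n
}

# all-pairs Mann-Whitney AUC, ties counted 1/2
bf_auc <- function(values, labels, positive) {
  vp <- values[labels == positive]
  vn <- values[labels != positive]
  wins <- 0
  for (p in vp) {
    for (q in vn) {
      wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  wins / (length(vp) * length(vn))
}

# exhaustive threshold sweep maximizing between-class variance of x > t
bf_otsu <- function(x) {
  v <- as.numeric(x)
  cand <- sort(unique(v))
  cand <- cand[-length(cand)]
  best <- cand[1]; best_bcv <- -Inf
  for (t in cand) {
    fg <- v > t
    w1 <- mean(fg); w0 <- 1 - w1
    bcv <- w0 * w1 * (mean(v[fg]) - mean(v[!fg]))^2
    if (bcv > best_bcv) { best_bcv <- bcv; best <- t }
  }
  best
}

# closed-form simple OLS
bf_ols <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# textbook Spearman rank formula (distinct values only)
bf_spearman_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# small painted-geometry helpers for constructed fields
disk_mask <- function(size, cx, cy, r) {
  m <- matrix(FALSE, size, size)
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- TRUE
    }
  }
  m
}

rect_mask <- function(size, r1, r2, c1, c2) {
  m <- matrix(FALSE, size, size)
  m[r1:r2, c1:c2] <- TRUE
  m
}
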