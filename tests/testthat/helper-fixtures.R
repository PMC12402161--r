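# shared fixtures, built in code

# small device rendered at 1 µm/px for fast transit tests
tinyGeometry <- function() deviceGeometry(pixelSize = 1)

# draw an axis-aligned ellipse mask (semi-axes in px) on a blank field
ellipseImage <- function(ny, nx, cy, cx, ay, ax, fg = 200, bg = 10) {
  img <- matrix(bg, ny, nx)
  rr <- row(img) - 1; cc <- col(img) - 1
  img[((rr - cy) / ay)^2 + ((cc - cx) / ax)^2 <= 1] <- fg
  img
}

# exhaustive-search oracle for the minimum cross-entropy objective,
# computed directly from the pixel values (not the histogram)
mceOracle <- function(v) {
  lv <- sort(unique(v))
  cand <- lv[-length(lv)]
  eta <- vapply(cand, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    e <- 0
    if (sum(lo) > 0) e <- e - sum(lo) * log(mean(lo))
    if (sum(hi) > 0) e <- e - sum(hi) * log(mean(hi))
    e
  }, numeric(1))
  cand[which.min(eta)]
}

# full-enumeration oracle for the exact two-sided Mann-Whitney p-value
mwEnumOracle <- function(a, b) {
  nA <- length(a); nB <- length(b); N <- nA + nB
  pooled <- c(a, b)
  M <- nA * nB
  combos <- combn(N, nA)
  r <- rank(pooled)
  Uall <- apply(combos, 2, function(ix) sum(r[ix]) - nA * (nA + 1) / 2)
  uObs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  uLow <- min(uObs, M - uObs); uHigh <- M - uLow
  mean(Uall <= uLow | Uall >= uHigh)
}

# brute-force Benjamini-Hochberg step-up oracle
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m))
    adj[i] <- min(1, min((m / seq(i, m)) * sorted[seq(i, m)]))
  out <- numeric(m)
  out[o] <- adj
  out
}
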