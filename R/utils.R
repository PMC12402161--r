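# internal helpers shared across modules

# run expr under a fixed RNG state without disturbing the caller's stream
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# fill an axis-aligned ellipse into matrix `img` (rows = y, cols = x).
# cy, cx: centre in 0-based pixel coordinates; ay, ax: semi-axes in pixels.
fillEllipse <- function(img, cy, cx, ay, ax, value) {
  r0 <- max(0L, floor(cy - ay)); r1 <- min(nrow(img) - 1L, ceiling(cy + ay))
  c0 <- max(0L, floor(cx - ax)); c1 <- min(ncol(img) - 1L, ceiling(cx + ax))
  if (r1 < r0 || c1 < c0) return(img)
  rr <- r0:r1; cc <- c0:c1
  dy2 <- ((rr - cy) / ay)^2
  dx2 <- ((cc - cx) / ax)^2
  inside <- outer(dy2, dx2, "+") <= 1
  sub <- img[rr + 1L, cc + 1L, drop = FALSE]
  sub[inside] <- value
  img[rr + 1L, cc + 1L] <- sub
  img
}

# camera noise: Gaussian read noise plus Poisson-like photon scaling,
# sd(pixel) = sqrt(readSd^2 + photonScale * signal); clamped at zero
addCameraNoise <- function(img, readSd = 0, photonScale = 0) {
  if (readSd <= 0 && photonScale <= 0) return(img)
  sdpx <- sqrt(readSd^2 + photonScale * pmax(img, 0))
  out <- img + rnorm(length(img), sd = sdpx)
  out[out < 0] <- 0
  dim(out) <- dim(img)
  out
}

# mid-quantile / linear-interpolation quantiles are the package-wide
# convention (stats::quantile type 7); this alias keeps that choice explicit
quantileLin <- function(x, probs) quantile(x, probs, type = 7, names = FALSE)

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
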