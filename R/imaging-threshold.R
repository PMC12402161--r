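# Minimum cross-entropy (MCE) global threshold selection.
#
# For a candidate split of the histogram into background (levels <= t) and
# foreground (levels > t) with mean levels mu0 and mu1, the cross entropy
# between the image and its two-level reconstruction reduces (up to a
# constant) to
#     eta(t) = -( S0(t) * log(mu0(t)) + S1(t) * log(mu1(t)) )
# where S0/S1 are the summed intensities on each side. The selected
# threshold minimizes eta over all candidate splits; the search is
# exhaustive over the histogram, so the result is deterministic.

# internal: extract one (y, x) frame from a matrix or ImageStack
getFrame <- function(img, channel = 1L, frame = 1L) {
  if (is(img, "ImageStack")) {
    if (is.character(channel)) channel <- match(channel, channelNames(img))
    imgData(img)[, , channel, frame]
  } else if (is.matrix(img)) {
    img
  } else stop("expected a matrix or an ImageStack")
}

#' Minimum cross-entropy threshold of an image
#'
#' Intensities must be non-negative. Integer-valued images with at most 256
#' levels are binned exactly at their integer levels; other images use 256
#' equal-width bins over the intensity range (the bin centre represents its
#' bin). Foreground is `pixels > threshold`.
#'
#' @param img a matrix or [ImageStack-class] (first channel/frame by
#'   default).
#' @param channel,frame channel and frame selectors when `img` is a stack.
#' @param nBins number of histogram bins for non-integer images.
#' @return The threshold value (numeric scalar).
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
#' mceThreshold(img)  # strictly between 10 and 200
#' @export
mceThreshold <- function(img, channel = 1L, frame = 1L, nBins = 256L) {
  v <- as.numeric(getFrame(img, channel, frame))
  stopIfNot(all(is.finite(v)), "image contains non-finite values")
  stopIfNot(all(v >= 0), "MCE thresholding requires non-negative intensities")
  rng <- range(v)
  if (rng[1] == rng[2]) stop("constant image: no threshold exists")
  isInt <- all(v == round(v)) && diff(rng) <= 255
  if (isInt) {
    levels <- rng[1]:rng[2]
    h <- tabulate(v - rng[1] + 1L, nbins = length(levels))
  } else {
    edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
    idx <- pmin(findInterval(v, edges, rightmost.closed = TRUE), nBins)
    h <- tabulate(idx, nbins = nBins)
    levels <- (edges[-1L] + edges[-(nBins + 1L)]) / 2
  }
  W0 <- cumsum(h)
  S0 <- cumsum(h * levels)
  W <- W0[length(W0)]; S <- S0[length(S0)]
  k <- seq_len(length(levels) - 1L)          # split after level k
  mu0 <- S0[k] / W0[k]
  mu1 <- (S - S0[k]) / (W - W0[k])
  term0 <- ifelse(S0[k] > 0, -S0[k] * log(mu0), 0)
  term1 <- ifelse(S - S0[k] > 0, -(S - S0[k]) * log(mu1), 0)
  eta <- term0 + term1
  # splits that leave one side empty carry no information; exclude them
  valid <- W0[k] > 0 & W0[k] < W
  eta[!valid] <- Inf
  best <- which.min(eta)
  if (isInt) levels[best] + 0.5 else (levels[best] + levels[best + 1L]) / 2
}
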