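# Illumination estimation and correction.
#
# Model: observed = truth * flatfield + darkfield. The estimator assumes an
# ensemble of frames of the same channel in which (i) any pixel is covered
# by foreground in fewer than half the frames, so the per-pixel temporal
# median reads out the darkfield, and (ii) foreground objects (cells) are
# individually of near-constant brightness, so the intensity shading seen
# *within* each object reads out the flatfield locally — the classic
# retrospective shading-correction idea. The flatfield is a smooth
# polynomial surface fit to all within-object shading jointly, with one
# free brightness factor per object (alternating least squares), which
# makes the estimate independent of object-to-object brightness variation
# and of where objects happen to land. The smooth-surface constraint also
# extrapolates the flatfield into field corners that objects rarely reach.

# weighted degree-2 polynomial surface fit; returns the fitted matrix
polySurface2 <- function(z, w = NULL) {
  ny <- nrow(z); nx <- ncol(z)
  yy <- (row(z) - 1) / (ny - 1) * 2 - 1
  xx <- (col(z) - 1) / (nx - 1) * 2 - 1
  X <- cbind(1, as.vector(yy), as.vector(xx),
             as.vector(yy)^2, as.vector(yy) * as.vector(xx),
             as.vector(xx)^2)
  zv <- as.vector(z)
  if (is.null(w)) {
    beta <- stats::lm.fit(X, zv)$coefficients
  } else {
    wv <- as.vector(w)
    keep <- wv > 0
    if (sum(keep) < 12L) return(NULL)
    beta <- stats::lm.wfit(X[keep, , drop = FALSE], zv[keep],
                           wv[keep])$coefficients
  }
  beta[is.na(beta)] <- 0
  matrix(X %*% beta, ny, nx)
}

normalizeFlatfield <- function(fit, ny, nx) {
  if (is.null(fit) || all(fit <= 0)) return(matrix(1, ny, nx))
  fit <- pmax(fit, 1e-6 * max(fit))
  fit / mean(fit)
}

# Fit a smooth flatfield surface from within-object shading across all
# frames. Objects are connected foreground components; each contributes a
# single near-constant brightness plateau (objects showing two intensity
# levels — e.g. a bright nucleus inside a dimmer body — are split at the
# midpoint of their log-intensity spread and only the dominant level is
# kept, kept whole so its noise is never truncated; truncating against a
# window would shrink the within-object shading slope). The surface and
# the log flatfield is then fit as a smooth polynomial surface from all
# within-object shading jointly, with a free intercept per object absorbed
# by within-object demeaning (a fixed-effects regression, which integrates
# the local shading gradients into a global field).
fitShadingSurface <- function(frames, thr, dark, ny, nx,
                              minBlobPx = 20L, levelTol = 0.2) {
  basisY <- ((seq_len(ny) - 1) / (ny - 1)) * 2 - 1
  basisX <- ((seq_len(nx) - 1) / (nx - 1)) * 2 - 1
  vs <- list(); ys <- list(); xs <- list(); bs <- list()
  blobOffset <- 0L
  for (t in seq_len(ncol(frames))) {
    fr <- frames[, t]
    fg <- matrix(fr > thr, ny, nx)
    if (!any(fg)) next
    lab <- as.matrix(EBImage::bwlabel(fg))
    idx <- which(lab > 0)
    if (!length(idx)) next
    blob <- lab[idx]
    keep <- blob %in% which(tabulate(blob) >= minBlobPx)
    if (!any(keep)) next
    idx <- idx[keep]; blob <- blob[keep]
    v <- pmax(fr[idx] - dark[idx], 1e-9)
    z <- log(v)
    q10 <- stats::ave(z, blob, FUN = function(u) quantileLin(u, 0.10))
    q90 <- stats::ave(z, blob, FUN = function(u) quantileLin(u, 0.90))
    twoLevel <- (q90 - q10) > 2 * levelTol
    side <- z > (q10 + q90) / 2
    upFrac <- stats::ave(side, blob, FUN = mean)
    lev <- !twoLevel | (side == (upFrac > 0.5))
    if (!any(lev)) next
    vs[[length(vs) + 1L]] <- v[lev]
    ys[[length(ys) + 1L]] <- basisY[((idx[lev] - 1) %% ny) + 1]
    xs[[length(xs) + 1L]] <- basisX[((idx[lev] - 1) %/% ny) + 1]
    bs[[length(bs) + 1L]] <- blob[lev] + blobOffset
    blobOffset <- blobOffset + max(blob)
  }
  if (!length(vs)) return(NULL)
  v <- unlist(vs); yy <- unlist(ys); xx <- unlist(xs)
  blob <- match(unlist(bs), sort(unique(unlist(bs))))
  if (length(v) < 50L) return(NULL)
  z <- log(v)
  X <- shadingBasis(yy, xx)
  # within-object demeaning absorbs per-object log-brightness intercepts
  for (j in seq_len(ncol(X))) X[, j] <- X[, j] - stats::ave(X[, j], blob)
  z <- z - stats::ave(z, blob)
  beta <- stats::lm.fit(X, z)$coefficients
  beta[is.na(beta)] <- 0
  yyF <- matrix(basisY, ny, nx)
  xxF <- matrix(basisX, ny, nx, byrow = TRUE)
  logF <- matrix(shadingBasis(as.vector(yyF), as.vector(xxF)) %*% beta,
                 ny, nx)
  surf <- exp(logF - max(logF))
  normalizeFlatfield(surf, ny, nx)
}

# full degree-4 polynomial basis (no intercept; intercepts are per-object)
# in normalized coordinates; degree 4 keeps enough curvature to
# extrapolate realistic vignettes into the corners without inflating the
# extrapolation variance
shadingBasis <- function(yy, xx) {
  cbind(yy, xx, yy^2, yy * xx, xx^2,
        yy^3, yy^2 * xx, yy * xx^2, xx^3,
        yy^4, yy^3 * xx, yy^2 * xx^2, yy * xx^3, xx^4)
}

#' Estimate per-channel flatfield and darkfield from a frame ensemble
#'
#' @param stack an [ImageStack-class] whose time axis holds the frame
#'   ensemble (e.g. one frame per well); at least 8 frames per channel are
#'   recommended (a warning is issued below that).
#' @param channels channels to estimate (default all).
#' @return An [IlluminationModel-class]; `metadata$warnings` records any
#'   degraded-mode estimates (single frame, empty channel).
#' @seealso [correctIllumination()], [plateChannelStack()]
#' @export
estimateIllumination <- function(stack, channels = NULL) {
  stopIfNot(is(stack, "ImageStack"), "stack must be an ImageStack")
  if (is.null(channels)) channels <- channelNames(stack)
  d <- imgData(stack)
  nT <- dim(d)[4L]
  if (nT < 8L)
    warning("fewer than 8 frames per channel; illumination estimates may be unstable")
  ff <- list(); dk <- list(); warns <- character()
  for (ch in channels) {
    ci <- match(ch, channelNames(stack))
    frames <- matrix(d[, , ci, ], nrow = prod(dim(d)[1:2]), ncol = nT)
    ny <- dim(d)[1L]; nx <- dim(d)[2L]
    if (all(frames == 0)) {
      warns <- c(warns, sprintf("channel %s is all zero; identity model", ch))
      ff[[ch]] <- matrix(1, ny, nx)
      dk[[ch]] <- matrix(0, ny, nx)
      next
    }
    if (nT == 1L) {
      warns <- c(warns, sprintf(
        "channel %s has a single frame; flatfield from its smoothed version", ch))
      darkFit <- matrix(0, ny, nx)
      fit <- polySurface2(matrix(frames[, 1L], ny, nx),
                          pmax(matrix(frames[, 1L], ny, nx), 0))
      ff[[ch]] <- normalizeFlatfield(fit, ny, nx)
      dk[[ch]] <- darkFit
      next
    }
    darkRaw <- apply(frames, 1L, median)
    darkFit <- pmax(polySurface2(matrix(darkRaw, ny, nx)), 0)
    # noise scale from temporal deviations around the per-pixel median
    sigma <- 1.4826 * median(abs(frames - darkRaw))
    thr <- as.vector(darkFit) + 5 * max(sigma, 1e-12)
    fit <- fitShadingSurface(frames, thr, as.vector(darkFit), ny, nx)
    if (is.null(fit)) {
      warns <- c(warns, sprintf(
        "channel %s has no usable foreground; identity flatfield", ch))
      ff[[ch]] <- matrix(1, ny, nx)
    } else {
      ff[[ch]] <- fit
    }
    dk[[ch]] <- darkFit
  }
  if (length(warns)) warning(paste(warns, collapse = "; "))
  illuminationModel(ff, dk, metadata = list(nFrames = nT, warnings = warns))
}

#' Apply an illumination model to a stack
#'
#' Corrected pixels are `(observed - darkfield) / flatfield`, clamped at
#' zero; the number of clamped pixels is recorded in the output metadata.
#'
#' @param stack an [ImageStack-class].
#' @param model an [IlluminationModel-class] covering the stack's channels.
#' @return The corrected [ImageStack-class].
#' @export
correctIllumination <- function(stack, model) {
  stopIfNot(is(stack, "ImageStack"), "stack must be an ImageStack")
  stopIfNot(is(model, "IlluminationModel"), "model must be an IlluminationModel")
  d <- imgData(stack)
  missing <- setdiff(channelNames(stack), names(flatfield(model)))
  if (length(missing))
    stop("model lacks channels: ", paste(missing, collapse = ", "))
  nClamped <- 0L
  for (ch in channelNames(stack)) {
    f <- flatfield(model)[[ch]]
    dkf <- darkfield(model)[[ch]]
    if (!identical(dim(f), dim(d)[1:2]))
      stop("illumination model shape does not match the stack")
    ci <- match(ch, channelNames(stack))
    for (t in seq_len(dim(d)[4L])) {
      corr <- (d[, , ci, t] - dkf) / f
      nClamped <- nClamped + sum(corr < 0)
      d[, , ci, t] <- pmax(corr, 0)
    }
  }
  md <- stack@metadata
  md$illuminationCorrected <- TRUE
  md$clampedPixels <- nClamped
  imageStack(d, pixelSize = pixelSize(stack),
             channelNames = channelNames(stack),
             origin = stackOrigin(stack), metadata = md)
}
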