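# Time-series quantification: calcium fold change and endothelial
# permeability from dye accumulation.

#' Calcium fold change relative to pre-entry baseline
#'
#' `fold change = max(in-region intensity) / mean(baseline intensity)`,
#' following the convention of extracting the maximum fluorescence and
#' normalizing to the baseline measured before the cell enters the
#' constriction. Scale-invariant: multiplying the whole trace by c > 0
#' leaves the result unchanged.
#'
#' @param trace data.frame with columns `time` and `intensity` (optionally
#'   `region`).
#' @param baselineWindow logical/integer index into `trace` rows selecting
#'   the baseline, or `NULL` to use rows with `region == "BASELINE"`.
#' @param responseWindow index selecting the in-region frames; default is
#'   every frame not in the baseline window. When `region` is present a
#'   region label (e.g. `"CC_5"`) may be given instead.
#' @return The fold change (numeric scalar).
#' @export
calciumFoldChange <- function(trace, baselineWindow = NULL,
                              responseWindow = NULL) {
  stopIfNot(all(c("time", "intensity") %in% names(trace)),
            "trace needs columns time and intensity")
  n <- nrow(trace)
  bidx <- if (is.null(baselineWindow)) {
    stopIfNot("region" %in% names(trace),
              "no baselineWindow given and no region column present")
    which(trace$region == "BASELINE")
  } else if (is.logical(baselineWindow)) which(baselineWindow)
  else as.integer(baselineWindow)
  stopIfNot(length(bidx) > 0, "baseline window is empty")
  ridx <- if (is.null(responseWindow)) setdiff(seq_len(n), bidx)
  else if (is.character(responseWindow)) which(trace$region == responseWindow)
  else if (is.logical(responseWindow)) which(responseWindow)
  else as.integer(responseWindow)
  stopIfNot(length(ridx) > 0, "response window is empty")
  stopIfNot(max(trace$time[bidx]) <= min(trace$time[ridx]),
            "baseline window must precede the response window")
  b <- mean(trace$intensity[bidx])
  if (b <= 0) stop("baseline mean intensity must be > 0")
  max(trace$intensity[ridx]) / b
}

#' Estimate an endothelial permeability coefficient
#'
#' Two-compartment initial-slope estimator: with tissue intensity I(t)
#' obeying `dI/dt = P * (S/V) * (I_vessel - I)`, the early accumulation is
#' linear and `P = (V/S) * slope / (I_vessel - I(0))`, with the slope from
#' an ordinary least-squares line over the initial fit window. The fit
#' window should stay in the linear regime (`P * (S/V) * t_window << 1`);
#' outside it the estimator is biased low.
#'
#' @param trace data.frame `time`, `intensity` for the tissue compartment.
#' @param iVessel vessel (donor) compartment intensity; must exceed the
#'   initial tissue intensity.
#' @param sOverV surface-to-volume ratio of the barrier in 1/cm.
#' @param fitFrames number of initial frames in the fit window (>= 3).
#' @param timeUnit unit of `trace$time` (`"min"` default, matching 2-min
#'   frame acquisition; converted to seconds so P is in cm/s).
#' @return A list of class `PermeabilityRecord`: `P` (cm/s, clamped at 0),
#'   `slope` (intensity/s), `iVessel`, `i0`, `fitFrames`, `r_squared`,
#'   `flag`.
#' @export
estimatePermeability <- function(trace, iVessel, sOverV, fitFrames = 10,
                                 timeUnit = c("min", "s")) {
  timeUnit <- match.arg(timeUnit)
  stopIfNot(all(c("time", "intensity") %in% names(trace)),
            "trace needs columns time and intensity")
  stopIfNot(fitFrames >= 3, "need at least 3 frames in the fit window")
  w <- head(seq_len(nrow(trace)), fitFrames)
  stopIfNot(length(w) >= 3, "trace shorter than 3 frames")
  tsec <- trace$time[w] * if (timeUnit == "min") 60 else 1
  i0 <- trace$intensity[w][1L]
  if (iVessel <= i0) stop("iVessel must exceed the initial tissue intensity")
  fit <- lm(trace$intensity[w] ~ tsec)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  flag <- NA_character_
  if (slope < 0) {
    flag <- "negative slope clamped to zero"
    slope0 <- 0
  } else slope0 <- slope
  P <- slope0 / (sOverV * (iVessel - i0))
  structure(list(P = P, slope = slope, iVessel = iVessel, i0 = i0,
                 fitFrames = length(w), r_squared = r2, flag = flag),
            class = "PermeabilityRecord")
}

#' @export
print.PermeabilityRecord <- function(x, ...) {
  cat(sprintf("Permeability: P = %.3g cm/s (slope %.3g /s over %d frames, R^2 %.3f)%s\n",
              x$P, x$slope, x$fitFrames, x$r_squared,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
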