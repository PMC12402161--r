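# Group-comparison primitives: Mann-Whitney U with an exact small-sample
# path, and Benjamini-Hochberg step-up adjustment.

#' Mann-Whitney U test
#'
#' U statistic for group A with midrank tie handling. The two-sided p-value
#' is exact (from the null permutation distribution of U) when
#' `length(a) + length(b) <= exactMax` and there are no ties, and otherwise
#' uses the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b numeric samples (both non-empty).
#' @param exactMax combined sample size at or below which the exact path is
#'   used (ties force the approximation).
#' @return A list with `U` (for group `a`), `p` (two-sided) and `method`.
#' @examples
#' mannWhitneyU(1:3, 4:6)$p  # 0.1
#' @export
mannWhitneyU <- function(a, b, exactMax = 12) {
  stopIfNot(length(a) > 0 && length(b) > 0, "both groups must be non-empty")
  nA <- length(a); nB <- length(b)
  r <- rank(c(a, b))                       # midranks
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  M <- nA * nB
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && nA + nB <= exactMax) {
    uLow <- min(U, M - U)
    uHigh <- M - uLow
    p <- pwilcox(uLow, nA, nB) +
      (1 - pwilcox(uHigh - 1, nA, nB))
    return(list(U = U, p = min(p, 1), method = "exact"))
  }
  # normal approximation, tie-corrected variance, continuity correction
  N <- nA + nB
  tieTab <- table(r)
  tieAdj <- sum(tieTab^3 - tieTab)
  sigma2 <- (M / 12) * ((N + 1) - tieAdj / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (abs(U - M / 2) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = U, p = min(2 * pnorm(-z), 1), method = "normal")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorted ascending, `adj_i = min over j >= i of (m / j) * p_(j)`, capped
#' at 1, returned in the original order. Guarantees `adj >= p` and
#' `adj <= 1`.
#'
#' @param p p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bhAdjust <- function(p) {
  stopIfNot(all(is.finite(p)) && all(p >= 0 & p <= 1),
            "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
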