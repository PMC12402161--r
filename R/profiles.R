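# Single-cell immunofluorescence statistics: N:C ratios, IQR outlier
# filtering, robust-Z standardization, PCA + 2D embedding, control-median
# normalization and fold-change summaries. The pipeline order is fixed:
# QC -> outlier filter -> robust-Z -> PCA -> embedding; normalization to
# the control median operates on unstandardized values (it serves plots
# and fold-change summaries, not the embedding).

#' Log10 nuclear-to-cytoplasmic ratio
#'
#' `log10(nuclear mean / cytoplasmic mean)`; a proxy for nuclear
#' localization of a marker. Non-positive cytoplasmic means yield `NA`
#' (the cell is excluded from that feature downstream).
#'
#' @param nuclear,cytoplasmic per-cell compartment mean intensities.
#' @return Numeric vector of log10 N:C ratios.
#' @examples
#' ncRatio(100, 10)  # 1
#' @export
ncRatio <- function(nuclear, cytoplasmic) {
  stopIfNot(all(nuclear > 0, na.rm = TRUE), "nuclear means must be > 0")
  out <- ifelse(is.na(cytoplasmic) | cytoplasmic <= 0, NA_real_,
                log10(nuclear / cytoplasmic))
  if (anyNA(out))
    attr(out, "qc") <- "non-positive cytoplasmic mean(s) set to NA"
  out
}

#' Interquartile-range outlier filtering
#'
#' A cell is removed when any of its feature values falls outside
#' `R = [Q1 - k*IQR, Q3 + k*IQR]` for that feature, with quartiles from
#' linear interpolation between order statistics and `k = 1.5` by default.
#' Ranges are computed within each condition-by-timepoint stratum.
#'
#' @param table single-cell feature data.frame.
#' @param features feature column names to screen; default: all numeric
#'   columns except `cell`/`well`.
#' @param k the IQR multiplier.
#' @param strata column names defining the strata (present columns only).
#' @return A list with `table` (retained rows), `report` (removals per
#'   feature and stratum with the applied range) and `removed` (row
#'   indices into the input).
#' @export
iqrOutlierFilter <- function(table, features = NULL, k = 1.5,
                             strata = c("condition", "timepoint")) {
  stopIfNot(nrow(table) >= 4, "need at least 4 cells")
  if (is.null(features)) {
    num <- vapply(table, is.numeric, logical(1))
    features <- setdiff(names(table)[num], c("cell", "well", "label"))
  }
  strata <- intersect(strata, names(table))
  sid <- if (length(strata)) interaction(table[strata], drop = TRUE)
         else factor(rep(1, nrow(table)))
  drop <- rep(FALSE, nrow(table))
  rep_rows <- list()
  for (s in levels(sid)) {
    rows <- which(sid == s)
    for (f in features) {
      x <- table[[f]][rows]
      ok <- !is.na(x)
      if (sum(ok) < 4) next
      q <- quantileLin(x[ok], c(0.25, 0.75))
      iqr <- q[2] - q[1]
      lo <- q[1] - k * iqr; hi <- q[2] + k * iqr
      bad <- ok & (x < lo | x > hi)
      if (any(bad)) drop[rows[bad]] <- TRUE
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(feature = f, stratum = s, n_removed = sum(bad),
                   lower = lo, upper = hi, stringsAsFactors = FALSE)
    }
  }
  if (all(drop)) stop("all cells removed by the outlier filter (degenerate input)")
  list(table = table[!drop, , drop = FALSE],
       report = if (length(rep_rows)) do.call(rbind, rep_rows)
                else data.frame(feature = character(), stratum = character(),
                                n_removed = integer(), lower = numeric(),
                                upper = numeric()),
       removed = which(drop))
}

#' Robust Z standardization
#'
#' `(x - median) / (1.4826 * MAD)` with the MAD the median absolute
#' deviation from the median; the 1.4826 factor makes the scale consistent
#' with the SD under normality. Affine-invariant for a > 0:
#' `robustZ(a*x + b) = robustZ(x)`.
#'
#' @param x numeric vector with at least 2 distinct non-NA values.
#' @return Standardized vector; all-`NA` with a warning when the MAD is 0
#'   (callers drop such features from embedding input).
#' @export
robustZ <- function(x) {
  stopIfNot(sum(!is.na(x)) >= 2, "need at least 2 values")
  m <- median(x, na.rm = TRUE)
  s <- mad(x, center = m, na.rm = TRUE)   # constant = 1.4826
  if (s == 0) {
    warning("MAD is zero; feature cannot be standardized")
    return(rep(NA_real_, length(x)))
  }
  (x - m) / s
}

#' PCA reduction retaining a fixed fraction of variance
#'
#' Scores on the smallest number of leading principal components whose
#' cumulative explained variance reaches `varianceRetained` (97% by
#' default). Component signs are fixed so the largest-magnitude loading of
#' each component is positive. Rank-deficient input truncates at the rank.
#'
#' @param mat numeric matrix, rows = cells, columns = standardized
#'   features.
#' @param varianceRetained cumulative explained-variance target in (0, 1].
#' @return Score matrix with attributes `explained` (per-component
#'   fraction) and `nComponents`.
#' @export
pcaReduce <- function(mat, varianceRetained = 0.97) {
  mat <- as.matrix(mat)
  stopIfNot(nrow(mat) >= 2 && ncol(mat) >= 1, "need >= 2 rows and >= 1 column")
  stopIfNot(varianceRetained > 0 && varianceRetained <= 1,
            "varianceRetained must be in (0, 1]")
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  expl <- ev / sum(ev)
  keep <- which(cumsum(expl) >= varianceRetained - 1e-12)[1L]
  if (is.na(keep)) keep <- length(expl)
  rank <- sum(ev > 1e-12 * ev[1])
  keep <- min(keep, rank)
  flip <- vapply(seq_len(keep), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(keep), drop = FALSE], 2, flip, "*")
  attr(scores, "explained") <- expl[seq_len(keep)]
  attr(scores, "nComponents") <- keep
  scores
}

#' 2D manifold embedding of component scores
#'
#' Nonlinear neighbor-graph embedding (UMAP) to two dimensions, used as a
#' visualization aid only: no downstream statistic depends on embedded
#' coordinates. Identical seed and input give identical output
#' (single-threaded optimization).
#'
#' @param scores numeric matrix (>= 10 rows), e.g. from [pcaReduce()].
#' @param seed integer RNG seed.
#' @param nNeighbors neighborhood size; shrunk with a warning when the
#'   input has fewer rows.
#' @return A two-column coordinate matrix.
#' @export
embed2d <- function(scores, seed = 1L, nNeighbors = 15) {
  scores <- as.matrix(scores)
  stopIfNot(nrow(scores) >= 10, "need at least 10 rows to embed")
  if (nrow(scores) <= nNeighbors) {
    nNeighbors <- nrow(scores) - 1L
    warning("fewer rows than the neighborhood size; shrinking n_neighbors to ",
            nNeighbors)
  }
  withSeed(seed, {
    uwot::umap(scores, n_components = 2, n_neighbors = nNeighbors,
               n_threads = 1, n_sgd_threads = 0, ret_model = FALSE)
  })
}

#' Center values on the control-group median per stratum
#'
#' `normalized = raw - control median`, computed per marker and timepoint
#' stratum.
#'
#' @param table data.frame holding `value`, a `condition` column, and the
#'   stratum columns.
#' @param controlLabel condition label of the control group.
#' @param strata stratum column names (those present are used).
#' @return The table with a `value_centered` column added.
#' @export
normalizeToControl <- function(table, controlLabel = "control",
                               strata = c("marker", "timepoint")) {
  stopIfNot(all(c("value", "condition") %in% names(table)),
            "table needs columns value and condition")
  strata <- intersect(strata, names(table))
  sid <- if (length(strata)) interaction(table[strata], drop = TRUE)
         else factor(rep(1, nrow(table)))
  out <- table
  out$value_centered <- NA_real_
  for (s in levels(sid)) {
    rows <- which(sid == s)
    ctrl <- table$value[rows][table$condition[rows] == controlLabel]
    if (!length(ctrl))
      stop("missing control stratum: ", s)
    out$value_centered[rows] <- table$value[rows] - median(ctrl, na.rm = TRUE)
  }
  out
}

#' Marker fold change between treated and control groups
#'
#' `fold change = mean(per-cell mean intensity, treated) /
#' mean(per-cell mean intensity, control)` for the chosen compartment
#' (mean-of-means estimator).
#'
#' @param control,treated single-cell feature data.frames with
#'   `mean_<marker>_<compartment>` columns.
#' @param marker marker name.
#' @param compartment `"cell"`, `"nucleus"` or `"cytoplasm"`.
#' @return The fold change (numeric scalar).
#' @export
markerFoldChange <- function(control, treated, marker,
                             compartment = "cell") {
  col <- paste0("mean_", marker, "_", compartment)
  stopIfNot(col %in% names(control) && col %in% names(treated),
            paste("missing column", col))
  stopIfNot(nrow(control) > 0 && nrow(treated) > 0,
            "both groups must be non-empty")
  mc <- mean(control[[col]], na.rm = TRUE)
  if (!is.finite(mc) || mc <= 0) stop("control mean must be > 0")
  mean(treated[[col]], na.rm = TRUE) / mc
}

#' Compare features between groups across timepoints
#'
#' Runs a two-sided Mann-Whitney U test per (feature, timepoint) contrast
#' of squeeze/treated vs control and adjusts p-values across timepoints
#' within each feature by Benjamini-Hochberg (the default family), or
#' globally with `bhFamily = "global"`. Also reports the median fold
#' change vs control.
#'
#' @param table single-cell feature data.frame with `condition` and
#'   `timepoint` columns.
#' @param features feature column names to test.
#' @param controlLabel,treatedLabel condition labels to contrast.
#' @param bhFamily `"per-feature"` (adjust across timepoints within each
#'   feature) or `"global"`.
#' @return A data.frame: `feature`, `timepoint`, `n_control`, `n_treated`,
#'   `U`, `p`, `p_adj`, `median_fold_change`.
#' @export
compareGroups <- function(table, features,
                          controlLabel = "control",
                          treatedLabel = "squeeze",
                          bhFamily = c("per-feature", "global")) {
  bhFamily <- match.arg(bhFamily)
  stopIfNot(all(c("condition", "timepoint") %in% names(table)),
            "table needs condition and timepoint columns")
  tps <- unique(table$timepoint)
  rows <- list()
  for (f in features) for (tp in tps) {
    a <- table[[f]][table$condition == treatedLabel & table$timepoint == tp]
    b <- table[[f]][table$condition == controlLabel & table$timepoint == tp]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) next
    mw <- mannWhitneyU(a, b)
    medb <- median(b)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, timepoint = tp, n_control = length(b),
      n_treated = length(a), U = mw$U, p = mw$p,
      median_fold_change = if (medb != 0) median(a) / medb else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  if (bhFamily == "global") {
    out$p_adj <- bhAdjust(out$p)
  } else {
    out$p_adj <- NA_real_
    for (f in unique(out$feature)) {
      idx <- out$feature == f
      out$p_adj[idx] <- bhAdjust(out$p[idx])
    }
  }
  out[, c("feature", "timepoint", "n_control", "n_treated", "U", "p",
          "p_adj", "median_fold_change")]
}
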