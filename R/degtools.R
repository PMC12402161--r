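# Threshold-based DEG classification on precomputed per-gene statistics
# (log2 fold change and p-value); the differential-expression model fit
# itself is upstream and out of scope here.

#' Classify genes as up/down-regulated or not significant
#'
#' `up` when `p < pCut` and `logFC > lfcCut`; `down` when `p < pCut` and
#' `logFC < -lfcCut`; `ns` otherwise. Genes with missing statistics are
#' labelled `ns` and flagged in the `qc` column. The p comparison direction
#' is configurable (`"less"` by default).
#'
#' @param table data.frame with columns `gene`, `logFC`, `pvalue` (unique
#'   gene ids; p-values in `[0, 1]`).
#' @param pCut p-value cutoff (0.01 by default).
#' @param lfcCut absolute log2 fold-change cutoff (0.6 by default,
#'   i.e. 1.5-fold).
#' @param adjusted use an `padj` column instead of `pvalue`.
#' @param pDirection `"less"` (p < pCut) or `"greater_equal"` (p >= pCut).
#' @return The table with `label` (factor up/down/ns) and `qc` columns
#'   added.
#' @export
classifyDEG <- function(table, pCut = 0.01, lfcCut = 0.6,
                        adjusted = FALSE,
                        pDirection = c("less", "greater_equal")) {
  pDirection <- match.arg(pDirection)
  stopIfNot(all(c("gene", "logFC", "pvalue") %in% names(table)),
            "table needs columns gene, logFC, pvalue")
  stopIfNot(!anyDuplicated(table$gene), "gene ids must be unique")
  p <- if (adjusted) table$padj else table$pvalue
  ok <- !is.na(p) & !is.na(table$logFC)
  stopIfNot(all(p[ok] >= 0 & p[ok] <= 1), "p-values must lie in [0, 1]")
  sig <- ok & if (pDirection == "less") p < pCut else p >= pCut
  lab <- rep("ns", nrow(table))
  lab[sig & table$logFC > lfcCut] <- "up"
  lab[sig & table$logFC < -lfcCut] <- "down"
  out <- table
  out$label <- factor(lab, levels = c("up", "down", "ns"))
  out$qc <- ifelse(ok, NA_character_, "missing statistics; labelled ns")
  out
}

#' Linear fold change of a log2 fold change
#'
#' `2^lfc`; summaries report it to 2 significant figures (so the 0.6
#' cutoff reads as 1.5-fold).
#'
#' @param lfc finite log2 fold change(s).
#' @param signif2 round to 2 significant figures.
#' @return Linear fold change(s).
#' @examples
#' log2fcToFold(0.6, signif2 = TRUE)  # 1.5
#' @export
log2fcToFold <- function(lfc, signif2 = FALSE) {
  stopIfNot(all(is.finite(lfc)), "lfc must be finite")
  out <- 2^lfc
  if (signif2) signif(out, 2) else out
}

#' Select the top n genes by p-value
#'
#' Genes with `p < pCut`, sorted ascending by p with ties broken by
#' decreasing `|logFC|` then gene id; the first `n` are returned. When
#' fewer than `n` genes qualify, all of them are returned with a warning.
#'
#' @param table data.frame with `gene`, `logFC`, `pvalue`.
#' @param n number of genes to select (100 by default).
#' @param pCut qualification cutoff.
#' @return The selected subset, in selection order.
#' @export
topNByP <- function(table, n = 100, pCut = 0.01) {
  stopIfNot(nrow(table) > 0, "table is empty")
  qual <- table[!is.na(table$pvalue) & table$pvalue < pCut, , drop = FALSE]
  ord <- order(qual$pvalue, -abs(qual$logFC), qual$gene)
  qual <- qual[ord, , drop = FALSE]
  if (nrow(qual) < n) {
    warning(sprintf("only %d genes qualify at p < %g (requested %d)",
                    nrow(qual), pCut, n))
    return(qual)
  }
  qual[seq_len(n), , drop = FALSE]
}

#' Volcano-plot data export
#'
#' Adds `neg_log10_p` and the classification label; every `up` gene lies
#' right of `+lfcCut` and above the p cutoff line in
#' (logFC, -log10 p) space.
#'
#' @inheritParams classifyDEG
#' @return A data.frame ready for plotting.
#' @export
volcanoData <- function(table, pCut = 0.01, lfcCut = 0.6) {
  out <- classifyDEG(table, pCut = pCut, lfcCut = lfcCut)
  out$neg_log10_p <- -log10(pmax(out$pvalue, .Machine$double.xmin))
  out
}
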