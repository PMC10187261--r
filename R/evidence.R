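#' Validate discretized differential-expression evidence
#'
#' Evidence is a named numeric vector with one entry per gene taking values in
#' -1 (down-regulated), 0 (unchanged) or +1 (up-regulated). Genes absent from
#' the vector are treated as unchanged throughout the package.
#'
#' @param evidence named numeric vector.
#' @return The validated vector (invisibly usable), with duplicate names
#'   rejected.
#' @export
validate_evidence <- function(evidence) {
  if (is.null(names(evidence)) || !all(nzchar(names(evidence))))
    stop("evidence must be a named vector (names are gene identifiers)")
  if (anyDuplicated(names(evidence)))
    stop("duplicate gene identifiers in evidence")
  v <- as.numeric(evidence)
  if (anyNA(v) || !all(v %in% c(-1, 0, 1)))
    stop("evidence values must lie in {-1, 0, +1}")
  stats::setNames(v, names(evidence))
}

#' Discretize a differential-expression table to three-state evidence
#'
#' Applies fold-change and significance cutoffs, keeps at most the `top_n`
#' most significant genes, and assigns each survivor the sign of its log
#' fold-change; every other gene is unchanged (0). The adjusted p-value column
#' is used when present, otherwise the raw p-value. Duplicate gene rows are
#' resolved by minimum p-value with a warning.
#'
#' @param deg data frame with columns `gene`, `log2fc` and `pvalue`
#'   (optionally `padj`). Common aliases (`lfc`, `logfc`, `p`, `pval`,
#'   `adj.p.val`, `fdr`) are recognised case-insensitively.
#' @param p_cutoff significance threshold (default 0.01).
#' @param fc_cutoff minimum absolute log2 fold-change (default 1).
#' @param top_n cap on the number of DEGs retained, smallest p-values first
#'   (default 800).
#' @return Named numeric evidence vector over all genes of the table.
#' @export
discretize_deg <- function(deg, p_cutoff = 0.01, fc_cutoff = 1, top_n = 800) {
  stopifnot(is.data.frame(deg), p_cutoff > 0, fc_cutoff >= 0, top_n >= 1)
  cols <- find_deg_columns(names(deg))
  gene <- as.character(deg[[cols$gene]])
  lfc <- as.numeric(deg[[cols$lfc]])
  p <- as.numeric(deg[[if (!is.na(cols$padj)) cols$padj else cols$p]])
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")

  if (anyDuplicated(gene)) {
    ord <- order(p)
    keep <- ord[!duplicated(gene[ord])]
    warning(sprintf("%d duplicate gene row(s) resolved by minimum p-value",
                    length(gene) - length(keep)))
    gene <- gene[keep]; lfc <- lfc[keep]; p <- p[keep]
  }

  pass <- !is.na(p) & !is.na(lfc) & p <= p_cutoff & abs(lfc) >= fc_cutoff
  if (!any(pass))
    stop("no gene passes the cutoffs; relax 'p_cutoff' or 'fc_cutoff'")
  idx <- which(pass)[order(p[pass])]
  idx <- idx[seq_len(min(top_n, length(idx)))]

  ev <- stats::setNames(numeric(length(gene)), gene)
  ev[idx] <- sign(lfc[idx])
  ev
}

# Locate DEG-table columns by common header aliases (case-insensitive).
find_deg_columns <- function(nms) {
  low <- tolower(nms)
  pick <- function(aliases) {
    i <- which(low %in% aliases)
    if (length(i)) nms[i[1L]] else NA_character_
  }
  gene <- pick(c("gene", "gene_id", "symbol", "id"))
  lfc <- pick(c("log2fc", "lfc", "logfc", "log2foldchange", "fold_change"))
  p <- pick(c("pvalue", "p", "pval", "p.value", "p_value"))
  padj <- pick(c("padj", "adj.p.val", "adj_pval", "fdr", "qvalue"))
  if (is.na(gene) || is.na(lfc) || is.na(p))
    stop("DEG table must provide gene, log2 fold-change and p-value columns")
  list(gene = gene, lfc = lfc, p = p, padj = padj)
}
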