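# Posterior summarisation and benchmarking: confidence tiers, explained-DEG
# fractions, ROC / precision-recall metrics and Fisher target enrichment.

#' Confidence tiers for posterior activation probabilities
#'
#' With the prior activation probability set to a small value (0.01 by
#' default), a TF with posterior probability p >= 0.2 is considered
#' potentially relevant; tiers are `high` (p >= 0.8), `mid` (0.5 <= p < 0.8),
#' `low` (0.2 <= p < 0.5) and `none` otherwise.
#'
#' @param posterior numeric vector of probabilities.
#' @return Ordered factor with levels `none < low < mid < high`.
#' @examples
#' assign_tiers(c(1, 0.8, 0.5, 0.2, 0.19999))
#' @export
assign_tiers <- function(posterior) {
  stopifnot(all(posterior >= 0 & posterior <= 1, na.rm = TRUE))
  cut(posterior, breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("none", "low", "mid", "high"),
      right = FALSE, ordered_result = TRUE)
}

#' Fraction of DEGs explained by inferred regulators
#'
#' Proportion of nonzero-evidence genes targeted by at least one TF whose
#' posterior activation probability reaches `threshold`.
#'
#' @param fit an [ornor()] fit.
#' @param threshold posterior cutoff defining an inferred-active regulator
#'   (default 0.2).
#' @param quiet suppress the zero-DEG warning.
#' @return A fraction in `[0, 1]`; defined as 0 (with a warning) when the
#'   evidence contains no DEG.
#' @export
explained_fraction <- function(fit, threshold = 0.2, quiet = FALSE) {
  stopifnot(inherits(fit, "ornor"), threshold >= 0, threshold <= 1)
  degs <- names(fit$evidence)[fit$evidence != 0]
  if (length(degs) == 0L) {
    if (!quiet) warning("evidence contains no differentially expressed gene")
    return(0)
  }
  active <- fit$tf$tf[fit$tf$posterior >= threshold]
  e <- fit$graph$edges
  explained <- unique(e$gene[e$tf %in% active])
  mean(degs %in% explained)
}

#' ROC and precision-recall curves for regulator recovery
#'
#' Ranks TFs by a score (posterior activation probability in simulation
#' benchmarks) against a ground-truth labelling and returns both curves with
#' their areas. ROC and its AUC come from pROC (trapezoidal rule, equivalent
#' to the Mann-Whitney pairwise-concordance statistic under ties); the
#' precision-recall curve is evaluated at every distinct score threshold and
#' integrated by the trapezoidal rule over recall.
#'
#' @param scores numeric vector.
#' @param truth logical (or 0/1) vector: `TRUE` for truly active TFs.
#' @return List with `roc` (data frame `fpr`, `tpr`), `pr` (data frame
#'   `recall`, `precision`), `auc_roc` and `auc_pr`.
#' @export
roc_pr <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  if (length(unique(truth)) < 2L)
    stop("ground truth must contain both active and inactive TFs")

  r <- pROC::roc(response = truth, predictor = scores, direction = "<",
                 quiet = TRUE)
  roc_df <- data.frame(fpr = rev(1 - r$specificities),
                       tpr = rev(r$sensitivities))
  auc_roc <- as.numeric(pROC::auc(r))

  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(truth)
  pr <- t(vapply(thr, function(t) {
    sel <- scores >= t
    c(recall = sum(truth & sel) / npos, precision = sum(truth & sel) / sum(sel))
  }, numeric(2)))
  pr_df <- data.frame(recall = c(0, pr[, "recall"]),
                      precision = c(pr[1, "precision"], pr[, "precision"]))
  auc_pr <- sum(diff(pr_df$recall) *
                  (utils::head(pr_df$precision, -1) +
                     utils::tail(pr_df$precision, -1)) / 2)
  list(roc = roc_df, pr = pr_df, auc_roc = auc_roc, auc_pr = auc_pr)
}

#' One-sided Fisher target-enrichment test
#'
#' For each TF, tests over-representation of DEGs among its target genes with
#' a one-sided Fisher exact test on the 2x2 table (target / non-target) x
#' (DE / non-DE) over all genes of the graph. This is the enrichment-only
#' score the Bayesian posterior is contrasted with: it ignores the global
#' network topology, so the two rankings can disagree.
#'
#' @param graph a [causal_graph()].
#' @param evidence named evidence vector (values in -1/0/+1).
#' @param tfs TFs to test (default: all TFs of the graph).
#' @return Named numeric vector of enrichment p-values.
#' @export
fisher_enrichment <- function(graph, evidence, tfs = NULL) {
  stopifnot(inherits(graph, "causal_graph"))
  evidence <- validate_evidence(evidence)
  if (is.null(tfs)) tfs <- graph$tf_ids
  stopifnot(all(tfs %in% graph$tf_ids))

  genes <- graph$gene_ids
  de <- genes %in% names(evidence)[evidence != 0]
  vapply(stats::setNames(tfs, tfs), function(tf) {
    targ <- genes %in% graph$edges$gene[graph$edges$tf == tf]
    tab <- matrix(c(sum(targ & de), sum(targ & !de),
                    sum(!targ & de), sum(!targ & !de)), nrow = 2)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
}

#' Randomization benchmark of regulator recovery
#'
#' Reproduces the simulation protocol used to assess robustness to noise: for
#' each replicate, a random network and ground-truth evidence are generated,
#' a fraction of either the evidence values (`target = "data"`) or the network
#' edges (`target = "network"`) is randomized, the model is fitted, and
#' recovery of the truly active TFs is scored by ROC and precision-recall
#' AUC.
#'
#' @param fractions randomization fractions to sweep (default
#'   `c(0, 0.25, 0.5, 0.75, 1)`).
#' @param target what to randomize: `"data"` or `"network"`.
#' @param n_replicates independent replicates per fraction (default 5).
#' @param n_tfs,n_genes,mean_targets,dispersion,p_activation network
#'   generator settings, see [sim_network()].
#' @param n_active,frac_de evidence generator settings, see [sim_evidence()].
#' @param hyper,control model and sampler settings.
#' @param seed integer; replicate r uses `seed + r` for generation and
#'   derived per-fit seeds, making the whole sweep reproducible.
#' @return An object of class `"ornor_benchmark"`: list with `metrics` (one
#'   row per fraction x replicate: AUCs, convergence), `tf_detail` (per-TF
#'   posterior, target count and truth label for every run) and the call
#'   settings.
#' @examples
#' \donttest{
#' bm <- benchmark_randomization(fractions = c(0, 1), target = "data",
#'                               n_replicates = 2, n_tfs = 25, n_genes = 400,
#'                               mean_targets = 40, n_active = 3, seed = 1)
#' bm
#' }
#' @export
benchmark_randomization <- function(fractions = c(0, 0.25, 0.5, 0.75, 1),
                                    target = c("data", "network"),
                                    n_replicates = 5, n_tfs = 250,
                                    n_genes = 5000, mean_targets = 120,
                                    dispersion = 2, p_activation = 0.65,
                                    n_active = 10, frac_de = 0.10,
                                    hyper = ornor_hyper(),
                                    control = ornor_control(), seed = 1L) {
  target <- match.arg(target)
  stopifnot(all(fractions >= 0 & fractions <= 1), n_replicates >= 1)
  metrics <- list()
  detail <- list()
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    g <- sim_network(n_tfs, n_genes, mean_targets, dispersion, p_activation)
    truth <- sim_evidence(g, n_active, frac_de)
    for (fi in seq_along(fractions)) {
      f <- fractions[fi]
      set.seed(seed + 1000L * r + fi)
      if (target == "data") {
        g_use <- g
        ev_use <- randomize_evidence(truth$evidence, f)
      } else {
        g_use <- randomize_network(g, f)
        ev_use <- truth$evidence
      }
      fit <- suppressWarnings(
        ornor(g_use, ev_use, hyper = hyper, control = control,
              seed = (seed + 7919L * r + 104729L * fi) %% 2147483647L))
      sc <- coef(fit)
      lab <- names(sc) %in% truth$active_tfs
      m <- roc_pr(sc, lab)
      metrics[[length(metrics) + 1L]] <-
        data.frame(target = target, fraction = f, replicate = r,
                   auc_roc = m$auc_roc, auc_pr = m$auc_pr,
                   converged = fit$converged, iterations = fit$iterations,
                   max_r = fit$max_r, stringsAsFactors = FALSE)
      detail[[length(detail) + 1L]] <-
        data.frame(target = target, fraction = f, replicate = r,
                   tf = fit$tf$tf, posterior = fit$tf$posterior,
                   n_targets = fit$tf$n_targets,
                   active = fit$tf$tf %in% truth$active_tfs,
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(metrics = do.call(rbind, metrics),
                 tf_detail = do.call(rbind, detail),
                 target = target, fractions = fractions, seed = seed),
            class = "ornor_benchmark")
}

#' @export
print.ornor_benchmark <- function(x, ...) {
  cat(sprintf("Randomization benchmark (%s), %d replicate(s) per fraction\n",
              x$target, max(x$metrics$replicate)))
  agg <- stats::aggregate(cbind(auc_roc, auc_pr) ~ fraction, data = x$metrics,
                          FUN = mean)
  conv <- stats::aggregate(converged ~ fraction, data = x$metrics, FUN = all)
  agg$all_converged <- conv$converged
  print(format(agg, digits = 3), row.names = FALSE)
  invisible(x)
}
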