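# Fitting interface: prepares the integer model representation consumed by the
# compiled Gibbs kernel and wraps its output in a classed fit object.

# Build the internal model representation. Genes of the declared universe with
# no incoming edge carry no latent state and are excluded from the likelihood;
# evidence on genes outside the graph cannot inform any TF and is dropped.
prepare_model <- function(graph, evidence, hyper, control) {
  stopifnot(inherits(graph, "causal_graph"))
  evidence <- validate_evidence(evidence)
  hyper <- resolve_hyper(hyper, graph, evidence)

  genes <- sort(unique(graph$edges$gene))
  tfs <- graph$tf_ids
  n_dropped <- sum(!(names(evidence) %in% genes) & evidence != 0)
  if (n_dropped > 0)
    message(sprintf("%d nonzero evidence gene(s) have no regulator in the graph and are ignored",
                    n_dropped))

  y <- stats::setNames(integer(length(genes)), genes)
  common <- intersect(names(evidence), genes)
  y[common] <- as.integer(evidence[common])

  e_tf <- match(graph$edges$tf, tfs) - 1L
  e_gene <- match(graph$edges$gene, genes) - 1L
  e_ann <- ifelse(graph$edges$mode == "A", 2L, 0L)

  s_prior <- matrix(hyper$s_prior_opp, nrow = length(e_ann), ncol = 3)
  s_prior[, 2] <- hyper$s_prior_na
  s_prior[cbind(seq_along(e_ann), e_ann + 1L)] <- hyper$s_prior_conf

  grid <- seq(0, 1, length.out = control$theta_grid)
  gprior <- stats::dbeta(grid, hyper$theta_a, hyper$theta_b)
  gprior <- gprior / sum(gprior)

  list(graph = graph, tfs = tfs, genes = genes, y = y,
       n_tf = length(tfs), n_gene = length(genes),
       e_tf = e_tf, e_gene = e_gene, e_ann = e_ann,
       zeta = ifelse(y != 0, hyper$zeta_deg, hyper$zeta_nondeg),
       s_prior = s_prior, grid = grid, gprior = gprior,
       hyper = hyper, control = control, n_dropped = n_dropped)
}

#' Infer active transcription factors by noisy OR-NOR Gibbs sampling
#'
#' Fits the noisy-logic Bayesian network relating latent TF activity states to
#' discretized differential-expression evidence over a signed causal graph,
#' and returns the posterior probability of activation for every TF. The
#' posterior is sampled by several independent Gibbs chains sweeping all latent
#' variables (TF states X, activity probabilities \eqn{\theta}, per-edge modes
#' of regulation S, true gene states H) in fixed order; sampling stops when the
#' Gelman-Rubin statistic drops below `control$r_threshold` for every variable,
#' or at `control$max_iter`.
#'
#' @param graph a [causal_graph()].
#' @param evidence named numeric vector of per-gene values in -1/0/+1 (see
#'   [discretize_deg()] to derive one from a DEG table). Genes absent from the
#'   vector count as unchanged; nonzero evidence on genes without regulators in
#'   the graph is dropped with a message.
#' @param hyper model hyper-parameters, see [ornor_hyper()].
#' @param control sampler settings, see [ornor_control()].
#' @param seed integer seed; the fit is fully reproducible given
#'   (graph, evidence, hyper, control, seed) and independent of R's RNG state.
#' @return An object of class `"ornor"` with components
#'   \describe{
#'     \item{tf}{data frame: `tf`, `posterior` (probability of activation),
#'       `mean_theta`, `n_targets`, `n_de_targets`.}
#'     \item{genes}{data frame of per-gene posteriors of the true state:
#'       `gene`, `y`, `p_down`, `p_zero`, `p_up`.}
#'     \item{edges}{data frame of per-edge posterior mode-of-regulation
#'       probabilities: `tf`, `gene`, `annotation`, `p_inhibition`, `p_na`,
#'       `p_activation`.}
#'     \item{converged, iterations, max_r, r_history}{convergence diagnostics;
#'       `r_var` holds the final per-variable Gelman-Rubin statistics,
#'       `x_chain` per-chain posterior means of X, and `states` the final
#'       state of every chain.}
#'     \item{hyper, control, seed}{the resolved settings used.}
#'   }
#' @examples
#' g <- causal_graph(tf   = rep(c("T1", "T2"), each = 3),
#'                   gene = c("g1", "g2", "g3", "g4", "g5", "g6"),
#'                   mode = c("A", "A", "I", "A", "A", "A"))
#' ev <- c(g1 = 1, g2 = 1, g3 = -1)
#' fit <- ornor(g, ev, seed = 1)
#' coef(fit)
#' summary(fit)
#' @seealso [summary.ornor()], [sim_network()], [benchmark_randomization()]
#' @export
ornor <- function(graph, evidence, hyper = ornor_hyper(),
                  control = ornor_control(), seed = 1L) {
  stopifnot(inherits(hyper, "ornor_hyper"), inherits(control, "ornor_control"))
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  prep <- prepare_model(graph, evidence, hyper, control)

  t0 <- proc.time()[["elapsed"]]
  res <- .gibbs_run(prep$n_tf, prep$n_gene, prep$e_tf, prep$e_gene, prep$e_ann,
                    unname(prep$y), prep$zeta, prep$hyper$q, prep$hyper$p0,
                    unname(prep$hyper$obs), prep$s_prior, prep$grid,
                    prep$gprior, prep$control$resample_s, prep$control$n_chains,
                    prep$control$check_period, prep$control$r_threshold,
                    prep$control$max_iter, prep$control$min_iter,
                    prep$control$burn_in, seed)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!res$converged)
    warning(sprintf("sampler stopped at max_iter = %d with max Gelman-Rubin R = %.3f >= %.2f",
                    prep$control$max_iter, res$max_r, prep$control$r_threshold))

  deg <- tf_degree(prep$graph)
  de_genes <- prep$genes[prep$y != 0]
  de_deg <- table(factor(prep$graph$edges$tf[prep$graph$edges$gene %in% de_genes],
                         levels = prep$tfs))

  tf_tab <- data.frame(tf = prep$tfs,
                       posterior = res$x_mean,
                       mean_theta = res$theta_mean,
                       n_targets = unname(deg[prep$tfs]),
                       n_de_targets = as.integer(de_deg),
                       stringsAsFactors = FALSE)
  gene_tab <- data.frame(gene = prep$genes, y = unname(prep$y),
                         p_down = res$h_mean[, 1], p_zero = res$h_mean[, 2],
                         p_up = res$h_mean[, 3], stringsAsFactors = FALSE)
  edge_tab <- data.frame(tf = prep$graph$edges$tf, gene = prep$graph$edges$gene,
                         annotation = prep$graph$edges$mode,
                         p_inhibition = res$s_mean[, 1],
                         p_na = res$s_mean[, 2],
                         p_activation = res$s_mean[, 3],
                         stringsAsFactors = FALSE)

  structure(list(tf = tf_tab, genes = gene_tab, edges = edge_tab,
                 converged = res$converged, iterations = res$iterations,
                 max_r = res$max_r, r_history = res$r_history,
                 r_var = res$r_var, states = res$states,
                 x_chain = res$x_chain,
                 hyper = prep$hyper, control = prep$control, seed = seed,
                 n_dropped_evidence = prep$n_dropped,
                 graph = prep$graph, evidence = prep$y,
                 elapsed = elapsed, call = match.call()),
            class = "ornor")
}

# Thin R access to the compiled full conditionals, for validation.
gibbs_conditional <- function(prep, state, what, index) {
  .gibbs_cond(what, as.integer(index) - 1L, as.integer(state$x),
              as.numeric(state$theta), as.integer(state$s),
              as.integer(state$h), prep$n_tf, prep$n_gene, prep$e_tf,
              prep$e_gene, prep$e_ann, unname(prep$y), prep$zeta,
              prep$hyper$q, prep$hyper$p0, unname(prep$hyper$obs),
              prep$s_prior, prep$grid, prep$gprior, prep$control$resample_s)
}

#' @export
print.ornor <- function(x, ...) {
  cat("Noisy OR-NOR Bayesian network fit\n")
  cat(sprintf("  %d TFs, %d genes (%d DE), %d edges\n",
              nrow(x$tf), nrow(x$genes), sum(x$evidence != 0),
              nrow(x$edges)))
  cat(sprintf("  %d chains, %.0f iterations, max Gelman-Rubin R = %.3f (%s)\n",
              x$control$n_chains, x$iterations, x$max_r,
              if (x$converged) "converged" else "NOT converged"))
  top <- x$tf[order(-x$tf$posterior), ][seq_len(min(5L, nrow(x$tf))), ]
  cat("  Top regulators:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-12s p = %.3f (%d targets, %d DE)\n", top$tf[i],
                top$posterior[i], top$n_targets[i], top$n_de_targets[i]))
  invisible(x)
}

#' Posterior activation probabilities
#' @param object an [ornor()] fit.
#' @param ... unused.
#' @return Named numeric vector of per-TF posterior probabilities.
#' @export
coef.ornor <- function(object, ...) {
  stats::setNames(object$tf$posterior, object$tf$tf)
}

#' Posterior distribution of the true gene states
#' @param object an [ornor()] fit.
#' @param ... unused.
#' @return Data frame with per-gene posterior probabilities of the true state
#'   being down-regulated, unchanged or up-regulated.
#' @export
fitted.ornor <- function(object, ...) object$genes

#' Summarise an inference run
#'
#' Ranks TFs by posterior activation probability, assigns confidence tiers
#' (high: p >= 0.8, mid: p >= 0.5, low: p >= 0.2), attaches one-sided Fisher
#' target-enrichment p-values for comparison with enrichment-only analysis,
#' and reports the fraction of DEGs explained by at least one regulator at
#' each tier threshold.
#'
#' @param object an [ornor()] fit.
#' @param fisher logical; compute per-TF Fisher enrichment p-values
#'   (default `TRUE`).
#' @param ... unused.
#' @return An object of class `"summary.ornor"`: list with elements `tf`
#'   (ranked data frame with `tier` and `fisher_p` columns), `explained`
#'   (named fractions at the 0.2/0.5/0.8 thresholds) and convergence fields.
#' @export
summary.ornor <- function(object, fisher = TRUE, ...) {
  tab <- object$tf
  tab$tier <- assign_tiers(tab$posterior)
  tab$fisher_p <- if (fisher)
    fisher_enrichment(object$graph, object$evidence)[tab$tf] else NA_real_
  tab <- tab[order(-tab$posterior, tab$tf),
             c("tf", "posterior", "tier", "n_targets", "n_de_targets",
               "fisher_p", "mean_theta")]
  rownames(tab) <- NULL
  expl <- vapply(c(low = 0.2, mid = 0.5, high = 0.8), function(thr)
    explained_fraction(object, threshold = thr, quiet = TRUE), numeric(1))
  structure(list(tf = tab, explained = expl, converged = object$converged,
                 iterations = object$iterations, max_r = object$max_r,
                 n_de = sum(object$evidence != 0)),
            class = "summary.ornor")
}

#' @export
print.summary.ornor <- function(x, digits = 3, ...) {
  cat(sprintf("Inferred regulators (%d DEGs; %s, max R = %.3f)\n", x$n_de,
              if (x$converged) "converged" else "NOT converged", x$max_r))
  shown <- x$tf[x$tf$tier != "none", ]
  if (nrow(shown) == 0L) {
    cat("  no TF above the relevance threshold (p >= 0.2)\n")
  } else {
    print(format(shown, digits = digits), row.names = FALSE)
  }
  cat(sprintf("DEGs explained by >=1 regulator: %.1f%% (p>=0.2), %.1f%% (p>=0.5), %.1f%% (p>=0.8)\n",
              100 * x$explained[["low"]], 100 * x$explained[["mid"]],
              100 * x$explained[["high"]]))
  invisible(x)
}

#' Plot posterior activation probability against regulon size
#'
#' Scatter of per-TF posterior probability versus the number of target genes,
#' the diagnostic view used to judge how regulon size limits detectability
#' (TFs with few targets contribute too little evidence to move far from the
#' prior).
#'
#' @param x an [ornor()] fit.
#' @param truth optional character vector of truly active TF identifiers
#'   (simulation ground truth); when given, active TFs are drawn filled.
#' @param ... passed to [plot()].
#' @return Invisibly, the data frame plotted.
#' @export
plot.ornor <- function(x, truth = NULL, ...) {
  tab <- x$tf
  act <- if (is.null(truth)) rep(FALSE, nrow(tab)) else tab$tf %in% truth
  plot(pmax(tab$n_targets, 0.5), tab$posterior, log = "x",
       xlab = "Number of target genes", ylab = "Posterior P(active)",
       ylim = c(0, 1), pch = ifelse(act, 19, 1),
       col = ifelse(act, "firebrick", "grey40"), ...)
  graphics::abline(h = c(0.2, 0.5, 0.8), lty = 3, col = "grey70")
  if (!is.null(truth))
    graphics::legend("topleft", pch = c(19, 1), col = c("firebrick", "grey40"),
                     legend = c("active (truth)", "inactive"), bty = "n")
  invisible(tab)
}
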