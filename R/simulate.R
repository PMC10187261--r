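# Simulation harness: random signed regulatory networks, ground-truth
# evidence, and the data / network randomization perturbations used for
# benchmarking. All functions draw from R's RNG; call set.seed() for
# reproducibility.

#' Simulate a random signed TF-gene network
#'
#' Draws each TF's out-degree from a negative binomial distribution, assigns
#' that many distinct target genes uniformly at random, and labels each edge
#' activation with probability `p_activation`, inhibition otherwise. The
#' defaults emulate a regulatory network of 250 TFs and 5000 genes with about
#' 30000 edges (65% activation) and a right-skewed out-degree distribution in
#' which a minority of TFs regulate fewer than 30 genes.
#'
#' @param n_tfs number of TFs (default 250).
#' @param n_genes number of target genes (default 5000).
#' @param mean_targets negative-binomial mean out-degree (default 120,
#'   calibrated so the expected edge total is ~30000 at the default sizes).
#' @param dispersion negative-binomial size parameter (default 2; smaller is
#'   more overdispersed). Out-degrees above `n_genes` are clipped with a
#'   message; zero out-degrees are kept (a TF may regulate no gene).
#' @param p_activation probability that an edge is an activation (default
#'   0.65).
#' @return A [causal_graph()] with TF ids `TF001, ...` and gene ids
#'   `G00001, ...`; the declared universes include TFs/genes left untouched by
#'   edges.
#' @examples
#' set.seed(7)
#' g <- sim_network(n_tfs = 20, n_genes = 200, mean_targets = 15)
#' g
#' @export
sim_network <- function(n_tfs = 250, n_genes = 5000, mean_targets = 120,
                        dispersion = 2, p_activation = 0.65) {
  stopifnot(n_tfs >= 1, n_genes >= 1, mean_targets > 0, dispersion > 0,
            p_activation >= 0, p_activation <= 1)
  tf_ids <- sprintf("TF%03d", seq_len(n_tfs))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  deg <- stats::rnbinom(n_tfs, size = dispersion, mu = mean_targets)
  if (any(deg > n_genes)) {
    message(sprintf("%d out-degree(s) clipped to the number of genes (%d)",
                    sum(deg > n_genes), n_genes))
    deg <- pmin(deg, n_genes)
  }

  tf <- rep(tf_ids, deg)
  gene <- unlist(lapply(deg, function(d) sample.int(n_genes, d)),
                 use.names = FALSE)
  mode <- ifelse(stats::runif(length(tf)) < p_activation, "A", "I")
  if (length(tf) == 0L)
    stop("simulated network has no edges; increase 'mean_targets'")
  causal_graph(tf, gene_ids[gene], mode, tf_ids = tf_ids, gene_ids = gene_ids)
}

#' Simulate ground-truth evidence from active TFs
#'
#' Selects `n_active` TFs uniformly at random as the ground truth, marks a
#' fraction of each one's targets as differentially expressed with the sign
#' its edge predicts (+1 under activation, -1 under inhibition), and resolves
#' genes hit by several active TFs by the sign of the algebraic sum of the
#' incoming contributions (exact cancellation gives 0). At the default network
#' scale this yields on the order of 120 DEGs.
#'
#' @param graph a [causal_graph()], typically from [sim_network()].
#' @param n_active number of truly active TFs (default 10).
#' @param frac_de fraction of each active TF's targets marked differentially
#'   expressed (default 0.10); the per-TF count is rounded up so every active
#'   TF marks at least one target (TFs without targets mark none).
#' @return A list with elements `active_tfs` (character) and `evidence`
#'   (named vector over all graph genes, values in -1/0/+1).
#' @examples
#' set.seed(7)
#' g <- sim_network(n_tfs = 20, n_genes = 200, mean_targets = 15)
#' truth <- sim_evidence(g, n_active = 3)
#' table(truth$evidence)
#' @export
sim_evidence <- function(graph, n_active = 10, frac_de = 0.10) {
  stopifnot(inherits(graph, "causal_graph"),
            n_active >= 1, n_active <= length(graph$tf_ids),
            frac_de > 0, frac_de <= 1)
  active <- sample(graph$tf_ids, n_active)

  contrib <- numeric(length(graph$gene_ids))
  names(contrib) <- graph$gene_ids
  for (a in active) {
    sel <- graph$edges[graph$edges$tf == a, ]
    if (nrow(sel) == 0L) next
    k <- min(nrow(sel), ceiling(frac_de * nrow(sel)))
    pick <- sel[sample.int(nrow(sel), k), ]
    contrib[pick$gene] <- contrib[pick$gene] + ifelse(pick$mode == "A", 1, -1)
  }
  list(active_tfs = active,
       evidence = stats::setNames(sign(contrib), graph$gene_ids))
}

#' Randomize a fraction of the evidence
#'
#' Corrupts the input data by selecting `round(fraction * length(evidence))`
#' entries uniformly at random and toggling each selected value. The default
#' toggle replaces the value by a uniformly random *different* value in
#' (-1, 0, +1), so full randomization changes every selected entry;
#' `uniform = TRUE` instead draws uniformly over all three values.
#'
#' @param evidence named evidence vector.
#' @param fraction fraction of entries to perturb, in `[0, 1]`.
#' @param uniform logical; use the uniform-over-all-values toggle.
#' @return The perturbed evidence vector.
#' @export
randomize_evidence <- function(evidence, fraction, uniform = FALSE) {
  evidence <- validate_evidence(evidence)
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(evidence)
  k <- round(fraction * length(evidence))
  idx <- sample.int(length(evidence), k)
  vals <- c(-1, 0, 1)
  if (uniform) {
    evidence[idx] <- sample(vals, k, replace = TRUE)
  } else {
    pick <- function(v) sample(vals[vals != v], 1L)
    evidence[idx] <- vapply(evidence[idx], pick, numeric(1))
  }
  evidence
}

#' Randomize a fraction of the network edges
#'
#' Selects `round(fraction * n_edges)` edges uniformly at random and reassigns
#' each to a new target gene drawn uniformly among the graph's genes, distinct
#' from the original target; the TF and sign are kept, the edge count is
#' preserved, and collisions with existing edges are resolved by redrawing.
#'
#' @param graph a [causal_graph()].
#' @param fraction fraction of edges to rewire, in `[0, 1]`.
#' @return A perturbed [causal_graph()] over the same node universes.
#' @export
randomize_network <- function(graph, fraction) {
  stopifnot(inherits(graph, "causal_graph"), fraction >= 0, fraction <= 1)
  if (fraction == 0) return(graph)
  e <- graph$edges
  genes <- graph$gene_ids
  if (length(genes) < 2L) stop("rewiring needs at least two genes")
  k <- round(fraction * nrow(e))
  idx <- sample.int(nrow(e), k)

  taken <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(e)))
    assign(paste(e$tf[r], e$gene[r], sep = "\r"), TRUE, envir = taken)

  for (r in idx) {
    old_key <- paste(e$tf[r], e$gene[r], sep = "\r")
    repeat {
      g <- genes[sample.int(length(genes), 1L)]
      if (g == e$gene[r]) next
      key <- paste(e$tf[r], g, sep = "\r")
      if (!exists(key, envir = taken, inherits = FALSE)) {
        rm(list = old_key, envir = taken)
        assign(key, TRUE, envir = taken)
        e$gene[r] <- g
        break
      }
    }
  }
  causal_graph(e$tf, e$gene, e$mode, tf_ids = graph$tf_ids,
               gene_ids = graph$gene_ids)
}
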