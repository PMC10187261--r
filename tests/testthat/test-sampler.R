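# A small but non-trivial fixture used throughout: 3 TFs, 6 genes, at most
# two parents per gene, mixed signs, mixed evidence.
tiny_graph <- function() {
  causal_graph(
    tf   = c("T1", "T1", "T1", "T2", "T2", "T3", "T3", "T2"),
    gene = c("g1", "g2", "g3", "g3", "g4", "g5", "g6", "g6"),
    mode = c("A", "A", "I", "A", "A", "I", "A", "I"))
}
tiny_evidence <- c(g1 = 1, g2 = 1, g3 = -1, g5 = 0, g6 = 1)

test_that("gelman_rubin follows the between/within variance formula", {
  # identical constant chains: exactly 1 by convention
  expect_identical(gelman_rubin(cbind(rep(2, 50), rep(2, 50))), 1)
  # constant but different chains: no mixing at all
  expect_equal(gelman_rubin(cbind(rep(0, 50), rep(1, 50))), Inf)

  # two long chains from the same distribution mix
  set.seed(1)
  expect_lt(gelman_rubin(cbind(rnorm(1e4), rnorm(1e4))), 1.1)

  # far-apart chains: value matches a direct evaluation of the formula
  set.seed(2)
  ch <- cbind(rnorm(500, 0), rnorm(500, 10))
  W <- mean(apply(ch, 2, var))
  vb <- var(colMeans(ch))
  n <- nrow(ch)
  expect_equal(gelman_rubin(ch),
               sqrt(((n - 1) / n * W + (1 + 1 / 2) * vb) / W))
  expect_gt(gelman_rubin(ch), 5)

  expect_error(gelman_rubin(matrix(1:10, ncol = 1)), "two chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "same length")
  # burn-in drops the transient
  ch2 <- cbind(c(rep(100, 50), rnorm(50)), c(rep(-100, 50), rnorm(50)))
  expect_gt(gelman_rubin(ch2), 1.1)
  expect_lt(gelman_rubin(ch2, burn_in = 0.5), 1.1)
})

test_that("compiled full conditionals match plain-R reference computations", {
  g <- tiny_graph()
  for (resample_s in c(TRUE, FALSE)) {
    control <- ornor_control(theta_grid = 21L, resample_s = resample_s)
    prep <- ornor:::prepare_model(g, tiny_evidence, ornor_hyper(), control)
    for (sd in 1:5) {
      st <- ref_state(prep, seed = sd)
      for (i in seq_len(prep$n_tf)) {
        expect_equal(ornor:::gibbs_conditional(prep, st, "x", i),
                     ref_cond_x(prep, st, i), tolerance = 1e-10)
        expect_equal(ornor:::gibbs_conditional(prep, st, "xm", i),
                     ref_cond_x_marginal(prep, st, i), tolerance = 1e-10)
        expect_equal(ornor:::gibbs_conditional(prep, st, "theta", i),
                     unname(ref_cond_theta(prep, st, i)), tolerance = 1e-10)
      }
      for (e in seq_along(prep$e_tf))
        expect_equal(ornor:::gibbs_conditional(prep, st, "s", e),
                     unname(ref_cond_s(prep, st, e)), tolerance = 1e-10)
      for (j in seq_len(prep$n_gene))
        expect_equal(ornor:::gibbs_conditional(prep, st, "h", j),
                     unname(ref_cond_h(prep, st, j)), tolerance = 1e-10)
    }
  }
})

test_that("documented conditional limits hold", {
  g <- tiny_graph()
  prep <- ornor:::prepare_model(g, tiny_evidence, ornor_hyper(),
                                ornor_control(theta_grid = 21L))
  st <- ref_state(prep, seed = 3)

  # a TF with no children is drawn from its prior p0
  g2 <- causal_graph(c("T1", "T2"), c("g1", "g2"), c("A", "A"),
                     tf_ids = c("T1", "T2", "T3"))
  prep2 <- ornor:::prepare_model(g2, c(g1 = 1), ornor_hyper(),
                                 ornor_control(theta_grid = 21L))
  st2 <- ref_state(prep2, seed = 1)
  expect_equal(ornor:::gibbs_conditional(prep2, st2, "x", 3), 0.01)

  # theta of an inactive TF is drawn from its (discretized) Beta prior
  st$x[] <- 0L
  expect_equal(ornor:::gibbs_conditional(prep, st, "theta", 1),
               rep(1 / 21, 21))

  # h conditional for a gene with uninformative parents and y = 0 is the
  # renormalised product of the observation column and the leak prior
  stz <- st
  stz$x[] <- 0L
  j <- which(prep$genes == "g5")  # y = 0
  q <- prep$hyper$q
  expected <- c(0.050 * q[1], 0.900 * q[2], 0.050 * q[3])
  expect_equal(ornor:::gibbs_conditional(prep, stz, "h", j),
               expected / sum(expected), tolerance = 1e-12)

  # degenerate S prior pins the mode at its annotation
  hyp <- ornor_hyper(s_prior_conf = 1, s_prior_na = 0, s_prior_opp = 0)
  prep3 <- ornor:::prepare_model(g, tiny_evidence, hyp,
                                 ornor_control(theta_grid = 21L))
  st3 <- ref_state(prep3, seed = 4)
  for (e in seq_along(prep3$e_tf)) {
    w <- ornor:::gibbs_conditional(prep3, st3, "s", e)
    expect_equal(which.max(w) - 1L, prep3$e_ann[e])
    expect_equal(max(w), 1)
  }

  # an inactive parent's S conditional is its prior
  st4 <- ref_state(prep, seed = 5)
  st4$x[] <- 0L
  for (e in seq_along(prep$e_tf))
    expect_equal(ornor:::gibbs_conditional(prep, st4, "s", e),
                 unname(prep$s_prior[e, ]), tolerance = 1e-12)
})

test_that("Gibbs posteriors match exhaustive enumeration on a 2-TF model", {
  g <- causal_graph(
    tf   = c("T1", "T1", "T1", "T2", "T2"),
    gene = c("g1", "g2", "g3", "g3", "g4"),
    mode = c("A", "A", "I", "A", "A"))
  ev <- c(g1 = 1, g2 = 1, g3 = -1, g4 = 0)
  control <- ornor_control(theta_grid = 51L, min_iter = 20000L,
                           max_iter = 20000L)
  exact <- oracle_posterior(g, ev, control = control)
  fit <- suppressWarnings(ornor(g, ev, control = control, seed = 9))
  expect_equal(coef(fit), exact, tolerance = 0.02)
})

test_that("all-zero evidence returns every TF to its prior", {
  set.seed(5)
  g <- sim_network(n_tfs = 10, n_genes = 100, mean_targets = 12)
  ev <- setNames(rep(0, 100), g$gene_ids)
  fit <- ornor(g, ev, seed = 2,
               control = ornor_control(min_iter = 2000L))
  expect_true(all(abs(coef(fit) - 0.01) < 0.01))
  expect_true(fit$converged)
})

test_that("saturating evidence drives a TF's posterior to one", {
  # 20 up-regulated activation targets inside a 200-gene universe, so the
  # empirical leak prior stays realistic (mostly unchanged genes)
  g <- causal_graph(rep("T1", 20), sprintf("g%02d", 1:20), rep("A", 20),
                    gene_ids = sprintf("g%02d", 1:200))
  ev <- setNames(rep(1, 20), sprintf("g%02d", 1:20))
  fit <- ornor(g, ev, seed = 3, control = ornor_control(min_iter = 500L))
  expect_gt(coef(fit)[["T1"]], 0.99)
})

test_that("fits are deterministic in the seed and stable across seeds", {
  g <- tiny_graph()
  ctl <- ornor_control(min_iter = 4000L, max_iter = 4000L)
  f1 <- suppressWarnings(ornor(g, tiny_evidence, control = ctl, seed = 7))
  f2 <- suppressWarnings(ornor(g, tiny_evidence, control = ctl, seed = 7))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$edges, f2$edges)
  f3 <- suppressWarnings(ornor(g, tiny_evidence, control = ctl, seed = 8))
  expect_equal(coef(f1), coef(f3), tolerance = 0.05)
})

test_that("posterior means are invariant to chain count beyond noise", {
  g <- tiny_graph()
  f3 <- suppressWarnings(ornor(g, tiny_evidence, seed = 1,
    control = ornor_control(n_chains = 3L, min_iter = 4000L, max_iter = 4000L)))
  f5 <- suppressWarnings(ornor(g, tiny_evidence, seed = 1,
    control = ornor_control(n_chains = 5L, min_iter = 4000L, max_iter = 4000L)))
  expect_equal(coef(f3), coef(f5), tolerance = 0.05)
})

test_that("theta grid refinement does not move posterior means", {
  g <- causal_graph(c("T1", "T1", "T1"), c("g1", "g2", "g3"),
                    c("A", "A", "A"))
  ev <- c(g1 = 1, g2 = 1, g3 = 0)
  ctl <- function(gr) ornor_control(theta_grid = gr, min_iter = 8000L,
                                    max_iter = 8000L)
  f101 <- suppressWarnings(ornor(g, ev, control = ctl(101L), seed = 4))
  f1001 <- suppressWarnings(ornor(g, ev, control = ctl(1001L), seed = 4))
  expect_lt(abs(f101$tf$mean_theta[1] - f1001$tf$mean_theta[1]), 0.01)
  expect_lt(abs(coef(f101)[[1]] - coef(f1001)[[1]]), 0.02)
})

test_that("conflicting evidence shifts an edge's posterior mode away from its annotation", {
  # T1 is forced active by ten concordant activation targets; one additional
  # edge is annotated A but its gene is observed down-regulated.
  g <- causal_graph(rep("T1", 11), sprintf("g%02d", 1:11), rep("A", 11),
                    gene_ids = sprintf("g%02d", 1:100))
  ev <- setNames(c(rep(1, 10), -1), sprintf("g%02d", 1:11))
  fit <- ornor(g, ev, seed = 6, control = ornor_control(min_iter = 2000L))
  edges <- fit$edges
  conflicted <- edges[edges$gene == "g11", ]
  concordant <- edges[edges$gene == "g01", ]
  expect_gt(coef(fit)[["T1"]], 0.95)
  # prior mass on A is 0.90; the discordant edge must fall well below both
  # its prior and the concordant edges' posterior
  expect_lt(conflicted$p_activation, 0.5)
  expect_gt(concordant$p_activation, 0.85)
  expect_gt(conflicted$p_inhibition + conflicted$p_na, 0.5)
})

test_that("non-convergence is reported, not fatal", {
  g <- tiny_graph()
  expect_warning(
    fit <- ornor(g, tiny_evidence, seed = 1,
                 control = ornor_control(max_iter = 4L, check_period = 2L)),
    "max_iter")
  expect_false(fit$converged)
  expect_s3_class(summary(fit), "summary.ornor")
})
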