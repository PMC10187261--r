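test_that("observation model matches the calibrated error-rate table", {
  obs <- observation_model()
  expect_equal(observation_likelihood(-1, -1), 0.945)
  expect_equal(observation_likelihood(0, 0), 0.900)
  expect_equal(observation_likelihood(1, -1), 0.005)
  expect_equal(unname(colSums(obs)), rep(1, 3))  # distribution of Y given H
  expect_error(observation_likelihood(2, 0), "-1, 0, \\+1")
  expect_error(observation_likelihood(0, "x"), "-1, 0, \\+1")
})

test_that("zeta_nondeg is the damped fraction of edges hitting DEGs", {
  # 30 edges, 3 of which point at DEGs: same ratio as 30000/3000 -> 0.01
  g <- causal_graph(rep("T1", 30), sprintf("g%02d", 1:30), rep("A", 30))
  ev <- c(g01 = 1, g02 = -1, g03 = 1)
  expect_equal(zeta_nondeg(g, ev), 0.01)

  # all-zero evidence floors at the smallest allowed positive value
  expect_equal(zeta_nondeg(g, c(g01 = 0)), 1e-4)

  # random fixture: value equals an independent brute-force edge recount
  set.seed(11)
  g2 <- sim_network(n_tfs = 15, n_genes = 120, mean_targets = 10)
  ev2 <- sim_evidence(g2, n_active = 4, frac_de = 0.3)$evidence
  hit <- vapply(seq_len(n_edges(g2)), function(i)
    ev2[[g2$edges$gene[i]]] != 0, logical(1))
  expect_equal(zeta_nondeg(g2, ev2),
               min(max(0.1 * sum(hit) / length(hit), 1e-4), 0.1))
})

test_that("q priors are empirical frequencies over the graph's genes", {
  g <- causal_graph(rep("T1", 4), c("g1", "g2", "g3", "g4"), rep("A", 4))
  q <- q_priors(g, c(g1 = 1, g2 = -1, g5 = 1))  # g5 not in graph
  expect_equal(unname(q), c(0.25, 0.5, 0.25))
  expect_equal(sum(q), 1)
})

test_that("outcome likelihood reduces to the leak prior without active parents", {
  q <- c(0.1, 0.7, 0.2)
  # no parents at all
  expect_equal(unname(h_likelihood(numeric(), numeric(), character(),
                                   zeta = 1, q = q)), q)
  # parents present but inactive, any zeta
  for (z in c(1, 0.99, 0.05))
    expect_equal(unname(h_likelihood(c(0, 0), c(0.9, 0.4), c("A", "I"),
                                     zeta = z, q = q)), q)
  # active parent whose latent mode is "not applicable" contributes nothing
  expect_equal(unname(h_likelihood(1, 0.9, "N", zeta = 0.99, q = q)), q)
})

test_that("outcome likelihood saturates at the logic gates' limits", {
  q <- c(0.1, 0.7, 0.2)
  # certain active inhibitor: down-regulation certain at zeta = 1
  p <- h_likelihood(1, 1, "I", zeta = 1, q = q)
  expect_equal(unname(p), c(1, 0, 0))
  # strictly larger than with theta = 0
  p0 <- h_likelihood(1, 0, "I", zeta = 1, q = q)
  expect_gt(p[["down"]], p0[["down"]])
  # certain activator, no inhibitor: up-regulation certain
  p <- h_likelihood(1, 1, "A", zeta = 1, q = q)
  expect_equal(unname(p), c(0, 0, 1))
  # activator AND inhibitor both certain: OR-NOR's NOR term kills 'up';
  # at zeta = 1 the leak weight is zero, so all mass goes to 'down'
  p <- h_likelihood(c(1, 1), c(1, 1), c("A", "I"), zeta = 1, q = q)
  expect_equal(p[["up"]], 0)
  expect_equal(p[["down"]], 1)
})

test_that("outcome likelihood agrees with the inclusion-exclusion oracle", {
  set.seed(21)
  q <- c(0.15, 0.6, 0.25)
  modes <- c("A", "I", "N")
  for (n_par in 1:3) {
    configs <- expand.grid(rep(list(seq_along(modes)), n_par))
    for (r in seq_len(nrow(configs))) {
      mode <- modes[as.integer(configs[r, ])]
      for (rep in 1:3) {
        x <- rbinom(n_par, 1, 0.6)
        theta <- runif(n_par)
        zeta <- sample(c(0.99, 0.5, 0.01), 1)
        expect_equal(unname(h_likelihood(x, theta, mode, zeta, q)),
                     unname(oracle_h_likelihood(x, theta, mode, zeta, q)),
                     tolerance = 1e-12)
      }
    }
  }
  # the documented two-inhibitor case, explicitly
  p <- h_likelihood(c(1, 1), c(0.6, 0.8), c("I", "I"), zeta = 0.99,
                    q = c(0.05, 0.9, 0.05))
  expect_equal(unname(p),
               unname(oracle_h_likelihood(c(1, 1), c(0.6, 0.8), c("I", "I"),
                                          0.99, c(0.05, 0.9, 0.05))),
               tolerance = 1e-12)
})

test_that("outcome probabilities always form a distribution", {
  set.seed(31)
  for (i in 1:200) {
    n_par <- sample(0:5, 1)
    q <- as.vector(stats::rmultinom(1, 100, runif(3)) / 100)
    p <- h_likelihood(rbinom(n_par, 1, 0.5), runif(n_par),
                      sample(c("A", "I", "N"), n_par, replace = TRUE),
                      zeta = runif(1, 0.01, 1), q = q)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("outcome likelihood is monotone in the activity of active parents", {
  q <- c(0.1, 0.8, 0.1)
  thetas <- seq(0, 1, by = 0.05)
  # single active activator: p_up non-decreasing, p_zero non-increasing
  up <- vapply(thetas, function(t)
    h_likelihood(1, t, "A", zeta = 0.9, q = q)[["up"]], numeric(1))
  zero <- vapply(thetas, function(t)
    h_likelihood(1, t, "A", zeta = 0.9, q = q)[["zero"]], numeric(1))
  expect_true(all(diff(up) >= -1e-12))
  expect_true(all(diff(zero) <= 1e-12))
  # active inhibitor next to an active activator: p_up non-increasing,
  # p_down non-decreasing in the inhibitor's theta
  up2 <- vapply(thetas, function(t)
    h_likelihood(c(1, 1), c(0.7, t), c("A", "I"), zeta = 0.9, q = q)[["up"]],
    numeric(1))
  down2 <- vapply(thetas, function(t)
    h_likelihood(c(1, 1), c(0.7, t), c("A", "I"), zeta = 0.9, q = q)[["down"]],
    numeric(1))
  expect_true(all(diff(up2) <= 1e-12))
  expect_true(all(diff(down2) >= -1e-12))
})

test_that("small zeta pulls the outcome distribution toward the leak prior", {
  q <- c(0.05, 0.9, 0.05)
  dist_to_q <- vapply(c(0.99, 0.5, 0.1, 0.01), function(z)
    sum(abs(h_likelihood(c(1, 1), c(0.9, 0.8), c("A", "I"), zeta = z,
                         q = q) - q)), numeric(1))
  expect_true(all(diff(dist_to_q) < 0))
})
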