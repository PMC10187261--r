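# Independent oracles used across the suite. They deliberately avoid the code
# paths they validate: the outcome-likelihood oracle expands the noisy-OR
# products by inclusion-exclusion instead of direct multiplication, and the
# posterior oracle integrates the model by exhaustive enumeration instead of
# Gibbs sampling.

# P(at least one of the independent events with probabilities u fires),
# by inclusion-exclusion over all non-empty subsets.
or_expansion <- function(u) {
  n <- length(u)
  if (n == 0L) return(0)
  total <- 0
  for (m in seq_len(2^n - 1)) {
    bits <- which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    total <- total + (-1)^(length(bits) + 1) * prod(u[bits])
  }
  total
}

# Outcome distribution (down, zero, up) recomputed symbolically from the
# subset expansion of the OR / OR-NOR / NOR-NOR gates plus the leak mixture.
oracle_h_likelihood <- function(x, theta, mode, zeta, q) {
  fire <- x * (mode != "N") * (1 - zeta * (1 - theta))
  p_or_inh <- or_expansion(fire[mode == "I"])
  p_or_act <- or_expansion(fire[mode == "A"])
  n_act <- sum(x == 1 & mode != "N")
  w <- (1 - zeta)^max(n_act, 0)
  if (n_act == 0) w <- 1
  p <- c((1 - w) * p_or_inh + w * q[1],
         (1 - w) * (1 - p_or_act) * (1 - p_or_inh) + w * q[2],
         (1 - w) * p_or_act * (1 - p_or_inh) + w * q[3])
  p / sum(p)
}

# --- exhaustive-enumeration posterior oracle ------------------------------
# Exact P(x_k = 1 | y) for tiny models (<= 3 TFs, <= 2 parents per gene):
# X enumerated, theta integrated on the sampler's grid, per-edge S summed out
# per gene, H summed out through the observation matrix.

oracle_posterior <- function(graph, evidence, hyper = ornor_hyper(),
                             control = ornor_control()) {
  prep <- ornor:::prepare_model(graph, evidence, hyper, control)
  n_tf <- prep$n_tf
  stopifnot(n_tf <= 3)
  grid <- prep$grid
  G <- length(grid)
  q <- prep$hyper$q
  obs <- unname(prep$hyper$obs)

  gene_parents <- lapply(seq_len(prep$n_gene) - 1L, function(j)
    which(prep$e_gene == j))  # edge row indices (1-based into edge vectors)
  stopifnot(all(lengths(gene_parents) <= 2))

  # P(h | x_par, theta_par, s_par) vectorised over the theta grid of one or
  # two parents; returns f(theta...) = sum_h P(y|h) P(h|...).
  gene_factor <- function(j, x) {
    edges <- gene_parents[[j]]
    k <- length(edges)
    tfs <- prep$e_tf[edges] + 1L
    yj <- prep$y[j]
    zj <- prep$zeta[j]
    scomb <- as.matrix(expand.grid(rep(list(0:2), k)))  # 0=I,1=NA,2=A
    out <- array(0, dim = rep(G, k))
    for (r in seq_len(nrow(scomb))) {
      sv <- scomb[r, ]
      spr <- prod(prep$s_prior[cbind(edges, sv + 1L)])
      if (!control$resample_s) {
        if (!all(sv == prep$e_ann[edges])) next
        spr <- 1
      }
      xv <- prep$x_probe[tfs]  # filled by caller below
      # firing probability per parent as a function of its theta
      fires <- lapply(seq_len(k), function(i) {
        if (xv[i] == 1 && sv[i] != 1) 1 - zj * (1 - grid) else rep(0, G)
      })
      dim_one <- function(v) if (k == 1) v else outer(v, rep(1, G))
      dim_two <- function(v) outer(rep(1, G), v)
      DI <- array(1, dim = rep(G, k))
      DA <- array(1, dim = rep(G, k))
      for (i in seq_len(k)) {
        fac <- 1 - fires[[i]]
        facA <- if (sv[i] == 2) fac else rep(1, G)
        facI <- if (sv[i] == 0) fac else rep(1, G)
        if (i == 1) { DA <- DA * dim_one(facA); DI <- DI * dim_one(facI) }
        else { DA <- DA * dim_two(facA); DI <- DI * dim_two(facI) }
      }
      nact <- sum(xv == 1 & sv != 1)
      w <- if (nact == 0) 1 else (1 - zj)^nact
      ph <- list(`-1` = (1 - w) * (1 - DI) + w * q[1],
                 `0`  = (1 - w) * DA * DI + w * q[2],
                 `1`  = (1 - w) * (1 - DA) * DI + w * q[3])
      f <- 0
      for (h in -1:1) f <- f + obs[yj + 2, h + 2] * ph[[as.character(h)]]
      out <- out + spr * f
    }
    out
  }

  gp_arr <- Reduce(function(a, b) outer(a, b), rep(list(prep$gprior), n_tf))
  xs <- as.matrix(expand.grid(rep(list(0:1), n_tf)))
  weights <- numeric(nrow(xs))
  for (r in seq_len(nrow(xs))) {
    x <- xs[r, ]
    prep$x_probe <- x
    L <- array(1, dim = rep(G, n_tf))
    for (j in seq_len(prep$n_gene)) {
      pd <- prep$e_tf[gene_parents[[j]]] + 1L  # parent tf indices
      tbl <- gene_factor(j, x)
      src <- c(pd, setdiff(seq_len(n_tf), pd))
      full <- array(tbl, dim = rep(G, n_tf))
      L <- L * aperm(full, src)
    }
    weights[r] <- sum(L * gp_arr) *
      prod(ifelse(x == 1, prep$hyper$p0, 1 - prep$hyper$p0))
  }
  post <- vapply(seq_len(n_tf), function(i)
    sum(weights[xs[, i] == 1]) / sum(weights), numeric(1))
  stats::setNames(post, prep$tfs)
}

# --- reference full conditionals (plain R, via the exported likelihood) ----

ref_state <- function(prep, seed = 1) {
  set.seed(seed)
  list(x = rbinom(prep$n_tf, 1, 0.5),
       theta = sample(prep$grid, prep$n_tf, replace = TRUE),
       s = if (prep$control$resample_s)
         sample(0:2, length(prep$e_tf), replace = TRUE) else prep$e_ann,
       h = sample(-1:1, prep$n_gene, replace = TRUE))
}

# P(h | parents) for gene j (1-based) under an explicit state.
ref_gene_lik <- function(prep, state, j, x = state$x, theta = state$theta,
                         s = state$s) {
  edges <- which(prep$e_gene == j - 1L)
  tfs <- prep$e_tf[edges] + 1L
  mode <- c("I", "N", "A")[s[edges] + 1L]
  h_likelihood(x[tfs], theta[tfs], mode, zeta = prep$zeta[j],
               q = prep$hyper$q)
}

ref_cond_x <- function(prep, state, i) {
  children <- which(prep$e_tf == i - 1L)
  w1 <- prep$hyper$p0
  w0 <- 1 - prep$hyper$p0
  for (e in children) {
    j <- prep$e_gene[e] + 1L
    x1 <- state$x; x1[i] <- 1L
    x0 <- state$x; x0[i] <- 0L
    hj <- state$h[j] + 2L
    w1 <- w1 * ref_gene_lik(prep, state, j, x = x1)[hj]
    w0 <- w0 * ref_gene_lik(prep, state, j, x = x0)[hj]
  }
  unname(w1 / (w1 + w0))
}

# Marginalised P(x_i = 1 | blanket) with theta_i summed over the prior grid.
ref_cond_x_marginal <- function(prep, state, i) {
  children <- which(prep$e_tf == i - 1L)
  lik1 <- vapply(prep$grid, function(g) {
    l <- 1
    for (e in children) {
      j <- prep$e_gene[e] + 1L
      x1 <- state$x; x1[i] <- 1L
      th <- state$theta; th[i] <- g
      l <- l * ref_gene_lik(prep, state, j, x = x1, theta = th)[state$h[j] + 2L]
    }
    l
  }, numeric(1))
  l0 <- 1
  for (e in children) {
    j <- prep$e_gene[e] + 1L
    x0 <- state$x; x0[i] <- 0L
    l0 <- l0 * ref_gene_lik(prep, state, j, x = x0)[state$h[j] + 2L]
  }
  num <- prep$hyper$p0 * sum(prep$gprior * lik1)
  unname(num / (num + (1 - prep$hyper$p0) * l0))
}

ref_cond_theta <- function(prep, state, i) {
  w <- prep$gprior
  if (state$x[i] == 1) {
    for (e in which(prep$e_tf == i - 1L)) {
      j <- prep$e_gene[e] + 1L
      hj <- state$h[j] + 2L
      lik <- vapply(prep$grid, function(g) {
        th <- state$theta; th[i] <- g
        ref_gene_lik(prep, state, j, theta = th)[hj]
      }, numeric(1))
      w <- w * lik
    }
  }
  w / sum(w)
}

ref_cond_s <- function(prep, state, e) {
  j <- prep$e_gene[e] + 1L
  hj <- state$h[j] + 2L
  w <- vapply(0:2, function(sv) {
    s2 <- state$s; s2[e] <- sv
    prep$s_prior[e, sv + 1L] * ref_gene_lik(prep, state, j, s = s2)[hj]
  }, numeric(1))
  w / sum(w)
}

ref_cond_h <- function(prep, state, j) {
  lik <- ref_gene_lik(prep, state, j)
  w <- unname(prep$hyper$obs)[prep$y[j] + 2L, ] * lik
  w / sum(w)
}
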