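#' Hyper-parameters of the noisy-logic regulation model
#'
#' Collects the fixed quantities of the likelihood. Data-dependent fields left
#' `NULL` are resolved at fit time from the graph and evidence:
#' `zeta_nondeg` via [zeta_nondeg()] and `q` via [q_priors()].
#'
#' @param zeta_deg interaction sensitivity \eqn{\zeta} applied to genes observed
#'   as differentially expressed (default 0.99). \eqn{\zeta = 1 - \xi}; values
#'   in (0, 1].
#' @param zeta_nondeg sensitivity for genes observed unchanged, or `NULL` to
#'   compute it from the data as one tenth of the fraction of network edges
#'   pointing at differentially expressed genes (clipped to `[1e-4, 0.1]`).
#' @param q length-3 numeric, the leak prior \eqn{(q_-, q_0, q_+)}: baseline
#'   probabilities of observing a down-regulated / unchanged / up-regulated
#'   gene irrespective of the network. `NULL` (default) estimates the empirical
#'   frequencies from the evidence over the graph's genes.
#' @param p0 prior TF activation probability (default 0.01).
#' @param theta_a,theta_b shape parameters of the Beta prior on each TF's
#'   activity probability \eqn{\theta} (default Beta(1, 1), uniform). Both must
#'   be >= 1 so the prior is bounded on the sampling grid.
#' @param s_prior_conf,s_prior_na,s_prior_opp prior mass on the annotated edge
#'   sign, on the "not applicable" state, and on the opposite sign, for the
#'   per-edge mode-of-regulation variables (defaults 0.90 / 0.08 / 0.02; must
#'   sum to 1). These allow posterior correction of noisy sign annotations.
#' @param obs 3x3 observation matrix `P(Y = y | H = h)` with rows indexed by
#'   the observed value y in (-1, 0, +1) and columns by the true state h; see
#'   [observation_model()] for the default error rates.
#' @return A list of class `"ornor_hyper"`.
#' @seealso [ornor()], [h_likelihood()]
#' @export
ornor_hyper <- function(zeta_deg = 0.99, zeta_nondeg = NULL, q = NULL,
                        p0 = 0.01, theta_a = 1, theta_b = 1,
                        s_prior_conf = 0.90, s_prior_na = 0.08,
                        s_prior_opp = 0.02, obs = observation_model()) {
  stopifnot(zeta_deg > 0, zeta_deg <= 1, p0 > 0, p0 < 1,
            theta_a >= 1, theta_b >= 1,
            s_prior_conf >= 0, s_prior_na >= 0, s_prior_opp >= 0)
  if (abs(s_prior_conf + s_prior_na + s_prior_opp - 1) > 1e-8)
    stop("S-node prior masses must sum to 1")
  if (!is.null(zeta_nondeg))
    stopifnot(zeta_nondeg > 0, zeta_nondeg <= 1)
  if (!is.null(q)) {
    q <- as.numeric(q)
    if (length(q) != 3L || any(q < 0) || abs(sum(q) - 1) > 1e-8)
      stop("'q' must be three non-negative probabilities summing to 1")
  }
  check_observation_model(obs)
  structure(list(zeta_deg = zeta_deg, zeta_nondeg = zeta_nondeg, q = q,
                 p0 = p0, theta_a = theta_a, theta_b = theta_b,
                 s_prior_conf = s_prior_conf, s_prior_na = s_prior_na,
                 s_prior_opp = s_prior_opp, obs = obs),
            class = "ornor_hyper")
}

#' Gibbs sampler settings
#'
#' @param n_chains number of independent chains (>= 2; default 3).
#' @param check_period iterations between Gelman-Rubin convergence checks
#'   (default 20).
#' @param r_threshold potential-scale-reduction cutoff below which sampling
#'   stops (default 1.1).
#' @param burn_in fraction of each chain discarded before summarising and
#'   before computing the convergence diagnostic (default 0.5).
#' @param max_iter hard iteration cap per chain (default 20000). Reaching it
#'   without convergence flags the fit but does not error.
#' @param min_iter minimum iterations per chain before early stopping is
#'   allowed (default 0); raise it when precise posterior means matter more
#'   than wall time.
#' @param theta_grid number of equispaced grid points on `[0, 1]` used to draw
#'   from the non-conjugate conditional of \eqn{\theta} (default 101).
#' @param resample_s logical; sample the per-edge mode-of-regulation variables
#'   (default `TRUE`), or hold them fixed at the annotated sign.
#' @return A list of class `"ornor_control"`.
#' @export
ornor_control <- function(n_chains = 3L, check_period = 20L, r_threshold = 1.1,
                          burn_in = 0.5, max_iter = 20000L, min_iter = 0L,
                          theta_grid = 101L, resample_s = TRUE) {
  n_chains <- as.integer(n_chains)
  stopifnot(n_chains >= 2L, check_period >= 1L, r_threshold > 1,
            burn_in >= 0, burn_in < 1, max_iter >= 1L, min_iter >= 0L,
            theta_grid >= 2L, is.logical(resample_s))
  structure(list(n_chains = n_chains, check_period = as.integer(check_period),
                 r_threshold = r_threshold, burn_in = burn_in,
                 max_iter = as.integer(max_iter), min_iter = as.integer(min_iter),
                 theta_grid = as.integer(theta_grid),
                 resample_s = isTRUE(resample_s)),
            class = "ornor_control")
}

#' Default observation model P(Y | H)
#'
#' Conditional probability of the observed discretized expression value given
#' the true gene state, encoding typical false-positive and false-negative
#' rates of differential-expression calls (dropped reads, type-I errors in the
#' upstream statistics). Rows are the observed value Y, columns the true state
#' H, both over (-1, 0, +1); each column is a probability distribution over Y.
#'
#' @return A 3x3 numeric matrix with dimnames `c("-1","0","1")`.
#' @export
observation_model <- function() {
  m <- matrix(c(0.945, 0.050, 0.005,
                0.050, 0.900, 0.050,
                0.005, 0.050, 0.945),
              nrow = 3, byrow = TRUE,
              dimnames = list(Y = c("-1", "0", "1"), H = c("-1", "0", "1")))
  m
}

check_observation_model <- function(obs) {
  if (!is.matrix(obs) || !identical(dim(obs), c(3L, 3L)) ||
      any(obs < 0) || any(obs > 1))
    stop("'obs' must be a 3x3 matrix of probabilities")
  if (any(abs(colSums(obs) - 1) > 1e-8))
    stop("each column of 'obs' (distribution of Y given H) must sum to 1")
  invisible(obs)
}

#' Observation likelihood P(Y = y | H = h)
#'
#' @param y observed discretized value, in -1/0/+1.
#' @param h true gene state, in -1/0/+1.
#' @param obs observation matrix, by default [observation_model()].
#' @return The matrix entry, a single probability. Vectorised over `y`/`h`.
#' @examples
#' observation_likelihood(-1, -1)  # 0.945
#' observation_likelihood(0, 0)    # 0.900
#' @export
observation_likelihood <- function(y, h, obs = observation_model()) {
  check_observation_model(obs)
  iy <- match(suppressWarnings(as.numeric(y)), c(-1, 0, 1))
  ih <- match(suppressWarnings(as.numeric(h)), c(-1, 0, 1))
  if (anyNA(iy) || anyNA(ih))
    stop("'y' and 'h' must take values in {-1, 0, +1}")
  obs[cbind(iy, ih)]
}

#' Sensitivity for non-differentially-expressed target genes
#'
#' Computes \eqn{\zeta_{non\text{-}deg}} as one tenth of the fraction of network
#' edges whose target gene carries nonzero evidence, clipped to `[1e-4, 0.1]`.
#' Tying this sensitivity to the share of the network that points at observed
#' DEGs keeps the likelihood tolerant of the (typically vast) majority of
#' unchanged genes.
#'
#' @param graph a [causal_graph()].
#' @param evidence named numeric vector of per-gene values in -1/0/+1; genes
#'   absent from it count as unchanged.
#' @return A single probability in `[1e-4, 0.1]`.
#' @examples
#' g <- causal_graph(c("T1", "T1"), c("g1", "g2"), c("A", "A"))
#' zeta_nondeg(g, c(g1 = 1))  # 1 of 2 edges hits a DEG -> 0.05
#' @export
zeta_nondeg <- function(graph, evidence) {
  stopifnot(inherits(graph, "causal_graph"))
  if (nrow(graph$edges) == 0L)
    stop("network has no edges; cannot calibrate zeta_nondeg")
  evidence <- validate_evidence(evidence)
  ev <- evidence[graph$edges$gene]
  n_to_deg <- sum(!is.na(ev) & ev != 0)
  min(max(0.1 * n_to_deg / nrow(graph$edges), 1e-4), 0.1)
}

#' Empirical leak priors (q-, q0, q+)
#'
#' Estimates the baseline outcome probabilities as the frequencies of
#' down-regulated, unchanged and up-regulated values among all genes of the
#' graph (genes missing from the evidence count as unchanged).
#'
#' @inheritParams zeta_nondeg
#' @return Named numeric of length 3: `q_minus`, `q_zero`, `q_plus`.
#' @export
q_priors <- function(graph, evidence) {
  stopifnot(inherits(graph, "causal_graph"))
  evidence <- validate_evidence(evidence)
  ev <- evidence[graph$gene_ids]
  ev[is.na(ev)] <- 0
  n <- length(ev)
  c(q_minus = sum(ev == -1) / n,
    q_zero  = sum(ev == 0) / n,
    q_plus  = sum(ev == 1) / n)
}

# Fill the data-dependent hyper-parameter fields for a concrete data set.
resolve_hyper <- function(hyper, graph, evidence) {
  stopifnot(inherits(hyper, "ornor_hyper"))
  if (is.null(hyper$zeta_nondeg))
    hyper$zeta_nondeg <- zeta_nondeg(graph, evidence)
  if (is.null(hyper$q))
    hyper$q <- unname(q_priors(graph, evidence))
  hyper
}
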