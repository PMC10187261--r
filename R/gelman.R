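#' Gelman-Rubin potential scale reduction factor
#'
#' Compares the between-chain and within-chain variances of a scalar quantity
#' sampled by several independent MCMC chains. Values near 1 indicate that the
#' chains have mixed; the sampler's stopping rule requires R < 1.1 for every
#' variable in the model.
#'
#' The estimate is \eqn{\hat R = \sqrt{\hat V / W}} with
#' \eqn{\hat V = \frac{n-1}{n} W + (1 + \frac{1}{m}) \frac{B}{n}}, where `W` is
#' the mean within-chain variance and `B/n` the variance of the chain means
#' (`m` chains of `n` retained samples). Discrete variables are monitored on
#' their numeric coding. By convention, chains that are all constant with equal
#' means give R = 1 exactly (trivial convergence); constant chains with
#' different means give `Inf`.
#'
#' @param chains numeric matrix with one column per chain (rows are
#'   iterations), or a list of equal-length numeric vectors.
#' @param burn_in fraction of initial samples to discard (default 0).
#' @return The scalar potential scale reduction factor.
#' @examples
#' set.seed(1)
#' gelman_rubin(cbind(rnorm(1000), rnorm(1000)))          # ~1
#' gelman_rubin(cbind(rnorm(1000), rnorm(1000, 10)))      # >> 1.1
#' gelman_rubin(cbind(rep(2, 50), rep(2, 50)))            # exactly 1
#' @export
gelman_rubin <- function(chains, burn_in = 0) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1L)
      stop("all chains must have the same length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains)
  if (m < 2L) stop("at least two chains are required")
  stopifnot(burn_in >= 0, burn_in < 1)
  keep <- seq.int(floor(nrow(chains) * burn_in) + 1L, nrow(chains))
  if (length(keep) < 2L) stop("each chain needs at least two retained samples")
  chains <- chains[keep, , drop = FALSE]
  n <- nrow(chains)

  mu <- colMeans(chains)
  W <- mean(apply(chains, 2, stats::var))
  vb <- stats::var(mu)  # = B / n
  if (W < 1e-18) return(if (vb < 1e-18) 1 else Inf)
  vhat <- (n - 1) / n * W + (1 + 1 / m) * vb
  sqrt(vhat / W)
}
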