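#' Noisy OR-NOR outcome likelihood of a gene's true state
#'
#' Computes the three outcome probabilities \eqn{P(H = -1), P(H = 0),
#' P(H = +1)} of a gene's true expression state given the activity of its
#' parent TFs. Regulation follows noisy Boolean logic: down-regulation fires
#' when at least one active inhibitor fires (noisy OR); up-regulation requires
#' at least one active activator to fire while no inhibitor fires (noisy
#' OR gated by NOR); the unchanged outcome is the complementary NOR-NOR event.
#'
#' An active, applicable parent (\eqn{x_i = 1}, mode not `"N"`) fires with
#' probability \eqn{1 - \zeta (1 - \theta_i)}; inactive parents and edges whose
#' latent mode is "not applicable" never fire. The pure-logic outcome
#' distribution is mixed with the leak prior \eqn{(q_-, q_0, q_+)} with weight
#' \eqn{\xi^{n_{act}}} where \eqn{\xi = 1 - \zeta} and \eqn{n_{act}} is the
#' number of active applicable parents, so that a gene with no active regulator
#' falls back on the leak distribution exactly, and small \eqn{\zeta} (as used
#' for unchanged genes) pulls the distribution toward the leak priors. The
#' three probabilities sum to one by construction.
#'
#' @param x 0/1 vector of parent TF activity states.
#' @param theta parent activity probabilities in `[0, 1]`, same length as `x`.
#' @param mode per-parent mode of regulation: `"A"` (activation), `"I"`
#'   (inhibition) or `"N"` (not applicable).
#' @param zeta interaction sensitivity \eqn{\zeta \in (0, 1]} for this gene
#'   (0.99 for observed DEGs; see [zeta_nondeg()] for unchanged genes).
#' @param q leak prior, length-3 `(q_minus, q_zero, q_plus)`.
#' @return Named numeric of length 3: `down`, `zero`, `up`; sums to 1.
#' @examples
#' # one active inhibitor at theta = 0.8
#' h_likelihood(x = 1, theta = 0.8, mode = "I", zeta = 0.99,
#'              q = c(0.05, 0.9, 0.05))
#' # no active parent: the leak prior itself
#' h_likelihood(x = 0, theta = 0.8, mode = "A", zeta = 0.99,
#'              q = c(0.05, 0.9, 0.05))
#' @export
h_likelihood <- function(x, theta, mode, zeta = 0.99, q = c(1, 1, 1) / 3) {
  stopifnot(length(x) == length(theta), length(theta) == length(mode),
            zeta > 0, zeta <= 1, length(q) == 3, all(q >= 0),
            abs(sum(q) - 1) < 1e-8)
  if (length(x)) {
    stopifnot(all(x %in% c(0, 1)), all(theta >= 0), all(theta <= 1))
    mode <- normalize_mode(mode, allow_na_mode = TRUE)
  }
  xi <- 1 - zeta
  fire <- x * (mode != "N") * (1 - zeta * (1 - theta))
  d_act <- prod(1 - fire[mode == "A"])
  d_inh <- prod(1 - fire[mode == "I"])
  n_act <- sum(x == 1 & mode != "N")
  w <- if (n_act == 0) 1 else xi^n_act
  p <- c(down = (1 - w) * (1 - d_inh) + w * q[1],
         zero = (1 - w) * d_act * d_inh + w * q[2],
         up   = (1 - w) * (1 - d_act) * d_inh + w * q[3])
  p <- pmax(p, 0)
  p / sum(p)
}
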