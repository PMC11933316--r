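#' Negative-binomial log-likelihood kernel
#'
#' Log pmf of the negative binomial in its mean/overdispersion
#' parameterization, `Var = mu + alpha * mu^2` (size = `1/alpha`). The
#' continuous limit `alpha -> 0` is the Poisson log pmf, used below
#' `alpha < 1e-12` for numerical stability of the size parameter.
#'
#' @param k non-negative integer count (vectorized).
#' @param mu positive mean (vectorized).
#' @param alpha non-negative overdispersion (scalar or vectorized).
#' @return log P(K = k), vectorized over the inputs.
#' @examples
#' nb_loglik(0, 1, 1)     # log(1/2)
#' nb_loglik(0, 1, 0)     # -1, the Poisson limit
#' @export
nb_loglik <- function(k, mu, alpha) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(alpha < 0)) stop("alpha must be non-negative")
  if (any(k < 0) || any(k != floor(k)))
    stop("k must be non-negative integer")
  n <- max(length(k), length(mu), length(alpha))
  k <- rep_len(k, n); mu <- rep_len(mu, n); alpha <- rep_len(alpha, n)
  out <- numeric(n)
  pois <- alpha < 1e-12
  if (any(pois)) out[pois] <- stats::dpois(k[pois], mu[pois], log = TRUE)
  if (any(!pois))
    out[!pois] <- stats::dnbinom(k[!pois], size = 1 / alpha[!pois],
                                 mu = mu[!pois], log = TRUE)
  out
}
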