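# Model parameters, the (h, rho, pi) <-> (sigma_a2, sigma_b2)
# re-parameterization, hyper-priors and the PVE/PGE definitions.
#
# The model for a quantitative trait y on n individuals and p markers is
#
#   y = 1 mu + X beta + u + e,   u ~ N(0, sigma_b2/tau K),
#   e ~ N(0, tau^{-1} I),        beta_j ~ pi N(0, sigma_a2/tau) + (1-pi) d0,
#
# with X centered and K the relatedness matrix. Variances sigma_a2 and
# sigma_b2 are expressed relative to the error variance 1/tau. The
# hyper-parameters are re-expressed as h (approximate expected PVE),
# rho (approximate expected PGE) and log pi; these have uniform priors
# (log pi over [log(1/p), 0]).

#' Population-style sample variance V(x)
#'
#' `V(x) = mean((x - mean(x))^2)` (divisor n, not n - 1). This is the
#' variance function entering the PVE and PGE definitions.
#'
#' @param x numeric vector, length >= 1.
#' @return scalar variance.
#' @export
sample_variance <- function(x) {
  if (length(x) < 1L) stop("sample_variance: empty vector")
  m <- mean(x)
  mean((x - m)^2)
}

#' Per-draw PVE and PGE from realized genetic components
#'
#' PVE is the proportion of phenotypic variance explained jointly by the
#' sparse (`X beta`) and random (`u`) genetic terms,
#' `V(g + u) / (V(g + u) + 1/tau)`; PGE is the share of that genetic
#' variance attributable to the sparse term, `V(g) / V(g + u)` (defined as
#' 0 when `V(g + u) = 0`, and clamped to \[0, 1\]).
#'
#' @param g_sparse realized sparse component `X beta`, length n.
#' @param u realized random effects, length n.
#' @param tau residual precision (> 0).
#' @return list with `pve` and `pge`, both in \[0, 1\].
#' @export
compute_pve_pge <- function(g_sparse, u, tau) {
  if (length(g_sparse) != length(u))
    stop("g_sparse and u must have the same length")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  v_tot <- sample_variance(g_sparse + u)
  v_g <- sample_variance(g_sparse)
  pve <- v_tot / (v_tot + 1 / tau)
  pge <- if (v_tot > 0) min(1, max(0, v_g / v_tot)) else 0
  list(pve = pve, pge = pge)
}

#' Map (h, rho, pi) to the variance components (sigma_a2, sigma_b2)
#'
#' With `G = h / (1 - h)`:
#' `sigma_a2 = rho * G / (p * pi * s_a)` and
#' `sigma_b2 = (1 - rho) * G / s_b`. The term `p * pi * s_a * sigma_a2` is
#' the expected genetic variance (relative to the error variance)
#' contributed by the sparse effects; `s_b * sigma_b2` the analogue for the
#' random effects. `rho = 1` gives BVSR (`sigma_b2 = 0`), `rho = 0` the LMM
#' (`sigma_a2 = 0`).
#'
#' @param h approximate expected PVE, in \[0, 1).
#' @param rho approximate expected PGE, in \[0, 1\].
#' @param pi prior inclusion proportion, in (0, 1\].
#' @param p number of markers.
#' @param s_a average genotype variance across markers.
#' @param s_b mean diagonal of the relatedness matrix.
#' @return list with `sigma_a2` and `sigma_b2`.
#' @export
hyper_to_variances <- function(h, rho, pi, p, s_a, s_b) {
  if (h >= 1) stop("h = 1 implies infinite genetic variance")
  if (h < 0 || rho < 0 || rho > 1) stop("h in [0,1), rho in [0,1] required")
  if (pi <= 0 || pi > 1) stop("pi must lie in (0, 1]")
  if (rho > 0 && s_a <= 0) stop("s_a must be positive when rho > 0")
  if (rho < 1 && s_b <= 0) stop("s_b must be positive when rho < 1")
  G <- h / (1 - h)
  list(
    sigma_a2 = if (rho > 0) rho * G / (p * pi * s_a) else 0,
    sigma_b2 = if (rho < 1) (1 - rho) * G / s_b else 0
  )
}

#' Map variance components back to (h, rho)
#'
#' Inverse of [hyper_to_variances()]: with expected relative variances
#' `A = p * pi * s_a * sigma_a2` (sparse) and `B = s_b * sigma_b2` (random),
#' `h = (A + B) / (1 + A + B)` and `rho = A / (A + B)` (`rho = 0` when both
#' are zero).
#'
#' @param sigma_a2,sigma_b2 variance components relative to the error
#'   variance.
#' @inheritParams hyper_to_variances
#' @return list with `h` and `rho`.
#' @export
variances_to_hyper <- function(sigma_a2, sigma_b2, pi, p, s_a, s_b) {
  A <- p * pi * s_a * sigma_a2
  B <- s_b * sigma_b2
  tot <- A + B
  list(h = tot / (1 + tot), rho = if (tot > 0) A / tot else 0)
}

#' Construct a hyper-parameter state
#'
#' Bundles `(h, rho, log_pi)` with the derived variance components, kept
#' consistent through [hyper_to_variances()].
#'
#' @param h,rho hyper-parameters in \[0, 1\] (`h < 1`).
#' @param log_pi log prior inclusion proportion, in \[log(1/p), 0\].
#' @inheritParams hyper_to_variances
#' @return An object of class `hyper_state`.
#' @export
hyper_state <- function(h, rho, log_pi, p, s_a, s_b) {
  v <- hyper_to_variances(h, rho, exp(log_pi), p, s_a, s_b)
  structure(list(h = h, rho = rho, log_pi = log_pi,
                 sigma_a2 = v$sigma_a2, sigma_b2 = v$sigma_b2,
                 p = p, s_a = s_a, s_b = s_b),
            class = "hyper_state")
}

#' Log prior density of the hyper-parameters
#'
#' Independent uniform priors: `h ~ U(0, 1)`, `rho ~ U(0, 1)` and
#' `log pi ~ U(log(1/p), 0)` (so the expected number of included markers
#' ranges from 1 to p). Returns `-Inf` outside the support. The intercept
#' and residual precision carry improper priors (flat, and the
#' shape/rate -> 0 Gamma limit) which are integrated out inside the
#' marginal likelihood and contribute no density term here.
#'
#' @param state a [hyper_state()], or a list with `h`, `rho`, `log_pi`.
#' @param p number of markers.
#' @return scalar log density.
#' @export
log_prior_hyper <- function(state, p) {
  h <- state$h; rho <- state$rho; lp <- state$log_pi
  if (!is.finite(h) || h <= 0 || h >= 1) return(-Inf)
  if (!is.finite(rho) || rho < 0 || rho > 1) return(-Inf)
  if (!is.finite(lp) || lp < log(1 / p) || lp > 0) return(-Inf)
  # uniform densities: 1 * 1 * 1/log(p)
  -log(log(p))
}

# log P(gamma | pi) = q log(pi) + (p - q) log(1 - pi)
log_prior_gamma <- function(q, p, log_pi) {
  pi <- exp(log_pi)
  if (pi >= 1) return(if (q == p) 0 else -Inf)
  q * log_pi + (p - q) * log1p(-pi)
}
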