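# Likelihood computations in the kinship eigenbasis.
#
# One eigendecomposition K = U diag(delta) U' turns the covariance
# tau^{-1}(sigma_b2 K + I) diagonal in the rotated coordinates, so every
# marginal-likelihood evaluation is linear in n (plus cubic in the small
# number q of included markers). The sparse effects beta_gamma, the
# intercept mu (flat prior) and the residual precision tau (improper Gamma
# limit) are integrated out analytically; see the C++ core and the methods
# vignette for the closed form.

#' Rotate phenotype and intercept into the kinship eigenbasis
#'
#' Computes `y_t = U' y` and `ones_t = U' 1` and sets up a lazy per-marker
#' cache for `x_t = U' x_j`. The orthonormal rotation preserves norms, so
#' `||y_t|| = ||y||`.
#'
#' @param y numeric vector (no missing values) or `phenotype_vector` with
#'   complete values.
#' @param kin a [kinship()] object whose dimension matches `length(y)`.
#' @param genotypes optional centered [genotype_matrix()] backing the
#'   on-demand marker cache.
#' @return An object of class `transformed_data` with `y_t`, `ones_t`,
#'   `eigenvalues`, `U`, `s_b`, `n` and the marker cache.
#' @export
transform_data <- function(y, kin, genotypes = NULL) {
  if (inherits(y, "phenotype_vector")) y <- y$values
  y <- as.numeric(y)
  if (anyNA(y))
    stop("transform_data requires complete phenotypes; subset first")
  if (!inherits(kin, "kinship")) stop("kin must be a kinship object")
  n <- length(y)
  if (nrow(kin$K) != n)
    stop("dimension mismatch: length(y) = ", n, ", kinship is ",
         nrow(kin$K), " x ", ncol(kin$K))
  U <- kin$eigenvectors
  structure(list(
    y_t = drop(crossprod(U, y)),
    ones_t = drop(crossprod(U, rep(1, n))),
    eigenvalues = kin$eigenvalues,
    U = U,
    s_b = kin$s_b,
    n = n,
    genotypes = genotypes,
    x_cache = new.env(parent = emptyenv())
  ), class = "transformed_data")
}

#' Transformed genotype column, cached
#'
#' `U' x_j` for marker `j`, computed on first use and cached.
#'
#' @param td a [transform_data()] object with genotypes attached.
#' @param j marker index.
#' @return numeric vector of length n.
#' @export
x_transformed <- function(td, j) {
  key <- as.character(j)
  if (!is.null(td$x_cache[[key]])) return(td$x_cache[[key]])
  if (is.null(td$genotypes)) stop("no genotypes attached to transformed data")
  v <- drop(crossprod(td$U, td$genotypes$dosages[, j]))
  td$x_cache[[key]] <- v
  v
}

# assemble the n x q transformed design for an index set
gamma_design <- function(td, gamma) {
  q <- length(gamma)
  if (q == 0L) return(matrix(0, td$n, 0L))
  out <- matrix(0, td$n, q)
  for (k in seq_len(q)) out[, k] <- x_transformed(td, gamma[k])
  out
}

#' Log marginal likelihood of a sparse configuration
#'
#' `log P(y | gamma, h, rho, pi)` with the sparse effects, intercept and
#' residual precision integrated out analytically. The value is fully
#' normalized (with respect to the improper flat-mu and 1/tau priors), so
#' differences between states are exact Metropolis-Hastings log ratios and
#' the absolute value can be checked against numerical quadrature.
#'
#' @param td a [transform_data()] object.
#' @param gamma integer vector of included marker indices (`q <= n - 2`).
#' @param hyper a [hyper_state()] (or list with `sigma_a2`, `sigma_b2`).
#' @return list with `log_marginal` and `q`.
#' @export
log_marginal_likelihood <- function(td, gamma, hyper) {
  q <- length(gamma)
  if (q > td$n - 2L)
    stop("q = ", q, " exceeds n - 2 = ", td$n - 2L,
         ": flat-intercept and tau integration need residual degrees of freedom")
  Xt <- gamma_design(td, gamma)
  val <- cpp_logml(td$y_t, td$ones_t, td$eigenvalues, Xt,
                   hyper$sigma_a2, hyper$sigma_b2)
  list(log_marginal = val, q = q)
}

#' REML estimation of the pure linear mixed model
#'
#' Maximizes the restricted log-likelihood of the LMM (no sparse effects)
#' over the variance ratio `sigma_b2` by 1-D optimization on the log scale.
#' With improper flat-intercept and 1/tau priors the restricted likelihood
#' coincides with the `gamma = {}` marginal likelihood, which is what is
#' optimized here. The PVE estimate is `s_b * sigma_b2 / (s_b * sigma_b2 + 1)`
#' and its standard error comes from the observed information on the
#' log-sigma_b2 scale by the delta method.
#'
#' @param td a [transform_data()] object.
#' @param grid_bounds bracket for `sigma_b2` (default `c(1e-5, 1e5)`, the
#'   usual variance-ratio range in LMM software).
#' @return list with `sigma_b2_hat`, `pve_hat`, `se_pve`, `loglik`,
#'   `boundary` (flag: optimum at or beyond the bracket, or likelihood flat).
#' @export
reml_lmm <- function(td, grid_bounds = c(1e-5, 1e5)) {
  if (td$n < 3L) stop("need at least 3 individuals")
  Xt0 <- matrix(0, td$n, 0L)
  ll <- function(loglam)
    cpp_logml(td$y_t, td$ones_t, td$eigenvalues, Xt0, 0, exp(loglam))
  lb <- log(grid_bounds[1]); ub <- log(grid_bounds[2])
  opt <- optimize(ll, c(lb, ub), maximum = TRUE, tol = 1e-8)
  loglam <- opt$maximum
  llmax <- opt$objective
  # flat likelihood (e.g. K = 0: all eigenvalues zero) or boundary optimum
  probe <- c(lb, (lb + ub) / 2, ub)
  flat <- diff(range(vapply(probe, ll, 0), llmax)) < 1e-10
  boundary <- flat || (loglam - lb < 1e-3) || (ub - loglam < 1e-3)
  lam <- exp(loglam)
  pve <- td$s_b * lam / (td$s_b * lam + 1)
  se <- NA_real_
  if (!flat) {
    eps <- 1e-3
    d2 <- (ll(loglam + eps) - 2 * llmax + ll(loglam - eps)) / eps^2
    if (is.finite(d2) && d2 < 0) {
      dpve <- td$s_b * lam / (td$s_b * lam + 1)^2
      se <- abs(dpve) * sqrt(-1 / d2)
    }
  }
  list(sigma_b2_hat = lam, pve_hat = pve, se_pve = se,
       loglik = llmax, boundary = boundary)
}

#' Draw (tau, mu, beta, u) from their conditional given a state
#'
#' Exact joint conditional draw given `(gamma, hyper, y)`: `tau` from its
#' Gamma conditional, `(mu, beta_gamma)` from their Gaussian conditional
#' (generalized least squares mean, covariance `A^{-1}/tau` in the
#' transformed basis), and `u` coordinatewise in the eigenbasis with mean
#' `sigma_b2 delta_i d_i r_i` and variance `sigma_b2 delta_i d_i / tau`,
#' where the residual is `y - 1 mu - X beta`.
#'
#' @param td a [transform_data()] object.
#' @param gamma integer vector of included marker indices.
#' @param hyper a [hyper_state()].
#' @param ndraws number of draws.
#' @return list with vectors `tau`, `mu`, `pve`, `pge` and matrices `beta`
#'   (ndraws x q), `u`, `g_sparse` (ndraws x n, original basis).
#' @export
sample_effects_given_state <- function(td, gamma, hyper, ndraws = 1L) {
  Xt <- gamma_design(td, gamma)
  out <- cpp_sample_effects(td$y_t, td$ones_t, td$eigenvalues, Xt,
                            hyper$sigma_a2, hyper$sigma_b2, as.integer(ndraws))
  # rotate random effects and sparse component back to the original basis
  out$u <- t(td$U %*% t(out$ut))
  out$g_sparse <- t(td$U %*% t(out$gt))
  out$ut <- NULL
  out$gt <- NULL
  out
}
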