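# Independent oracles used across the suite. These deliberately avoid the
# eigen-trick code path: dense matrix algebra and brute-force numerical
# integration only.

# Marginal likelihood via dense covariance algebra: fold the sparse-effect
# prior into the covariance, integrate the intercept by GLS and the
# residual precision by the Gamma integral.
logml_dense_oracle <- function(y, X, K, sigma_a2, sigma_b2) {
  n <- length(y)
  H <- sigma_b2 * K + diag(n)
  Sig <- H + sigma_a2 * tcrossprod(X)
  Si <- solve(Sig)
  o <- rep(1, n)
  s11 <- drop(crossprod(o, Si %*% o))
  r <- drop(Si %*% y)
  Sq <- sum(y * r) - sum(o * r)^2 / s11
  ld <- as.numeric(determinant(Sig, logarithm = TRUE)$modulus)
  -((n - 1) / 2) * log(2 * pi) + lgamma((n - 1) / 2) +
    ((n - 1) / 2) * log(2) - 0.5 * ld - 0.5 * log(s11) -
    ((n - 1) / 2) * log(Sq)
}

# Marginal likelihood by midpoint quadrature over (mu, beta, log tau), with
# the model's priors: beta ~ N(0, sigma_a2/tau), mu flat, p(tau) = 1/tau
# (density 1 in log tau). Accurate to well under 1e-3 log units for the
# n = 6 instances it is used on.
logml_quad_oracle <- function(y, X, K, sigma_a2, sigma_b2,
                              mu_lim = 8, beta_lim = 8, lt_lim = c(-12, 9),
                              n_mu = 121, n_beta = 101, n_lt = 161) {
  n <- length(y)
  q <- ncol(X)
  H <- sigma_b2 * K + diag(n)
  Hi <- solve(H)
  ldH <- as.numeric(determinant(H, logarithm = TRUE)$modulus)
  W <- cbind(1, X)
  WtHiW <- crossprod(W, Hi %*% W)
  WtHiy <- drop(crossprod(W, Hi %*% y))
  yHiy <- drop(crossprod(y, Hi %*% y))
  mu_g <- seq(mean(y) - mu_lim, mean(y) + mu_lim, length.out = n_mu)
  d_mu <- mu_g[2] - mu_g[1]
  lt_g <- seq(lt_lim[1], lt_lim[2], length.out = n_lt)
  d_lt <- lt_g[2] - lt_g[1]
  if (q > 0) {
    b_g <- seq(-beta_lim, beta_lim, length.out = n_beta)
    d_b <- b_g[2] - b_g[1]
    theta <- as.matrix(expand.grid(c(list(mu_g), rep(list(b_g), q))))
    vol <- d_mu * d_b^q
  } else {
    theta <- matrix(mu_g, ncol = 1)
    vol <- d_mu
  }
  quad <- rowSums((theta %*% WtHiW) * theta) - 2 * drop(theta %*% WtHiy) + yHiy
  bb <- if (q > 0) rowSums(theta[, -1, drop = FALSE]^2) else
    numeric(nrow(theta))
  total <- -Inf
  for (lt in lt_g) {
    tau <- exp(lt)
    ll <- 0.5 * n * (lt - log(2 * pi)) - 0.5 * ldH - 0.5 * tau * quad
    if (q > 0)
      ll <- ll + 0.5 * q * (lt - log(2 * pi) - log(sigma_a2)) -
        0.5 * tau * bb / sigma_a2
    m <- max(ll)
    if (is.finite(m)) {
      s <- m + log(sum(exp(ll - m))) + log(vol) + log(d_lt)
      mm <- max(total, s)
      total <- mm + log(exp(total - mm) + exp(s - mm))
    }
  }
  total
}

# Exhaustive posterior over all subsets of 1:p for fixed hyper-parameters.
enumerate_gamma_posterior <- function(td, p, hyper) {
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  lp <- vapply(subsets, function(gm) {
    log_marginal_likelihood(td, gm, hyper)$log_marginal +
      length(gm) * hyper$log_pi +
      (p - length(gm)) * log1p(-exp(hyper$log_pi))
  }, 0)
  w <- exp(lp - max(lp))
  list(subsets = subsets, prob = w / sum(w))
}

# small centered genotype + kinship + phenotype fixture
make_small_data <- function(n, p, seed, maf = c(0.2, 0.5), pve = 0.5,
                            S = max(1L, round(p / 4))) {
  set.seed(seed)
  g <- impute_and_center(simulate_genotypes(n, p, maf_range = maf))
  kin <- compute_kinship(g)
  sim <- simulate_scenario1(g, S, pve)
  list(g = g, kin = kin, y = sim$phenotype$values, sim = sim)
}

default_cfg_list <- function(cfg = proposal_config(), p = 10L) {
  bslmm:::cfg_to_list(cfg, p)
}
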