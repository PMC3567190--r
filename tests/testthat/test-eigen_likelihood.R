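# the computational core: eigenbasis transform, analytic marginal
# likelihood (vs quadrature and dense oracles), REML, conditional draws

test_that("transform_data rotates correctly and preserves norms", {
  set.seed(21)
  n <- 15
  k <- kinship(diag(n))
  y <- rnorm(n)
  td <- transform_data(y, k)
  # for K = I the eigenvectors are an (arbitrary) orthonormal basis of a
  # fully degenerate eigenspace; the rotation must still be exact
  expect_equal(drop(k$eigenvectors %*% td$y_t), y, tolerance = 1e-12)
  expect_equal(sort(abs(td$y_t)), sort(abs(y)), tolerance = 1e-12)
  expect_equal(sum(td$y_t^2), sum(y^2), tolerance = 1e-8)

  g <- impute_and_center(simulate_genotypes(n, 30))
  k <- compute_kinship(g)
  td <- transform_data(y, k, g)
  expect_equal(sum(td$y_t^2), sum(y^2), tolerance = 1e-8)
  # lazy cache matches the direct product
  v <- x_transformed(td, 7)
  expect_equal(v, drop(crossprod(k$eigenvectors, g$dosages[, 7])),
               tolerance = 1e-10)
  expect_error(transform_data(rnorm(n + 1), k), "dimension mismatch")
})

test_that("empty model with sigma_b2 = 0 equals the iid closed form", {
  set.seed(22)
  n <- 12
  y <- rnorm(n)
  k <- kinship(diag(n))
  td <- transform_data(y, k)
  hy <- list(sigma_a2 = 0.3, sigma_b2 = 0)
  got <- log_marginal_likelihood(td, integer(0), hy)$log_marginal
  expected <- -((n - 1) / 2) * log(2 * pi) + lgamma((n - 1) / 2) +
    ((n - 1) / 2) * log(2) - 0.5 * log(n) -
    ((n - 1) / 2) * log(sum((y - mean(y))^2))
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("sigma_a2 -> 0 collapses a nonempty model onto the empty one", {
  d <- make_small_data(20, 10, seed = 23)
  td <- transform_data(d$y, d$kin, d$g)
  base <- log_marginal_likelihood(td, integer(0),
                                  list(sigma_a2 = 0, sigma_b2 = 0.4))
  for (sa2 in c(1e-4, 1e-6, 1e-8)) {
    v <- log_marginal_likelihood(td, c(3L),
                                 list(sigma_a2 = sa2, sigma_b2 = 0.4))
    expect_equal(v$log_marginal, base$log_marginal, tolerance = 100 * sa2)
  }
})

test_that("analytic marginal matches quadrature on tiny instances", {
  # n = 6, q in {0,1,2}; tolerance 1e-3 in log units
  set.seed(24)
  for (rep in 1:8) {
    q <- rep %% 3
    d <- make_small_data(6, 4, seed = 240 + rep, maf = c(0.3, 0.5))
    # standardize the fixture phenotype so the oracle's fixed quadrature
    # grids resolve the posterior (the grid ranges assume unit scale)
    d$y <- d$y / sd(d$y)
    td <- transform_data(d$y, d$kin, d$g)
    gamma <- if (q > 0) sample(4, q) else integer(0)
    hy <- hyper_state(runif(1, 0.3, 0.7), runif(1, 0.3, 0.7),
                      runif(1, log(1 / 4), 0) / 2, 4, d$g$s_a, d$kin$s_b)
    got <- log_marginal_likelihood(td, gamma, hy)$log_marginal
    want <- logml_quad_oracle(d$y, d$g$dosages[, gamma, drop = FALSE],
                              d$kin$K, hy$sigma_a2, hy$sigma_b2)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("eigen-trick equals dense-matrix evaluation within 1e-8", {
  set.seed(25)
  for (rep in 1:6) {
    n <- sample(10:50, 1)
    d <- make_small_data(n, 40, seed = 250 + rep)
    td <- transform_data(d$y, d$kin, d$g)
    q <- sample(0:5, 1)
    gamma <- if (q > 0) sample(40, q) else integer(0)
    hy <- hyper_state(runif(1, 0.1, 0.9), runif(1, 0.1, 0.9),
                      runif(1) * log(1 / 40), 40, d$g$s_a, d$kin$s_b)
    got <- log_marginal_likelihood(td, gamma, hy)$log_marginal
    want <- logml_dense_oracle(d$y, d$g$dosages[, gamma, drop = FALSE],
                               d$kin$K, hy$sigma_a2, hy$sigma_b2)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant under joint permutation of individuals", {
  d <- make_small_data(18, 12, seed = 26)
  hy <- hyper_state(0.4, 0.6, log(0.2), 12, d$g$s_a, d$kin$s_b)
  td1 <- transform_data(d$y, d$kin, d$g)
  v1 <- log_marginal_likelihood(td1, c(2L, 5L), hy)$log_marginal
  perm <- sample(18)
  g2 <- d$g; g2$dosages <- d$g$dosages[perm, ]
  k2 <- kinship(d$kin$K[perm, perm])
  td2 <- transform_data(d$y[perm], k2, g2)
  v2 <- log_marginal_likelihood(td2, c(2L, 5L), hy)$log_marginal
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("rescaling y shifts the log marginal by a gamma-independent constant", {
  d <- make_small_data(24, 15, seed = 27)
  hy <- hyper_state(0.5, 0.5, log(0.1), 15, d$g$s_a, d$kin$s_b)
  td1 <- transform_data(d$y, d$kin, d$g)
  td2 <- transform_data(3.2 * d$y, d$kin, d$g)
  gammas <- list(integer(0), 1L, c(2L, 9L), c(1L, 4L, 11L))
  shifts <- vapply(gammas, function(gm)
    log_marginal_likelihood(td2, gm, hy)$log_marginal -
      log_marginal_likelihood(td1, gm, hy)$log_marginal, 0)
  expect_equal(diff(range(shifts)), 0, tolerance = 1e-9)
  expect_equal(shifts[1], -(24 - 1) * log(3.2), tolerance = 1e-8)
})

test_that("q > n - 2 is rejected", {
  d <- make_small_data(6, 10, seed = 28)
  td <- transform_data(d$y, d$kin, d$g)
  hy <- hyper_state(0.5, 0.5, log(0.5), 10, d$g$s_a, d$kin$s_b)
  expect_error(log_marginal_likelihood(td, 1:5, hy), "exceeds n - 2")
})

test_that("REML recovers a known variance ratio and flags degeneracy", {
  set.seed(29)
  ests <- replicate(10, {
    g <- impute_and_center(simulate_genotypes(300, 400))
    kin <- compute_kinship(g)
    # LMM generative model: u ~ N(0, sigma_b2 K), sigma_b2 = 1, tau = 1
    e <- eigen(kin$K, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    u <- drop(e$vectors %*% (sqrt(lam) * rnorm(300)))
    y <- 2 + u + rnorm(300)
    td <- transform_data(y, kin)
    reml_lmm(td)$sigma_b2_hat
  })
  expect_lt(abs(median(ests) - 1), 0.25)

  # K = 0: flat restricted likelihood -> boundary flag
  td0 <- transform_data(rnorm(20), kinship(matrix(0, 20, 20)))
  expect_true(reml_lmm(td0)$boundary)

  # optimality: restricted likelihood at the optimum beats random points
  d <- make_small_data(80, 100, seed = 291)
  td <- transform_data(d$y, d$kin)
  fit <- reml_lmm(td)
  ll <- function(lam) log_marginal_likelihood(
    td, integer(0), list(sigma_a2 = 0, sigma_b2 = lam))$log_marginal
  for (lam in exp(runif(10, log(1e-4), log(1e4))))
    expect_gte(fit$loglik + 1e-8, ll(lam))
})

test_that("conditional effect draws match their analytic moments", {
  d <- make_small_data(25, 8, seed = 30)
  td <- transform_data(d$y, d$kin, d$g)
  hy <- hyper_state(0.6, 0.7, log(0.3), 8, d$g$s_a, d$kin$s_b)

  # sigma_b2 = 0 -> u identically zero
  hy0 <- hyper_state(0.6, 1, log(0.3), 8, d$g$s_a, d$kin$s_b)
  set.seed(1)
  out0 <- sample_effects_given_state(td, c(1L, 2L), hy0, ndraws = 5)
  expect_equal(max(abs(out0$u)), 0)

  # posterior mean of beta matches the GLS formula (3 MC standard errors)
  gamma <- c(2L, 5L)
  set.seed(2)
  out <- sample_effects_given_state(td, gamma, hy, ndraws = 10000)
  n <- 25
  H <- hy$sigma_b2 * d$kin$K + diag(n)
  Hi <- solve(H)
  W <- cbind(1, d$g$dosages[, gamma])
  # ridge on the effect coordinates only, not the intercept
  M <- crossprod(W, Hi %*% W) + diag(c(0, 1, 1)) / hy$sigma_a2
  theta_hat <- solve(M, crossprod(W, Hi %*% d$y))
  mc_se <- apply(out$beta, 2, sd) / sqrt(nrow(out$beta))
  expect_lt(abs(mean(out$beta[, 1]) - theta_hat[2]), 3.5 * mc_se[1])
  expect_lt(abs(mean(out$beta[, 2]) - theta_hat[3]), 3.5 * mc_se[2])
  expect_lt(abs(mean(out$mu) - theta_hat[1]),
            3.5 * sd(out$mu) / sqrt(length(out$mu)))

  # empty gamma: E[u] equals the dense BLUP formula
  set.seed(3)
  outu <- sample_effects_given_state(td, integer(0), hy, ndraws = 8000)
  mu_hat <- solve(crossprod(rep(1, n), Hi %*% rep(1, n)),
                  crossprod(rep(1, n), Hi %*% d$y))
  blup <- drop(hy$sigma_b2 * d$kin$K %*%
                 solve(hy$sigma_b2 * d$kin$K + diag(n),
                       d$y - rep(mu_hat, n)))
  u_bar <- colMeans(outu$u)
  u_se <- apply(outu$u, 2, sd) / sqrt(nrow(outu$u))
  expect_true(mean(abs(u_bar - blup) < 4 * u_se + 1e-8) > 0.9)
})
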