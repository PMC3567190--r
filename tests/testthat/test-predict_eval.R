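# prediction for held-out individuals and the evaluation metrics

test_that("metrics match brute-force definitions", {
  set.seed(60)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, a + 1), 1)
  expect_equal(rmse(a, b), sqrt(sum((a - b)^2) / 30), tolerance = 1e-12)
  expect_equal(correlation(a, a), 1)
  expect_equal(correlation(a, b),
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
               tolerance = 1e-12)
  expect_error(correlation(a, rep(1, 30)), "zero variance")
  expect_error(rmse(1, 1), "length")
})

test_that("RPG anchors at 0 (mean predictor) and 1 (optimal predictor)", {
  set.seed(61)
  g <- impute_and_center(simulate_genotypes(100, 200))
  for (pve in c(0.2, 0.6)) {
    sim <- simulate_scenario1(g, 20, pve)
    y <- sim$phenotype$values
    opt <- sim$truth$genetic_component
    expect_equal(rpg(y, rep(mean(y), 100), opt), 0)
    expect_equal(rpg(y, opt, opt), 1)
    # worse than the mean predictor -> negative
    expect_lt(rpg(y, mean(y) - 2 * (opt - mean(opt)), opt), 0)
  }
  expect_error(rpg(1:5, 1:5, rep(mean(1:5), 5)), "undefined")
})

test_that("auc equals the brute-force pair count and ignores monotone maps", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  set.seed(62)
  lab <- rbinom(50, 1, 0.4)
  sc <- rnorm(50) + lab
  pairs <- 0; wins <- 0
  for (i in which(lab == 1)) for (j in which(lab == 0)) {
    pairs <- pairs + 1
    wins <- wins + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  }
  expect_equal(auc(lab, sc), wins / pairs, tolerance = 1e-12)
  expect_equal(auc(lab, exp(3 * sc)), auc(lab, sc), tolerance = 1e-12)
  expect_error(auc(rep(1, 5), rnorm(5)), "both classes")
  # ties get half credit
  expect_equal(auc(c(0, 1), c(0.5, 0.5)), 0.5)
})

test_that("brier is the mean squared probability error", {
  lab <- c(0, 1, 1, 0)
  expect_equal(brier(lab, lab), 0)
  expect_equal(brier(lab, c(0.5, 0.5, 0.5, 0.5)), 0.25)
  expect_equal(brier(lab, c(0.2, 0.6, 1, 0)), mean(c(0.04, 0.16, 0, 0)))
})

test_that("liability correction matches its closed form and a simulation", {
  # K = P = 0.5: factor pi/2
  expect_equal(liability_correction(0.2, 0.5, 0.5), 0.2 * pi / 2,
               tolerance = 1e-12)
  expect_equal(liability_correction(0, 0.3, 0.5), 0)
  expect_warning(liability_correction(0.9, 0.5, 0.5), "clamped")
  expect_error(liability_correction(0.2, 0, 0.5), "prevalence")

  # liability-threshold simulation: estimate observed-scale PVE by
  # regression of the binary trait on the true liability-scale genetic
  # values, transform, compare with the liability h2
  set.seed(63)
  h2 <- 0.4; K <- 0.5
  reps <- replicate(40, {
    n <- 4000
    gen <- rnorm(n, sd = sqrt(h2))
    liab <- gen + rnorm(n, sd = sqrt(1 - h2))
    cc <- as.numeric(liab > qnorm(1 - K))
    pve_obs <- var(fitted(lm(cc ~ gen))) / var(cc)
    liability_correction(pve_obs, K, mean(cc))
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - h2), 3.5 * se + 0.02)
})

test_that("prediction decomposes exactly and matches the dense BLUP oracle", {
  set.seed(64)
  graw <- simulate_genotypes(120, 150)
  g <- impute_and_center(graw)
  kin <- compute_kinship(g)
  sim <- simulate_scenario1(g, 10, 0.5)
  sp <- split_train_test(120, 0.75)
  ytr <- sim$phenotype$values
  ytr[sp$test] <- NA  # held out

  fit <- run_mcmc(g, ytr, kin,
                  chain = chain_config(n_iter = 3000, burn_in = 500,
                                       thin = 5, seed = 2))
  gte <- subset_genotypes(graw, individuals = sp$test)
  gtr_raw <- subset_genotypes(graw, individuals = sp$train)
  gtr <- impute_and_center(gtr_raw)
  # cross-kinship built from the full-data centered X, train columns
  kc <- (g$dosages[sp$test, ] %*% t(g$dosages[sp$train, ])) / 150

  pred <- predict(fit, gte, kin_cross = kc)
  expect_equal(pred$y_hat, pred$mean + pred$sparse + pred$random,
               tolerance = 1e-12)

  # random component equals the dense BLUP solve
  resid <- fit$y_train - fit$mu_hat - fit$sparse_fitted
  sb2 <- fit$sigma_b2_mean
  want <- drop(sb2 * kc %*% solve(sb2 * fit$K_train + diag(length(sp$train)),
                                  resid))
  expect_equal(pred$random, want, tolerance = 1e-8)

  # beta = 0, sigma_b2 = 0 -> predictions collapse to the mean
  fit0 <- fit
  fit0$beta_mean[] <- 0
  fit0$sigma_b2_mean <- 0
  fit0$sparse_fitted[] <- 0
  p0 <- predict(fit0, gte, kin_cross = kc)
  expect_equal(p0$y_hat, rep(fit0$mu_hat, length(sp$test)))

  # shift equivariance: training on y + c shifts predictions by c
  fitc <- run_mcmc(g, ytr + 5, kin,
                   chain = chain_config(n_iter = 3000, burn_in = 500,
                                        thin = 5, seed = 2))
  predc <- predict(fitc, gte, kin_cross = kc)
  expect_equal(predc$y_hat, pred$y_hat + 5, tolerance = 1e-6)

  # marker mismatch is caught
  gbad <- gte
  gbad$marker_ids[3] <- "nonesuch"
  expect_error(predict(fit, gbad, kin_cross = kc), "marker mismatch")
})

test_that("draw-averaged prediction agrees with the plug-in on easy data", {
  set.seed(66)
  graw <- simulate_genotypes(80, 60)
  g <- impute_and_center(graw)
  kin <- compute_kinship(g)
  sim <- simulate_scenario1(g, 4, 0.7)
  ytr <- sim$phenotype$values; ytr[61:80] <- NA
  fit <- run_mcmc(g, ytr, kin,
                  chain = chain_config(n_iter = 4000, burn_in = 1000,
                                       thin = 5, seed = 4,
                                       record_effects = TRUE),
                  keep_genotypes = TRUE)
  gte <- subset_genotypes(graw, individuals = 61:80)
  kc <- (g$dosages[61:80, ] %*% t(g$dosages[1:60, ])) / 60
  pm <- predict(fit, gte, kin_cross = kc)
  pd <- predict(fit, gte, kin_cross = kc, average = "draws", ndraws = 60)
  expect_equal(pd$y_hat, pd$mean + pd$sparse + pd$random, tolerance = 1e-12)
  # the two estimators target the same posterior functional up to
  # nonlinearity in sigma_b2; on well-identified data they agree closely
  expect_gt(cor(pm$y_hat, pd$y_hat), 0.99)
  expect_lt(rmse(pm$y_hat, pd$y_hat), 0.5 * sd(fit$y_train))
})

test_that("prediction on test twins of training individuals (sigma_b2 = 0)", {
  set.seed(65)
  graw <- simulate_genotypes(60, 80)
  g <- impute_and_center(graw)
  sim <- simulate_scenario1(g, 5, 0.6)
  fit <- run_mcmc(g, sim$phenotype$values, compute_kinship(g),
                  chain = chain_config(n_iter = 2000, burn_in = 500,
                                       thin = 5, seed = 3),
                  mode = "bvsr")
  # test set = copies of training individuals 1:5
  gte <- subset_genotypes(graw, individuals = 1:5)
  pred <- predict(fit, gte)
  expect_equal(pred$sparse, fit$sparse_fitted[1:5], tolerance = 1e-10)
  expect_equal(pred$random, rep(0, 5))
})
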