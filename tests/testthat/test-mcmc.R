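# proposal machinery, MH kernel correctness, chain modes

test_that("rank_markers orders by marginal association with ties by index", {
  set.seed(40)
  g <- impute_and_center(simulate_genotypes(60, 20))
  y <- g$dosages[, 7] + rnorm(60, sd = 0.01)
  r <- rank_markers(g, y)
  expect_equal(r[1], 7L)

  # a zero-variance marker scores 0 and ranks last
  g$dosages[, 13] <- 0
  r <- rank_markers(g, y)
  expect_true(13L %in% tail(r, sum(apply(g$dosages, 2, var) == 0)))

  # ordering agrees with per-marker simple-regression F statistics
  fstat <- apply(g$dosages, 2, function(x) {
    if (var(x) == 0) return(0)
    f <- summary(lm(y ~ x))$fstatistic
    if (is.null(f)) 0 else f[1]
  })
  expect_equal(r, order(-fstat, seq_along(fstat)))
})

test_that("gamma proposal probabilities normalize and match empirical draws", {
  p <- 4L
  ranking <- c(2L, 4L, 1L, 3L)
  cfg <- proposal_config(long_range_prob = 0)
  from <- c(1L)
  # enumerate all states reachable in one elementary move
  to_sets <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L),          # adds
                  integer(0),                                # remove
                  2L, 3L, 4L)                                # swaps
  dens <- vapply(to_sets, function(to)
    exp(gamma_proposal_logdensity(from, to, ranking, cfg, p, n = 50L)), 0)
  expect_equal(sum(dens), 1, tolerance = 1e-12)

  set.seed(41)
  draws <- replicate(20000, {
    pr <- propose_gamma(from, ranking, cfg, p, n = 50L)
    paste(sort(pr$gamma), collapse = ",")
  })
  keys <- vapply(to_sets, function(s) paste(sort(s), collapse = ","), "")
  emp <- vapply(keys, function(k) mean(draws == k), 0)
  expect_equal(unname(emp), dens, tolerance = 0.02)
})

test_that("returned log ratio equals the reverse/forward density ratio", {
  p <- 4L
  ranking <- c(3L, 1L, 4L, 2L)
  cfg <- proposal_config(long_range_prob = 0)
  set.seed(42)
  starts <- list(integer(0), 1L, c(1L, 3L), c(2L, 4L), c(1L, 2L, 3L))
  for (from in starts) {
    for (i in 1:200) {
      pr <- propose_gamma(from, ranking, cfg, p, n = 50L)
      to <- sort(pr$gamma)
      lf <- gamma_proposal_logdensity(from, to, ranking, cfg, p, 50L)
      lr <- gamma_proposal_logdensity(to, from, ranking, cfg, p, 50L)
      expect_equal(pr$log_ratio, lr - lf, tolerance = 1e-12)
    }
  }
})

test_that("geometric_rank_param -> 1 gives a uniform add kernel", {
  p <- 6L
  ranking <- 1:6
  cfg <- proposal_config(geometric_rank_param = 1, unif_mix = 0,
                         p_add = 1, p_remove = 0, p_swap = 0,
                         long_range_prob = 0)
  from <- integer(0)
  dens <- vapply(1:6, function(j)
    exp(gamma_proposal_logdensity(from, j, ranking, cfg, p, 50L)), 0)
  expect_equal(dens, rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("compound proposals keep exact ratios on an enumerable space", {
  # run an MCMC with compound moves on p = 3 and compare occupancy with
  # the enumerated posterior: any bookkeeping error in compound log
  # ratios would bias the stationary distribution
  d <- make_small_data(12, 3, seed = 43, S = 1, pve = 0.5)
  td <- transform_data(d$y, d$kin, d$g)
  hy <- hyper_state(0.5, 0.5, log(1 / 3) / 2, 3, d$g$s_a, d$kin$s_b)
  enum <- enumerate_gamma_posterior(td, 3, hy)
  fit <- run_mcmc(d$g, d$y, d$kin,
                  chain = chain_config(n_iter = 1.5e5, burn_in = 5e3,
                                       thin = 1, seed = 7),
                  proposal = proposal_config(long_range_prob = 0.3),
                  fix = list(h = hy$h, rho = hy$rho, log_pi = hy$log_pi))
  emp <- table(factor(fit$samples$q, levels = 0:3)) / nrow(fit$samples)
  want_q <- vapply(0:3, function(k)
    sum(enum$prob[lengths(enum$subsets) == k]), 0)
  expect_lt(max(abs(as.numeric(emp) - want_q)), 0.02)
})

test_that("hyper proposal reflects at the boundaries and is symmetric", {
  expect_equal(bslmm:::reflect_into(1.04, 0, 1), 0.96)
  expect_equal(bslmm:::reflect_into(-0.03, 0, 1), 0.03)
  expect_equal(bslmm:::reflect_into(0.5, 0, 1), 0.5)
  expect_equal(bslmm:::reflect_into(2.6, 0, 1), 0.6)  # double wrap

  # interior start where the walk never reflects: proposal mean = start
  p <- 100; s_a <- 0.5; s_b <- 1
  st <- hyper_state(0.5, 0.5, log(1 / p) / 2, p, s_a, s_b)
  set.seed(44)
  cfgp <- proposal_config(h_step = 0.05, rho_step = 0.05)
  prop <- replicate(2e4, {
    out <- propose_hyper(st, cfgp)
    c(out$state$h, out$state$rho, out$state$log_pi, out$log_ratio)
  })
  expect_true(all(prop[4, ] == 0))
  for (i in 1:3) {
    se <- sd(prop[i, ]) / sqrt(ncol(prop))
    start <- c(st$h, st$rho, st$log_pi)[i]
    expect_lt(abs(mean(prop[i, ]) - start), 3.5 * se + 1e-12)
  }
  # near a boundary the kernel stays inside the support
  stb <- hyper_state(0.99, 0.01, log(1 / p) * 0.99, p, s_a, s_b)
  propb <- replicate(2e3, {
    out <- propose_hyper(stb, proposal_config(h_step = 0.2, rho_step = 0.2,
                                              logpi_step = 0.2))
    c(out$state$h, out$state$rho, out$state$log_pi)
  })
  expect_true(all(propb[1, ] > 0 & propb[1, ] < 1))
  expect_true(all(propb[2, ] >= 0 & propb[2, ] <= 1))
  expect_true(all(propb[3, ] >= log(1 / p) & propb[3, ] <= 0))
})

test_that("chain occupancy matches the enumerated posterior (fixed hyper)", {
  d <- make_small_data(12, 3, seed = 45, S = 2, pve = 0.6)
  td <- transform_data(d$y, d$kin, d$g)
  hy <- hyper_state(0.4, 0.6, log(0.4), 3, d$g$s_a, d$kin$s_b)
  enum <- enumerate_gamma_posterior(td, 3, hy)
  fit <- run_mcmc(d$g, d$y, d$kin,
                  chain = chain_config(n_iter = 2e5, burn_in = 1e4,
                                       thin = 1, seed = 11),
                  proposal = proposal_config(long_range_prob = 0),
                  fix = list(h = hy$h, rho = hy$rho, log_pi = hy$log_pi))
  # occupancy by |gamma| (the per-set posterior is checked in acceptance)
  emp <- as.numeric(table(factor(fit$samples$q, levels = 0:3))) /
    nrow(fit$samples)
  want <- vapply(0:3, function(k)
    sum(enum$prob[lengths(enum$subsets) == k]), 0)
  expect_lt(0.5 * sum(abs(emp - want)), 0.02)
})

test_that("modes pin the right coordinates and chains are reproducible", {
  d <- make_small_data(80, 60, seed = 46, S = 5, pve = 0.5)
  ch <- chain_config(n_iter = 4000, burn_in = 1000, thin = 5, seed = 3)

  bvsr <- run_mcmc(d$g, d$y, d$kin, chain = ch, mode = "bvsr")
  expect_true(all(bvsr$samples$rho == 1))
  expect_true(all(bvsr$samples$sigma_b2 == 0))

  lmm <- run_mcmc(d$g, d$y, d$kin, chain = ch, mode = "lmm_bayes")
  expect_true(all(lmm$samples$rho == 0))
  expect_true(all(lmm$samples$q == 0))
  expect_true(all(lmm$samples$sigma_a2 == 0))

  eb <- run_mcmc(d$g, d$y, d$kin, chain = ch, mode = "bslmm_eb")
  expect_equal(unique(eb$samples$sigma_b2), eb$reml$sigma_b2_hat)

  fit1 <- run_mcmc(d$g, d$y, d$kin, chain = ch, mode = "bslmm")
  fit2 <- run_mcmc(d$g, d$y, d$kin, chain = ch, mode = "bslmm")
  expect_identical(fit1$samples, fit2$samples)
  expect_identical(fit1$pip, fit2$pip)

  # all kept PVE/PGE in [0,1]; inclusion counts bounded by kept draws
  for (f in list(bvsr, lmm, eb, fit1)) {
    expect_true(all(f$samples$pve >= 0 & f$samples$pve <= 1))
    expect_true(all(f$samples$pge >= 0 & f$samples$pge <= 1))
    expect_true(all(f$pip >= 0 & f$pip <= 1))
  }
})

test_that("fit files are written with the documented columns", {
  d <- make_small_data(40, 30, seed = 47)
  fit <- run_mcmc(d$g, d$y, d$kin,
                  chain = chain_config(n_iter = 1000, burn_in = 200,
                                       thin = 5, seed = 1))
  pre <- file.path(withr::local_tempdir(), "fit")
  write_fit_files(fit, pre)
  hyp <- read.table(paste0(pre, ".hyp.txt"), header = TRUE)
  expect_equal(names(hyp), c("h", "pve", "rho", "pge", "pi", "n_gamma"))
  expect_equal(nrow(hyp), nrow(fit$samples))
  par <- read.table(paste0(pre, ".param.txt"), header = TRUE)
  expect_equal(names(par), c("id", "pip", "beta", "beta_incl"))
  expect_equal(nrow(par), 30L)
  expect_true(file.exists(paste0(pre, ".log.txt")))
})
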