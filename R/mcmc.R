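# Metropolis-Hastings sampling over (gamma, h, rho, log pi) with
# rank-based gamma proposals, plus chain management and posterior
# summaries. The per-iteration work is done in C++ (see src/).

#' Proposal configuration for the sampler
#'
#' @param p_add,p_remove,p_swap mixture over the elementary gamma moves
#'   (renormalized automatically when a move type is unavailable).
#' @param geometric_rank_param decay of the rank-based add kernel: the
#'   probability of proposing the marker of rank r decays like
#'   `geometric_rank_param^r`, so computation concentrates on SNPs with
#'   strong marginal associations. Values near 1 approach a uniform kernel.
#' @param unif_mix weight of the uniform component mixed into the add
#'   kernel; keeps every excluded marker reachable regardless of rank.
#' @param long_range_prob probability of a compound move chaining 2 to
#'   `compound_max` elementary gamma moves.
#' @param compound_max maximum compound length.
#' @param h_step,rho_step random-walk half-widths for h and rho
#'   (reflected into \[0, 1\]).
#' @param logpi_step half-width for log pi per unit of `log(p)` (the
#'   effective step is `logpi_step * log(p)`, reflected into
#'   \[log(1/p), 0\]).
#' @param hyper_move_prob probability that an iteration updates the
#'   hyper-parameters instead of gamma.
#' @param qcap soft cap on the number of included markers; proposals beyond
#'   `min(n - 2, qcap)` are auto-rejected (likelihood validity requires
#'   `q <= n - 2`; the cap also bounds per-iteration cost).
#' @return list of class `proposal_config`.
#' @export
proposal_config <- function(p_add = 0.4, p_remove = 0.4, p_swap = 0.2,
                            geometric_rank_param = 0.3, unif_mix = 0.3,
                            long_range_prob = 0.05, compound_max = 5L,
                            h_step = 0.02, rho_step = 0.02,
                            logpi_step = 0.1, hyper_move_prob = 0.3,
                            qcap = 300L) {
  tot <- p_add + p_remove + p_swap
  stopifnot(tot > 0, geometric_rank_param > 0, geometric_rank_param <= 1,
            unif_mix >= 0, unif_mix <= 1, compound_max >= 2L)
  structure(list(p_add = p_add / tot, p_remove = p_remove / tot,
                 p_swap = p_swap / tot,
                 geometric_rank_param = geometric_rank_param,
                 unif_mix = unif_mix, long_range_prob = long_range_prob,
                 compound_max = as.integer(compound_max),
                 h_step = h_step, rho_step = rho_step,
                 logpi_step = logpi_step, hyper_move_prob = hyper_move_prob,
                 qcap = as.integer(qcap)),
            class = "proposal_config")
}

#' Chain configuration
#'
#' @param n_iter number of sampling iterations (after burn-in).
#' @param burn_in number of discarded initial iterations.
#' @param thin keep every `thin`-th draw.
#' @param seed integer seed for the (single, shared) random number stream.
#' @param record_effects store the sparse effect draws per kept iteration
#'   (needed for draw-averaged prediction).
#' @return list of class `chain_config`.
#' @export
chain_config <- function(n_iter = 1e6, burn_in = 1e5, thin = 10L,
                         seed = 1L, record_effects = FALSE) {
  stopifnot(n_iter >= 1, burn_in >= 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 record_effects = isTRUE(record_effects)),
            class = "chain_config")
}

#' Rank markers by marginal association
#'
#' Markers sorted by decreasing squared correlation between the (centered)
#' genotype column and the phenotype, with deterministic tie-break by
#' marker index. Zero-variance markers score 0 and rank last.
#'
#' @param g a centered [genotype_matrix()].
#' @param y numeric phenotype vector (or `phenotype_vector`), complete.
#' @return integer permutation: marker indices in rank order (best first).
#' @export
rank_markers <- function(g, y) {
  if (inherits(y, "phenotype_vector")) y <- y$values
  X <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  yc <- y - mean(y)
  xm <- colMeans(X)
  num <- drop(crossprod(X, yc)) - nrow(X) * xm * mean(yc)
  ssx <- colSums(X^2) - nrow(X) * xm^2
  ssy <- sum(yc^2)
  score <- ifelse(ssx > 0 & ssy > 0, num^2 / (ssx * ssy), 0)
  order(-score, seq_along(score))
}

#' Propose a new sparse configuration
#'
#' One rank-based gamma proposal (possibly compound), with the exact log
#' proposal-density ratio needed for Metropolis-Hastings. Uses R's random
#' number stream.
#'
#' @param current integer vector of currently included marker indices.
#' @param ranking permutation from [rank_markers()].
#' @param cfg a [proposal_config()].
#' @param p number of markers.
#' @param n number of individuals (for the `q <= n - 2` cap).
#' @return list with `gamma`, `log_ratio`, `valid` (FALSE means auto-reject:
#'   the soft cap was exceeded), `compound`, `n_steps`.
#' @export
propose_gamma <- function(current, ranking, cfg, p, n) {
  cpp_propose_gamma(as.integer(current), as.integer(p),
                    as.integer(ranking), cfg_to_list(cfg, p), as.integer(n))
}

#' Proposal density of a single elementary gamma move
#'
#' `log q(to | from)` for configurations differing by one add, remove or
#' swap; `-Inf` if `to` is not reachable in one elementary move. Used to
#' verify detailed balance by enumeration.
#'
#' @inheritParams propose_gamma
#' @param from,to integer index vectors.
#' @return scalar log density.
#' @export
gamma_proposal_logdensity <- function(from, to, ranking, cfg, p, n) {
  cpp_gamma_logdensity(as.integer(from), as.integer(to), as.integer(p),
                       as.integer(ranking), cfg_to_list(cfg, p), as.integer(n))
}

#' Symmetric reflected random-walk proposal for the hyper-parameters
#'
#' Uniform increments on `h` and `rho` reflected into \[0, 1\] and on
#' `log pi` reflected into \[log(1/p), 0\]. Reflection of a symmetric
#' kernel keeps the proposal symmetric, so the log proposal ratio is 0.
#'
#' @param state a [hyper_state()].
#' @param cfg a [proposal_config()].
#' @return list with `state` (new [hyper_state()]) and `log_ratio` (always 0).
#' @export
propose_hyper <- function(state, cfg) {
  p <- state$p
  h <- reflect_into(state$h + cfg$h_step * runif(1, -1, 1), 0, 1)
  rho <- reflect_into(state$rho + cfg$rho_step * runif(1, -1, 1), 0, 1)
  lp <- reflect_into(state$log_pi + cfg$logpi_step * log(p) * runif(1, -1, 1),
                     log(1 / p), 0)
  list(state = hyper_state(h, rho, lp, p, state$s_a, state$s_b), log_ratio = 0)
}

# reflect x into [lo, hi] (same algorithm as the C++ core)
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(lo)
  s <- (x - lo) / (2 * w)
  t <- (s - floor(s)) * 2 * w
  if (t <= w) lo + t else hi - (t - w)
}

cfg_to_list <- function(cfg, p) {
  list(p_add = cfg$p_add, p_remove = cfg$p_remove, p_swap = cfg$p_swap,
       geometric_rank_param = cfg$geometric_rank_param,
       unif_mix = cfg$unif_mix, long_range_prob = cfg$long_range_prob,
       compound_max = cfg$compound_max, qcap = cfg$qcap)
}

#' Run the BSLMM Metropolis-Hastings sampler
#'
#' Samples `(gamma, h, rho, log pi)` from the posterior; every kept draw is
#' completed with a conditional draw of `(tau, mu, beta_gamma, u)` from
#' which PVE and PGE are computed. Modes:
#'
#' * `"bslmm"`: the full model.
#' * `"bvsr"`: `rho` pinned at 1 (no random effect).
#' * `"lmm_bayes"`: `gamma` pinned empty and `rho` at 0 (Bayesian LMM; only
#'   `h` is sampled).
#' * `"bslmm_eb"`: `sigma_b2` fixed at its REML estimate from the
#'   null model ([reml_lmm()]); `h` and `log pi` are sampled with `rho`
#'   derived from the constraint.
#'
#' Individuals with missing phenotype are dropped from the training arrays
#' here; pass a kinship built on all genotyped individuals when predictions
#' for the held-out rows are wanted later.
#'
#' @param g a centered [genotype_matrix()].
#' @param y `phenotype_vector` or numeric vector (length n, `NA` allowed).
#' @param kin optional [kinship()]; computed from `g` when missing.
#' @param chain a [chain_config()].
#' @param proposal a [proposal_config()].
#' @param mode one of `"bslmm"`, `"bvsr"`, `"lmm_bayes"`, `"bslmm_eb"`.
#' @param fix optional named list pinning hyper-parameters (`h`, `rho`,
#'   `log_pi`) at fixed values, or `gamma` at a fixed index set.
#' @param keep_genotypes store the training design in the fit (needed by
#'   draw-averaged prediction).
#' @return An object of class `bslmm_fit`: posterior draws
#'   (`$samples`, a data frame over kept iterations), per-marker summaries
#'   (`$pip`, `$beta_mean`, `$beta_incl_mean`), posterior summaries
#'   (`$pve_mean`, `$pve_sd`, `$pge_mean`, `$pge_sd`), acceptance rates,
#'   and the training context needed by [predict.bslmm_fit()].
#' @export
run_mcmc <- function(g, y, kin = NULL, chain = chain_config(),
                     proposal = proposal_config(),
                     mode = c("bslmm", "bvsr", "lmm_bayes", "bslmm_eb"),
                     fix = list(), keep_genotypes = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "genotype_matrix"))
  if (!g$centered) stop("genotypes must be centered (impute_and_center) first")
  yv <- if (inherits(y, "phenotype_vector")) y$values else as.numeric(y)
  n_all <- nrow(g$dosages)
  if (length(yv) != n_all)
    stop("phenotype length ", length(yv), " != individuals ", n_all)
  if (is.null(kin)) kin <- compute_kinship(g)

  obs <- which(!is.na(yv))
  if (length(obs) < 3L) stop("need at least 3 observed phenotypes")
  g_tr <- if (length(obs) < n_all) subset_genotypes(g, individuals = obs) else g
  kin_tr <- if (length(obs) < n_all) kinship(kin$K[obs, obs, drop = FALSE]) else kin
  y_tr <- yv[obs]
  n <- length(obs)
  p <- ncol(g_tr$dosages)

  # one eigendecomposition; all likelihood work happens in this basis
  U <- kin_tr$eigenvectors
  yt <- drop(crossprod(U, y_tr))
  onest <- drop(crossprod(U, rep(1, n)))
  UtX <- crossprod(U, g_tr$dosages)
  ranking <- rank_markers(g_tr, y_tr)
  s_a <- g_tr$s_a
  s_b <- kin_tr$s_b
  logpi_min <- log(1 / p)

  # mode -> pinned coordinates
  fix_h <- !is.null(fix$h)
  fix_rho <- !is.null(fix$rho)
  fix_logpi <- !is.null(fix$log_pi)
  fix_gamma <- !is.null(fix$gamma)
  eb_mode <- FALSE
  sigma_b2_fixed <- 0
  h0 <- if (fix_h) fix$h else 0.5
  rho0 <- if (fix_rho) fix$rho else 0.5
  logpi0 <- if (fix_logpi) fix$log_pi else logpi_min / 2
  reml <- NULL
  if (mode == "bvsr") {
    rho0 <- 1; fix_rho <- TRUE
  } else if (mode == "lmm_bayes") {
    rho0 <- 0; fix_rho <- TRUE
    logpi0 <- logpi_min; fix_logpi <- TRUE
    fix_gamma <- TRUE; fix$gamma <- integer(0)
  } else if (mode == "bslmm_eb") {
    td0 <- transform_data(y_tr, kin_tr)
    reml <- reml_lmm(td0)
    eb_mode <- TRUE
    sigma_b2_fixed <- reml$sigma_b2_hat
    hmin <- sigma_b2_fixed * s_b / (1 + sigma_b2_fixed * s_b)
    if (!fix_h) h0 <- (hmin + 1) / 2
    rho0 <- 1 - sigma_b2_fixed * s_b * (1 - h0) / h0
    rho0 <- min(1, max(0, rho0))
  }

  # initial gamma: top-ranked markers, size from the prior mean of log pi
  init_q <- max(1L, min(10L, round(p * exp((logpi_min + 0) / 2))))
  init_gamma <- if (fix_gamma) as.integer(fix$gamma) else ranking[seq_len(min(init_q, p))]

  cfg <- c(cfg_to_list(proposal, p), list(
    n_iter = chain$n_iter, burn_in = chain$burn_in, thin = chain$thin,
    hyper_move_prob = proposal$hyper_move_prob,
    h_step = proposal$h_step, rho_step = proposal$rho_step,
    logpi_step = proposal$logpi_step * log(p),
    fix_h = fix_h, fix_rho = fix_rho, fix_logpi = fix_logpi,
    fix_gamma = fix_gamma, eb_mode = eb_mode,
    sigma_b2_fixed = sigma_b2_fixed,
    record_effects = chain$record_effects))

  set.seed(chain$seed)
  res <- NULL
  for (attempt in 1:10) {
    res <- tryCatch(
      cpp_bslmm_mcmc(yt, onest, kin_tr$eigenvalues, UtX, s_a, s_b,
                     as.integer(ranking), as.integer(init_gamma),
                     h0, rho0, logpi0, cfg),
      error = function(e) e)
    if (!inherits(res, "error")) break
    if (!grepl("initialization", conditionMessage(res)) || attempt == 10)
      stop(res)
    # re-initialize: jitter the starting point
    h0 <- runif(1, 0.2, 0.8)
    init_gamma <- if (fix_gamma) init_gamma else ranking[seq_len(min(attempt, p))]
  }

  kept <- res$n_kept
  samples <- data.frame(
    h = res$h, rho = res$rho, log_pi = res$log_pi, q = res$q,
    pve = res$pve, pge = res$pge, mu = res$mu, tau = res$tau,
    sigma_a2 = res$sigma_a2, sigma_b2 = res$sigma_b2)
  pip <- res$inclusion_count / kept
  beta_mean <- res$beta_sum / kept
  beta_incl_mean <- ifelse(res$inclusion_count > 0,
                           res$beta_abs_sum / pmax(res$inclusion_count, 1), 0)
  mu_hat <- mean(samples$mu)
  sparse_fitted <- drop(g_tr$dosages %*% beta_mean)

  structure(list(
    samples = samples,
    pip = pip,
    beta_mean = beta_mean,
    beta_incl_mean = beta_incl_mean,
    pve_mean = mean(samples$pve), pve_sd = sd(samples$pve),
    pge_mean = mean(samples$pge), pge_sd = sd(samples$pge),
    acceptance = res$accept,
    n_capped = res$n_capped,
    effect_draws = res$effect_draws,
    mode = mode,
    reml = reml,
    chain = chain, proposal = proposal,
    marker_ids = g_tr$marker_ids,
    # training context for prediction
    mu_hat = mu_hat,
    sigma_b2_mean = mean(samples$sigma_b2),
    y_train = y_tr,
    obs_index = obs,
    K_train = kin_tr$K,
    train_col_means = g$col_means,
    X_train = if (keep_genotypes) g_tr$dosages else NULL,
    sparse_fitted = sparse_fitted,
    n = n, p = p, s_a = s_a, s_b = s_b
  ), class = "bslmm_fit")
}

#' @export
print.bslmm_fit <- function(x, ...) {
  cat(sprintf("bslmm_fit (mode %s): n = %d, p = %d, %d kept draws\n",
              x$mode, x$n, x$p, nrow(x$samples)))
  cat(sprintf("  PVE %.3f (%.3f)   PGE %.3f (%.3f)   mean |gamma| %.1f\n",
              x$pve_mean, x$pve_sd, x$pge_mean, x$pge_sd, mean(x$samples$q)))
  invisible(x)
}

#' Write fit output files
#'
#' `<prefix>.hyp.txt` has one row per kept draw (h, pve, rho, pge, pi,
#' n_gamma); `<prefix>.param.txt` one row per marker (id, posterior
#' inclusion probability, posterior mean effect, posterior mean |effect|
#' given inclusion); `<prefix>.log.txt` records configuration, seed and
#' acceptance rates.
#'
#' @param fit a `bslmm_fit`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_fit_files <- function(fit, prefix) {
  hyp <- data.frame(h = fit$samples$h, pve = fit$samples$pve,
                    rho = fit$samples$rho, pge = fit$samples$pge,
                    pi = exp(fit$samples$log_pi), n_gamma = fit$samples$q)
  f1 <- paste0(prefix, ".hyp.txt")
  write.table(format(hyp, digits = 8, trim = TRUE), f1, quote = FALSE,
              row.names = FALSE)
  par <- data.frame(id = fit$marker_ids, pip = fit$pip,
                    beta = fit$beta_mean, beta_incl = fit$beta_incl_mean)
  f2 <- paste0(prefix, ".param.txt")
  write.table(format(par, digits = 8, trim = TRUE), f2, quote = FALSE,
              row.names = FALSE)
  f3 <- paste0(prefix, ".log.txt")
  acc <- fit$acceptance
  lines <- c(
    sprintf("package bslmm %s", as.character(utils::packageVersion("bslmm"))),
    sprintf("mode = %s", fit$mode),
    sprintf("n = %d, p = %d", fit$n, fit$p),
    sprintf("seed = %d", fit$chain$seed),
    sprintf("n_iter = %d, burn_in = %d, thin = %d",
            fit$chain$n_iter, fit$chain$burn_in, fit$chain$thin),
    sprintf("acceptance: gamma = %.4f, compound = %.4f, hyper = %.4f",
            acc$gamma, acc$compound, acc$hyper),
    sprintf("proposals beyond q cap (auto-rejected) = %g", fit$n_capped),
    sprintf("pve_mean = %.6f, pve_sd = %.6f", fit$pve_mean, fit$pve_sd),
    sprintf("pge_mean = %.6f, pge_sd = %.6f", fit$pge_mean, fit$pge_sd),
    sprintf("mu_hat = %.6f, sigma_b2_mean = %.6f",
            fit$mu_hat, fit$sigma_b2_mean))
  writeLines(lines, f3)
  invisible(c(f1, f2, f3))
}
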