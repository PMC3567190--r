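# Phenotype prediction for held-out individuals and the evaluation
# metrics (RMSE, correlation, relative predictive gain, AUC, Brier score,
# liability-scale PVE correction).

#' Predict phenotypes for new individuals from a fitted model
#'
#' The prediction decomposes as mean + sparse part + random part:
#' `y_hat = mu_hat + X_test beta_bar +
#'   sigma_b2_bar K_cross (sigma_b2_bar K_train + I)^{-1}
#'   (y_train - mu_hat - X_train beta_bar)`,
#' the BLUP-style transfer of the polygenic random effect. By default the
#' posterior means of `mu`, `beta` and `sigma_b2` are plugged in
#' (`average = "means"`); with `average = "draws"` the whole expression is
#' averaged over kept draws (requires a fit run with
#' `record_effects = TRUE`; `ndraws` subsamples the kept draws since each
#' one costs a dense solve).
#'
#' Test dosages are centered with the *training* column means.
#'
#' @param object a `bslmm_fit` from [run_mcmc()].
#' @param g_test [genotype_matrix()] of test individuals (raw dosages),
#'   same markers as training.
#' @param kin_cross n_test x n_train cross-relatedness block
#'   ([compute_kinship_cross()]); required whenever the fitted `sigma_b2`
#'   is nonzero (the fit does not retain the training genotypes by
#'   default, so the block cannot be rebuilt here).
#' @param average `"means"` (default) or `"draws"`.
#' @param ndraws number of kept draws used when `average = "draws"`.
#' @param ... unused.
#' @return An object of class `bslmm_prediction`: `y_hat`, `sparse`,
#'   `random`, `mean` with `y_hat = mean + sparse + random` exactly.
#' @export
predict.bslmm_fit <- function(object, g_test, kin_cross = NULL,
                              average = c("means", "draws"),
                              ndraws = 100L, ...) {
  average <- match.arg(average)
  stopifnot(inherits(g_test, "genotype_matrix"))
  if (!identical(g_test$marker_ids, object$marker_ids)) {
    off <- setdiff(union(g_test$marker_ids, object$marker_ids),
                   intersect(g_test$marker_ids, object$marker_ids))
    stop("marker mismatch between train and test: ",
         paste(head(off, 5L), collapse = ", "),
         if (length(off) > 5L) " ..." else "")
  }
  Xte <- center_with_means(g_test, object$train_col_means)
  n_tr <- object$n
  sb2 <- object$sigma_b2_mean
  if (is.null(kin_cross)) {
    if (sb2 > 1e-12)
      stop("kin_cross is required when the fitted sigma_b2 is nonzero")
    kin_cross <- matrix(0, nrow(Xte), n_tr)
  }
  if (!all(dim(kin_cross) == c(nrow(Xte), n_tr)))
    stop("kin_cross must be n_test x n_train = ", nrow(Xte), " x ", n_tr)

  if (average == "means") {
    sparse <- drop(Xte %*% object$beta_mean)
    random <- if (sb2 > 0) {
      resid <- object$y_train - object$mu_hat - object$sparse_fitted
      drop(sb2 * kin_cross %*% solve(sb2 * object$K_train + diag(n_tr), resid))
    } else rep(0, nrow(Xte))
    mu <- object$mu_hat
  } else {
    ed <- object$effect_draws
    if (is.null(ed))
      stop("average = 'draws' requires a fit with record_effects = TRUE")
    kept <- nrow(object$samples)
    use <- unique(round(seq(1, kept, length.out = min(ndraws, kept))))
    sparse_acc <- numeric(nrow(Xte))
    random_acc <- numeric(nrow(Xte))
    mu_acc <- 0
    Ktr <- object$K_train
    for (d in use) {
      beta_d <- numeric(object$p)
      sel <- which(ed$draw == d)
      if (length(sel)) beta_d[ed$marker[sel]] <- ed$beta[sel]
      mu_d <- object$samples$mu[d]
      sb2_d <- object$samples$sigma_b2[d]
      sp <- drop(Xte %*% beta_d)
      rd <- if (sb2_d > 0) {
        resid <- object$y_train - mu_d - sparse_fitted_draw(object, beta_d)
        drop(sb2_d * kin_cross %*% solve(sb2_d * Ktr + diag(n_tr), resid))
      } else rep(0, nrow(Xte))
      sparse_acc <- sparse_acc + sp
      random_acc <- random_acc + rd
      mu_acc <- mu_acc + mu_d
    }
    k <- length(use)
    sparse <- sparse_acc / k
    random <- random_acc / k
    mu <- mu_acc / k
  }
  structure(list(y_hat = mu + sparse + random, sparse = sparse,
                 random = random, mean = mu), class = "bslmm_prediction")
}

# training sparse fitted values for one draw's beta (needs the training
# genotypes only through the cross products stored in the fit)
sparse_fitted_draw <- function(fit, beta_d) {
  if (is.null(fit$X_train))
    stop("draw-averaged prediction needs the training genotypes; ",
         "refit with run_mcmc(..., chain_config(record_effects = TRUE)) ",
         "and keep_genotypes = TRUE")
  drop(fit$X_train %*% beta_d)
}

#' Root mean squared error
#' @param y_true,y_pred numeric vectors of equal length (>= 2).
#' @return scalar RMSE.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    stop("y_true and y_pred must have equal length >= 2")
  sqrt(mean((y_true - y_pred)^2))
}

#' Pearson correlation between truth and prediction
#' @inheritParams rmse
#' @return scalar correlation in \[-1, 1\].
#' @export
correlation <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    stop("y_true and y_pred must have equal length >= 2")
  if (sd(y_true) == 0 || sd(y_pred) == 0)
    stop("correlation undefined: zero variance input")
  cor(y_true, y_pred)
}

#' Relative predictive gain
#'
#' A standardized mean squared error:
#' `RPG = (MSE_null - MSE_pred) / (MSE_null - MSE_opt)` where the null
#' predictor assigns everyone the mean of the true phenotypes and the
#' optimal predictor `y_opt` is the best achievable given the simulation
#' setup (its true genetic component). RPG = 1 for the optimal predictor,
#' 0 for the mean predictor, and can be negative for predictors worse than
#' the mean.
#'
#' @param y_true observed phenotypes.
#' @param y_pred predictions under evaluation.
#' @param y_opt best-possible predictions (simulation truth).
#' @return scalar RPG (<= 1).
#' @export
rpg <- function(y_true, y_pred, y_opt) {
  stopifnot(length(y_true) == length(y_pred),
            length(y_true) == length(y_opt))
  mse_null <- mean((y_true - mean(y_true))^2)
  mse_pred <- mean((y_true - y_pred)^2)
  mse_opt <- mean((y_true - y_opt)^2)
  if (mse_null == mse_opt)
    stop("RPG undefined: optimal predictor no better than the mean predictor")
  (mse_null - mse_pred) / (mse_null - mse_opt)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the proportion of case-control pairs where the case
#' scores higher, with half credit for ties.
#'
#' @param labels binary 0/1 vector (both classes present).
#' @param scores numeric risk scores.
#' @return scalar AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("auc requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and 0/1 label.
#'
#' @param labels binary 0/1 vector.
#' @param probs predicted probabilities (clamped to \[0, 1\]).
#' @return scalar in \[0, 1\].
#' @export
brier <- function(labels, probs) {
  stopifnot(length(labels) == length(probs))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  probs <- pmin(1, pmax(0, probs))
  mean((probs - labels)^2)
}

#' Liability-scale correction of observed-scale PVE
#'
#' For a 1/0 case-control trait analyzed as quantitative, transforms the
#' PVE estimated on the observed scale to the latent liability scale,
#' accounting for disease prevalence K and the (possibly ascertained) case
#' fraction P in the sample:
#' `PVE_liab = PVE_obs * K^2 (1 - K)^2 / (z^2 P (1 - P))` with `z` the
#' standard normal density at the K-upper-tail threshold. The result is
#' clamped to \[0, 1\] with a warning if the factor pushes it beyond.
#'
#' @param pve_observed observed-scale PVE.
#' @param prevalence population disease prevalence K, in (0, 1).
#' @param case_fraction proportion of cases in the sample P, in (0, 1).
#' @return liability-scale PVE.
#' @export
liability_correction <- function(pve_observed, prevalence, case_fraction) {
  if (prevalence <= 0 || prevalence >= 1 || case_fraction <= 0 ||
      case_fraction >= 1)
    stop("prevalence and case_fraction must lie in (0, 1)")
  K <- prevalence; P <- case_fraction
  z <- dnorm(qnorm(1 - K))
  out <- pve_observed * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  if (out > 1 || out < 0) {
    warning("liability-scale PVE outside [0, 1]; clamped")
    out <- min(1, max(0, out))
  }
  out
}

#' Prediction metric report
#'
#' Convenience wrapper computing RMSE, correlation and (when the optimal
#' predictor is available) RPG, plus AUC and Brier score for binary
#' truths.
#'
#' @param y_true observed phenotypes.
#' @param y_pred predictions.
#' @param y_opt optional optimal predictor for RPG.
#' @return named list of metrics (missing ones are `NA`).
#' @export
prediction_metrics <- function(y_true, y_pred, y_opt = NULL) {
  out <- list(
    rmse = rmse(y_true, y_pred),
    correlation = tryCatch(correlation(y_true, y_pred),
                           error = function(e) NA_real_),
    rpg = if (!is.null(y_opt)) rpg(y_true, y_pred, y_opt) else NA_real_,
    auc = NA_real_, brier = NA_real_)
  if (all(y_true %in% c(0, 1)) && length(unique(y_true)) == 2L) {
    out$auc <- auc(y_true, y_pred)
    out$brier <- brier(y_true, y_pred)
  }
  out
}

#' Write predictions to `<prefix>.pred.txt`
#' @param pred a `bslmm_prediction`.
#' @param prefix output prefix.
#' @param ids optional individual identifiers.
#' @export
write_prediction <- function(pred, prefix, ids = NULL) {
  n <- length(pred$y_hat)
  df <- data.frame(id = if (is.null(ids)) seq_len(n) else ids,
                   y_hat = pred$y_hat, sparse = pred$sparse,
                   random = pred$random)
  path <- paste0(prefix, ".pred.txt")
  write.table(format(df, digits = 8, trim = TRUE), path, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
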