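# Synthetic GWAS-like data: binomial genotype dosages with optional local
# LD, and the two phenotype architectures used for benchmarking --
# Scenario I (a fixed number of causal SNPs with standard-normal effects)
# and Scenario II (a small group of moderate effects plus a large polygenic
# group of tiny effects). Residual noise is rescaled per replicate so the
# realized PVE equals the target exactly, which gives every simulated
# dataset a known "true PVE" line.

#' Simulate GWAS-like genotype dosages
#'
#' Per-marker minor allele frequencies are drawn uniformly in `maf_range`;
#' dosages are the sum of two Bernoulli(MAF) haplotype alleles. With
#' `ld_block > 1`, markers are grouped into blocks of consecutive markers
#' and each haplotype allele is copied from the block's first marker with
#' probability `copy_prob`, inducing local correlation. No population
#' structure is simulated (see the methods vignette for what this does and
#' does not emulate).
#'
#' @param n individuals.
#' @param p markers.
#' @param maf_range MAF interval, subset of (0, 0.5\].
#' @param ld_block markers per LD block (1 = independent markers).
#' @param copy_prob within-block haplotype copying probability.
#' @return A raw (uncentered) [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.05, 0.5), ld_block = 1L,
                               copy_prob = 0.7) {
  stopifnot(n >= 1, p >= 1, ld_block >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  maf <- runif(p, maf_range[1], maf_range[2])
  if (ld_block == 1L) {
    dos <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  } else {
    dos <- matrix(0L, n, p)
    j <- 1L
    while (j <= p) {
      j_end <- min(j + ld_block - 1L, p)
      h1 <- rbinom(n, 1L, maf[j]); h2 <- rbinom(n, 1L, maf[j])
      dos[, j] <- h1 + h2
      for (k in seq.int(j + 1L, length.out = j_end - j)) {
        c1 <- rbinom(n, 1L, copy_prob); c2 <- rbinom(n, 1L, copy_prob)
        a1 <- ifelse(c1 == 1L, h1, rbinom(n, 1L, maf[k]))
        a2 <- ifelse(c2 == 1L, h2, rbinom(n, 1L, maf[k]))
        dos[, k] <- a1 + a2
      }
      j <- j_end + 1L
    }
  }
  g <- genotype_matrix(dos, validate = FALSE)
  g$maf <- maf
  g
}

# shared helper: rescale iid noise so the realized variance ratio
# V(g)/(V(g) + V(noise)) equals target exactly
scale_noise_to_pve <- function(genetic, target_pve) {
  vg <- sample_variance(genetic)
  e <- rnorm(length(genetic))
  ve <- sample_variance(e)
  c_e <- sqrt(vg * (1 - target_pve) / (target_pve * ve))
  e * c_e
}

#' Scenario I phenotype simulation: S causal SNPs
#'
#' Chooses `S` causal markers uniformly at random, draws their effects from
#' a standard normal distribution, and adds iid Gaussian noise scaled so
#' that the realized PVE, `V(X beta) / (V(X beta) + V(e))` with `V` the
#' population-style variance, equals `target_pve` exactly.
#'
#' @param g a centered [genotype_matrix()].
#' @param S number of causal SNPs (`<= p`).
#' @param target_pve realized PVE, in (0, 1).
#' @return list with `phenotype` (a `phenotype_vector`) and `truth`
#'   (class `sim_truth`: `causal_ids`, `beta_true`, `genetic_component`,
#'   `realized_pve`, `scenario`, ...).
#' @export
simulate_scenario1 <- function(g, S, target_pve) {
  stopifnot(inherits(g, "genotype_matrix"), g$centered)
  p <- ncol(g$dosages)
  stopifnot(S >= 1, S <= p, target_pve > 0, target_pve < 1)
  for (try in 1:10) {
    causal <- sort(sample.int(p, S))
    beta <- numeric(p)
    beta[causal] <- rnorm(S)
    genetic <- drop(g$dosages[, causal, drop = FALSE] %*% beta[causal])
    if (sample_variance(genetic) > 0) break
    if (try == 10) stop("all sampled causal sets give zero genetic variance")
  }
  noise <- scale_noise_to_pve(genetic, target_pve)
  y <- genetic + noise
  truth <- structure(list(
    causal_ids = causal, beta_true = beta, genetic_component = genetic,
    u_true = rep(0, length(genetic)), noise = noise,
    realized_pve = sample_variance(genetic) /
      (sample_variance(genetic) + sample_variance(noise)),
    scenario = "I", group_sizes = c(S = S)), class = "sim_truth")
  list(phenotype = phenotype_vector(y), truth = truth)
}

#' Scenario II phenotype simulation: moderate + polygenic causal groups
#'
#' Two disjoint causal groups: `S_large` SNPs of moderate effect and
#' `S_small` SNPs of small effect (the polygenic component). Both groups'
#' effects are drawn standard normal, then the moderate group is rescaled
#' so its realized share of the total genetic variance equals `pge_target`
#' exactly (solving a quadratic that accounts for the realized covariance
#' between the two groups' contributions); noise is then scaled as in
#' Scenario I so the realized PVE equals `target_pve`.
#'
#' @param g a centered [genotype_matrix()].
#' @param S_large,S_small group sizes (`S_large + S_small <= p`;
#'   `S_large = 0` gives a pure polygenic background).
#' @param pge_target realized share of genetic variance from the moderate
#'   group, in \[0, 1).
#' @param target_pve realized PVE, in (0, 1).
#' @return As [simulate_scenario1()]; `truth$u_true` holds the polygenic
#'   group's contribution.
#' @export
simulate_scenario2 <- function(g, S_large, S_small, pge_target, target_pve) {
  stopifnot(inherits(g, "genotype_matrix"), g$centered)
  p <- ncol(g$dosages)
  stopifnot(S_large >= 0, S_small >= 1, S_large + S_small <= p,
            pge_target >= 0, pge_target < 1, target_pve > 0, target_pve < 1)
  for (try in 1:10) {
    idx <- sample.int(p, S_large + S_small)
    large <- sort(idx[seq_len(S_large)])
    small <- sort(idx[seq.int(S_large + 1L, length.out = S_small)])
    beta_l <- rnorm(S_large)
    beta_s <- rnorm(S_small)
    gl <- if (S_large > 0)
      drop(g$dosages[, large, drop = FALSE] %*% beta_l) else numeric(nrow(g$dosages))
    gs <- drop(g$dosages[, small, drop = FALSE] %*% beta_s)
    vl <- sample_variance(gl); vs <- sample_variance(gs)
    if (vs > 0 && (S_large == 0 || vl > 0)) break
    if (try == 10) stop("causal groups give zero genetic variance")
  }
  if (S_large > 0 && pge_target > 0) {
    # find r scaling the moderate group so V(r gl)/V(r gl + gs) = pge_target
    cv <- mean(gl * gs) - mean(gl) * mean(gs)
    a <- vl * (1 - pge_target); b <- -2 * pge_target * cv
    cc <- -pge_target * vs
    r <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
    gl <- r * gl
    beta_l <- r * beta_l
  } else {
    gl <- 0 * gl; beta_l <- 0 * beta_l
  }
  genetic <- gl + gs
  noise <- scale_noise_to_pve(genetic, target_pve)
  y <- genetic + noise
  beta <- numeric(p)
  if (S_large > 0) beta[large] <- beta_l
  beta[small] <- beta_s
  vtot <- sample_variance(genetic)
  truth <- structure(list(
    causal_ids = sort(c(large, small)), causal_large = large,
    causal_small = small, beta_true = beta, genetic_component = genetic,
    u_true = gs, noise = noise,
    realized_pve = vtot / (vtot + sample_variance(noise)),
    realized_pge = if (vtot > 0) sample_variance(gl) / vtot else 0,
    scenario = "II",
    group_sizes = c(S_large = S_large, S_small = S_small)),
    class = "sim_truth")
  list(phenotype = phenotype_vector(y), truth = truth)
}

#' Split individuals into training and test sets
#'
#' `mode = "random"` splits individuals at random; `mode = "by_group"`
#' splits whole groups (e.g. families) so no group appears on both sides
#' (the inter-family setting of pedigreed populations).
#'
#' @param n number of individuals.
#' @param fraction training fraction, in (0, 1).
#' @param families optional group labels (length n), required for
#'   `by_group`.
#' @param mode `"random"` or `"by_group"`.
#' @return list with `train` and `test` index vectors (disjoint, covering
#'   `1:n`).
#' @export
split_train_test <- function(n, fraction, families = NULL,
                             mode = c("random", "by_group")) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction < 1)
  if (mode == "random") {
    train <- sort(sample.int(n, round(fraction * n)))
  } else {
    if (is.null(families)) stop("by_group split requires group labels")
    stopifnot(length(families) == n)
    fam <- unique(families)
    fam <- fam[sample.int(length(fam))]
    sizes <- cumsum(vapply(fam, function(f) sum(families == f), 0L))
    k <- which.min(abs(sizes - fraction * n))
    train <- sort(which(families %in% fam[seq_len(k)]))
  }
  list(train = train, test = sort(setdiff(seq_len(n), train)))
}

#' Write a simulated dataset to disk
#'
#' Emits the BIMBAM genotype file, phenotype file, kinship (optional),
#' a truth sidecar (`<prefix>.truth.txt`: marker id, true effect, causal
#' flag) and a JSON manifest with the scenario, seed and realized PVE.
#'
#' @param g raw [genotype_matrix()] (as simulated, uncentered).
#' @param sim result of [simulate_scenario1()] / [simulate_scenario2()].
#' @param prefix output path prefix.
#' @param seed seed recorded in the manifest.
#' @param kin optional [kinship()] to write alongside.
#' @return invisibly, the written file paths.
#' @export
write_simulation <- function(g, sim, prefix, seed = NA_integer_, kin = NULL) {
  fgeno <- paste0(prefix, ".geno.txt")
  fpheno <- paste0(prefix, ".pheno.txt")
  ftruth <- paste0(prefix, ".truth.txt")
  fman <- paste0(prefix, ".json")
  write_bimbam_genotypes(g, fgeno)
  write_phenotypes(sim$phenotype, fpheno)
  truth <- sim$truth
  df <- data.frame(id = g$marker_ids, beta_true = truth$beta_true,
                   causal = as.integer(seq_along(truth$beta_true) %in%
                                         truth$causal_ids))
  write.table(format(df, digits = 17, trim = TRUE), ftruth, quote = FALSE,
              row.names = FALSE)
  man <- list(seed = seed, scenario = truth$scenario,
              n = nrow(g$dosages), p = ncol(g$dosages),
              group_sizes = as.list(truth$group_sizes),
              realized_pve = truth$realized_pve)
  if (!is.null(truth$realized_pge)) man$realized_pge <- truth$realized_pge
  jsonlite::write_json(man, fman, auto_unbox = TRUE, digits = NA)
  paths <- c(fgeno, fpheno, ftruth, fman)
  if (!is.null(kin)) {
    fk <- paste0(prefix, ".kinship.txt")
    write_kinship(kin, fk)
    paths <- c(paths, fk)
  }
  invisible(paths)
}
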