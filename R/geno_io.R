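# Genotype, phenotype and relatedness-matrix I/O plus the derived
# quantities the model needs (centering, imputation, kinship, s_a, s_b).

#' Construct a genotype matrix object
#'
#' A `genotype_matrix` holds an n (individuals) by p (markers) dosage matrix
#' with dosages coded as 0, 1 or 2 copies of the reference allele, together
#' with marker metadata and, after [impute_and_center()], per-column means,
#' variances and the average genotype variance `s_a` used to scale the
#' expected sparse genetic variance.
#'
#' @param dosages numeric n x p matrix, raw values in \[0, 2\]; `NA` marks
#'   missing dosages.
#' @param marker_ids character vector of length p (default `snp1..snpp`).
#' @param allele_pair optional p x 2 character matrix (minor, major allele).
#' @param validate check the dosage range (default `TRUE`).
#' @return An object of class `genotype_matrix` with fields `dosages`,
#'   `marker_ids`, `allele_pair`, `missing_mask`, `centered`, `col_means`,
#'   `col_vars`, `s_a`.
#' @export
genotype_matrix <- function(dosages, marker_ids = NULL, allele_pair = NULL,
                            validate = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  p <- ncol(dosages)
  if (is.null(marker_ids)) marker_ids <- paste0("snp", seq_len(p))
  if (length(marker_ids) != p)
    stop("marker_ids length (", length(marker_ids), ") != number of markers (", p, ")")
  if (validate) {
    rng <- range(dosages, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < -1e-6 || rng[2] > 2 + 1e-6))
      stop("dosages outside [0, 2]: observed range [",
           signif(rng[1], 6), ", ", signif(rng[2], 6), "]")
  }
  structure(list(
    dosages = dosages,
    marker_ids = as.character(marker_ids),
    allele_pair = allele_pair,
    missing_mask = is.na(dosages),
    centered = FALSE,
    col_means = NULL,
    col_vars = NULL,
    s_a = NULL
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%s, %d missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              if (x$centered) "centered" else "raw", sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read a BIMBAM mean-genotype file
#'
#' Each line holds one marker: marker id, two allele codes, then n dosages
#' in \[0, 2\] (`NA` allowed), separated by commas and/or whitespace.
#'
#' @param path file path.
#' @return A [genotype_matrix()] (n x p, raw dosages, marker order as in the
#'   file).
#' @export
read_bimbam_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty genotype file: ", path)
  toks <- strsplit(trimws(lines), "[,[:space:]]+")
  len <- lengths(toks)
  if (any(len != len[1]))
    stop("parse error in ", path, ": ragged line ",
         which(len != len[1])[1], " (", len[which(len != len[1])[1]],
         " fields, expected ", len[1], ")")
  if (len[1] < 4L)
    stop("parse error in ", path, ": need marker id, two alleles and at least one dosage")
  p <- length(toks)
  n <- len[1] - 3L
  marker_ids <- vapply(toks, `[[`, "", 1L)
  allele_pair <- cbind(vapply(toks, `[[`, "", 2L), vapply(toks, `[[`, "", 3L))
  vals <- suppressWarnings(
    vapply(toks, function(tk) as.numeric(tk[-(1:3)]), numeric(n)))
  bad <- vapply(toks, function(tk) {
    v <- tk[-(1:3)]
    any(is.na(suppressWarnings(as.numeric(v))) & toupper(v) != "NA")
  }, logical(1))
  if (any(bad))
    stop("parse error in ", path, ": non-numeric dosage on line ", which(bad)[1])
  dosages <- matrix(vals, nrow = n, ncol = p)  # vapply: one column per marker
  genotype_matrix(dosages, marker_ids, allele_pair)
}

#' Write a BIMBAM mean-genotype file
#'
#' Dosages are written with 17 significant digits so that a write/read
#' round-trip reproduces them bit-exactly.
#'
#' @param g a [genotype_matrix()] (raw, uncentered dosages).
#' @param path output file path.
#' @export
write_bimbam_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$centered) stop("refusing to write centered dosages in BIMBAM format")
  ap <- g$allele_pair
  if (is.null(ap)) ap <- cbind(rep("A", ncol(g$dosages)), rep("B", ncol(g$dosages)))
  lines <- vapply(seq_len(ncol(g$dosages)), function(j) {
    v <- g$dosages[, j]
    vs <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
    paste(c(g$marker_ids[j], ap[j, 1], ap[j, 2], vs), collapse = ", ")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain n x p genotype dosage matrix
#'
#' Header-free whitespace-delimited text, one individual per row; an
#' optional sidecar file gives one marker id per line.
#'
#' @param path matrix file path.
#' @param marker_file optional path of the marker-id sidecar.
#' @return A [genotype_matrix()].
#' @export
read_plain_genotypes <- function(path, marker_file = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  ids <- if (!is.null(marker_file)) readLines(marker_file) else NULL
  genotype_matrix(m, marker_ids = ids)
}

#' Read a phenotype file
#'
#' One value per line, `NA` for missing. Individuals with missing phenotype
#' are excluded from the likelihood by [run_mcmc()] but retained for
#' prediction.
#'
#' @param path file path.
#' @return A list of class `phenotype_vector` with `values`, `missing_mask`
#'   and `is_binary` (all observed values in \{0, 1\}).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  v <- suppressWarnings(as.numeric(trimws(readLines(path))))
  phenotype_vector(v)
}

#' Construct a phenotype vector object
#'
#' @param values numeric vector, `NA` for missing.
#' @return A `phenotype_vector` (see [read_phenotypes()]).
#' @export
phenotype_vector <- function(values) {
  values <- as.numeric(values)
  obs <- values[!is.na(values)]
  structure(list(
    values = values,
    missing_mask = is.na(values),
    is_binary = length(obs) > 0 && all(obs %in% c(0, 1))
  ), class = "phenotype_vector")
}

#' Write a phenotype file
#' @param y `phenotype_vector` or numeric vector.
#' @param path output path.
#' @export
write_phenotypes <- function(y, path) {
  v <- if (inherits(y, "phenotype_vector")) y$values else as.numeric(y)
  writeLines(ifelse(is.na(v), "NA", sprintf("%.17g", v)), path)
  invisible(path)
}

#' Impute missing dosages and center genotype columns
#'
#' Missing entries are replaced by the per-marker mean of the observed
#' dosages (common mixed-model practice), then every column is centered to
#' mean zero. Columns are deliberately not standardized. Populates
#' `col_means`, `col_vars` (population-style variance, divisor n) and
#' `s_a`, the average variance of genotypes across markers.
#'
#' @param g a [genotype_matrix()] with raw dosages.
#' @return The centered `genotype_matrix`.
#' @export
impute_and_center <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$centered) return(g)
  X <- g$dosages
  n <- nrow(X)
  n_obs <- n - colSums(g$missing_mask)
  if (any(n_obs == 0L))
    stop("marker(s) fully missing: ",
         paste(g$marker_ids[n_obs == 0L], collapse = ", "))
  if (any(g$missing_mask)) {
    mu_obs <- colSums(ifelse(g$missing_mask, 0, X)) / n_obs
    idx <- which(g$missing_mask, arr.ind = TRUE)
    X[idx] <- mu_obs[idx[, 2]]
  }
  cm <- colMeans(X)
  X <- sweep(X, 2L, cm)
  g$dosages <- X
  g$col_means <- cm
  g$col_vars <- colSums(X^2) / n
  g$s_a <- mean(g$col_vars)
  g$centered <- TRUE
  g
}

#' Construct a kinship (relatedness) object from a matrix
#'
#' Computes and caches the eigendecomposition. Eigenvalues below
#' `1e-8 * max(eigenvalue)` (including small negatives from round-off; the
#' genomic relationship matrix has rank at most min(n - 1, p)) are clamped
#' to exactly zero.
#'
#' @param K symmetric n x n numeric matrix.
#' @return An object of class `kinship` with fields `K`, `s_b` (mean
#'   diagonal), `eigenvalues` (descending) and `eigenvectors`.
#' @export
kinship <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kinship matrix must be square")
  asym <- max(abs(K - t(K)))
  if (asym > 1e-6)
    stop("kinship matrix asymmetric beyond tolerance (max |K - t(K)| = ",
         signif(asym, 4), ")")
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  lam <- e$values
  if (length(lam) > 0 && max(lam) > 0) {
    lam[lam < 1e-8 * max(lam)] <- 0
  } else {
    lam[lam < 0] <- 0
  }
  structure(list(
    K = K,
    s_b = mean(diag(K)),
    eigenvalues = lam,
    eigenvectors = e$vectors
  ), class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("kinship: %d x %d, mean diagonal s_b = %.4g, rank %d\n",
              nrow(x$K), ncol(x$K), x$s_b, sum(x$eigenvalues > 0)))
  invisible(x)
}

#' Compute the genomic relationship matrix from centered genotypes
#'
#' `K = X X' / p` with `X` the centered (not standardized) dosage matrix.
#'
#' @param g a centered [genotype_matrix()].
#' @return A [kinship()] object.
#' @export
compute_kinship <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!g$centered) stop("genotypes must be centered first (impute_and_center)")
  p <- ncol(g$dosages)
  if (p == 0L) stop("no markers: cannot compute kinship")
  kinship(tcrossprod(g$dosages) / p)
}

#' Read a plain-text kinship matrix
#'
#' Whitespace-delimited n x n numeric text. The matrix is symmetrized as
#' `(K + t(K))/2` when the asymmetry is within 1e-6, otherwise an error is
#' raised.
#'
#' @param path file path.
#' @param n expected dimension.
#' @return A [kinship()] object.
#' @export
read_kinship <- function(path, n) {
  if (!file.exists(path)) stop("kinship file not found: ", path)
  K <- as.matrix(read.table(path, header = FALSE))
  dimnames(K) <- NULL
  if (nrow(K) != n || ncol(K) != n)
    stop("kinship dimensions ", nrow(K), " x ", ncol(K),
         " do not match expected n = ", n)
  kinship(K)
}

#' Write a kinship matrix as whitespace-delimited text
#' @param kin a [kinship()] object or plain matrix.
#' @param path output path.
#' @export
write_kinship <- function(kin, path) {
  K <- if (inherits(kin, "kinship")) kin$K else as.matrix(kin)
  write.table(format(K, digits = 17, scientific = TRUE, trim = TRUE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Cross-block relatedness between test and training individuals
#'
#' Rows are test individuals, columns training individuals, built with the
#' training marker set and the same `1/p` scaling as the training kinship.
#' Test dosages are centered with the training column means so prediction
#' never peeks at the test distribution.
#'
#' @param g_test raw (uncentered) test [genotype_matrix()].
#' @param g_train centered training [genotype_matrix()].
#' @return numeric n_test x n_train matrix.
#' @export
compute_kinship_cross <- function(g_test, g_train) {
  stopifnot(inherits(g_test, "genotype_matrix"),
            inherits(g_train, "genotype_matrix"))
  if (!g_train$centered) stop("training genotypes must be centered")
  if (!identical(g_test$marker_ids, g_train$marker_ids)) {
    off <- setdiff(union(g_test$marker_ids, g_train$marker_ids),
                   intersect(g_test$marker_ids, g_train$marker_ids))
    stop("marker mismatch between train and test: ",
         paste(head(off, 5L), collapse = ", "),
         if (length(off) > 5L) " ..." else "")
  }
  Xte <- center_with_means(g_test, g_train$col_means)
  tcrossprod(Xte, g_train$dosages) / ncol(g_train$dosages)
}

# center (possibly raw) test dosages using training means; imputes missing
# test dosages with the training means (i.e. centered value 0).
center_with_means <- function(g, means) {
  X <- g$dosages
  if (g$centered) return(X)
  if (any(g$missing_mask)) {
    idx <- which(g$missing_mask, arr.ind = TRUE)
    X[idx] <- means[idx[, 2]]
  }
  sweep(X, 2L, means)
}

#' Subset a genotype matrix by individuals and/or markers
#' @param g a [genotype_matrix()].
#' @param individuals,markers index vectors (default: keep all).
#' @return A `genotype_matrix`; centering metadata is preserved (column
#'   means/variances are recomputed when markers are dropped on a centered
#'   matrix).
#' @export
subset_genotypes <- function(g, individuals = NULL, markers = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  ii <- if (is.null(individuals)) seq_len(nrow(g$dosages)) else individuals
  jj <- if (is.null(markers)) seq_len(ncol(g$dosages)) else markers
  out <- g
  out$dosages <- g$dosages[ii, jj, drop = FALSE]
  out$missing_mask <- g$missing_mask[ii, jj, drop = FALSE]
  out$marker_ids <- g$marker_ids[jj]
  if (!is.null(g$allele_pair)) out$allele_pair <- g$allele_pair[jj, , drop = FALSE]
  if (g$centered) {
    out$col_means <- g$col_means[jj]
    # population-style variance of the retained rows; after dropping
    # individuals the columns need not be exactly mean-zero any more
    out$col_vars <- colMeans(out$dosages^2) - colMeans(out$dosages)^2
    out$s_a <- mean(out$col_vars)
  }
  out
}
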