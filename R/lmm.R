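#' Centered genetic relatedness matrix
#'
#' `K = (1/m) * sum_j (x_j - mean(x_j)) (x_j - mean(x_j))'` over all `m` SNPs,
#' with missing dosages imputed to the per-SNP mean before centering.
#' Monomorphic SNPs contribute zeros (centering annihilates constants). The
#' spectral decomposition is computed once and cached for the mixed-model
#' fits; eigenvalues are clamped at zero (the matrix is PSD up to roundoff).
#'
#' @param dataset a [genotype_dataset()], or a plain dosage matrix
#'   (individuals x SNPs).
#' @return an object of class `KinshipMatrix`: list with `K`, `n`,
#'   `eigenvalues`, `eigenvectors`.
#' @export
centered_grm <- function(dataset) {
  G <- if (inherits(dataset, "GenotypeDataset")) dataset$genotypes else dataset
  n <- nrow(G)
  if (n < 2) stop("need at least 2 individuals")
  M <- impute_mean_cols(G)
  M <- scale(M, center = TRUE, scale = FALSE)
  poly <- apply(M, 2, function(x) any(x != 0))
  if (!any(poly)) stop("no polymorphic SNPs: cannot build a relatedness matrix")
  K <- tcrossprod(M) / ncol(M)
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  structure(list(K = K, n = n,
                 eigenvalues = pmax(e$values, 0),
                 eigenvectors = e$vectors),
            class = "KinshipMatrix")
}

#' @export
print.KinshipMatrix <- function(x, ...) {
  cat("KinshipMatrix:", x$n, "x", x$n, "; leading eigenvalues:",
      paste(sprintf("%.3g", utils::head(x$eigenvalues, 3)), collapse = " "),
      "\n")
  invisible(x)
}

# per-column mean imputation of missing dosages
impute_mean_cols <- function(G) {
  if (!anyNA(G)) return(G)
  mu <- colMeans(G, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(G))
  G[idx] <- mu[(idx - 1) %/% nrow(G) + 1]
  G
}

as_kinship <- function(K) {
  if (inherits(K, "KinshipMatrix")) return(K)
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  structure(list(K = K, n = nrow(K), eigenvalues = pmax(e$values, 0),
                 eigenvectors = e$vectors), class = "KinshipMatrix")
}

#' Profile ML log-likelihood of the mixed model at fixed lambda
#'
#' For `y = 1a + xb + u + e`, `u ~ N(0, lambda/tau K)`, `e ~ N(0, I/tau)`,
#' rotates into the kinship eigenbasis, profiles the fixed effects and `tau`
#' out in closed form, and returns the maximized log-likelihood at the given
#' variance ratio `lambda`. This is the quantity the optimizer in [fit_lmm()]
#' maximizes over `lambda`.
#'
#' @param y phenotype vector.
#' @param x optional SNP dosage vector (intercept-only null model if NULL).
#' @param K a `KinshipMatrix` (or symmetric matrix).
#' @param lambda genetic-to-residual variance ratio (> 0 or 0).
#' @return log-likelihood value.
#' @export
lmm_profile_logL <- function(y, x = NULL, K, lambda) {
  K <- as_kinship(K)
  y <- y - mean(y)  # see fit_lmm; the intercept stays in the model
  Ut <- t(K$eigenvectors)
  uy <- drop(Ut %*% y)
  uw <- drop(Ut %*% rep(1, K$n))
  ux <- if (is.null(x)) NULL else drop(Ut %*% impute_mean_vec(x))
  cpp_profile_logL(lambda, K$eigenvalues, uy, uw, ux)
}

impute_mean_vec <- function(x) {
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  x
}

#' Fit the univariate linear mixed model for one SNP
#'
#' Maximum-likelihood fit obtained by rotating `y`, `x` and the intercept into
#' the kinship eigenbasis, profiling out the fixed effects and the residual
#' precision, and maximizing the 1-d profile log-likelihood in `log10(lambda)`
#' over `[-5, 5]` (coarse multi-start grid plus golden-section refinement;
#' ties broken toward smaller lambda). ML rather than REML likelihoods are
#' returned so that likelihood-ratio tests between nested models are valid.
#'
#' @param y phenotype vector (finite).
#' @param x SNP dosage vector, or NULL for the intercept-only null model;
#'   missing dosages are imputed to the SNP mean.
#' @param K a `KinshipMatrix` from [centered_grm()].
#' @return list with `beta`, `se_beta`, `lambda_hat`, `logL`, and `flagged`
#'   (TRUE when `x` is constant after imputation; then `beta = 0`).
#' @export
fit_lmm <- function(y, x = NULL, K) {
  K <- as_kinship(K)
  stopifnot(length(y) == K$n, all(is.finite(y)))
  y <- y - mean(y)  # intercept absorbs the mean; centering is numerically safer
  Ut <- t(K$eigenvectors)
  uy <- drop(Ut %*% y)
  uw <- drop(Ut %*% rep(1, K$n))
  null <- cpp_lmm_null(K$eigenvalues, uy, uw)
  if (is.null(x)) {
    return(list(beta = NA_real_, se_beta = NA_real_,
                lambda_hat = unname(null["lambda"]),
                logL = unname(null["logL"]), flagged = FALSE))
  }
  x <- impute_mean_vec(x)
  if (stats::sd(x) == 0) {
    return(list(beta = 0, se_beta = NA_real_, lambda_hat = NA_real_,
                logL = unname(null["logL"]), flagged = TRUE))
  }
  fit <- cpp_lmm_scan(K$eigenvalues, uy, uw, Ut %*% matrix(x, ncol = 1))
  if (is.na(fit[1, "logL"])) {
    return(list(beta = 0, se_beta = NA_real_, lambda_hat = NA_real_,
                logL = unname(null["logL"]), flagged = TRUE))
  }
  list(beta = unname(fit[1, "beta"]), se_beta = unname(fit[1, "se_beta"]),
       lambda_hat = unname(fit[1, "lambda"]), logL = unname(fit[1, "logL"]),
       flagged = FALSE)
}

#' Genome-wide LMM likelihood-ratio scan
#'
#' Fits the null (intercept-only) mixed model once, then the SNP-inclusive
#' model for every SNP, and tests each SNP by the likelihood-ratio statistic
#' `2 (logL_alt - logL_null)` (clamped at 0) referred to chi-square with 1
#' degree of freedom. SNPs that are monomorphic after mean imputation are
#' flagged (`beta = 0`, `p = 1`) rather than aborting the scan.
#'
#' @param dataset a [genotype_dataset()].
#' @param y per-individual phenotype vector, e.g. from
#'   [assign_breed_means()].
#' @param K optional precomputed [centered_grm()]; built from `dataset` when
#'   NULL.
#' @return data.frame of association records: `snp`, `chrom`, `pos`, `beta`,
#'   `se_beta`, `lambda_hat`, `logL_alt`, `logL_null`, `lrt_stat`, `p_value`,
#'   `flagged`.
#' @export
lmm_lrt_scan <- function(dataset, y, K = NULL) {
  validate_genotype_dataset(dataset)
  stopifnot(length(y) == length(dataset$individuals), all(is.finite(y)))
  if (is.null(K)) K <- centered_grm(dataset)
  K <- as_kinship(K)
  y <- y - mean(y)  # see fit_lmm
  G <- impute_mean_cols(dataset$genotypes)
  mono <- apply(G, 2, function(x) all(x == x[1]))
  Ut <- t(K$eigenvectors)
  uy <- drop(Ut %*% y)
  uw <- drop(Ut %*% rep(1, K$n))
  null <- cpp_lmm_null(K$eigenvalues, uy, uw)
  m <- ncol(G)
  beta <- numeric(m); se <- rep(NA_real_, m)
  lam <- rep(NA_real_, m); logL <- rep(unname(null["logL"]), m)
  flagged <- mono
  if (any(!mono)) {
    UX <- Ut %*% G[, !mono, drop = FALSE]
    fit <- cpp_lmm_scan(K$eigenvalues, uy, uw, UX)
    bad <- is.na(fit[, "logL"])
    fit[bad, "beta"] <- 0
    fit[bad, "logL"] <- unname(null["logL"])
    flagged[!mono][bad] <- TRUE
    beta[!mono] <- fit[, "beta"]; se[!mono] <- fit[, "se_beta"]
    lam[!mono] <- fit[, "lambda"]; logL[!mono] <- fit[, "logL"]
    lam[!mono][bad] <- NA_real_; se[!mono][bad] <- NA_real_
  }
  lrt <- pmax(0, 2 * (logL - unname(null["logL"])))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  p[flagged] <- 1
  lrt[flagged] <- 0
  data.frame(snp = dataset$snp_map$snp, chrom = dataset$snp_map$chrom,
             pos = dataset$snp_map$pos, beta = beta, se_beta = se,
             lambda_hat = lam, logL_alt = logL,
             logL_null = unname(null["logL"]), lrt_stat = lrt,
             p_value = p, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Genome-wide significance policy
#'
#' @param threshold inclusive p-value cutoff in (0, 1); the conventions used
#'   for the two array cohorts in this line of work are `1e-8` (CanineHD,
#'   ~175k SNPs) and `1e-5` (~45k SNPs).
#' @return a `significance_policy` object.
#' @export
significance_policy <- function(threshold = 1e-8) {
  stopifnot(threshold > 0, threshold < 1)
  structure(list(threshold = threshold), class = "significance_policy")
}

#' Filter a scan to genome-wide significant hits
#'
#' Retains records with `p_value <= threshold` (inclusive), sorted by
#' ascending p-value.
#'
#' @param records data.frame from [lmm_lrt_scan()].
#' @param policy a [significance_policy()] or bare numeric threshold.
#' @return the filtered, sorted records.
#' @export
significant_hits <- function(records, policy = significance_policy()) {
  thr <- if (inherits(policy, "significance_policy")) policy$threshold
         else as.numeric(policy)
  out <- records[records$p_value <= thr, , drop = FALSE]
  out[order(out$p_value), , drop = FALSE]
}

#' Naive per-SNP ordinary least squares scan
#'
#' Simple linear regression of phenotype on dosage with no relatedness
#' correction, as a structure-blind baseline: under strong breed structure its
#' type-I error is badly inflated, which is what the mixed model corrects.
#'
#' @param dataset a [genotype_dataset()].
#' @param y per-individual phenotype vector.
#' @return data.frame with `snp`, `p_value`.
#' @export
ols_scan <- function(dataset, y) {
  G <- impute_mean_cols(dataset$genotypes)
  n <- nrow(G)
  xc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  syy <- sum(yc^2)
  r2 <- ifelse(sxx > 0, sxy^2 / (sxx * syy), 0)
  r2 <- pmin(r2, 1 - 1e-15)
  tstat <- sqrt(r2 * (n - 2) / (1 - r2))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  p[sxx == 0] <- 1
  data.frame(snp = dataset$snp_map$snp, p_value = p,
             stringsAsFactors = FALSE)
}
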