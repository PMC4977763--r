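#' Pairwise linkage disequilibrium (r-squared and D')
#'
#' Composite r-squared is the squared Pearson correlation of genotype
#' dosages (pairwise-complete individuals). D' uses two-locus haplotype
#' frequencies inferred by EM over the double-heterozygote phase ambiguity,
#' normalized by the admissible maximum of D. Monomorphic SNPs in the chosen
#' subset are excluded with a message.
#'
#' @param dataset a [genotype_dataset()].
#' @param region either a vector of SNP ids, or a list/vector
#'   `c(chrom, start, end)` selecting mapped SNPs; NULL for all SNPs.
#' @param breeds optional breed subset (default all individuals).
#' @param em_iter,em_tol EM iteration cap and convergence tolerance.
#' @return list with matrices `r2` and `dprime` and the `snps` used.
#' @export
pairwise_ld <- function(dataset, region = NULL, breeds = NULL,
                        em_iter = 100L, em_tol = 1e-10) {
  map <- dataset$snp_map
  sel <- if (is.null(region)) seq_len(nrow(map))
  else if (is.character(region)) {
    miss <- setdiff(region, map$snp)
    if (length(miss)) stop("unknown SNP(s): ", paste(miss, collapse = ", "))
    match(region, map$snp)
  } else {
    which(map$chrom == region[[1]] & map$pos >= region[[2]] &
          map$pos <= region[[3]])
  }
  rows <- if (is.null(breeds)) seq_along(dataset$individuals)
          else which(dataset_breeds(dataset) %in% breeds)
  G <- dataset$genotypes[rows, sel, drop = FALSE]
  poly <- apply(G, 2, function(x) length(unique(x[!is.na(x)])) > 1)
  if (any(!poly))
    message("excluding ", sum(!poly), " monomorphic SNP(s) from LD")
  G <- G[, poly, drop = FALSE]
  snps <- map$snp[sel][poly]
  m <- ncol(G)
  if (m < 2) stop("need at least 2 polymorphic SNPs in region")
  r2 <- stats::cor(G, use = "pairwise.complete.obs")^2
  dp <- matrix(1, m, m, dimnames = list(snps, snps))
  for (a in seq_len(m - 1)) {
    for (b in seq(a + 1, m)) {
      dp[a, b] <- dp[b, a] <- em_dprime(G[, a], G[, b], em_iter, em_tol)
    }
  }
  dimnames(r2) <- list(snps, snps)
  list(r2 = r2, dprime = dp, snps = snps)
}

# |D'| between two dosage vectors via EM haplotype-frequency estimation
em_dprime <- function(g1, g2, em_iter = 100L, em_tol = 1e-10) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  N <- length(g1)
  if (N < 2) return(NA_real_)
  n <- table(factor(g1, 0:2), factor(g2, 0:2))
  p <- mean(g1) / 2; q <- mean(g2) / 2
  if (p %in% c(0, 1) || q %in% c(0, 1)) return(NA_real_)
  h <- c(p * q, p * (1 - q), (1 - p) * q, (1 - p) * (1 - q))  # h11 h12 h21 h22
  for (it in seq_len(em_iter)) {
    cis <- h[1] * h[4]
    trans <- h[2] * h[3]
    cshare <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    dh <- n["1", "1"]
    cnt <- c(2 * n["2", "2"] + n["2", "1"] + n["1", "2"] + cshare * dh,
             2 * n["2", "0"] + n["2", "1"] + n["1", "0"] + (1 - cshare) * dh,
             2 * n["0", "2"] + n["1", "2"] + n["0", "1"] + (1 - cshare) * dh,
             2 * n["0", "0"] + n["1", "0"] + n["0", "1"] + cshare * dh)
    h_new <- cnt / (2 * N)
    if (max(abs(h_new - h)) < em_tol) { h <- h_new; break }
    h <- h_new
  }
  p1 <- h[1] + h[2]; q1 <- h[1] + h[3]
  D <- h[1] - p1 * q1
  dmax <- if (D >= 0) min(p1 * (1 - q1), (1 - p1) * q1)
          else min(p1 * q1, (1 - p1) * (1 - q1))
  if (dmax <= 0) return(NA_real_)
  abs(D) / dmax
}
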