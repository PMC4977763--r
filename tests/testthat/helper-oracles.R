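# Shared fixtures and independent oracles used across the suite.

# tiny GenotypeDataset built directly from a dosage matrix
tiny_dataset <- function(g, breeds, chrom = 1L, pos = NULL,
                         a1 = NULL, a2 = NULL) {
  n <- nrow(g); m <- ncol(g)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  ind <- sprintf("i%02d", seq_len(n))
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("C", m)
  map <- data.frame(snp = sprintf("s%03d", seq_len(m)),
                    chrom = rep(chrom, length.out = m), pos = pos,
                    allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  dimnames(g) <- list(ind, map$snp)
  genotype_dataset(ind, stats::setNames(rep(breeds, length.out = n), ind),
                   map, g)
}

# explicit-inverse generalized least squares profile log-likelihood
gls_logL_oracle <- function(lambda, y, X, Kmat) {
  n <- length(y)
  H <- lambda * Kmat + diag(n)
  Hi <- solve(H)
  b <- solve(t(X) %*% Hi %*% X, t(X) %*% Hi %*% y)
  r <- y - X %*% b
  rss <- drop(t(r) %*% Hi %*% r)
  as.numeric(-0.5 * n * log(2 * pi) - 0.5 * determinant(H)$modulus -
             0.5 * n * log(rss / n) - 0.5 * n)
}

# exhaustive enumeration of the maximal peak-containing interval whose SNPs
# all satisfy the majority-frequency rule within the homozygote subset
block_oracle <- function(sub, snp_pass) {
  # snp_pass: logical per SNP on the chromosome (peak index pk)
  function(pk) {
    best <- c(pk, pk)
    for (lo in seq_len(pk)) {
      for (hi in pk:length(snp_pass)) {
        if (all(snp_pass[lo:hi]) && (hi - lo) > (best[2] - best[1]))
          best <- c(lo, hi)
      }
    }
    best
  }
}

# independent stepwise forward/backward selection oracle built on lm()
stepwise_oracle <- function(X, y, alpha = 0.05) {
  candidates <- colnames(X)[apply(X, 2, stats::sd) > 0]
  selected <- character(0)
  seen <- character(0)
  repeat {
    if (length(selected) >= length(y) - 1) break
    pool <- setdiff(candidates, selected)
    if (!length(pool)) break
    ps <- sapply(pool, function(v) {
      df <- as.data.frame(X[, c(selected, v), drop = FALSE])
      fit <- summary(stats::lm(y ~ 0 + ., data = df))
      p <- stats::coef(fit)[, "Pr(>|t|)"]
      if (nrow(stats::coef(fit)) < length(selected) + 1) NA else
        p[length(p)]
    })
    if (!any(!is.na(ps) & ps <= alpha)) break
    selected <- c(selected, pool[which(ps == min(ps, na.rm = TRUE))[1]])
    repeat {
      df <- as.data.frame(X[, selected, drop = FALSE])
      fit <- summary(stats::lm(y ~ 0 + ., data = df))
      p <- stats::coef(fit)[, "Pr(>|t|)"]
      if (max(p) <= alpha) break
      selected <- selected[-which.max(p)]
      if (!length(selected)) break
    }
    key <- paste(sort(selected), collapse = ",")
    if (key %in% seen) break
    seen <- c(seen, key)
  }
  coefs <- if (length(selected)) {
    df <- as.data.frame(X[, selected, drop = FALSE])
    stats::setNames(stats::coef(stats::lm(y ~ 0 + ., data = df)), selected)
  } else stats::setNames(numeric(0), character(0))
  list(selected = selected, coefficients = coefs)
}

# positional A/B label of a fixture's planted risk allele
risk_allele_label <- function(dataset, truth) {
  j <- match(truth$snp, dataset$snp_map$snp)
  ifelse(truth$risk_allele == dataset$snp_map$allele1[j], "A", "B")
}
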