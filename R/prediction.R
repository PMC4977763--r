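#' Breed allele frequencies at selected markers
#'
#' Per breed, the frequency of each marker's counted (allele1) allele:
#' dosage sum over 2 x genotyped count, missing genotypes excluded. Dosage is
#' minor-allele oriented over the full cohort, so the orientation is
#' consistent across breeds.
#'
#' @param dataset a [genotype_dataset()].
#' @param markers SNP ids.
#' @return breed x marker matrix of frequencies.
#' @export
breed_allele_frequencies <- function(dataset, markers) {
  miss <- setdiff(markers, dataset$snp_map$snp)
  if (length(miss)) stop("marker(s) absent from map: ",
                         paste(miss, collapse = ", "))
  bm <- breed_freq_matrix(dataset)
  out <- bm$freq[, match(markers, dataset$snp_map$snp), drop = FALSE]
  colnames(out) <- markers
  out
}

# no-intercept least squares with per-coefficient t tests
ls_no_intercept <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NULL)  # collinear
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  if (df <= 0) return(NULL)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(diag(XtXinv), 0) * s2)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(beta = beta, se = se, p = p, df = df, rss = sum(res^2))
}

#' Stepwise forward selection of breed-frequency predictors
#'
#' Regresses breed trait values on candidate marker allele frequencies with
#' no intercept, adding at each step the candidate with the smallest partial
#' t-test p-value at or below `entry_alpha` (exact ties broken by candidate
#' order) and then removing any included marker whose p-value rises above
#' `stay_alpha`, until no candidate qualifies. Constant candidate columns are
#' excluded with a warning. The model never holds more markers than
#' `breeds - 1`.
#'
#' @param X breed x marker frequency matrix (column names = marker ids).
#' @param y breed trait values (same row order).
#' @param alpha single inclusion/exclusion cutoff used for both entry and
#'   stay (default 0.05).
#' @param entry_alpha,stay_alpha override the two cutoffs separately.
#' @param trait optional trait label carried in the model.
#' @return a `PredictionModel`: list with `trait`, `candidates`, `selected`,
#'   `coefficients`, `p_values`, `entry_alpha`, `stay_alpha`, `train_mean`,
#'   `empty`.
#' @export
stepwise_fit <- function(X, y, alpha = 0.05, entry_alpha = alpha,
                         stay_alpha = alpha, trait = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y),
            entry_alpha > 0, entry_alpha < 1, stay_alpha > 0, stay_alpha < 1)
  if (is.null(colnames(X))) colnames(X) <- paste0("m", seq_len(ncol(X)))
  const <- apply(X, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("constant candidate column(s) excluded: ",
            paste(colnames(X)[const], collapse = ", "))
  }
  candidates <- colnames(X)[!const]
  selected <- character(0)
  seen <- character(0)
  repeat {
    if (length(selected) >= length(y) - 1) break  # keep breeds > markers
    if (length(selected)) {
      cur <- ls_no_intercept(X[, selected, drop = FALSE], y)
      # a perfect fit leaves no residual variance: partial tests degenerate
      if (!is.null(cur) && cur$rss <= 1e-10 * max(sum(y^2), 1e-300)) break
    }
    pool <- setdiff(candidates, selected)
    if (!length(pool)) break
    entry_p <- rep(NA_real_, length(pool))
    for (k in seq_along(pool)) {
      fit <- ls_no_intercept(X[, c(selected, pool[k]), drop = FALSE], y)
      if (!is.null(fit)) entry_p[k] <- fit$p[length(fit$p)]
    }
    if (!any(!is.na(entry_p) & entry_p <= entry_alpha)) break
    best <- which(entry_p == min(entry_p, na.rm = TRUE))[1]  # ties: order
    selected <- c(selected, pool[best])
    # backward pass at stay_alpha
    repeat {
      fit <- ls_no_intercept(X[, selected, drop = FALSE], y)
      if (is.null(fit)) { selected <- selected[-length(selected)]; break }
      worst <- which.max(fit$p)
      if (fit$p[worst] <= stay_alpha) break
      selected <- selected[-worst]
      if (!length(selected)) break
    }
    key <- paste(sort(selected), collapse = ",")
    if (key %in% seen) break  # cycle guard
    seen <- c(seen, key)
  }
  if (length(selected)) {
    fit <- ls_no_intercept(X[, selected, drop = FALSE], y)
    coefs <- stats::setNames(drop(fit$beta), selected)
    pvals <- stats::setNames(drop(fit$p), selected)
  } else {
    coefs <- stats::setNames(numeric(0), character(0))
    pvals <- coefs
  }
  structure(list(trait = trait, candidates = candidates, selected = selected,
                 coefficients = coefs, p_values = pvals,
                 entry_alpha = entry_alpha, stay_alpha = stay_alpha,
                 train_mean = mean(y), empty = !length(selected)),
            class = "PredictionModel")
}

#' @export
print.PredictionModel <- function(x, ...) {
  cat("PredictionModel", if (!is.null(x$trait)) paste0("(", x$trait, ")"),
      ":", length(x$selected), "of", length(x$candidates),
      "markers selected\n")
  if (length(x$selected)) print(round(x$coefficients, 4))
  else cat("  empty model; predictions fall back to the training mean\n")
  invisible(x)
}

#' Predict breed stereotypes from allele frequencies
#'
#' Linear combination of the selected markers' frequencies with no intercept.
#' An empty model falls back to the training mean; the result then carries
#' attribute `fallback = TRUE`.
#'
#' @param model a [stepwise_fit()] model.
#' @param X_new breed x marker frequency matrix containing the selected
#'   markers as columns.
#' @return named numeric vector of predictions.
#' @export
predict_breeds <- function(model, X_new) {
  if (model$empty) {
    out <- stats::setNames(rep(model$train_mean, nrow(X_new)),
                           rownames(X_new))
    attr(out, "fallback") <- TRUE
    return(out)
  }
  miss <- setdiff(model$selected, colnames(X_new))
  if (length(miss)) stop("missing marker column(s): ",
                         paste(miss, collapse = ", "))
  stats::setNames(
    drop(X_new[, model$selected, drop = FALSE] %*% model$coefficients),
    rownames(X_new))
}

#' Success/failure matrix of breed predictions
#'
#' Scores each breed x trait cell as a success or failure. The default
#' criterion accepts a prediction within `tolerance` times the across-breed
#' SD of the observed trait (`"half_sd"`, tolerance 0.5). The `"rank_window"`
#' alternative accepts a cell when the predicted value's rank within its
#' column is within `window` of the observed value's rank. A custom
#' `function(predicted, observed)` returning a logical matrix is also
#' accepted. Both criteria are stand-ins: the exact cell-level rule used with
#' real breed data is a reporting choice, so it is kept configurable.
#'
#' @param predicted,observed breed x trait matrices of equal shape.
#' @param criterion `"half_sd"`, `"rank_window"`, or a function.
#' @param tolerance SD multiple for `"half_sd"` (default 0.5).
#' @param window rank tolerance for `"rank_window"` (default 0).
#' @return a `SuccessMatrix`: list with `success` (logical matrix),
#'   `row_totals`, `col_totals`, `success_rate`.
#' @export
success_matrix <- function(predicted, observed, criterion = "half_sd",
                           tolerance = 0.5, window = 0L) {
  if (!all(dim(predicted) == dim(observed)))
    stop("predicted and observed must share breed x trait shape")
  succ <- if (is.function(criterion)) criterion(predicted, observed)
  else if (identical(criterion, "half_sd")) {
    sds <- apply(observed, 2, stats::sd)
    abs(predicted - observed) <= matrix(tolerance * sds, nrow(observed),
                                        ncol(observed), byrow = TRUE)
  } else if (identical(criterion, "rank_window")) {
    rp <- apply(predicted, 2, rank, ties.method = "first")
    ro <- apply(observed, 2, rank, ties.method = "first")
    abs(rp - ro) <= window
  } else stop("unknown criterion")
  dimnames(succ) <- dimnames(observed)
  structure(list(success = succ,
                 row_totals = rowSums(succ),
                 col_totals = colSums(succ),
                 success_rate = mean(succ)),
            class = "SuccessMatrix")
}

#' @export
print.SuccessMatrix <- function(x, ...) {
  cat(sprintf("SuccessMatrix: %d x %d cells, success rate %.3f\n",
              nrow(x$success), ncol(x$success), x$success_rate))
  invisible(x)
}

#' Permutation chance rate for a success matrix
#'
#' Null distribution of the success rate obtained by shuffling observed
#' values across breeds independently within each trait, re-scoring against
#' the same predictions and criterion. The chance rate is the null mean; the
#' p-value for the achieved rate is `(1 + #{null >= achieved}) / (n_perm +
#' 1)`.
#'
#' @param predicted,observed breed x trait matrices.
#' @param criterion,tolerance,window as in [success_matrix()].
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return list with `chance_rate`, `p_value`, `achieved`, `null_rates`.
#' @export
permutation_chance <- function(predicted, observed, criterion = "half_sd",
                               tolerance = 0.5, window = 0L,
                               n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 100)
  achieved <- success_matrix(predicted, observed, criterion,
                             tolerance, window)$success_rate
  set.seed(seed)
  nb <- nrow(observed)
  null_rates <- vapply(seq_len(n_perm), function(i) {
    shuf <- apply(observed, 2, function(col) col[sample.int(nb)])
    success_matrix(predicted, shuf, criterion, tolerance,
                   window)$success_rate
  }, numeric(1))
  list(chance_rate = mean(null_rates),
       p_value = (1 + sum(null_rates >= achieved)) / (n_perm + 1),
       achieved = achieved, null_rates = null_rates)
}
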