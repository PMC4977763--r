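#' Assign breed stereotype values to individuals
#'
#' The cross-breed design maps breed-average trait scores, not individual
#' phenotypes: every individual receives its breed's stereotype value for the
#' requested trait.
#'
#' @param dataset a [genotype_dataset()].
#' @param table a [stereotype_table()].
#' @param trait trait name (a column of `table`).
#' @return named numeric vector, one phenotype per individual, in dataset
#'   order.
#' @export
assign_breed_means <- function(dataset, table, trait) {
  if (!trait %in% table$traits) stop("unknown trait: ", trait)
  br <- dataset_breeds(dataset)
  missing_breeds <- setdiff(unique(br), table$breeds)
  if (length(missing_breeds))
    stop("breeds missing from stereotype table: ",
         paste(missing_breeds, collapse = ", "))
  stats::setNames(table$values[match(br, table$breeds), trait],
                  dataset$individuals)
}

#' Principal component analysis of breed stereotype traits
#'
#' PCA of the breed x trait score matrix. By default traits are standardized
#' (zero mean, unit variance), i.e. the decomposition is of the trait
#' correlation matrix; set `standardize = FALSE` for covariance PCA. Loadings
#' are the eigenvectors ("component pattern"), breed scores the projections
#' ("component scores"), and each component's sign is fixed by making its
#' largest-magnitude loading positive so outputs are reproducible.
#'
#' @param table a [stereotype_table()] with at least 3 breeds and 2 traits.
#' @param standardize standardize traits before PCA (default TRUE).
#' @return an object of class `TraitPCA`: list with `loadings` (trait x
#'   component), `scores` (breed x component), `explained_variance`
#'   (fractions, non-increasing, summing to 1 over all components).
#' @export
pca_traits <- function(table, standardize = TRUE) {
  X <- table$values
  if (nrow(X) < 3) stop("need at least 3 breeds")
  if (ncol(X) < 2) stop("need at least 2 traits")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Xc <- scale(X, center = TRUE, scale = standardize)
  S <- stats::cov(Xc)
  e <- eigen(S, symmetric = TRUE)
  vec <- e$vectors
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, k]))
    if (vec[i, k] < 0) vec[, k] <- -vec[, k]
  }
  comp <- paste0("PC", seq_len(ncol(vec)))
  dimnames(vec) <- list(colnames(X), comp)
  scores <- Xc %*% vec
  dimnames(scores) <- list(table$breeds, comp)
  ev <- pmax(e$values, 0)
  structure(list(loadings = vec, scores = scores,
                 explained_variance = ev / sum(ev)),
            class = "TraitPCA")
}

#' @export
print.TraitPCA <- function(x, ...) {
  cat("TraitPCA:", nrow(x$loadings), "traits,", nrow(x$scores), "breeds\n")
  cat("explained variance:",
      paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  invisible(x)
}
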