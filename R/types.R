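#' Genotype dataset container
#'
#' Bundles a diploid SNP genotype matrix with per-individual breed labels and
#' a SNP map. Genotypes are stored as minor-allele dosages in \{0, 1, 2\} with
#' `NA` for missing calls. The SNP map follows the PLINK MAP convention:
#' 1-based base-pair positions, sorted by (chromosome, position). `allele1` is
#' the counted (minor) allele; a cohort-monomorphic SNP carries the PLINK-style
#' placeholder code `"0"` as its unobserved minor allele.
#'
#' @param individuals character vector of individual ids (unique).
#' @param breed_of named character vector mapping individual id to breed code.
#' @param snp_map data.frame with columns `snp`, `chrom`, `pos`, `allele1`,
#'   `allele2`.
#' @param genotypes numeric matrix, individuals x SNPs, values in
#'   \{0, 1, 2, NA\}; dimnames must match `individuals` and `snp_map$snp`.
#' @param validate check invariants (default TRUE).
#' @return an object of class `GenotypeDataset`.
#' @export
genotype_dataset <- function(individuals, breed_of, snp_map, genotypes,
                             validate = TRUE) {
  obj <- structure(
    list(individuals = as.character(individuals),
         breed_of = breed_of,
         snp_map = snp_map,
         genotypes = genotypes),
    class = "GenotypeDataset")
  if (validate) validate_genotype_dataset(obj)
  obj
}

validate_genotype_dataset <- function(x) {
  stopifnot(inherits(x, "GenotypeDataset"))
  if (anyDuplicated(x$individuals))
    stop("duplicate individual ids")
  if (!all(x$individuals %in% names(x$breed_of)))
    stop("individuals missing a breed code: ",
         paste(setdiff(x$individuals, names(x$breed_of)), collapse = ", "))
  req <- c("snp", "chrom", "pos", "allele1", "allele2")
  if (!all(req %in% names(x$snp_map)))
    stop("snp_map must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(x$snp_map$snp)) stop("duplicate SNP ids in map")
  ord <- order(x$snp_map$chrom, x$snp_map$pos)
  if (!identical(ord, seq_len(nrow(x$snp_map))))
    stop("snp_map must be sorted by (chromosome, position)")
  if (any(x$snp_map$pos < 1)) stop("MAP positions are 1-based; pos >= 1")
  if (!identical(dim(x$genotypes),
                 c(length(x$individuals), nrow(x$snp_map))))
    stop("genotype matrix dimensions do not match id lists")
  g <- x$genotypes
  if (!all(g[!is.na(g)] %in% c(0, 1, 2)))
    stop("dosages must be in {0, 1, 2} or NA")
  invisible(x)
}

#' @export
print.GenotypeDataset <- function(x, ...) {
  cat("GenotypeDataset:", length(x$individuals), "individuals x",
      nrow(x$snp_map), "SNPs,",
      length(unique(x$breed_of[x$individuals])), "breeds,",
      length(unique(x$snp_map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotype fraction: %.4f\n", miss))
  invisible(x)
}

#' Breeds of a GenotypeDataset, in individual order
#' @param dataset a `GenotypeDataset`.
#' @return character vector, one breed code per individual.
#' @export
dataset_breeds <- function(dataset) {
  unname(dataset$breed_of[dataset$individuals])
}

#' The nine C-BARQ stereotype traits used throughout
#'
#' Four aggression and five fear/anxiety classes of owner-questionnaire
#' breed-average scores.
#' @return character vector of trait names.
#' @export
cbarq_traits <- function() {
  c("stranger_directed_aggression", "dog_directed_aggression",
    "owner_directed_aggression", "dog_rivalry",
    "stranger_oriented_fear", "dog_oriented_fear", "nonsocial_fear",
    "separation_related_anxiety", "touch_sensitivity")
}

#' Breed stereotype table
#'
#' One row per breed of nonnegative continuous breed-average trait scores.
#'
#' @param breeds character vector of breed codes (unique).
#' @param values numeric matrix breeds x traits with trait column names.
#' @param validate check invariants (default TRUE).
#' @param allow_negative permit negative scores (used by simulation when
#'   clipping is disabled).
#' @return an object of class `BreedStereotypeTable`.
#' @export
stereotype_table <- function(breeds, values, validate = TRUE,
                             allow_negative = FALSE) {
  rownames(values) <- breeds
  obj <- structure(
    list(breeds = as.character(breeds),
         traits = colnames(values),
         values = values),
    class = "BreedStereotypeTable")
  if (validate) {
    if (anyDuplicated(obj$breeds))
      stop("duplicate breed rows: ",
           paste(unique(obj$breeds[duplicated(obj$breeds)]), collapse = ", "))
    if (is.null(obj$traits) || any(!nzchar(obj$traits)))
      stop("trait columns must be named")
    if (!is.numeric(values) || anyNA(values))
      stop("stereotype scores must be numeric and complete")
    if (!allow_negative && any(values < 0))
      stop("stereotype scores must be nonnegative")
  }
  obj
}

#' @export
print.BreedStereotypeTable <- function(x, ...) {
  cat("BreedStereotypeTable:", length(x$breeds), "breeds x",
      length(x$traits), "traits\n")
  print(utils::head(round(x$values, 3)))
  invisible(x)
}
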