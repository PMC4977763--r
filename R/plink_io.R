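#' Read PLINK text genotypes (PED/MAP or TPED/TFAM)
#'
#' The dialect is auto-detected from the file extension (`.ped` or `.tped`;
#' a bare prefix is probed for both). Allele pairs are converted to
#' minor-allele dosage per SNP, with the minor allele determined over the full
#' cohort and ties broken toward the lexicographically smaller allele code.
#' `0 0` (and half-called) genotypes become missing; an allele that is never
#' observed is recorded with the placeholder code `"0"`.
#'
#' Breed codes are taken from a two-column breeds TSV (individual id, breed
#' code). If `breed_path` is `NULL`, `<prefix>.breeds.tsv` is used when
#' present, and otherwise the PED/TFAM family id column serves as the breed
#' code (the layout [write_plink_text()] emits).
#'
#' @param genotype_path path to the `.ped`/`.tped` file or a bare prefix.
#' @param breed_path optional path to the breeds TSV.
#' @return a [genotype_dataset()].
#' @export
read_plink_text <- function(genotype_path, breed_path = NULL) {
  paths <- resolve_plink_paths(genotype_path)
  if (is.null(breed_path)) {
    cand <- paste0(paths$prefix, ".breeds.tsv")
    if (file.exists(cand)) breed_path <- cand
  }
  ds <- if (paths$dialect == "ped") read_ped_map(paths$geno, paths$meta)
        else read_tped_tfam(paths$geno, paths$meta)
  if (!is.null(breed_path)) {
    bt <- utils::read.table(breed_path, header = TRUE, sep = "\t",
                            colClasses = "character")
    if (ncol(bt) < 2) stop("breeds TSV needs two columns: individual, breed")
    missing_ind <- setdiff(ds$individuals, bt[[1]])
    if (length(missing_ind))
      stop("individuals missing from breed table: ",
           paste(missing_ind, collapse = ", "))
    ds$breed_of <- stats::setNames(bt[[2]], bt[[1]])[ds$individuals]
    names(ds$breed_of) <- ds$individuals
  }
  validate_genotype_dataset(ds)
  ds
}

resolve_plink_paths <- function(genotype_path) {
  lower <- tolower(genotype_path)
  if (endsWith(lower, ".ped")) {
    prefix <- sub("\\.ped$", "", genotype_path, ignore.case = TRUE)
    list(dialect = "ped", geno = genotype_path,
         meta = paste0(prefix, ".map"), prefix = prefix)
  } else if (endsWith(lower, ".tped")) {
    prefix <- sub("\\.tped$", "", genotype_path, ignore.case = TRUE)
    list(dialect = "tped", geno = genotype_path,
         meta = paste0(prefix, ".tfam"), prefix = prefix)
  } else if (file.exists(paste0(genotype_path, ".ped"))) {
    resolve_plink_paths(paste0(genotype_path, ".ped"))
  } else if (file.exists(paste0(genotype_path, ".tped"))) {
    resolve_plink_paths(paste0(genotype_path, ".tped"))
  } else {
    stop("no .ped or .tped file found for '", genotype_path, "'")
  }
}

read_map_file <- function(map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("integer", "character",
                                          "numeric", "numeric"))
  names(map) <- c("chrom", "snp", "cm", "pos")
  if (is.unsorted(order(map$chrom, map$pos)) ||
      !identical(order(map$chrom, map$pos), seq_len(nrow(map))))
    stop("MAP file must be sorted by (chromosome, position)")
  map
}

# Convert an individuals x (2m) allele-token matrix to oriented dosages.
tokens_to_dataset <- function(tok, map, ind, breed_of, source) {
  n <- length(ind); m <- nrow(map)
  a1 <- character(m); a2 <- character(m)
  g <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    x <- tok[, 2 * j - 1L]; y <- tok[, 2 * j]
    half <- xor(x == "0", y == "0")
    x[half] <- "0"; y[half] <- "0"
    obs <- x != "0"
    alleles <- sort(unique(c(x[obs], y[y != "0"])))
    if (length(alleles) > 2)
      stop("SNP ", map$snp[j], " in ", source, " has more than two alleles: ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0) { a1[j] <- "0"; a2[j] <- "0"; next }
    cnt <- (x == alleles[1]) + (y == alleles[1])
    cnt[!obs] <- NA_real_
    if (length(alleles) == 1) {
      # monomorphic: the unobserved minor allele gets the placeholder code
      a1[j] <- "0"; a2[j] <- alleles[1]; g[, j] <- cnt * 0
    } else {
      c1 <- sum(cnt, na.rm = TRUE); c2 <- 2 * sum(obs) - c1
      if (c1 <= c2) {  # tie goes to the lexicographically smaller allele
        a1[j] <- alleles[1]; a2[j] <- alleles[2]; g[, j] <- cnt
      } else {
        a1[j] <- alleles[2]; a2[j] <- alleles[1]; g[, j] <- 2 - cnt
      }
    }
  }
  map_out <- data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos,
                        allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  dimnames(g) <- list(ind, map$snp)
  genotype_dataset(ind, breed_of, map_out, g, validate = FALSE)
}

read_ped_map <- function(ped_path, map_path) {
  map <- read_map_file(map_path)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  ind <- character(n); fid <- character(n)
  tok <- matrix("0", n, 2 * m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop("PED line ", i, ": expected ", 6 + 2 * m, " fields (6 mandatory + ",
           2 * m, " alleles), got ", length(f))
    fid[i] <- f[1]; ind[i] <- f[2]
    if (m > 0) tok[i, ] <- f[-(1:6)]
  }
  if (anyDuplicated(ind)) stop("duplicate individual ids in PED")
  tokens_to_dataset(tok, map, ind, stats::setNames(fid, ind), ped_path)
}

read_tped_tfam <- function(tped_path, tfam_path) {
  fam <- utils::read.table(tfam_path, header = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 2) stop("TFAM needs at least family and individual ids")
  ind <- fam[[2]]
  if (anyDuplicated(ind)) stop("duplicate individual ids in TFAM")
  n <- length(ind)
  lines <- readLines(tped_path)
  lines <- lines[nzchar(trimws(lines))]
  m <- length(lines)
  map <- data.frame(chrom = integer(m), snp = character(m),
                    cm = numeric(m), pos = numeric(m))
  tok <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    f <- strsplit(trimws(lines[j]), "[ \t]+")[[1]]
    if (length(f) != 4 + 2 * n)
      stop("TPED line ", j, ": expected ", 4 + 2 * n, " fields, got ",
           length(f))
    map$chrom[j] <- as.integer(f[1]); map$snp[j] <- f[2]
    map$cm[j] <- as.numeric(f[3]); map$pos[j] <- as.numeric(f[4])
    tok[, (2 * j - 1):(2 * j)] <- matrix(f[-(1:4)], n, 2, byrow = TRUE)
  }
  if (!identical(order(map$chrom, map$pos), seq_len(max(m, 0L))) && m > 0)
    stop("TPED rows must be sorted by (chromosome, position)")
  tokens_to_dataset(tok, map, ind, stats::setNames(fam[[1]], ind), tped_path)
}

#' Write PLINK text genotypes
#'
#' Emits `<prefix>.ped` + `<prefix>.map` (or `<prefix>.tped` +
#' `<prefix>.tfam`) plus a `<prefix>.breeds.tsv` mapping individual id to
#' breed code. The family id column also carries the breed code. Missing
#' dosage is written as `0 0`; MAP positions are written bit-exact.
#'
#' @param dataset a [genotype_dataset()].
#' @param prefix output path prefix.
#' @param format `"ped"` or `"tped"`.
#' @return invisibly, the paths written.
#' @export
write_plink_text <- function(dataset, prefix, format = c("ped", "tped")) {
  format <- match.arg(format)
  validate_genotype_dataset(dataset)
  map <- dataset$snp_map
  n <- length(dataset$individuals); m <- nrow(map)
  breeds <- dataset_breeds(dataset)

  # allele-pair strings per SNP: dosage 2 -> "a1 a1", 1 -> "a1 a2", 0 -> "a2 a2"
  pair_for <- function(j) {
    a1 <- map$allele1[j]; a2 <- map$allele2[j]
    codes <- c(paste(a2, a2), paste(a1, a2), paste(a1, a1))
    out <- rep("0 0", n)
    ok <- !is.na(dataset$genotypes[, j])
    out[ok] <- codes[dataset$genotypes[ok, j] + 1L]
    out
  }
  map_lines <- sprintf("%d\t%s\t0\t%s", map$chrom, map$snp,
                       format(map$pos, scientific = FALSE, trim = TRUE))
  paths <- character(0)
  if (format == "ped") {
    ped <- paste0(prefix, ".ped"); mp <- paste0(prefix, ".map")
    geno <- if (m > 0) {
      cols <- vapply(seq_len(m), pair_for, character(n))
      if (n == 1L) cols <- matrix(cols, nrow = 1L)
      apply(cols, 1L, paste, collapse = " ")
    } else character(n)
    lead <- sprintf("%s %s 0 0 2 -9", breeds, dataset$individuals)
    writeLines(ifelse(nzchar(geno), paste(lead, geno), lead), ped)
    writeLines(map_lines, mp)
    paths <- c(ped, mp)
  } else {
    tped <- paste0(prefix, ".tped"); tfam <- paste0(prefix, ".tfam")
    rows <- vapply(seq_len(m), function(j) paste(pair_for(j), collapse = " "),
                   character(1))
    writeLines(if (m > 0) paste(gsub("\t", " ", map_lines), rows)
               else character(0), tped)
    writeLines(sprintf("%s %s 0 0 2 -9", breeds, dataset$individuals), tfam)
    paths <- c(tped, tfam)
  }
  bt <- paste0(prefix, ".breeds.tsv")
  writeLines(c("individual\tbreed",
               sprintf("%s\t%s", dataset$individuals, breeds)), bt)
  invisible(c(paths, bt))
}

#' Read a breed stereotype table from delimited text
#'
#' Expects a header row (first column the breed code, remaining columns trait
#' names) and one numeric row per breed. Trait columns outside the nine
#' C-BARQ traits are preserved and flagged in the `extra_traits` attribute.
#'
#' @param path TSV/CSV path (delimiter sniffed from the header line).
#' @return a [stereotype_table()].
#' @export
read_stereotypes <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character")
  breeds <- df[[1]]
  dup <- unique(breeds[duplicated(breeds)])
  if (length(dup)) stop("duplicated breed row(s): ", paste(dup, collapse = ", "))
  raw <- df[, -1, drop = FALSE]
  vals <- suppressWarnings(
    vapply(raw, as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) vals <- matrix(vals, 1L, dimnames = list(NULL, names(raw)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at breed '", breeds[bad[1]], "', trait '",
         colnames(vals)[bad[2]], "'")
  }
  tab <- stereotype_table(breeds, vals)
  extra <- setdiff(tab$traits, cbarq_traits())
  if (length(extra)) {
    attr(tab, "extra_traits") <- extra
    warning("trait column(s) outside the nine C-BARQ traits kept and flagged: ",
            paste(extra, collapse = ", "))
  }
  tab
}

#' Write a breed stereotype table as TSV
#'
#' Values are written with full (17 significant digit) precision so the table
#' round-trips exactly.
#' @param table a [stereotype_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_stereotypes <- function(table, path) {
  hdr <- paste(c("breed", table$traits), collapse = "\t")
  rows <- vapply(seq_along(table$breeds), function(i) {
    paste(c(table$breeds[i],
            formatC(table$values[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
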