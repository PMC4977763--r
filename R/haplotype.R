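#' Direct phased-haplotype block around a peak SNP
#'
#' Within one breed, restricts to the individuals homozygous for the chosen
#' allele at the peak SNP ("direct phasing": homozygotes need no statistical
#' phasing). If fewer than `min_homozygotes` (default 4) such dogs exist, no
#' block is emitted. Otherwise the block is extended SNP by SNP upstream and
#' downstream from the peak, retaining each SNP while the majority allele's
#' frequency among the homozygote subset is at least `freq_threshold`
#' (default 0.95) and stopping at the first failing SNP on each side - the
#' maximal contiguous interval through the peak.
#'
#' Missing genotypes are excluded from the frequency denominator; a flanking
#' SNP whose subset genotypes are all missing passes (no evidence against)
#' and is counted in `n_all_missing`. With `founder_allele = TRUE` the rule
#' is applied to the frequency of a fixed founder allele (the subset majority
#' allele at the first evaluation) instead of the per-SNP majority.
#'
#' @param dataset a [genotype_dataset()].
#' @param breed breed code.
#' @param peak_snp SNP id of the association peak.
#' @param allele which peak allele to phase: `"A"`/`"B"` are positional
#'   labels for the SNP's allele1/allele2 (allele letters are arbitrary);
#'   any other string is matched against the SNP's literal allele codes.
#' @param freq_threshold retention threshold (default 0.95).
#' @param min_homozygotes minimum homozygous carriers (default 4).
#' @param founder_allele use the fixed-founder-allele reading of the rule.
#' @return a `PhasedHaplotypeBlock` (list with `breed`, `peak_snp`, `allele`,
#'   `chrom`, `start`, `end`, `n_homozygotes`, `n_snps`, `n_all_missing`), or
#'   invisibly `NULL` - with the reason given as a message - when no block
#'   can be built.
#' @export
phased_block <- function(dataset, breed, peak_snp, allele,
                         freq_threshold = 0.95, min_homozygotes = 4L,
                         founder_allele = FALSE) {
  j <- match(peak_snp, dataset$snp_map$snp)
  if (is.na(j)) stop("unknown peak SNP: ", peak_snp)
  a1 <- dataset$snp_map$allele1[j]; a2 <- dataset$snp_map$allele2[j]
  allele <- match_peak_allele(allele, a1, a2)
  br <- dataset_breeds(dataset)
  if (!breed %in% br) stop("breed absent from dataset: ", breed)
  g_peak <- dataset$genotypes[br == breed, j]
  # dosage counts allele1, so "A"-homozygotes carry dosage 2
  target_dose <- if (allele == "A") 2 else 0
  homo <- which(!is.na(g_peak) & g_peak == target_dose)
  if (length(homo) < min_homozygotes) {
    message(sprintf(
      "no block: %d homozygous carrier(s) of allele %s in %s (need >= %d)",
      length(homo), allele, breed, min_homozygotes))
    return(invisible(NULL))
  }
  sub <- dataset$genotypes[which(br == breed)[homo], , drop = FALSE]
  chrom <- dataset$snp_map$chrom[j]
  on_chr <- which(dataset$snp_map$chrom == chrom)
  peak_k <- match(j, on_chr)

  passes <- function(col) {
    g <- sub[, col]
    g <- g[!is.na(g)]
    if (!length(g)) return(c(pass = TRUE, allmiss = TRUE))
    n1 <- sum(2 - g); n2 <- sum(g)  # allele1 / allele2 counts in subset
    f <- if (founder_allele) {
      maj <- if (n1 >= n2) "a1" else "a2"
      if (maj == "a1") n1 / (n1 + n2) else n2 / (n1 + n2)
    } else max(n1, n2) / (n1 + n2)
    c(pass = f >= freq_threshold, allmiss = FALSE)
  }

  lo <- peak_k; hi <- peak_k; n_allmiss <- 0L
  while (lo > 1) {
    r <- passes(on_chr[lo - 1])
    if (!r["pass"]) break
    n_allmiss <- n_allmiss + r["allmiss"]
    lo <- lo - 1
  }
  while (hi < length(on_chr)) {
    r <- passes(on_chr[hi + 1])
    if (!r["pass"]) break
    n_allmiss <- n_allmiss + r["allmiss"]
    hi <- hi + 1
  }
  structure(list(breed = breed, peak_snp = peak_snp, allele = allele,
                 chrom = chrom,
                 start = dataset$snp_map$pos[on_chr[lo]],
                 end = dataset$snp_map$pos[on_chr[hi]],
                 n_homozygotes = length(homo),
                 n_snps = hi - lo + 1L,
                 n_all_missing = as.integer(n_allmiss)),
            class = "PhasedHaplotypeBlock")
}

# "A"/"B" are positional labels for allele1/allele2 (arbitrary, PLINK A1/A2
# style); any other string is matched against the SNP's literal allele codes.
match_peak_allele <- function(allele, a1, a2) {
  stopifnot(length(allele) == 1L)
  if (allele %in% c("A", "B")) return(allele)
  if (allele == a1) "A" else if (allele == a2) "B"
  else stop("allele '", allele, "' is neither A/B nor an allele code (",
            a1, "/", a2, ")")
}

#' @export
print.PhasedHaplotypeBlock <- function(x, ...) {
  cat(sprintf(
    "PhasedHaplotypeBlock %s allele %s @ %s: chr%s:%s-%s (%.1f kb, %d SNPs, %d homozygotes)\n",
    x$breed, x$allele, x$peak_snp, x$chrom,
    format(x$start, big.mark = ","), format(x$end, big.mark = ","),
    (x$end - x$start) / 1000, x$n_snps, x$n_homozygotes))
  invisible(x)
}

#' Block length in kb
#' @param block a `PhasedHaplotypeBlock`.
#' @return `(end - start) / 1000`.
#' @export
block_length_kb <- function(block) (block$end - block$start) / 1000

#' Cross-breed overlap of phased-haplotype blocks
#'
#' Intersection of the block intervals (max of starts, min of ends). All
#' blocks must share a chromosome and peak allele. An empty intersection is
#' returned flagged rather than as an error.
#'
#' @param blocks list of `PhasedHaplotypeBlock` (NULL entries, i.e. breeds
#'   without a block, are dropped).
#' @return list `chrom`, `start`, `end`, `empty`, `breeds`.
#' @export
cross_breed_overlap <- function(blocks) {
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) return(list(chrom = NA, start = NA_real_,
                                   end = NA_real_, empty = TRUE,
                                   breeds = character(0)))
  chrom <- unique(vapply(blocks, function(b) as.numeric(b$chrom), numeric(1)))
  if (length(chrom) > 1) stop("blocks on mixed chromosomes: ",
                              paste(chrom, collapse = ", "))
  allele <- unique(vapply(blocks, `[[`, character(1), "allele"))
  if (length(allele) > 1) stop("blocks for mixed peak alleles: ",
                               paste(allele, collapse = ", "))
  s <- max(vapply(blocks, function(b) as.numeric(b$start), numeric(1)))
  e <- min(vapply(blocks, function(b) as.numeric(b$end), numeric(1)))
  list(chrom = chrom, allele = allele, start = s, end = e, empty = s > e,
       breeds = vapply(blocks, `[[`, character(1), "breed"))
}

#' Maximum and minimum map intervals for a locus
#'
#' The maximum map interval is the cross-breed overlap of phased-haplotype
#' blocks. The minimum map interval intersects it with the smallest
#' cross-breed overlap of d_i or s_i signal regions: for each statistic, each
#' carrier breed contributes its region containing the peak (or abutting
#' within one window of it); breeds with no qualifying region are skipped,
#' and a statistic qualifies only if at least one breed contributes and the
#' intersection still covers the peak. If neither statistic qualifies, the
#' minimum interval equals the maximum interval (a peak can lack selection
#' evidence yet still be mapped by its haplotypes).
#'
#' @param overlap result of [cross_breed_overlap()] (non-empty).
#' @param regions list with elements `di` and `si`, each a named per-breed
#'   list of region data.frames as from [call_signal_regions()].
#' @param carrier_breeds breeds whose regions are consulted.
#' @param peak_pos bp position of the peak SNP.
#' @param window_size bp tolerance for "abutting" regions (one window).
#' @param label locus label.
#' @return a `MapIntervalCall`: list with `label`, `allele`, `chrom`,
#'   `max_interval`, `min_interval` (each `c(start, end)`), `min_source`
#'   (`"di"`, `"si"` or `"none"`), `supporting_breeds`, `empty`.
#' @export
map_intervals <- function(overlap, regions, carrier_breeds, peak_pos,
                          window_size = 5e5, label = "locus") {
  if (isTRUE(overlap$empty)) stop("cross-breed overlap is empty")
  candidate <- list()
  for (stat in c("di", "si")) {
    ivs <- NULL
    sup <- character(0)
    for (b in intersect(carrier_breeds, names(regions[[stat]]))) {
      rb <- regions[[stat]][[b]]
      if (is.null(rb) || !nrow(rb)) next
      rb <- rb[rb$chrom == overlap$chrom &
               rb$start - window_size <= peak_pos &
               rb$end + window_size >= peak_pos, , drop = FALSE]
      if (!nrow(rb)) next
      # closest region to the peak for this breed
      d <- pmax(rb$start - peak_pos, peak_pos - rb$end, 0)
      r <- rb[which.min(d), ]
      ivs <- if (is.null(ivs)) c(r$start, r$end)
             else c(max(ivs[1], r$start), min(ivs[2], r$end))
      sup <- c(sup, b)
    }
    if (!is.null(ivs) && ivs[1] <= ivs[2] &&
        ivs[1] <= peak_pos && peak_pos <= ivs[2]) {
      candidate[[stat]] <- list(iv = ivs, breeds = sup)
    }
  }
  max_iv <- c(overlap$start, overlap$end)
  if (length(candidate)) {
    lens <- vapply(candidate, function(x) diff(x$iv), numeric(1))
    best <- names(candidate)[which.min(lens)]
    iv <- candidate[[best]]$iv
    min_iv <- c(max(max_iv[1], iv[1]), min(max_iv[2], iv[2]))
    if (min_iv[1] > min_iv[2]) { min_iv <- max_iv; best <- "none" }
    sup <- candidate[[best]]$breeds %||% overlap$breeds
  } else {
    min_iv <- max_iv; best <- "none"; sup <- overlap$breeds
  }
  structure(list(label = label, allele = overlap$allele %||% NA,
                 chrom = overlap$chrom, max_interval = max_iv,
                 min_interval = min_iv, min_source = best,
                 supporting_breeds = sup,
                 empty = !(max_iv[1] <= peak_pos && peak_pos <= max_iv[2])),
            class = "MapIntervalCall")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.MapIntervalCall <- function(x, ...) {
  cat(sprintf("MapIntervalCall %s: max chr%s:%s-%s (%.1f kb), min %s-%s (%.1f kb, %s)\n",
              x$label, x$chrom,
              format(x$max_interval[1], big.mark = ","),
              format(x$max_interval[2], big.mark = ","),
              diff(x$max_interval) / 1000,
              format(x$min_interval[1], big.mark = ","),
              format(x$min_interval[2], big.mark = ","),
              diff(x$min_interval) / 1000, x$min_source))
  invisible(x)
}
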