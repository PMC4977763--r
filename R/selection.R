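#' @importFrom stats setNames quantile sd
NULL

# per-breed allele-1 sample frequencies and haploid sample sizes
breed_freq_matrix <- function(dataset) {
  br <- dataset_breeds(dataset)
  breeds <- sort(unique(br))
  G <- dataset$genotypes
  f <- matrix(NA_real_, length(breeds), ncol(G),
              dimnames = list(breeds, colnames(G)))
  nh <- matrix(0, length(breeds), ncol(G), dimnames = dimnames(f))
  for (b in seq_along(breeds)) {
    Gb <- G[br == breeds[b], , drop = FALSE]
    cnt <- colSums(Gb, na.rm = TRUE)
    den <- 2 * colSums(!is.na(Gb))
    f[b, ] <- ifelse(den > 0, cnt / den, NA_real_)
    nh[b, ] <- den
  }
  list(freq = f, n_hap = nh, breeds = breeds)
}

hudson_fst_vec <- function(p1, p2, n1, n2, min_ind = 2L) {
  ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 * min_ind & n2 >= 2 * min_ind
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- ifelse(ok & den > 0, num / den, NA_real_)
  out
}

#' Per-SNP Hudson F_ST between two breeds
#'
#' Hudson's two-population estimator from sample allele frequencies and
#' haploid sample sizes, which is unbiased under unequal sample sizes.
#' Negative estimates are retained (not clamped) so genomewide moments stay
#' unbiased. A SNP needs at least `min_ind` genotyped individuals in each
#' breed, and a defined denominator (the breeds polymorphic or divergently
#' fixed); otherwise `NA`.
#'
#' @param dataset a [genotype_dataset()].
#' @param breed_i,breed_j breed codes.
#' @param min_ind minimum genotyped individuals per breed per SNP (default 2).
#' @return named per-SNP numeric vector.
#' @export
pairwise_fst <- function(dataset, breed_i, breed_j, min_ind = 2L) {
  bm <- breed_freq_matrix(dataset)
  for (b in c(breed_i, breed_j))
    if (!b %in% bm$breeds) stop("breed absent from dataset: ", b)
  setNames(hudson_fst_vec(bm$freq[breed_i, ], bm$freq[breed_j, ],
                          bm$n_hap[breed_i, ], bm$n_hap[breed_j, ], min_ind),
           dataset$snp_map$snp)
}

#' Genomewide mean pairwise F_ST (ratio of averages)
#'
#' Hudson numerator and denominator summed over SNPs before taking the
#' ratio, per breed pair, then averaged over pairs. The ratio-of-averages
#' form is the standard genomewide F_ST summary (per-SNP ratios are biased
#' toward 0 when averaged); under Balding-Nichols divergence `F` for every
#' breed its expectation is `F`.
#'
#' @param dataset a [genotype_dataset()].
#' @param min_ind per-SNP minimum genotyped individuals per breed.
#' @return list with `overall` (mean over pairs) and `per_pair` (named
#'   vector).
#' @export
mean_pairwise_fst <- function(dataset, min_ind = 2L) {
  bm <- breed_freq_matrix(dataset)
  B <- length(bm$breeds)
  if (B < 2) stop("need at least 2 breeds")
  pairs <- t(utils::combn(B, 2))
  per_pair <- numeric(nrow(pairs))
  names(per_pair) <- paste(bm$breeds[pairs[, 1]], bm$breeds[pairs[, 2]],
                           sep = ":")
  for (k in seq_len(nrow(pairs))) {
    p1 <- bm$freq[pairs[k, 1], ]; p2 <- bm$freq[pairs[k, 2], ]
    n1 <- bm$n_hap[pairs[k, 1], ]; n2 <- bm$n_hap[pairs[k, 2], ]
    ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 * min_ind & n2 >= 2 * min_ind
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    per_pair[k] <- sum(num[ok]) / sum(den[ok])
  }
  list(overall = mean(per_pair), per_pair = per_pair)
}

#' Tile chromosomes into fixed-size windows
#'
#' Non-overlapping windows of `size` bp from position 1, last window
#' truncated at the chromosome end (the largest mapped position unless
#' `chrom_lengths` is given). Coordinates are 1-based inclusive, matching the
#' MAP convention.
#'
#' @param dataset a [genotype_dataset()].
#' @param size window size in bp (default 500 kb).
#' @param chrom_lengths optional named/ordered chromosome lengths.
#' @return data.frame `window`, `chrom`, `start`, `end`.
#' @export
make_windows <- function(dataset, size = 5e5, chrom_lengths = NULL) {
  chroms <- sort(unique(dataset$snp_map$chrom))
  out <- do.call(rbind, lapply(chroms, function(ch) {
    len <- if (is.null(chrom_lengths))
      max(dataset$snp_map$pos[dataset$snp_map$chrom == ch])
    else if (!is.null(names(chrom_lengths))) chrom_lengths[[as.character(ch)]]
    else chrom_lengths[[match(ch, chroms)]]
    starts <- seq(1, len, by = size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size - 1, len))
  }))
  out <- cbind(window = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

snp_window_index <- function(snp_map, windows) {
  idx <- rep(NA_integer_, nrow(snp_map))
  for (w in seq_len(nrow(windows))) {
    hit <- snp_map$chrom == windows$chrom[w] &
           snp_map$pos >= windows$start[w] & snp_map$pos <= windows$end[w]
    idx[hit] <- windows$window[w]
  }
  idx
}

#' Pairwise F_ST table over windows
#'
#' Computes per-SNP Hudson F_ST for every breed pair, the per-window mean
#' F_ST per pair, and each pair's genomewide window mean and SD (the moments
#' the d_i statistic standardizes against). Windows with no usable SNP for a
#' pair are missing and excluded from the moments.
#'
#' @param dataset a [genotype_dataset()].
#' @param windows from [make_windows()]; built with defaults when NULL.
#' @param min_ind per-SNP minimum genotyped individuals per breed.
#' @return an `FstTable`: list with `pairs` (data.frame `i`, `j`), `snp_fst`
#'   (SNP x pair), `window_fst` (window x pair), `pair_mean`, `pair_sd`,
#'   `windows`, `breeds`.
#' @export
fst_table <- function(dataset, windows = NULL, min_ind = 2L) {
  if (is.null(windows)) windows <- make_windows(dataset)
  bm <- breed_freq_matrix(dataset)
  B <- length(bm$breeds)
  if (B < 2) stop("need at least 2 breeds")
  pairs <- t(utils::combn(B, 2))
  snp_fst <- matrix(NA_real_, ncol(dataset$genotypes), nrow(pairs))
  pname <- paste(bm$breeds[pairs[, 1]], bm$breeds[pairs[, 2]], sep = ":")
  colnames(snp_fst) <- pname
  rownames(snp_fst) <- dataset$snp_map$snp
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    snp_fst[, k] <- hudson_fst_vec(bm$freq[i, ], bm$freq[j, ],
                                   bm$n_hap[i, ], bm$n_hap[j, ], min_ind)
  }
  widx <- snp_window_index(dataset$snp_map, windows)
  window_fst <- matrix(NA_real_, nrow(windows), nrow(pairs),
                       dimnames = list(windows$window, pname))
  for (w in seq_len(nrow(windows))) {
    rows <- which(widx == windows$window[w])
    if (length(rows))
      window_fst[w, ] <- colMeans(snp_fst[rows, , drop = FALSE], na.rm = TRUE)
  }
  window_fst[is.nan(window_fst)] <- NA_real_
  structure(list(pairs = data.frame(i = bm$breeds[pairs[, 1]],
                                    j = bm$breeds[pairs[, 2]],
                                    stringsAsFactors = FALSE),
                 snp_fst = snp_fst, window_fst = window_fst,
                 pair_mean = colMeans(window_fst, na.rm = TRUE),
                 pair_sd = apply(window_fst, 2, sd, na.rm = TRUE),
                 windows = windows, breeds = bm$breeds),
            class = "FstTable")
}

#' Windowed per-breed differentiation statistic d_i
#'
#' For breed `b` and window `w`,
#' `d_i(b, w) = sum_{j != b} (Fbar^{bj}(w) - mu^{bj}) / sigma^{bj}`:
#' each pair's window-mean F_ST is standardized against that pair's
#' genomewide window mean and SD, then summed over all pairs involving `b`.
#' Large positive values flag windows where `b` is unusually differentiated
#' from the rest of the panel. Pairs with zero genomewide variance are
#' excluded from the sum with a warning.
#'
#' @param fst an `FstTable` from [fst_table()].
#' @return breed x window matrix.
#' @export
windowed_di <- function(fst) {
  stopifnot(inherits(fst, "FstTable"))
  bad <- !is.na(fst$pair_sd) & fst$pair_sd == 0
  if (any(bad))
    warning("pair(s) with zero genomewide F_ST variance excluded: ",
            paste(colnames(fst$window_fst)[bad], collapse = ", "))
  z <- sweep(fst$window_fst, 2, fst$pair_mean, "-")
  z <- sweep(z, 2, fst$pair_sd, "/")
  z[, bad] <- NA_real_
  di <- matrix(0, length(fst$breeds), nrow(fst$windows),
               dimnames = list(fst$breeds, fst$windows$window))
  for (b in seq_along(fst$breeds)) {
    k <- which(fst$pairs$i == fst$breeds[b] | fst$pairs$j == fst$breeds[b])
    di[b, ] <- rowSums(z[, k, drop = FALSE], na.rm = TRUE)
  }
  di[, rowSums(!is.na(z)) == 0] <- NA_real_  # windows with no usable pair
  di
}

#' Windowed per-breed reduced-heterozygosity statistic s_i
#'
#' Window expected heterozygosity per breed is `2p(1-p)` averaged over the
#' window's SNPs, normalized by that breed's genomewide window average
#' (relative heterozygosity). For each pair the window difference in relative
#' heterozygosity is standardized by its genomewide window SD, and
#' `s_i(b, w)` sums those standardized deviations over all pairs involving
#' `b`. Strongly negative values flag windows of reduced heterozygosity in
#' breed `b` - the footprint of a selective sweep. Windows with no SNPs are
#' missing and excluded from the moments.
#'
#' @param dataset a [genotype_dataset()].
#' @param windows from [make_windows()]; defaults when NULL.
#' @return breed x window matrix.
#' @export
windowed_si <- function(dataset, windows = NULL) {
  if (is.null(windows)) windows <- make_windows(dataset)
  bm <- breed_freq_matrix(dataset)
  B <- length(bm$breeds)
  if (B < 2) stop("need at least 2 breeds")
  het <- 2 * bm$freq * (1 - bm$freq)
  widx <- snp_window_index(dataset$snp_map, windows)
  H <- matrix(NA_real_, B, nrow(windows),
              dimnames = list(bm$breeds, windows$window))
  for (w in seq_len(nrow(windows))) {
    rows <- which(widx == windows$window[w])
    if (length(rows))
      H[, w] <- rowMeans(het[, rows, drop = FALSE], na.rm = TRUE)
  }
  H[is.nan(H)] <- NA_real_
  rel <- H / rowMeans(H, na.rm = TRUE)
  si <- matrix(0, B, nrow(windows), dimnames = dimnames(H))
  for (b in seq_len(B - 1)) {
    for (j in seq(b + 1, B)) {
      delta <- rel[b, ] - rel[j, ]
      s <- sd(delta, na.rm = TRUE)
      if (is.na(s) || s == 0) next
      z <- delta / s
      z0 <- ifelse(is.na(z), 0, z)
      si[b, ] <- si[b, ] + z0
      si[j, ] <- si[j, ] - z0
    }
  }
  si[, colSums(!is.na(H)) == 0] <- NA_real_  # windows with no SNPs
  si
}

#' Run the full windowed selection scan
#'
#' Convenience wrapper building windows, the F_ST table, the d_i and s_i
#' matrices and their called signal regions.
#'
#' @param dataset a [genotype_dataset()].
#' @param window_size bp (default 500 kb).
#' @param percentile region-calling percentile (default 99).
#' @param chrom_lengths optional chromosome lengths for windowing.
#' @return a `SelectionScan`: list with `windows`, `di`, `si`, `regions`
#'   (lists `di`, `si` of per-breed region data.frames), `fst`.
#' @export
selection_scan <- function(dataset, window_size = 5e5, percentile = 99,
                           chrom_lengths = NULL) {
  windows <- make_windows(dataset, window_size, chrom_lengths)
  fst <- fst_table(dataset, windows)
  di <- windowed_di(fst)
  si <- windowed_si(dataset, windows)
  scan <- structure(list(windows = windows, di = di, si = si, fst = fst),
                    class = "SelectionScan")
  scan$regions <- list(di = call_signal_regions(scan, "di", percentile),
                       si = call_signal_regions(scan, "si", percentile))
  scan
}

#' @export
print.SelectionScan <- function(x, ...) {
  cat("SelectionScan:", nrow(x$di), "breeds x", nrow(x$windows), "windows\n")
  invisible(x)
}

#' Call per-breed signal regions from a selection scan
#'
#' Windows strictly beyond the breed's genomewide percentile (above it for
#' d_i, below the mirrored percentile for s_i) are merged into maximal
#' contiguous runs with chromosome-aware boundaries.
#'
#' @param scan a `SelectionScan` (or list with `windows` plus `di`/`si`).
#' @param statistic `"di"` or `"si"`.
#' @param percentile in (50, 100).
#' @return named list (one element per breed) of data.frames `chrom`,
#'   `start`, `end`, `n_windows`, `extreme` (the most extreme window value).
#' @export
call_signal_regions <- function(scan, statistic = c("di", "si"),
                                percentile = 99) {
  statistic <- match.arg(statistic)
  stopifnot(percentile > 50, percentile < 100)
  mat <- scan[[statistic]]
  windows <- scan$windows
  out <- vector("list", nrow(mat))
  names(out) <- rownames(mat)
  for (b in seq_len(nrow(mat))) {
    v <- mat[b, ]
    if (statistic == "di") {
      thr <- quantile(v, percentile / 100, na.rm = TRUE, names = FALSE)
      sel <- !is.na(v) & v > thr
    } else {
      thr <- quantile(v, 1 - percentile / 100, na.rm = TRUE, names = FALSE)
      sel <- !is.na(v) & v < thr
    }
    out[[b]] <- merge_window_runs(windows, sel, v)
  }
  out
}

# maximal runs of selected windows, not crossing chromosome boundaries
merge_window_runs <- function(windows, sel, values) {
  empty <- data.frame(chrom = integer(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      extreme = numeric(0))
  if (!any(sel)) return(empty)
  idx <- which(sel)
  new_run <- c(TRUE, diff(idx) != 1L |
                     windows$chrom[idx[-1]] != windows$chrom[idx[-length(idx)]])
  grp <- split(idx, cumsum(new_run))
  rows <- lapply(grp, function(ix) {
    data.frame(chrom = windows$chrom[ix[1]],
               start = windows$start[ix[1]],
               end = windows$end[ix[length(ix)]],
               n_windows = length(ix),
               extreme = values[ix][which.max(abs(values[ix]))])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
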