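test_that("a fixed homozygote subset spans the whole chromosome", {
  # breed "p" homozygous for allele1 everywhere: no boundary is ever hit
  g <- rbind(matrix(2, 5, 8), matrix(rbinom(40, 2, 0.5), 5, 8))
  ds <- tiny_dataset(g, rep(c("p", "q"), each = 5),
                     pos = c(100, 250, 400, 900, 1500, 2200, 3100, 4000))
  b <- phased_block(ds, "p", "s004", "A")
  expect_equal(c(b$start, b$end), c(100, 4000))
  expect_equal(b$n_snps, 8L)
  expect_equal(b$n_homozygotes, 5L)
})

test_that("fewer than four homozygous dogs never yield a block", {
  g <- rbind(matrix(2, 3, 5), matrix(0, 7, 5))   # only 3 allele1 homozygotes
  ds <- tiny_dataset(g, rep("p", 10))
  expect_message(b <- phased_block(ds, "p", "s003", "A"), "3 homozygous")
  expect_null(b)
  expect_message(b4 <- phased_block(ds, "p", "s003", "A",
                                    min_homozygotes = 3L), NA)
  expect_false(is.null(b4))
})

test_that("block construction equals the exhaustive-interval oracle", {
  set.seed(101)
  for (rep in 1:60) {
    n <- 8; m <- 25
    freqs <- runif(m, 0, 1)
    g <- sapply(freqs, function(p) rbinom(n, 2, p))
    pk <- sample(3:(m - 2), 1)
    g[, pk] <- 2                                   # everyone homozygous A
    ds <- tiny_dataset(g, rep("p", n), pos = sort(sample.int(1e5, m)))
    b <- phased_block(ds, "p", ds$snp_map$snp[pk], "A")
    # oracle: per-SNP pass under the subset-majority >= 0.95 rule
    pass <- sapply(seq_len(m), function(j) {
      x <- g[, j]
      max(sum(x), sum(2 - x)) / (2 * n) >= 0.95
    })
    # maximal contiguous run through the peak
    lo <- pk; while (lo > 1 && pass[lo - 1]) lo <- lo - 1
    hi <- pk; while (hi < m && pass[hi + 1]) hi <- hi + 1
    expect_equal(c(b$start, b$end), ds$snp_map$pos[c(lo, hi)])
    # no strictly longer all-pass interval through the peak exists
    for (l2 in 1:pk) for (h2 in pk:m) {
      if (all(pass[l2:h2])) expect_lte(ds$snp_map$pos[h2] -
                                       ds$snp_map$pos[l2], b$end - b$start)
    }
  }
})

test_that("blocks grow monotonically as the threshold is lowered", {
  for (seed in 1:5) {
    fx <- make_fixture(seed)
    tr <- fx$truth
    lab <- risk_allele_label(fx$dataset, tr)
    for (b in strsplit(tr$risk_breeds, ",")[[1]]) {
      b95 <- phased_block(fx$dataset, b, tr$snp, lab, freq_threshold = 0.95)
      b90 <- phased_block(fx$dataset, b, tr$snp, lab, freq_threshold = 0.90)
      if (is.null(b95) || is.null(b90)) next
      expect_lte(b90$start, b95$start)
      expect_gte(b90$end, b95$end)
    }
  }
})

test_that("blocks are invariant to individual order and allele flips", {
  fx <- make_fixture(5)
  ds <- fx$dataset
  tr <- fx$truth
  lab <- risk_allele_label(ds, tr)
  b1 <- phased_block(ds, "BR01", tr$snp, lab)
  perm <- sample(length(ds$individuals))
  ds2 <- genotype_dataset(ds$individuals[perm], ds$breed_of, ds$snp_map,
                          ds$genotypes[perm, , drop = FALSE])
  b2 <- phased_block(ds2, "BR01", tr$snp, lab)
  expect_equal(b1[c("start", "end", "n_snps", "n_homozygotes")],
               b2[c("start", "end", "n_snps", "n_homozygotes")])
  # flip every SNP's labels: the same block arises for the mirrored allele
  ds3 <- ds
  ds3$genotypes <- 2 - ds3$genotypes
  a1 <- ds3$snp_map$allele1
  ds3$snp_map$allele1 <- ds3$snp_map$allele2
  ds3$snp_map$allele2 <- a1
  b3 <- phased_block(ds3, "BR01", tr$snp, setdiff(c("A", "B"), lab))
  expect_equal(b1[c("start", "end", "n_snps", "n_homozygotes")],
               b3[c("start", "end", "n_snps", "n_homozygotes")])
})

test_that("cross-breed overlap is plain interval intersection", {
  mk <- function(breed, s, e) structure(
    list(breed = breed, peak_snp = "s", allele = "A", chrom = 1L,
         start = s, end = e, n_homozygotes = 5L, n_snps = 10L),
    class = "PhasedHaplotypeBlock")
  one <- cross_breed_overlap(list(mk("a", 100e3, 500e3)))
  expect_equal(c(one$start, one$end), c(100e3, 500e3))
  two <- cross_breed_overlap(list(mk("a", 100e3, 500e3),
                                  mk("b", 300e3, 900e3)))
  expect_equal(c(two$start, two$end), c(300e3, 500e3))
  expect_false(two$empty)
  apart <- cross_breed_overlap(list(mk("a", 1e5, 2e5), mk("b", 3e5, 4e5)))
  expect_true(apart$empty)
  bad <- list(mk("a", 1e5, 2e5), mk("b", 1e5, 2e5))
  bad[[2]]$chrom <- 2L
  expect_error(cross_breed_overlap(bad), "mixed chromosomes")
  # random interval sets vs pointwise-membership oracle
  set.seed(77)
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    ss <- sort(sample.int(1e4, k)); ee <- ss + sample.int(5e3, k)
    ov <- cross_breed_overlap(mapply(mk, letters[1:k], ss, ee,
                                     SIMPLIFY = FALSE))
    pts <- seq_len(16e3)
    member <- rep(TRUE, length(pts))
    for (i in seq_len(k)) member <- member & pts >= ss[i] & pts <= ee[i]
    if (any(member)) {
      expect_false(ov$empty)
      expect_equal(c(ov$start, ov$end), range(pts[member]))
    } else expect_true(ov$empty)
  }
})

test_that("map intervals fall back to the haplotype overlap without signal", {
  ov <- list(chrom = 3, allele = "B", start = 2e6, end = 3e6, empty = FALSE,
             breeds = c("x", "y"))
  none <- list(di = list(x = data.frame(), y = data.frame()),
               si = list(x = data.frame(), y = data.frame()))
  mi <- map_intervals(ov, none, c("x", "y"), peak_pos = 2.5e6)
  expect_equal(mi$min_interval, mi$max_interval)
  expect_equal(mi$min_source, "none")
  # a single breed region strictly inside the overlap becomes the minimum
  regs <- list(di = list(x = data.frame(chrom = 3, start = 2.2e6,
                                        end = 2.8e6)),
               si = list())
  mi2 <- map_intervals(ov, regs, "x", peak_pos = 2.5e6)
  expect_equal(mi2$min_interval, c(2.2e6, 2.8e6))
  expect_equal(mi2$min_source, "di")
  # minimum interval is always inside the maximum interval
  expect_gte(mi2$min_interval[1], mi2$max_interval[1])
  expect_lte(mi2$min_interval[2], mi2$max_interval[2])
})

test_that("sweep fixtures: risk blocks dwarf alternative-allele blocks and
           the minimum interval keeps the causal SNP", {
  n <- 12; cover <- 0; longer <- 0
  for (seed in 1:n) {
    fx <- make_fixture(seed)
    ds <- fx$dataset; tr <- fx$truth
    rb <- strsplit(tr$risk_breeds, ",")[[1]]
    lab <- risk_allele_label(ds, tr)
    alt <- setdiff(c("A", "B"), lab)
    bl <- Filter(Negate(is.null),
                 suppressMessages(lapply(rb, function(b)
                   phased_block(ds, b, tr$snp, lab))))
    ab <- Filter(Negate(is.null),
                 suppressMessages(lapply(setdiff(sim_breed_ids(12), rb),
                   function(b) phased_block(ds, b, tr$snp, alt))))
    if (length(bl) && length(ab)) {
      longer <- longer + (mean(sapply(bl, block_length_kb)) >
                          mean(sapply(ab, block_length_kb)))
    }
    sc <- selection_scan(ds)
    ov <- cross_breed_overlap(bl)
    if (!ov$empty) {
      mi <- map_intervals(ov, sc$regions, rb, tr$pos)
      cover <- cover + (mi$min_interval[1] <= tr$pos &&
                        tr$pos <= mi$min_interval[2])
    }
  }
  expect_gte(longer, n - 1)
  expect_gte(cover, n - 1)
})
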