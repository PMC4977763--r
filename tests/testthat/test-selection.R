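test_that("Hudson F_ST hits its exact boundary cases", {
  # breeds fixed for opposite alleles -> F_ST = 1
  g <- rbind(matrix(2, 5, 3), matrix(0, 5, 3))
  ds <- tiny_dataset(g, rep(c("p1", "p2"), each = 5))
  expect_equal(unname(pairwise_fst(ds, "p1", "p2")), rep(1, 3))
  expect_error(pairwise_fst(ds, "p1", "zz"), "zz")

  # no differentiation: estimator is unbiased around 0 (sample-size
  # corrected), so the genomewide mean is near 0
  set.seed(21)
  g0 <- matrix(rbinom(40 * 400, 2, rep(runif(400, 0.2, 0.8),
                                       each = 40)), 40, 400)
  ds0 <- tiny_dataset(g0, rep(c("p1", "p2"), each = 20))
  expect_lt(abs(mean(pairwise_fst(ds0, "p1", "p2"), na.rm = TRUE)), 0.02)
})

test_that("realized F_ST tracks the configured Balding-Nichols divergence", {
  cfg <- sim_config(n_breeds = 30, dogs_per_breed = 12,
                    n_snps_per_chrom = 400, chrom_lengths = rep(12e6, 5),
                    breed_divergence_F = 0.2, missing_rate = 0, seed = 77)
  ds <- simulate_breed_genotypes(cfg)
  fst <- mean_pairwise_fst(ds)
  expect_gt(fst$overall, 0.15)
  expect_lt(fst$overall, 0.25)
})

test_that("windows tile chromosomes without overlap and truncate the last", {
  fx <- make_fixture(1)
  w <- make_windows(fx$dataset, 5e5, chrom_lengths = rep(12e6, 5))
  expect_equal(nrow(w), 5 * 24)
  for (ch in unique(w$chrom)) {
    wc <- w[w$chrom == ch, ]
    expect_equal(wc$start, seq(1, 12e6, by = 5e5))
    expect_equal(wc$end[-nrow(wc)], wc$start[-1] - 1)
    expect_equal(wc$end[nrow(wc)], 12e6)
  }
})

test_that("d_i equals the hand-evaluated normalized sum on a 3-breed toy", {
  # construct an FstTable by hand: 3 breeds, 2 windows
  wf <- cbind("b1:b2" = c(0.30, 0.10),
              "b1:b3" = c(0.40, 0.20),
              "b2:b3" = c(0.05, 0.15))
  ft <- structure(list(
    pairs = data.frame(i = c("b1", "b1", "b2"), j = c("b2", "b3", "b3")),
    window_fst = wf,
    pair_mean = colMeans(wf),
    pair_sd = apply(wf, 2, sd),
    windows = data.frame(window = 1:2, chrom = 1,
                         start = c(1, 5e5 + 1), end = c(5e5, 1e6)),
    breeds = c("b1", "b2", "b3")), class = "FstTable")
  di <- windowed_di(ft)
  z <- scale(wf)
  expect_equal(unname(di["b1", ]), unname(z[, "b1:b2"] + z[, "b1:b3"]))
  expect_equal(unname(di["b2", ]), unname(z[, "b1:b2"] + z[, "b2:b3"]))
  expect_equal(unname(di["b3", ]), unname(z[, "b1:b3"] + z[, "b2:b3"]))
  # each pair's standardized deviations sum to zero over windows
  expect_equal(sum(di), 0, tolerance = 1e-12)
})

test_that("panmictic data produce centered d_i and rare region calls", {
  set.seed(9)
  g <- matrix(rbinom(60 * 500, 2, rep(runif(500, 0.2, 0.8), each = 60)),
              60, 500)
  ds <- tiny_dataset(g, rep(sprintf("p%d", 1:6), each = 10),
                     pos = sort(sample.int(5e6, 500)))
  sc <- selection_scan(ds, window_size = 5e5)
  expect_lt(abs(mean(sc$di, na.rm = TRUE)), 0.5)
  # per-breed row sums over windows are ~0 by construction
  expect_equal(unname(rowSums(sc$di, na.rm = TRUE)),
               rep(0, 6), tolerance = 1e-8)
  n_called <- sum(vapply(sc$regions$di, nrow, numeric(1)))
  # 99th percentile of 10 windows: at most one window per breed, often zero
  expect_lte(n_called, 6)
})

test_that("s_i is invariant to uniform heterozygosity scaling and centered", {
  fx <- make_fixture(6)
  w <- make_windows(fx$dataset)
  si <- windowed_si(fx$dataset, w)
  expect_equal(unname(rowSums(si, na.rm = TRUE)),
               rep(0, nrow(si)), tolerance = 1e-8)
  # identical per-window profiles for two breeds => their pair contributes 0
  g <- matrix(rbinom(20 * 100, 2, rep(runif(100, 0.3, 0.7), each = 20)),
              20, 100)
  g2 <- rbind(g[1:10, ], g[1:10, ])   # breed q duplicates breed p
  ds2 <- tiny_dataset(g2, rep(c("p", "q"), each = 10),
                      pos = sort(sample.int(2e6, 100)))
  si2 <- windowed_si(ds2, make_windows(ds2, 5e5))
  expect_equal(unname(si2["p", ]), -unname(si2["q", ]), tolerance = 1e-10)
  expect_equal(unname(si2["p", ]), rep(0, ncol(si2)), tolerance = 1e-10)
})

test_that("sweep fixtures put the carrier's extreme windows on the sweep", {
  hits_di <- 0; hits_si <- 0; n <- 10
  for (seed in 1:n) {
    fx <- make_fixture(seed)
    sc <- selection_scan(fx$dataset)
    tr <- fx$truth
    b <- strsplit(tr$risk_breeds, ",")[[1]][1]
    overlaps <- function(w) sc$windows$chrom[w] == tr$chrom &
      sc$windows$start[w] <= tr$sweep_end &
      sc$windows$end[w] >= tr$sweep_start
    hits_di <- hits_di + overlaps(which.max(sc$di[b, ]))
    hits_si <- hits_si + overlaps(which.min(sc$si[b, ]))
  }
  expect_gte(hits_di, 9)
  expect_gte(hits_si, 9)
})

test_that("statistics are invariant to allele-label flips", {
  fx <- make_fixture(8)
  ds <- fx$dataset
  flip <- seq(1, nrow(ds$snp_map), by = 3)
  ds2 <- ds
  ds2$genotypes[, flip] <- 2 - ds2$genotypes[, flip]
  a1 <- ds2$snp_map$allele1[flip]
  ds2$snp_map$allele1[flip] <- ds2$snp_map$allele2[flip]
  ds2$snp_map$allele2[flip] <- a1
  expect_equal(pairwise_fst(ds, "BR01", "BR05"),
               pairwise_fst(ds2, "BR01", "BR05"))
  w <- make_windows(ds)
  expect_equal(windowed_si(ds, w), windowed_si(ds2, w))
  expect_equal(windowed_di(fst_table(ds, w)), windowed_di(fst_table(ds2, w)))
})

test_that("region merging matches a brute-force run-length scan", {
  windows <- data.frame(window = 1:10, chrom = c(rep(1, 6), rep(2, 4)),
                        start = c(seq(1, 2.6e6, 5e5), seq(1, 1.6e6, 5e5)),
                        end = c(seq(5e5, 3e6, 5e5), seq(5e5, 2e6, 5e5)))
  # constant surface -> no regions
  sc <- list(windows = windows,
             di = matrix(1, 1, 10, dimnames = list("b", NULL)))
  expect_equal(nrow(call_signal_regions(sc, "di", 99)$b), 0L)
  # one isolated extreme window -> exactly that window's interval
  v <- rep(0, 10); v[4] <- 5
  sc$di <- matrix(v, 1, 10, dimnames = list("b", NULL))
  r <- call_signal_regions(sc, "di", 90)$b
  expect_equal(r[, c("start", "end")],
               data.frame(start = windows$start[4], end = windows$end[4]))
  # adjacent extremes merge; chromosome boundaries split
  set.seed(40)
  for (rep in 1:50) {
    v <- rnorm(10)
    sc$di <- matrix(v, 1, 10, dimnames = list("b", NULL))
    pct <- sample(c(80, 90, 95), 1)
    r <- call_signal_regions(sc, "di", pct)$b
    thr <- quantile(v, pct / 100)
    sel <- v > thr
    # brute force: walk the windows, break runs at chromosome changes
    runs <- list()
    cur <- NULL
    for (w in 1:10) {
      if (sel[w]) {
        if (is.null(cur) || windows$chrom[w] != cur$chrom ||
            w != cur$last + 1) {
          if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
          cur <- list(chrom = windows$chrom[w], first = w, last = w)
        } else cur$last <- w
      }
    }
    if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
    expect_equal(nrow(r), length(runs))
    if (length(runs)) {
      expect_equal(r$start, sapply(runs, function(x) windows$start[x$first]))
      expect_equal(r$end, sapply(runs, function(x) windows$end[x$last]))
    }
  }
})
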