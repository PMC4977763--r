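test_that("a hand-written PED/MAP pair converts to the expected dosages", {
  td <- withr::local_tempdir()
  # 2 individuals x 3 SNPs; minor alleles by cohort count: s1 -> G (1 copy),
  # s2 -> tie A/C broken to A, s3 -> monomorphic T
  writeLines(c("b1 d1 0 0 2 -9 A G A A T T",
               "b2 d2 0 0 2 -9 A A C C T T"),
             file.path(td, "toy.ped"))
  writeLines(c("1\ts1\t0\t100", "1\ts2\t0\t200", "1\ts3\t0\t300"),
             file.path(td, "toy.map"))
  ds <- read_plink_text(file.path(td, "toy.ped"))
  expect_equal(unname(ds$genotypes),
               matrix(c(1, 0,   # G dosage
                        2, 0,   # A dosage (tie -> lexicographically first)
                        0, 0),  # monomorphic: minor unobserved
                      2, 3))
  expect_equal(ds$snp_map$allele1, c("G", "A", "0"))
  expect_equal(ds$snp_map$allele2, c("A", "C", "T"))
  expect_equal(unname(dataset_breeds(ds)), c("b1", "b2"))
})

test_that("malformed PED lines fail with the line number", {
  td <- withr::local_tempdir()
  writeLines(c("b1 d1 0 0 2 -9 A G A A",          # truncated genotypes
               "b2 d2 0 0 2 -9 A A C C T T"),
             file.path(td, "bad.ped"))
  writeLines(c("1\ts1\t0\t100", "1\ts2\t0\t200", "1\ts3\t0\t300"),
             file.path(td, "bad.map"))
  expect_error(read_plink_text(file.path(td, "bad.ped")), "line 1")
})

test_that("more than two alleles at a SNP is a descriptive error", {
  td <- withr::local_tempdir()
  writeLines(c("b1 d1 0 0 2 -9 A G", "b2 d2 0 0 2 -9 C C"),
             file.path(td, "tri.ped"))
  writeLines("1\ts1\t0\t100", file.path(td, "tri.map"))
  expect_error(read_plink_text(file.path(td, "tri.ped")), "s1")
})

test_that("individuals missing from an explicit breed table are reported", {
  td <- withr::local_tempdir()
  fx <- tiny_dataset(matrix(c(0, 1, 2, 0, 1, 2), 3, 2), c("x", "x", "y"))
  write_plink_text(fx, file.path(td, "t"))
  writeLines(c("individual\tbreed", "i01\tx"), file.path(td, "part.tsv"))
  expect_error(read_plink_text(file.path(td, "t.ped"),
                               file.path(td, "part.tsv")),
               "i02")
})

test_that("PED/MAP and TPED/TFAM round-trips are the identity", {
  fx <- make_fixture(9)
  td <- withr::local_tempdir()
  for (fmt in c("ped", "tped")) {
    write_plink_text(fx$dataset, file.path(td, fmt), format = fmt)
    back <- read_plink_text(file.path(td, fmt))
    expect_equal(unname(fx$dataset$genotypes), unname(back$genotypes))
    expect_equal(fx$dataset$snp_map$snp, back$snp_map$snp)
    expect_equal(fx$dataset$snp_map$pos, as.numeric(back$snp_map$pos))
    expect_equal(fx$dataset$snp_map$allele1, back$snp_map$allele1)
    expect_equal(fx$dataset$snp_map$allele2, back$snp_map$allele2)
    expect_equal(dataset_breeds(fx$dataset), dataset_breeds(back))
  }
  # orientation is a pure function of cohort counts: re-reading never flips
  write_plink_text(read_plink_text(file.path(td, "ped")),
                   file.path(td, "again"))
  expect_identical(readLines(file.path(td, "ped.ped")),
                   readLines(file.path(td, "again.ped")))
})

test_that("an empty dataset writes a valid empty MAP and mandatory-column PED", {
  g <- matrix(numeric(0), nrow = 2, ncol = 0)
  map <- data.frame(snp = character(0), chrom = integer(0), pos = numeric(0),
                    allele1 = character(0), allele2 = character(0))
  ds <- genotype_dataset(c("i1", "i2"),
                         c(i1 = "b1", i2 = "b2"), map, g)
  td <- withr::local_tempdir()
  write_plink_text(ds, file.path(td, "empty"))
  expect_equal(length(readLines(file.path(td, "empty.map"))), 0L)
  ped <- readLines(file.path(td, "empty.ped"))
  expect_equal(length(ped), 2L)
  expect_equal(length(strsplit(ped[1], " ")[[1]]), 6L)
})

test_that("MAP row count always equals the dataset SNP count", {
  fx <- make_fixture(2)
  td <- withr::local_tempdir()
  write_plink_text(fx$dataset, file.path(td, "fx"))
  expect_equal(length(readLines(file.path(td, "fx.map"))),
               nrow(fx$dataset$snp_map))
})

test_that("stereotype tables round-trip at full precision and reject bad input", {
  td <- withr::local_tempdir()
  fx <- make_fixture(3)
  st <- fx$stereotypes
  write_stereotypes(st, file.path(td, "st.tsv"))
  back <- read_stereotypes(file.path(td, "st.tsv"))
  expect_identical(unname(st$values), unname(back$values))
  expect_equal(st$breeds, back$breeds)

  writeLines(c("breed\tdog_rivalry", "b1\t1.0", "b1\t2.0"),
             file.path(td, "dup.tsv"))
  expect_error(read_stereotypes(file.path(td, "dup.tsv")), "b1")
  writeLines(c("breed\tdog_rivalry", "b1\tNaNope"),
             file.path(td, "txt.tsv"))
  expect_error(read_stereotypes(file.path(td, "txt.tsv")), "dog_rivalry")
  # unknown trait columns are preserved but flagged
  writeLines(c("breed\tdog_rivalry\tbarking", "b1\t1\t2", "b2\t0\t1",
               "b3\t2\t0"), file.path(td, "extra.tsv"))
  expect_warning(tab <- read_stereotypes(file.path(td, "extra.tsv")),
                 "barking")
  expect_true("barking" %in% tab$traits)
  expect_equal(attr(tab, "extra_traits"), "barking")
})

test_that("an 11-breed, 9-trait table parses with the right shape", {
  td <- withr::local_tempdir()
  vals <- matrix(abs(rnorm(99)), 11, 9,
                 dimnames = list(NULL, cbarq_traits()))
  write_stereotypes(stereotype_table(sprintf("b%02d", 1:11), vals),
                    file.path(td, "t11.tsv"))
  tab <- read_stereotypes(file.path(td, "t11.tsv"))
  expect_equal(dim(tab$values), c(11L, 9L))
})
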