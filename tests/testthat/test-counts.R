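tiny_library <- function(n = 5, seed = 61) {
  withr::with_seed(seed, {
    spacers <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
      "")
  })
  data.frame(guide_id = paste0("g", seq_len(n)), spacer = spacers,
             stringsAsFactors = FALSE)
}

test_that("exact deconvolution assigns reads and conserves totals", {
  lib <- tiny_library()
  fq <- withr::local_tempfile(fileext = ".fastq")
  reads <- c(rep(paste0(lib$spacer[1], "GTTT"), 100),
             rep(paste0(lib$spacer[2], "GTTT"), 7),
             paste0(strrep("A", 20), "GTTT"))  # matches nothing
  write_fastq(reads, fq)
  got <- deconvolve(fq, lib, spacer_start = 0L)
  expect_equal(unname(got$counts[c("g1", "g2")]), c(100L, 7L))
  expect_equal(got$unassigned, 1L)
  expect_equal(sum(got$counts) + got$unassigned, got$total)
  expect_equal(got$total, length(reads))
})

test_that("prefix-scan extraction finds the spacer after CACCG at any stagger", {
  lib <- tiny_library()
  fq <- withr::local_tempfile(fileext = ".fastq")
  stagger <- c("", "T", "AT", "GAT")
  reads <- paste0(stagger, "CACCG", lib$spacer[c(1, 1, 2, 3)], "GTTTAA")
  write_fastq(reads, fq)
  got <- deconvolve(fq, lib, spacer_start = -1L)
  expect_equal(unname(got$counts[1:3]), c(2L, 1L, 1L))
  expect_equal(got$unassigned, 0L)
})

test_that("one-mismatch reads are recovered only when unambiguous", {
  lib <- tiny_library()
  mut <- lib$spacer[1]
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(mut, 5, 5))[1]
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(paste0(mut, "GTTT"), fq)
  expect_equal(unname(deconvolve(fq, lib, 0L, mismatches = 1L)$counts["g1"]),
               1L)
  strict <- deconvolve(fq, lib, 0L, mismatches = 0L)
  expect_equal(strict$unassigned, 1L)
  # a read equidistant (Hamming 1) from two spacers stays unassigned
  s1 <- strrep("A", 20)
  s2 <- paste0("CG", strrep("A", 18))
  amb <- paste0("C", strrep("A", 19))   # distance 1 from both
  lib2 <- data.frame(guide_id = c("x1", "x2"), spacer = c(s1, s2))
  write_fastq(paste0(amb, "GTTT"), fq)
  got <- deconvolve(fq, lib2, 0L, mismatches = 1L)
  expect_equal(sum(got$counts), 0L)
  expect_equal(got$unassigned, 1L)
})

test_that("deconvolution agrees with a per-read linear-scan oracle", {
  lib <- tiny_library(n = 8, seed = 67)
  withr::with_seed(68, {
    idx <- sample(8, 200, replace = TRUE)
    reads <- lib$spacer[idx]
    flip <- runif(200) < 0.4   # mutate 40% of reads at one position
    for (r in which(flip)) {
      p <- sample(20, 1)
      substr(reads[r], p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
  })
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  for (mm in c(0L, 1L)) {
    got <- deconvolve(fq, lib, 0L, mismatches = mm)
    want <- oracle_assign_reads(reads, lib$spacer, mm)
    expect_equal(unname(got$counts),
                 tabulate(want, nbins = 8), info = paste("mm =", mm))
    expect_equal(got$unassigned, sum(is.na(want)))
  }
  # order independence
  shuf <- withr::with_seed(69, sample(length(reads)))
  write_fastq(reads[shuf], fq)
  expect_equal(deconvolve(fq, lib, 0L)$counts,
               {write_fastq(reads, fq); deconvolve(fq, lib, 0L)$counts})
})

test_that("median-ratio size factors match closed forms", {
  m <- matrix(c(10L, 20L, 40L, 10L, 20L, 40L), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors_median_ratio(m)), c(1, 1))
  m2 <- m
  m2[, 2] <- m[, 1] * 2L
  expect_equal(unname(size_factors_median_ratio(m2)),
               c(1 / sqrt(2), sqrt(2)))
  one <- matrix(c(4L, 16L), 1, dimnames = list("g1", c("a", "b")))
  expect_equal(unname(size_factors_median_ratio(one)), c(0.5, 2))
  bad <- m
  bad[, 2] <- 0L
  expect_error(size_factors_median_ratio(bad), "all-zero")
})

test_that("guide lfc, ranks and normalised ranks follow their definitions", {
  m <- matrix(c(8L, 8L, 8L, 1L, 4L, 32L), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("pool", "d21")))
  out <- guide_lfc(m, reference = "pool", pseudocount = 1e-9,
                   size_factors = c(pool = 1, d21 = 1))
  expect_equal(out$lfc, c(-3, -1, 2), tolerance = 1e-6)
  expect_equal(out$rank, c(1L, 2L, 3L))
  expect_equal(out$norm_rank, c(1, 2, 3) / 3)
  # equal normalised counts give lfc 0
  eq <- guide_lfc(matrix(c(5L, 5L), 1, dimnames = list("g", c("pool", "s"))),
                  reference = "pool", size_factors = c(pool = 1, s = 1))
  expect_equal(eq$lfc, 0)
  # day21 = reference / 4 gives lfc -2 in the small-pseudocount limit
  q <- guide_lfc(matrix(c(400L, 100L), 1,
                        dimnames = list("g", c("pool", "s"))),
                 reference = "pool", pseudocount = 1e-9,
                 size_factors = c(pool = 1, s = 1))
  expect_equal(q$lfc, -2, tolerance = 1e-9)
  expect_error(guide_lfc(m, reference = "nope"), "unknown reference")
})

test_that("tied lfc values share average normalised ranks", {
  m <- matrix(c(10L, 10L, 10L, 5L, 5L, 40L), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("pool", "s")))
  out <- guide_lfc(m, reference = "pool", size_factors = c(pool = 1, s = 1))
  expect_equal(out$norm_rank[1:2], c(0.5, 0.5))   # average of ranks 1,2
  expect_equal(sort(out$rank), 1:3)               # still a permutation
})

test_that("doubling one sample's depth leaves lfc essentially unchanged", {
  withr::with_seed(71, {
    m <- matrix(rnbinom(300, mu = 1000, size = 20), ncol = 3,
                dimnames = list(sprintf("g%03d", 1:100),
                                c("pool", "r1", "r2")))
  })
  a <- guide_lfc(m, reference = "pool")
  m2 <- m
  m2[, "r1"] <- m[, "r1"] * 2L
  b <- guide_lfc(m2, reference = "pool")
  expect_equal(b$lfc, a$lfc, tolerance = 1e-3)
  expect_equal(b$rank, a$rank)
})

test_that("count matrices round-trip through TSV", {
  withr::with_seed(72,
    m <- matrix(rnbinom(30, mu = 100, size = 20), ncol = 3,
                dimnames = list(paste0("g", 1:10), c("pool", "a", "b"))))
  storage.mode(m) <- "integer"
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(m, tsv)
  expect_identical(read_counts_tsv(tsv), m)
})
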