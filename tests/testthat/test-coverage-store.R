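test_that("encoding regimes match the three-regime byte scheme", {
  e <- encode_coverage(c(0, 150, 200, 201, 2699, 2700, 3000))
  expect_equal(e$byte, c(0L, 150L, 200L, 201L, 249L, 255L, 255L))
  expect_equal(e$overflow, c(F, F, F, F, F, T, T))
  expect_error(encode_coverage(-1), "non-negative")
})

test_that("decoding inverts each regime", {
  expect_equal(decode_coverage(c(0, 150, 200)), c(0, 150, 200))
  expect_equal(decode_coverage(249), 2650) # midpoint of preimage [2601, 2699]
  expect_equal(decode_coverage(255, overflow_value = 8123), 8123)
  expect_error(decode_coverage(255), "overflow record")
  expect_error(decode_coverage(252), "reserved")
  expect_error(decode_coverage(300), "255")
})

test_that("round-trip error is bounded and encoding is monotone", {
  v <- 0:2699
  enc <- encode_coverage(v)
  expect_false(any(enc$overflow))
  dec <- decode_coverage(enc$byte)
  bound <- 2 * sqrt(pmax(v - 200, 0)) + 1
  expect_true(all(abs(dec - v) <= bound))
  expect_true(all(diff(enc$byte) >= 0))
  # overflow values are kept exactly
  big <- c(2700, 5000, 99999.5)
  e2 <- encode_coverage(big)
  expect_equal(decode_coverage(e2$byte, overflow_value = big), big)
})

test_that("condense averages 20-bp windows with rounding and partial ends", {
  d <- data.frame(chrom = "chr1", pos = 1:40, depth = 7)
  expect_equal(condense(d, c(chr1 = 40L))$bytes$chr1, c(7L, 7L))

  # 20 depths summing to 252: mean 12.6, rounds half-up to 13
  d <- data.frame(chrom = "chr1", pos = 1:20, depth = c(rep(13, 12), rep(12, 8)))
  stopifnot(sum(d$depth) == 252)
  expect_equal(condense(d, c(chr1 = 20L))$bytes$chr1, 13L)

  # terminal partial window averages over existing bases only
  d <- data.frame(chrom = "chr1", pos = 1:30, depth = 10)
  expect_equal(condense(d, c(chr1 = 30L))$bytes$chr1, c(10L, 10L))

  # absent positions count as zero depth
  d <- data.frame(chrom = "chr1", pos = 1:10, depth = 20)
  expect_equal(condense(d, c(chr1 = 40L))$bytes$chr1, c(10L, 0L))
})

test_that("condense rejects malformed input", {
  d <- data.frame(chrom = "chr1", pos = c(5, 3), depth = 1)
  expect_error(condense(d, c(chr1 = 40L)), "sorted")
  d <- data.frame(chrom = "chr1", pos = 50, depth = 1)
  expect_error(condense(d, c(chr1 = 40L)), "beyond")
  expect_error(condense(data.frame(chrom = "chrX", pos = 1, depth = 1),
                        c(chr1 = 40L)), "unknown")
})

test_that("overflow windows carry the unrounded mean in the sidecar", {
  d <- data.frame(chrom = "chr1", pos = 1:40,
                  depth = c(rep(3000, 20), rep(5, 20)))
  tr <- condense(d, c(chr1 = 40L))
  expect_equal(tr$bytes$chr1, c(255L, 5L))
  expect_equal(tr$overflow$window_start, 0L)
  expect_equal(tr$overflow$value, 3000)
  expect_equal(query_track(tr, "chr1", 0, 40), c(3000, 5))
})

test_that("query returns decoded values for overlapping windows only", {
  d <- data.frame(chrom = "chr1", pos = 1:200, depth = rep(1:10, each = 20))
  tr <- condense(d, c(chr1 = 200L))
  expect_equal(query_track(tr, "chr1", 40, 100), c(3, 4, 5)) # windows 3-5
  expect_equal(query_track(tr, "chr1", 50, 50), numeric(0))
  expect_equal(query_track(tr, "chr1", 0, 1), 1)
  expect_equal(query_track(tr, "chr1", 199, 200), 10)
  expect_error(query_track(tr, "chr2", 0, 10), "unknown")
  expect_error(query_track(tr, "chr1", 0, 300), "bounds")
})

test_that("condense then query reproduces window means within quantization", {
  set.seed(41)
  len <- 1003L
  depth <- rpois(len, 60)
  d <- data.frame(chrom = "chr1", pos = seq_len(len), depth = depth)
  tr <- condense(d, c(chr1 = len))
  got <- query_track(tr, "chr1", 0, len)
  truth <- vapply(seq_len(ceiling(len / 20)), function(w) {
    mean(depth[((w - 1) * 20 + 1):min(w * 20, len)])
  }, numeric(1))
  bound <- 2 * sqrt(pmax(truth - 200, 0)) + 1
  expect_true(all(abs(got - truth) <= bound))
})

test_that("binary track files round-trip and support region reads", {
  set.seed(42)
  lens <- c(chr1 = 2040L, chr2 = 1500L)
  d <- rbind(
    data.frame(chrom = "chr1", pos = 1:2040, depth = rpois(2040, 30)),
    data.frame(chrom = "chr2", pos = 1:1500, depth = rpois(1500, 2500)))
  tr <- condense(d, lens)
  path <- withr::local_tempfile(fileext = ".rcpc")
  write_condensed(tr, path)
  back <- read_condensed(path)
  expect_equal(back$bytes, tr$bytes)
  expect_equal(back$chrom_lengths, tr$chrom_lengths)
  expect_equal(back$overflow$value, tr$overflow$value, tolerance = 1e-9)
  expect_equal(read_condensed(path, "chr2", 100, 900),
               query_track(tr, "chr2", 100, 900))
  # payload is one byte per window (plus a fixed-size header)
  expect_lt(file.size(path), sum(ceiling(lens / 20)) + 200)
})

test_that("autocorrelation matches analytic cases", {
  expect_true(all(is.na(coverage_autocorr(rep(5, 100), 3))))
  alt <- rep(c(0, 1), 50)
  expect_equal(coverage_autocorr(alt, 2), c(-1, 1))
  set.seed(9)
  x <- rnorm(10000)
  expect_lt(abs(coverage_autocorr(x, 1)[1]), 0.05)
  expect_error(coverage_autocorr(1:5, 5), "longer")
  # positively autocorrelated signal is detected
  y <- as.numeric(stats::filter(rnorm(5000), rep(1, 10), sides = 1))[-(1:9)]
  expect_gt(coverage_autocorr(y, 1)[1], 0.8)
})

test_that("depth reader handles bare and named-column formats", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1\t5", "chr1\t2\t6"), path)
  d <- read_depth(path)
  expect_equal(d$depth, c(5L, 6L))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tgcCorrectedCoverage",
               "chr1\t1\t5.5", "chr1\t2\t6.1"), path2)
  d2 <- read_depth(path2, depth_col = "gcCorrectedCoverage")
  expect_equal(d2$depth, c(5.5, 6.1))
  expect_error(read_depth(path2, depth_col = "nope"), "not found")
})
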