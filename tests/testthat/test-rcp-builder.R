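test_that("bin_mad is the unscaled median absolute deviation", {
  expect_equal(bin_mad(rep(3.2, 10)), 0)
  expect_equal(bin_mad(c(1, 2, 3, 4, 100)), 1)
  x <- rlnorm(50)
  expect_equal(bin_mad(7 * x), 7 * bin_mad(x))
  expect_error(bin_mad(numeric(0)), "at least one")
})

test_that("tight bins use the median; the level is accurate", {
  set.seed(31)
  v <- rnorm(200, 1, 0.03)
  est <- estimate_diploid_level(v)
  expect_equal(est$method, "median")
  expect_equal(est$level, 1, tolerance = 0.01)
})

test_that("HWE deletion mixtures recover the diploid level", {
  set.seed(32)
  g <- rbinom(300, 2, 0.3) # deletion alleles per individual
  v <- pmax((2 - g) / 2 + rnorm(300, 0, 0.03), 0)
  est <- estimate_diploid_level(v)
  expect_equal(est$level, 1, tolerance = 0.05)
})

test_that("a common deletion with hemizygotes modal is not aliased", {
  set.seed(33)
  g <- rbinom(300, 2, 0.8)
  v <- pmax((2 - g) / 2 + rnorm(300, 0, 0.02), 0)
  est <- estimate_diploid_level(v)
  # the correct answer is the (rare) diploid level, not the hemizygous or
  # nullizygous cluster the cohort is dominated by
  expect_equal(est$level, 1, tolerance = 0.1)
  expect_equal(est$method, "peak-model")
})

test_that("duplication mixtures recover the diploid level too", {
  set.seed(34)
  g <- rbinom(300, 2, 0.3)
  v <- (2 + g) / 2 + rnorm(300, 0, 0.03)
  expect_equal(estimate_diploid_level(v)$level, 1, tolerance = 0.05)
})

test_that("median and peak-model paths agree on unimodal bins", {
  set.seed(35)
  for (sdev in c(0.1, 0.2, 0.3)) {
    v <- pmax(rnorm(400, 1, sdev), 0)
    est <- suppressWarnings(estimate_diploid_level(v))
    expect_equal(est$level, median(v), tolerance = 0.02)
  }
})

test_that("an all-zero bin is masked", {
  expect_equal(estimate_diploid_level(rep(0, 50))$method, "masked")
  expect_error(estimate_diploid_level(numeric(0)), "no values")
})

test_that("build_rcp estimates per-bin level, MAD and support", {
  profs <- replicate(10, flat_profile(30, 1), simplify = FALSE)
  rcp <- build_rcp(profs, rcp_params(min_support = 5))
  expect_s3_class(rcp, "ReferenceCoverageProfile")
  expect_equal(rcp$level, rep(1, 30))
  expect_equal(rcp$mad, rep(0, 30))
  expect_equal(rcp$n, rep(10L, 30))
  expect_error(build_rcp(profs[1]), "at least two")
})

test_that("a hemizygous minority does not deflate the RCP level", {
  set.seed(36)
  profs <- lapply(1:10, function(i) {
    v <- rnorm(30, 1, 0.02)
    if (i <= 3) v[11:20] <- v[11:20] / 2 # 3 of 10 genomes hemizygous there
    flat_profile(30, v)
  })
  rcp <- build_rcp(profs, rcp_params(min_support = 5))
  expect_equal(rcp$level, rep(1, 30), tolerance = 0.06)
})

test_that("bins with thin support or mostly-missing data are masked", {
  profs <- replicate(10, {
    p <- flat_profile(20, 1)
    p$value[1:5] <- NA_real_   # missing in every genome
    p
  }, simplify = FALSE)
  for (i in 1:6) profs[[i]]$value[6] <- NA_real_ # missing in 6 of 10
  rcp <- build_rcp(profs, rcp_params(min_support = 5))
  expect_true(all(rcp$flag[1:6] == "masked"))
  expect_true(all(rcp$flag[7:20] == "median"))
})

test_that("the cohort is capped at max_genomes", {
  profs <- replicate(30, flat_profile(3, 1), simplify = FALSE)
  expect_warning(rcp <- build_rcp(profs, rcp_params(min_support = 5,
                                                    max_genomes = 25)),
                 "capped")
  expect_true(all(rcp$n == 25))
})

test_that("RCP levels are equivariant to a cohort-wide rescaling", {
  set.seed(37)
  vals <- matrix(rnorm(20 * 40, 1, 0.05), nrow = 40)
  profs <- lapply(1:20, function(j) flat_profile(40, vals[, j]))
  profs_scaled <- lapply(1:20, function(j) flat_profile(40, 3 * vals[, j]))
  a <- build_rcp(profs, rcp_params(min_support = 5))
  b <- build_rcp(profs_scaled, rcp_params(min_support = 5))
  expect_equal(b$level, 3 * a$level, tolerance = 1e-8)
})

test_that("profile correlation behaves like Pearson r on joint bins", {
  set.seed(38)
  a <- build_rcp(replicate(5, flat_profile(100, rlnorm(100, 0, 0.3)),
                           simplify = FALSE)[c(1, 1)] , rcp_params(min_support = 2))
  expect_equal(correlate_profiles(a, a), 1.0)
  b <- a; b$level <- 2 * b$level
  expect_equal(correlate_profiles(a, b), 1.0)
  set.seed(39)
  r1 <- flat_profile(10000, rlnorm(10000, 0, 0.2))
  r2 <- flat_profile(10000, rlnorm(10000, 0, 0.2))
  pa <- build_rcp(list(r1, r1), rcp_params(min_support = 2))
  pb <- build_rcp(list(r2, r2), rcp_params(min_support = 2))
  expect_lt(abs(correlate_profiles(pa, pb)), 0.05)
  expect_error(correlate_profiles(pa[1, ], pb[1, ]), "at least two")
})

test_that("uniformity statistics are cumulative distributions", {
  profs <- replicate(4, flat_profile(10, 2), simplify = FALSE)
  rcp <- build_rcp(profs, rcp_params(min_support = 2))
  u <- uniformity_stats(rcp)
  expect_equal(unique(u$level$value), 2)
  expect_equal(max(u$level$cum_fraction), 1)
  two <- uniformity_stats(c(rep(1, 5), rep(2, 5)))
  expect_equal(two$cum_fraction[two$value == 1][5], 0.5)
  expect_equal(max(two$cum_fraction[two$value == 2]), 1.0)
  # noise widens the spread of the level distribution
  set.seed(40)
  quiet <- uniformity_stats(rnorm(1000, 100, 1))
  noisy <- uniformity_stats(rnorm(1000, 100, 10))
  iqr <- function(u) diff(u$value[findInterval(c(0.25, 0.75), u$cum_fraction)])
  expect_gt(iqr(noisy), iqr(quiet))
})

test_that("RCPs round-trip through the TSV representation", {
  profs <- replicate(5, flat_profile(8, 1.5), simplify = FALSE)
  rcp <- build_rcp(profs, rcp_params(min_support = 2))
  rcp$level[3] <- NA_real_; rcp$flag[3] <- "masked"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rcp(rcp, path)
  back <- read_rcp(path)
  expect_equal(back$level, rcp$level)
  expect_equal(back$flag, rcp$flag)
  # minimal three-column file is accepted
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t0\t1000\t1.5", "chr1\t1000\t2000\tNA"), path2)
  mini <- read_rcp(path2)
  expect_equal(mini$level, c(1.5, NA))
  expect_equal(mini$flag, c("median", "masked"))
})
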