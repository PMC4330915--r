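make_panel <- function(state_matrix) {
  # state_matrix: bins x individuals
  panel_states(lapply(seq_len(ncol(state_matrix)), function(j) {
    state_track(state_matrix[, j])
  }))
}

test_that("genotype frequency is the median per-bin matching count", {
  m <- matrix(2L, nrow = 5, ncol = 100)
  m[, 1:10] <- 1L # 10 of 100 individuals hemizygous everywhere
  panel <- make_panel(m)
  seg <- list(chrom = "chr1", start = 0L, end = 5000L, state = 1L)
  expect_equal(genotype_frequency(seg, panel), 0.10)
  # per-bin counts 5, 10, 15 -> median 10
  m2 <- matrix(2L, nrow = 3, ncol = 100)
  m2[1, 1:5] <- 1L; m2[2, 1:10] <- 1L; m2[3, 1:15] <- 1L
  seg2 <- list(chrom = "chr1", start = 0L, end = 3000L, state = 1L)
  expect_equal(genotype_frequency(seg2, make_panel(m2)), 0.10)
  # nobody matches
  seg0 <- list(chrom = "chr1", start = 0L, end = 5000L, state = 0L)
  expect_equal(genotype_frequency(seg0, make_panel(matrix(2L, 5, 20))), 0)
  # no overlap
  segx <- list(chrom = "chr9", start = 0L, end = 5000L, state = 1L)
  expect_true(is.na(genotype_frequency(segx, panel)))
})

test_that("allele frequency integrates ploidy observations", {
  m <- matrix(2L, nrow = 1, ncol = 100)
  m[, 1:9] <- 1L; m[, 10] <- 0L
  panel <- make_panel(m)
  seg <- list(chrom = "chr1", start = 0L, end = 1000L, state = 1L)
  expect_equal(allele_frequency(seg, panel), (9 + 2) / 200)
  expect_equal(allele_frequency(seg, make_panel(matrix(2L, 1, 100))), 0)
  mdup <- matrix(2L, nrow = 1, ncol = 100); mdup[, 1:10] <- 3L
  segd <- list(chrom = "chr1", start = 0L, end = 1000L, state = 3L)
  expect_equal(allele_frequency(segd, make_panel(mdup)), 10 / 200)
  seg2 <- list(chrom = "chr1", start = 0L, end = 1000L, state = 2L)
  expect_true(is.na(allele_frequency(seg2, panel)))
})

test_that("allele frequency is bounded by the direct genotype count", {
  set.seed(61)
  for (i in 1:20) {
    m <- matrix(sample(0:4, 50 * 40, replace = TRUE,
                       prob = c(0.02, 0.08, 0.8, 0.08, 0.02)),
                nrow = 50)
    panel <- make_panel(m)
    seg <- list(chrom = "chr1", start = 0L, end = 50000L, state = 1L)
    af <- allele_frequency(seg, panel)
    expect_gte(af, 0); expect_lte(af, 1)
    # oracle: per-bin (het + 2*hom)/2n, then the median
    oracle <- median(vapply(seq_len(50), function(b) {
      (sum(m[b, ] == 1) + 2 * sum(m[b, ] == 0)) / (2 * 40)
    }, numeric(1)))
    expect_equal(af, oracle)
  }
})

test_that("panel allele frequency converges to the HWE allele frequency", {
  set.seed(62)
  p <- 0.3
  g <- rbinom(500, 2, p) # deletion alleles per individual
  m <- matrix(rep(2L - g, each = 10), nrow = 10)
  seg <- list(chrom = "chr1", start = 0L, end = 10000L, state = 1L)
  expect_lt(abs(allele_frequency(seg, make_panel(m)) - p), 0.02)
})

test_that("junction clustering chains within the distance cutoff", {
  j <- data.frame(assembly = "a1", chrom = "chr1", pos = c(1000, 1200, 5000))
  cl <- cluster_junctions(j, cutoff = 400)
  expect_equal(cl$start, c(1000, 5000))
  expect_equal(cl$end, c(1200, 5000))
  expect_equal(cl$n, c(2L, 1L))
  # single linkage: 0-300-600 chains into one cluster despite 600 > 400
  j2 <- data.frame(assembly = "a1", chrom = "chr1", pos = c(0, 300, 600))
  expect_equal(nrow(cluster_junctions(j2, cutoff = 400)), 1)
  # frequency counts assemblies, not junctions
  j3 <- data.frame(assembly = c("a1", "a1", "a2", "a3", "a4"),
                   chrom = "chr1", pos = c(100, 150, 120, 130, 9000))
  cl3 <- cluster_junctions(j3, cutoff = 400)
  expect_equal(cl3$frequency, c(3 / 4, 1 / 4))
  expect_equal(cluster_junctions(j3, cutoff = 400, n_assemblies = 1584)$frequency,
               c(3 / 1584, 1 / 1584))
  expect_equal(nrow(cluster_junctions(j3[0, ], 400)), 0)
})

test_that("junction clusters match a quadratic single-linkage oracle", {
  set.seed(63)
  for (i in 1:10) {
    n <- sample(5:200, 1)
    pos <- sort(sample(1:20000, n))
    j <- data.frame(assembly = sample(paste0("a", 1:8), n, replace = TRUE),
                    chrom = "chr1", pos = pos)
    got <- cluster_junctions(j[sample(n), ], cutoff = 400)
    oracle <- brute_force_single_linkage(pos, 400)
    expect_equal(nrow(got), length(oracle))
    expect_equal(got$start, vapply(oracle, function(g) min(pos[g]), numeric(1)))
    expect_equal(got$end, vapply(oracle, function(g) max(pos[g]), numeric(1)))
  }
})

test_that("rare-deletion filtering applies state, length and frequency", {
  segs <- data.frame(chrom = "chr1",
                     start = c(0, 10000, 20000, 30000, 40000),
                     end = c(5000, 12000, 25000, 35000, 45000),
                     state = c(1L, 1L, 1L, 2L, 0L),
                     genotype_freq = c(0.005, 0.005, 0.02, 0.001, 0.0))
  kept <- filter_rare_deletions(segs)
  expect_equal(kept$start, c(0, 40000)) # 2 kb and freq 0.02 and state 2 dropped
})

test_that("gene impact trims terminal bins before exon overlap", {
  exons <- data.frame(chrom = "chr1",
                      start = c(15200, 10100, 52000),
                      end = c(15400, 10400, 52200),
                      gene = c("GENE_A", "GENE_B", "GENE_C"))
  del <- data.frame(chrom = "chr1", start = c(10000, 50000),
                    end = c(21000, 55000), state = c(1L, 0L),
                    individual = c("s1", "s2"))
  gi <- gene_impact(del, exons)
  # GENE_A exon is interior to the state-1 deletion: affected
  expect_true(gi$genes$affected[gi$genes$gene == "GENE_A"])
  # GENE_B exon lies only in the deletion's first (trimmed) bin
  expect_false(gi$genes$affected[gi$genes$gene == "GENE_B"])
  # GENE_C overlaps the trimmed span of a state-0 deletion: knocked out
  expect_true(gi$genes$knocked_out[gi$genes$gene == "GENE_C"])
  expect_false(gi$genes$affected[gi$genes$gene == "GENE_C"])
  expect_equal(gi$individuals$n_affected, c(1L, 0L))
  expect_equal(gi$individuals$n_knocked_out, c(0L, 1L))
})

test_that("a deletion of two bins or fewer never matches a gene", {
  exons <- data.frame(chrom = "chr1", start = 10100, end = 10900,
                      gene = "GENE_A")
  del <- data.frame(chrom = "chr1", start = 10000, end = 12000, state = 1L)
  gi <- gene_impact(del, exons)
  expect_false(gi$genes$affected[1])
})

test_that("segment annotation appends both frequencies", {
  m <- matrix(2L, nrow = 6, ncol = 50); m[4:6, 1:5] <- 1L
  panel <- make_panel(m)
  segs <- data.frame(chrom = "chr1", start = c(0, 3000), end = c(3000, 6000),
                     state = c(2L, 1L), n_bins = c(3L, 3L),
                     median_ncp = c(100, 50))
  ann <- annotate_segments(segs, panel)
  expect_equal(ann$genotype_freq, c(50 / 50, 5 / 50))
  expect_equal(ann$allele_freq, c(NA_real_, 5 / 100))
})
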