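# Synthetic cohorts with known truth. The generator reproduces the
# statistical structure the pipeline assumes: every genome shares
# locus-specific expected-coverage fluctuations (lognormal per-bin effects
# only partially explained by %GC), each genome adds its own sequencing
# depth and per-%GC-bucket bias, per-base sampling is Poisson, CNV alleles
# segregate at stated population frequencies in Hardy-Weinberg proportions,
# and trio children inherit one haplotype per parent.

#' Simulate a reference model
#'
#' Per-bin lognormal locus effects (median 1) and %GC values spread widely
#' enough to populate all 25 buckets; rank-based cutoffs and bucket
#' assignments are computed on the simulated %GC.
#'
#' @param n_bins bins per chromosome; a named vector makes several
#'   chromosomes (e.g. `c(chr1 = 800, chr2 = 700)`).
#' @param locus_sd sd of log locus effect (default 0.25; 0 = flat genome).
#' @param gc_mean,gc_sd mean and sd of per-bin %GC (defaults 0.41, 0.05,
#'   the genome-wide regime of the human reference).
#' @param bin_size bin width in bases; must be a multiple of the 20-bp
#'   storage window (default 1000).
#' @param seed optional integer seed (`NULL` continues the current RNG
#'   stream).
#' @return list of class `SyntheticReference`: `bins` (data.frame `chrom`,
#'   `start`, `end`, `gc`, `bucket`, `locus_effect`), `cutoffs`,
#'   `chrom_lengths`, `bin_size`.
#' @export
simulate_reference <- function(n_bins, locus_sd = 0.25, gc_mean = 0.41,
                               gc_sd = 0.05, bin_size = GC_BIN_SIZE,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(n_bins >= 1), bin_size %% WINDOW_SIZE == 0)
  if (is.null(names(n_bins))) names(n_bins) <- paste0("chr", seq_along(n_bins))
  total <- sum(n_bins)
  gc <- pmin(pmax(stats::rnorm(total, gc_mean, gc_sd), 0.2), 0.75)
  effect <- exp(stats::rnorm(total, 0, locus_sd))
  chrom <- rep(names(n_bins), n_bins)
  start <- unlist(lapply(n_bins, function(k) (seq_len(k) - 1L) * bin_size),
                  use.names = FALSE)
  cutoffs <- if (total >= GC_N_BUCKETS) {
    compute_cutoffs(gc, GC_N_BUCKETS)
  } else {
    # toy references: too few bins for rank-based cutoffs
    seq(0.2, 0.75, length.out = GC_N_BUCKETS + 1L)[2:GC_N_BUCKETS]
  }
  bins <- data.frame(chrom = chrom, start = start, end = start + bin_size,
                     gc = gc, bucket = assign_bucket(gc, cutoffs),
                     locus_effect = effect)
  structure(list(bins = bins, cutoffs = cutoffs,
                 chrom_lengths = stats::setNames(as.integer(n_bins * bin_size),
                                                 names(n_bins)),
                 bin_size = bin_size),
            class = "SyntheticReference")
}

#' Write the reference model as a FASTA sequence
#'
#' Generates one nucleotide sequence per chromosome whose per-bin base
#' composition matches the model's %GC, so that %GC stratification can be
#' exercised from sequence. The output is synthetic sequence, not any real
#' genome.
#'
#' @param ref a `SyntheticReference`.
#' @param path optional FASTA path; when given the sequences are written
#'   there (with a .fai-style index built by [Biostrings::fasta.index()]
#'   consumers if needed).
#' @param seed optional integer seed.
#' @return a `Biostrings::DNAStringSet`, invisibly when `path` is given.
#' @export
synth_reference_fasta <- function(ref, path = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- lapply(names(ref$chrom_lengths), function(chr) {
    b <- ref$bins[ref$bins$chrom == chr, ]
    paste(vapply(seq_len(nrow(b)), function(i) {
      gc <- b$gc[i]
      width <- b$end[i] - b$start[i]
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1)), collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(ref$chrom_lengths)
  if (!is.null(path)) {
    Biostrings::writeXStringSet(out, path)
    return(invisible(out))
  }
  out
}

#' Place CNV loci on a reference model
#'
#' Lays out non-overlapping deletion/duplication loci of the requested
#' lengths and population allele frequencies, separated by at least
#' `gap_bins` diploid bins, in order along the genome.
#'
#' @param ref a `SyntheticReference`.
#' @param spec data.frame with columns `type` ("del" or "dup"), `af`
#'   (population allele frequency) and `len_bins` (length in bins); one
#'   locus per row.
#' @param gap_bins minimum diploid gap between loci (default 5).
#' @param offset_bins bins to skip at each chromosome start (default 5).
#' @return data.frame `locus`, `chrom`, `start`, `end`, `type`, `af`,
#'   `bin_index` (list column of global bin indices).
#' @export
place_cnv_loci <- function(ref, spec, gap_bins = 5L, offset_bins = 5L) {
  stopifnot(all(spec$type %in% c("del", "dup")), all(spec$af >= 0 & spec$af <= 1))
  loci <- list()
  row <- 1L
  for (chr in names(ref$chrom_lengths)) {
    if (row > nrow(spec)) break
    idx <- which(ref$bins$chrom == chr)
    at <- offset_bins + 1L
    while (row <= nrow(spec) && at + spec$len_bins[row] - 1L <= length(idx) - offset_bins) {
      len <- spec$len_bins[row]
      bin_index <- idx[at:(at + len - 1L)]
      loci[[row]] <- data.frame(
        locus = row, chrom = chr,
        start = ref$bins$start[bin_index[1]],
        end = ref$bins$end[bin_index[len]],
        type = spec$type[row], af = spec$af[row])
      loci[[row]]$bin_index <- list(bin_index)
      at <- at + len + gap_bins
      row <- row + 1L
    }
  }
  if (row <= nrow(spec)) stop("reference too small for the requested loci")
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Sample founder genotypes in Hardy-Weinberg proportions
#'
#' Two haplotypes per founder per locus, each carrying the CNV allele with
#' probability `af`, independently: genotype frequencies follow
#' p-squared / 2pq / q-squared as the cohort grows.
#'
#' @param loci data.frame from [place_cnv_loci()] (needs `af`).
#' @param n_founders number of founders.
#' @param seed optional integer seed.
#' @return integer array `n_founders x n_loci x 2` of 0/1 allele
#'   indicators.
#' @export
sample_genotypes <- function(loci, n_founders, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_loci <- nrow(loci)
  array(stats::rbinom(n_founders * n_loci * 2, 1L,
                      rep(loci$af, each = n_founders)),
        dim = c(n_founders, n_loci, 2))
}

# copy number per locus from a haplotype slab [ind, locus, 2]
copies_from_haps <- function(haps, loci) {
  alleles <- haps[, , 1, drop = FALSE] + haps[, , 2, drop = FALSE]
  dim(alleles) <- dim(haps)[1:2]
  sweep_sign <- ifelse(loci$type == "del", -1L, 1L)
  t(2L + t(alleles) * sweep_sign)
}

# per-bin copy numbers (length nrow(ref$bins)) for one individual
bin_copies <- function(ref, loci, copies) {
  cp <- rep(2L, nrow(ref$bins))
  for (j in seq_len(nrow(loci))) cp[loci$bin_index[[j]]] <- copies[j]
  cp
}

#' Simulate one genome's coverage
#'
#' Expected depth per base is `mean_depth * locus_effect * bucket_bias *
#' copies / 2`; observed depth is Poisson. At `"window"` resolution the
#' 20-bp window means are drawn directly (the mean of 20 independent
#' Poisson draws is a scaled Poisson of 20 times the rate — statistically
#' identical and 20 times cheaper) and returned as a `CondensedTrack`; at
#' `"base"` resolution a per-base depth data.frame is returned for
#' exercising [condense()] itself.
#'
#' @param ref a `SyntheticReference`.
#' @param copies integer copy number per locus for this individual (from
#'   [copies_from_haps()] via [simulate_cohort()]), or `NULL` for all-diploid.
#' @param loci the loci the copies refer to (`NULL` when `copies` is).
#' @param mean_depth genome-wide expected diploid depth (default 40).
#' @param gc_bias two coefficients `(a, b)` of the genome's smooth %GC bias
#'   curve `exp(a*z + b*(z^2 - 1))` with `z = (gc - 0.41)/0.1`; GC bias in
#'   sequencing data is a smooth, genome-specific function of %GC, which is
#'   what the 25-bucket scaling step approximates and removes. Default no
#'   bias.
#' @param resolution `"window"` or `"base"`.
#' @param seed optional integer seed.
#' @return a `CondensedTrack`, or a data.frame `chrom`, `pos`, `depth`
#'   (zero-depth positions omitted) for `"base"`.
#' @export
simulate_genome <- function(ref, copies = NULL, loci = NULL, mean_depth = 40,
                            gc_bias = c(0, 0),
                            resolution = c("window", "base"), seed = NULL) {
  resolution <- match.arg(resolution)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(mean_depth > 0)
  cp <- if (is.null(copies)) rep(2L, nrow(ref$bins)) else bin_copies(ref, loci, copies)
  z <- (ref$bins$gc - 0.41) / 0.1
  bias <- exp(gc_bias[1] * z + gc_bias[2] * (z^2 - 1))
  bias[is.na(bias)] <- 1
  lambda <- mean_depth * ref$bins$locus_effect * bias * cp / 2
  wpb <- ref$bin_size %/% WINDOW_SIZE
  if (resolution == "window") {
    means_by_chrom <- lapply(names(ref$chrom_lengths), function(chr) {
      l <- rep(lambda[ref$bins$chrom == chr], each = wpb)
      stats::rpois(length(l), WINDOW_SIZE * l) / WINDOW_SIZE
    })
    names(means_by_chrom) <- names(ref$chrom_lengths)
    return(condense_window_means(means_by_chrom, ref$chrom_lengths))
  }
  res <- lapply(names(ref$chrom_lengths), function(chr) {
    l <- rep(lambda[ref$bins$chrom == chr], each = ref$bin_size)
    d <- stats::rpois(length(l), l)
    keep <- d > 0L
    data.frame(chrom = chr, pos = which(keep), depth = d[keep])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build a condensed track from precomputed window means
#'
#' Applies the same rounding, encoding and overflow rules as [condense()],
#' starting from already-averaged 20-bp window values.
#'
#' @param window_means named list (by chromosome) of numeric window means.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return a `CondensedTrack`.
#' @export
condense_window_means <- function(window_means, chrom_lengths) {
  bytes <- list()
  ov <- list()
  for (chr in names(chrom_lengths)) {
    means <- window_means[[chr]]
    stopifnot(length(means) == ceiling(chrom_lengths[[chr]] / WINDOW_SIZE))
    enc <- encode_coverage(round_half_up(means))
    bytes[[chr]] <- enc$byte
    if (any(enc$overflow)) {
      ov[[chr]] <- data.frame(chrom = chr,
                              window_start = (which(enc$overflow) - 1L) * WINDOW_SIZE,
                              value = means[enc$overflow])
    }
  }
  overflow <- if (length(ov)) do.call(rbind, ov) else {
    data.frame(chrom = character(), window_start = integer(), value = numeric())
  }
  rownames(overflow) <- NULL
  structure(list(window_size = WINDOW_SIZE, chrom_lengths = chrom_lengths,
                 bytes = bytes, overflow = overflow),
            class = "CondensedTrack")
}

#' Simulate scaled profiles directly at bin resolution
#'
#' Skips the per-base/per-window layers and draws each genome's scaled
#' kilobase profile directly: `locus_effect * copies/2` with multiplicative
#' lognormal noise. This is the post-scaling view of a cohort (depth and
#' %GC bias already removed) and is the natural input for studying the
#' diploid-level estimator on large cohorts.
#'
#' @param ref a `SyntheticReference`.
#' @param loci CNV loci from [place_cnv_loci()].
#' @param n_genomes cohort size.
#' @param noise_sd sd of log residual noise per bin (default 0.05, the
#'   few-percent residual variation left after scaling a deep genome).
#' @param seed optional integer seed.
#' @return list with `profiles` (list of scaled-profile data.frames) and
#'   `copies` (genomes x loci integer matrix).
#' @export
simulate_scaled_cohort <- function(ref, loci, n_genomes, noise_sd = 0.05,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  haps <- sample_genotypes(loci, n_genomes)
  copies <- copies_from_haps(haps, loci)
  n_bins <- nrow(ref$bins)
  profiles <- lapply(seq_len(n_genomes), function(i) {
    cp <- bin_copies(ref, loci, copies[i, ])
    data.frame(ref$bins[c("chrom", "start", "end")],
               value = ref$bins$locus_effect * cp / 2 *
                 exp(stats::rnorm(n_bins, 0, noise_sd)))
  })
  list(profiles = profiles, copies = copies)
}

#' Simulate a cohort with families and known truth
#'
#' Founders carry CNV alleles in Hardy-Weinberg proportions; each trio's
#' child inherits one haplotype per parent at every locus. Every genome
#' gets its own depth multiplier and per-bucket %GC bias, then Poisson
#' coverage.
#'
#' @param ref a `SyntheticReference` (e.g. [simulate_reference()]).
#' @param cnv_spec locus spec for [place_cnv_loci()]; `NULL` for no CNVs.
#' @param n_trios number of father/mother/child families.
#' @param n_extra_founders unrelated singletons beyond the parents.
#' @param depth_range range of per-genome mean depths (default 35-45,
#'   the ">40x" regime).
#' @param bias_sd sd of the per-genome %GC bias-curve coefficients
#'   (default 0.1; see [simulate_genome()]).
#' @param gap_bins minimum diploid gap between planted loci, in bins
#'   (passed to [place_cnv_loci()]).
#' @param resolution passed to [simulate_genome()]; `"none"` skips
#'   coverage simulation (truth only).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return list of class `SyntheticCohort`: `ref`, `loci`, `individuals`
#'   (data.frame `id`, `role`), `pedigree` (`family`, `child`, `father`,
#'   `mother`), `copies` (individuals x loci), `tracks` (named list of
#'   `CondensedTrack` or depth data.frames), `depths`, `seed`.
#' @export
simulate_cohort <- function(ref, cnv_spec = NULL, n_trios = 0L,
                            n_extra_founders = 0L, depth_range = c(35, 45),
                            bias_sd = 0.1, gap_bins = 5L,
                            resolution = c("window", "base", "none"),
                            seed = 1L) {
  resolution <- match.arg(resolution)
  set.seed(seed)
  n_parents <- 2L * n_trios
  n_founders <- n_parents + n_extra_founders
  stopifnot(n_founders >= 1)
  loci <- if (is.null(cnv_spec) || !nrow(cnv_spec)) {
    data.frame(locus = integer(), chrom = character(), start = integer(),
               end = integer(), type = character(), af = numeric())
  } else {
    place_cnv_loci(ref, cnv_spec, gap_bins = gap_bins)
  }
  n_loci <- nrow(loci)
  fhaps <- sample_genotypes(loci, n_founders)
  ids <- c(if (n_trios) as.vector(rbind(sprintf("F%03d-father", seq_len(n_trios)),
                                        sprintf("F%03d-mother", seq_len(n_trios)))),
           if (n_extra_founders) sprintf("S%03d", seq_len(n_extra_founders)),
           if (n_trios) sprintf("F%03d-child", seq_len(n_trios)))
  roles <- c(rep(c("father", "mother"), n_trios),
             rep("singleton", n_extra_founders), rep("child", n_trios))
  n_ind <- length(ids)
  haps <- array(0L, c(n_ind, max(n_loci, 1L), 2))
  if (n_loci) haps[seq_len(n_founders), , ] <- fhaps
  pedigree <- NULL
  if (n_trios) {
    child_rows <- n_founders + seq_len(n_trios)
    for (t in seq_len(n_trios)) {
      fa <- 2L * t - 1L; mo <- 2L * t
      if (n_loci) {
        pick_f <- sample(2L, n_loci, replace = TRUE)
        pick_m <- sample(2L, n_loci, replace = TRUE)
        haps[child_rows[t], , 1] <- fhaps[cbind(fa, seq_len(n_loci), pick_f)]
        haps[child_rows[t], , 2] <- fhaps[cbind(mo, seq_len(n_loci), pick_m)]
      }
    }
    pedigree <- data.frame(family = sprintf("F%03d", seq_len(n_trios)),
                           child = ids[child_rows],
                           father = ids[2L * seq_len(n_trios) - 1L],
                           mother = ids[2L * seq_len(n_trios)])
  }
  copies <- if (n_loci) copies_from_haps(haps, loci) else {
    matrix(integer(0), nrow = n_ind, ncol = 0)
  }
  rownames(copies) <- ids
  depths <- stats::runif(n_ind, depth_range[1], depth_range[2])
  tracks <- NULL
  if (resolution != "none") {
    tracks <- lapply(seq_len(n_ind), function(i) {
      simulate_genome(ref, copies = if (n_loci) copies[i, ] else NULL,
                      loci = if (n_loci) loci else NULL,
                      mean_depth = depths[i],
                      gc_bias = stats::rnorm(2, 0, bias_sd),
                      resolution = resolution)
    })
    names(tracks) <- ids
  }
  structure(list(ref = ref, loci = loci,
                 individuals = data.frame(id = ids, role = roles),
                 pedigree = pedigree, copies = copies, depths = depths,
                 tracks = tracks, seed = seed),
            class = "SyntheticCohort")
}

#' True copy-number states of a cohort member
#'
#' @param cohort a `SyntheticCohort`.
#' @param id individual ID.
#' @return state track data.frame `chrom`, `start`, `end`, `state`
#'   (copies capped at 4).
#' @export
true_states <- function(cohort, id) {
  cp <- if (nrow(cohort$loci)) {
    bin_copies(cohort$ref, cohort$loci, cohort$copies[id, ])
  } else rep(2L, nrow(cohort$ref$bins))
  data.frame(cohort$ref$bins[c("chrom", "start", "end")],
             state = pmin(cp, 4L))
}
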