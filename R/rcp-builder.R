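# Reference Coverage Profile (RCP) estimation. An RCP records, per 1-kb
# bin, the scaled coverage level that corresponds to two copies, learned
# from a cohort of scaled profiles. For most bins the cohort median is that
# level. Where a CNV is common, the cohort is a mixture of copy-number
# clusters and the median can sit on the wrong cluster (with a deletion
# allele frequency of 0.8, hemizygotes are the majority and the median is
# the one-copy level). Three constraints recover the diploid level anyway:
# scaled coverage clusters near integer multiples of a haploid level; the
# most abundant cluster should be the expected (diploid) ploidy; and the
# implied genotype counts should not deviate from Hardy-Weinberg
# equilibrium.

#' Parameters of the diploid-level estimator
#'
#' @param dispersion_trigger MAD/median ratio above which integer-multiple
#'   peak modeling replaces the plain median (default 0.15; below it the
#'   cohort is effectively unimodal and the median is used as-is).
#' @param copy_cap maximum modeled copy count (default 6).
#' @param cluster_cv assumed coefficient of variation of a coverage cluster,
#'   as a fraction of the haploid level (default 0.12); the working
#'   cluster sd is never taken below what the residuals themselves show.
#' @param hwe_weight weight of the Hardy-Weinberg chi-squared penalty
#'   against the cluster misfit score (default 2).
#' @param grid_points number of candidate haploid levels scanned (default 200).
#' @param outlier_frac largest fraction of genomes allowed farther than a
#'   quarter of the median from it for the median still to be trusted
#'   (default 0.05): more distant mass than that means a second cluster, and
#'   the median of a near-balanced two-cluster mixture can land between the
#'   clusters while keeping a small MAD.
#' @param modal_prior strength (per genome) of the preference for reading
#'   the modal nonzero cluster as the diploid level (default 0.5):
#'   re-anchoring the modal cluster to copy 2 is accepted unless it worsens
#'   the penalized score by more than `modal_prior` per genome. A common
#'   deletion whose hemizygotes are the modal cluster produces a far larger
#'   Hardy-Weinberg deficit than this and still escapes the prior.
#' @param min_support minimum genomes with data for a bin to be estimated
#'   (default 20); below it the bin is masked.
#' @param max_genomes cohort cap per profile (default 500).
#' @return list of class `RCPEstimatorParams`.
#' @export
rcp_params <- function(dispersion_trigger = 0.15, copy_cap = 6L,
                       cluster_cv = 0.12, hwe_weight = 2, grid_points = 200L,
                       outlier_frac = 0.05, modal_prior = 0.5,
                       min_support = 20L, max_genomes = 500L) {
  p <- list(dispersion_trigger = dispersion_trigger, copy_cap = as.integer(copy_cap),
            cluster_cv = cluster_cv, hwe_weight = hwe_weight,
            grid_points = as.integer(grid_points),
            outlier_frac = outlier_frac, modal_prior = modal_prior,
            min_support = as.integer(min_support),
            max_genomes = as.integer(max_genomes))
  stopifnot(all(unlist(p) > 0), p$copy_cap >= 4L)
  class(p) <- "RCPEstimatorParams"
  p
}

#' Median absolute deviation from the median
#'
#' The robust per-bin dispersion used throughout: `median(|x - median(x)|)`,
#' with no consistency constant.
#'
#' @param values numeric vector (at least one value).
#' @return the MAD.
#' @export
bin_mad <- function(values) {
  if (!length(values)) stop("bin_mad needs at least one value")
  stats::mad(values, constant = 1)
}

# Hardy-Weinberg chi-squared for a vector of assigned copy numbers.
# Haplotype dosages 0 (deletion), 1 (reference), 2 (duplication) at
# frequencies (q, 1-q-p, p) estimated from the assignments; the expected
# copy-number distribution is the convolution of two such haplotypes. For a
# single biallelic deletion or duplication this reduces to p^2/2pq/q^2.
hwe_chisq <- function(copies) {
  n <- length(copies)
  k <- pmin(pmax(copies, 0L), 4L)
  q <- sum(pmax(2L - k, 0L)) / (2 * n)
  p <- sum(pmax(k - 2L, 0L)) / (2 * n)
  r <- max(1 - q - p, 0)
  hap <- c(q, r, p)
  exp_p <- numeric(5)
  for (a in 0:2) for (b in 0:2) {
    exp_p[a + b + 1L] <- exp_p[a + b + 1L] + hap[a + 1L] * hap[b + 1L]
  }
  obs <- tabulate(k + 1L, nbins = 5L)
  expn <- n * exp_p
  sum((obs - expn)^2 / pmax(expn, 0.5))
}

# Penalized fit of one candidate haploid level: assign each genome its
# nearest integer copy and score the squared residuals relative to the
# assumed cluster sd (cluster_cv * h), minus the HWE penalty. The score
# deliberately omits the Gaussian log-density normalization: with it,
# halving h always gains n*log(2) on data with no cluster structure, so
# arbitrarily small haploid levels would win. On normalized residuals,
# structureless data scores the same at every h (the wrapped residual
# variance scales with h^2), while genuine clusters reward the largest h
# that aligns them -- the parsimonious interpretation.
score_haploid <- function(h, values, params) {
  k <- pmin(as.integer(round_half_up(values / h)), params$copy_cap)
  resid <- values - k * h
  misfit <- sum(resid^2) / (2 * (params$cluster_cv * h)^2)
  list(score = -misfit - params$hwe_weight * hwe_chisq(k), k = k,
       msr = mean(resid^2))
}

# TRUE when the cohort looks like a single cluster: small relative MAD and
# no more than outlier_frac of the mass farther than a quarter of the
# median (halfway to where a neighboring copy-number cluster would sit).
median_trusted <- function(values, med, params) {
  med > 0 &&
    bin_mad(values) / med <= params$dispersion_trigger &&
    mean(abs(values - med) > med / 4) <= params$outlier_frac
}

#' Estimate the diploid coverage level of one bin
#'
#' Given one bin's scaled coverages across a cohort: if the bin is tight
#' (MAD/median at or below `dispersion_trigger`) the median is the diploid
#' level. Otherwise a grid of candidate haploid levels is scored by the
#' integer-multiple cluster likelihood with a Hardy-Weinberg penalty on the
#' implied genotype counts; the winning level is refined by least squares
#' and re-anchored so that the modal nonzero cluster is copy 2 unless that
#' worsens the penalized score. Assignments implying a deletion and a
#' duplication segregating at once (both at >5% of genomes) fall back to the
#' median with a warning.
#'
#' @param values scaled coverages of one bin across genomes (`NA` dropped).
#' @param params an `RCPEstimatorParams`.
#' @return list with `level` (diploid scaled coverage, `NA` when masked)
#'   and `method` (`"median"`, `"peak-model"` or `"masked"`).
#' @export
estimate_diploid_level <- function(values, params = rcp_params()) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values for bin")
  if (all(values == 0)) return(list(level = NA_real_, method = "masked"))
  med <- stats::median(values)
  if (median_trusted(values, med, params)) {
    return(list(level = med, method = "median"))
  }
  pos <- values[values > 0]
  anchor <- as.numeric(stats::quantile(pos, 0.9))
  grid <- seq(anchor / params$copy_cap, anchor * 1.05,
              length.out = params$grid_points)
  scores <- vapply(grid, function(h) score_haploid(h, values, params)$score,
                   numeric(1))
  h <- grid[which.max(scores)]
  # refine: least-squares haploid level for the assigned copies, twice
  for (i in 1:2) {
    k <- pmin(as.integer(round_half_up(values / h)), params$copy_cap)
    if (sum(k^2) == 0) break
    h <- sum(values * k) / sum(k^2)
  }
  fit <- score_haploid(h, values, params)
  nz <- fit$k[fit$k > 0L]
  if (length(nz)) {
    modal <- as.integer(names(which.max(table(nz))))
    if (modal != 2L) {
      h2 <- modal * h / 2
      fit2 <- score_haploid(h2, values, params)
      if (fit2$score >= fit$score - params$modal_prior * length(values)) {
        h <- h2
        fit <- fit2
      }
    }
  }
  # no cluster evidence: quantizing ANY values to a grid of spacing h leaves
  # mean squared residuals of about h^2/12, so genuine clusters must sit
  # well inside that. A bin that cannot beat half the quantization noise is
  # a smeared unimodal bin, and its median is the honest level.
  if (fit$msr > h^2 / 24) {
    return(list(level = med, method = "median"))
  }
  frac_del <- mean(fit$k < 2L)
  frac_dup <- mean(fit$k > 2L)
  if (frac_del > params$outlier_frac && frac_dup > params$outlier_frac) {
    warning("bin implies both a deletion and a duplication; using the median")
    return(list(level = med, method = "median"))
  }
  list(level = 2 * h, method = "peak-model")
}

#' Build a Reference Coverage Profile from a cohort
#'
#' Per shared 1-kb bin, estimates the diploid coverage level
#' ([estimate_diploid_level()]) and the MAD across genomes. Bins missing in
#' more than half the cohort, or with fewer than `min_support` genomes, are
#' masked. At most `max_genomes` profiles are used (the first, with a
#' warning).
#'
#' @param profiles list of at least two scaled profiles
#'   ([scale_profile()]) sharing their binning.
#' @param params an `RCPEstimatorParams`.
#' @return data.frame of class `ReferenceCoverageProfile`: `chrom`, `start`,
#'   `end`, `level`, `mad`, `n`, `flag`.
#' @export
build_rcp <- function(profiles, params = rcp_params()) {
  if (length(profiles) < 2) stop("need at least two scaled profiles")
  if (length(profiles) > params$max_genomes) {
    warning("cohort capped at ", params$max_genomes, " genomes")
    profiles <- profiles[seq_len(params$max_genomes)]
  }
  bins <- profiles[[1]][c("chrom", "start", "end")]
  for (p in profiles[-1]) {
    if (!identical(p$chrom, bins$chrom) || !identical(p$start, bins$start)) {
      stop("profiles do not share a common binning")
    }
  }
  V <- matrix(vapply(profiles, `[[`, numeric(nrow(bins)), "value"),
              nrow = nrow(bins))
  n_ok <- rowSums(!is.na(V))
  use <- n_ok >= max(params$min_support, 1L) & n_ok >= ncol(V) / 2
  level <- rep(NA_real_, nrow(bins))
  madv <- rep(NA_real_, nrow(bins))
  flag <- rep("masked", nrow(bins))
  med <- apply(V, 1, stats::median, na.rm = TRUE)
  madv[use] <- apply(V[use, , drop = FALSE], 1, function(x) bin_mad(x[!is.na(x)]))
  frac_far <- rowMeans(abs(V - med) > med / 4, na.rm = TRUE)
  tight <- use & med > 0 & madv / med <= params$dispersion_trigger &
    frac_far <= params$outlier_frac
  level[tight] <- med[tight]
  flag[tight] <- "median"
  for (i in which(use & !tight)) {
    est <- estimate_diploid_level(V[i, ], params)
    level[i] <- est$level
    flag[i] <- est$method
  }
  out <- cbind(bins, level = level, mad = madv, n = n_ok, flag = flag)
  out$flag[use & is.na(out$level)] <- "masked"
  class(out) <- c("ReferenceCoverageProfile", "data.frame")
  out
}

#' Pearson correlation of two RCPs
#'
#' Correlation of the diploid levels over jointly unmasked bins; the global
#' similarity measure used to compare profiles trained on different
#' technologies or pipeline versions.
#'
#' @param a,b `ReferenceCoverageProfile`s sharing their binning.
#' @return Pearson r.
#' @export
correlate_profiles <- function(a, b) {
  key <- match(paste(a$chrom, a$start), paste(b$chrom, b$start))
  ok <- !is.na(key) & !is.na(a$level) & !is.na(b$level[key])
  if (sum(ok) < 2) stop("need at least two jointly unmasked bins")
  stats::cor(a$level[ok], b$level[key][ok])
}

#' Cumulative distributions of per-bin level and dispersion
#'
#' Sorted value / cumulative-genome-fraction pairs for the estimated levels
#' and the per-bin MADs of an RCP (or for any numeric vector): the curves
#' used to compare coverage uniformity within and consistency among
#' genomes. No plotting is performed.
#'
#' @param x a `ReferenceCoverageProfile`, or a numeric vector.
#' @return for an RCP, a list of two data.frames (`level`, `mad`), each with
#'   columns `value` and `cum_fraction`; for a vector, one such data.frame.
#' @export
uniformity_stats <- function(x) {
  cdf <- function(v) {
    v <- sort(v[!is.na(v)])
    data.frame(value = v, cum_fraction = seq_along(v) / length(v))
  }
  if (is.data.frame(x) && all(c("level", "mad") %in% names(x))) {
    list(level = cdf(x$level), mad = cdf(x$mad))
  } else {
    cdf(as.numeric(x))
  }
}

#' Write / read an RCP as bedGraph-like TSV
#'
#' Columns: chrom, start, end, level, mad, n, flag; masked bins carry `NA`
#' level. The reader tolerates files without the optional mad/n/flag
#' columns.
#'
#' @param rcp a `ReferenceCoverageProfile`.
#' @param path file path.
#' @return `path` invisibly; [read_rcp()] returns the profile.
#' @export
write_rcp <- function(rcp, path) {
  data.table::fwrite(as.data.frame(rcp), path, sep = "\t", col.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_rcp
#' @export
read_rcp <- function(path) {
  dt <- as.data.frame(data.table::fread(path, header = FALSE, na.strings = "NA"))
  names(dt) <- c("chrom", "start", "end", "level", "mad", "n", "flag")[seq_len(ncol(dt))]
  if (is.null(dt$mad)) dt$mad <- NA_real_
  if (is.null(dt$n)) dt$n <- NA_integer_
  if (is.null(dt$flag)) dt$flag <- ifelse(is.na(dt$level), "masked", "median")
  class(dt) <- c("ReferenceCoverageProfile", "data.frame")
  dt
}
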