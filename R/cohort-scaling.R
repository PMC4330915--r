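# Depth equalization across genomes. Each genome is fingerprinted by the
# total autosomal coverage it places in each of the 25 %GC buckets; a cohort
# is summarized by the entry-wise geometric mean of those fingerprints; and
# each genome's per-kilobase coverage is rescaled, bucket by bucket, so its
# totals match the cohort target. Working per bucket (rather than with one
# global factor) removes batch- and technology-dependent %GC bias along with
# sequencing depth.

#' Characteristic coverage vector of a genome
#'
#' Totals the decoded window coverages of the autosomes within each %GC
#' bucket. Overflow (sentinel) windows are skipped: they are dominated by
#' high-copy repeats and mitochondria and would destabilize the totals.
#' Windows in bins with masked %GC contribute to no bucket.
#'
#' @param track a `CondensedTrack`.
#' @param map a `GCBucketMap` on the same reference.
#' @param autosomes chromosome names to include; by default every shared
#'   chromosome that is not X/Y/M.
#' @return numeric vector of `map$n_buckets` non-negative totals.
#' @export
characteristic_vector <- function(track, map, autosomes = NULL) {
  shared <- intersect(names(track$bytes), unique(map$bins$chrom))
  if (!length(shared)) stop("track and map share no chromosomes")
  if (is.null(autosomes)) autosomes <- shared[!is_sex_or_mito(shared)]
  wpb <- map$bin_size %/% track$window_size # windows per GC bin
  out <- numeric(map$n_buckets)
  for (chr in intersect(autosomes, shared)) {
    b <- track$bytes[[chr]]
    keep <- b != OVERFLOW_SENTINEL
    vals <- decode_coverage(ifelse(keep, b, 0L))
    bucket_by_bin <- map$bins$bucket[map$bins$chrom == chr]
    win_bucket <- bucket_by_bin[(seq_along(b) - 1L) %/% wpb + 1L]
    ok <- keep & !is.na(win_bucket)
    if (!any(ok)) next
    agg <- rowsum(vals[ok], win_bucket[ok])
    out[as.integer(rownames(agg)) + 1L] <- out[as.integer(rownames(agg)) + 1L] + agg[, 1L]
  }
  out
}

#' Cohort target coverage vector
#'
#' Entry-wise geometric mean of characteristic coverage vectors, computed in
#' log space. A zero entry (a bucket empty in one genome) would annihilate
#' the geometric mean, so zero entries are dropped from that entry's mean
#' with a warning; an entry zero in every genome stays zero.
#'
#' @param vectors a list of characteristic vectors, or a matrix with one row
#'   per genome.
#' @return numeric target vector of the same length.
#' @export
target_vector <- function(vectors) {
  if (is.list(vectors)) {
    if (!length(vectors)) stop("need at least one characteristic vector")
    vectors <- do.call(rbind, vectors)
  }
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = 1)
  if (nrow(vectors) == 0) stop("need at least one characteristic vector")
  if (any(vectors < 0)) stop("coverage totals must be non-negative")
  if (any(vectors == 0)) {
    warning("zero entries excluded from the geometric mean of their bucket")
  }
  apply(vectors, 2, function(col) {
    col <- col[col > 0]
    if (!length(col)) return(0)
    exp(mean(log(col)))
  })
}

#' Aggregate a condensed track to per-kilobase mean coverage
#'
#' Bridges the 20-bp storage resolution to the 1-kb analysis resolution:
#' each bin's value is the mean of its 50 decoded window values (overflow
#' windows contribute their full-resolution value; a terminal partial bin
#' averages the windows that exist).
#'
#' @param track a `CondensedTrack`.
#' @param bin_size analysis bin width in bases (default 1000).
#' @return data.frame `chrom`, `start` (0-based), `end`, `value`.
#' @export
aggregate_to_kb <- function(track, bin_size = GC_BIN_SIZE) {
  wpb <- bin_size %/% track$window_size
  res <- list()
  for (chr in names(track$bytes)) {
    vals <- decode_chrom(track, chr)
    bin <- (seq_along(vals) - 1L) %/% wpb
    means <- rowsum(vals, bin)[, 1L] / tabulate(bin + 1L)
    n_bins <- length(means)
    start <- (seq_len(n_bins) - 1L) * bin_size
    res[[chr]] <- data.frame(
      chrom = chr, start = start,
      end = pmin(start + bin_size, track$chrom_lengths[[chr]]),
      value = as.vector(means))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Scale a binned coverage profile to the cohort target
#'
#' Equalizes a genome's per-bucket coverage totals to the cohort's:
#' `scaled(bin) = raw(bin) * target[bucket] / own[bucket]`. After scaling,
#' a typical diploid bin sits at the cohort-typical coverage level
#' regardless of the genome's own sequencing depth or %GC bias. Bins with
#' masked %GC are masked (`NA`).
#'
#' @param binned per-kilobase coverage from [aggregate_to_kb()].
#' @param map a `GCBucketMap` sharing the binning.
#' @param own the genome's own characteristic vector.
#' @param target the cohort target vector.
#' @param literal_divide if `TRUE`, divide raw coverage by the target entry
#'   alone (no own-vector term). This leaves the genome's own depth in the
#'   signal and is provided only for comparison; the default removes it.
#' @return data.frame `chrom`, `start`, `end`, `value` (the `ScaledProfile`).
#' @export
scale_profile <- function(binned, map, own, target, literal_divide = FALSE) {
  key <- match(paste(binned$chrom, binned$start),
               paste(map$bins$chrom, map$bins$start))
  if (all(is.na(key))) stop("profile and map share no bins")
  bucket <- map$bins$bucket[key]
  idx <- bucket + 1L
  bad <- !is.na(idx) & own[pmax(idx, 1L)] == 0 & binned$value > 0
  if (!literal_divide && any(bad, na.rm = TRUE)) {
    stop("nonzero coverage in a bucket with zero own-vector total")
  }
  factor <- if (literal_divide) 1 / target[idx] else target[idx] / own[idx]
  out <- binned
  out$value <- binned$value * factor
  out$value[is.na(bucket)] <- NA_real_
  out
}

#' Write / read a 25-entry coverage vector as TSV
#'
#' Two tab-separated columns: bucket index (0-based) and total.
#'
#' @param vec numeric coverage vector.
#' @param path file path.
#' @return `path` invisibly; [read_coverage_vector()] returns the vector.
#' @export
write_coverage_vector <- function(vec, path) {
  data.table::fwrite(data.frame(bucket = seq_along(vec) - 1L, total = vec),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage_vector
#' @export
read_coverage_vector <- function(path) {
  dt <- data.table::fread(path, header = FALSE, col.names = c("bucket", "total"))
  dt$total[order(dt$bucket)]
}
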