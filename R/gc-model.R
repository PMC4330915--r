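# %GC stratification: the GC content of a 1-kb window biases its depth of
# coverage in a technology- and batch-dependent way. Binning the genome into
# 25 rank-based %GC buckets of (approximately) equal genomic span gives
# strata large enough to estimate per-bucket scaling factors reliably even
# at extreme %GC.

GC_BIN_SIZE <- 1000L
GC_N_BUCKETS <- 25L

#' GC fraction of nucleotide windows
#'
#' (G+C)/(A+C+G+T), case-insensitive, ignoring N. Windows with more than
#' half their bases N (assembly gaps) are reported as missing.
#'
#' @param sequences character vector of nucleotide windows, or a
#'   `Biostrings::DNAStringSet`.
#' @return numeric vector of GC fractions in `[0, 1]`, `NA` for gap windows.
#' @examples
#' gc_fraction(strrep("ACGT", 250))
#' @export
gc_fraction <- function(sequences) {
  if (!methods::is(sequences, "DNAStringSet")) {
    bad <- grepl("[^ACGTNacgtn]", sequences)
    if (any(bad)) stop("non-nucleotide characters in sequence")
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  freq <- Biostrings::letterFrequency(sequences, c("A", "C", "G", "T", "N"))
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- rowSums(freq[, c("C", "G"), drop = FALSE]) / acgt
  width <- Biostrings::width(sequences)
  gc[freq[, "N"] > width / 2] <- NA_real_
  unname(gc)
}

#' Rank-based %GC bucket cutoffs
#'
#' Empirical k/n_buckets quantiles (type-1, i.e. the ceil(k*n/n_buckets)-th
#' smallest value) of the non-missing per-bin GC values, for
#' k = 1..n_buckets-1. Rank-based cutoffs make every bucket hold an
#' approximately equal share of the genome, avoiding sparse strata at
#' extreme %GC.
#'
#' @param gc_values numeric vector of per-bin GC fractions (`NA` allowed).
#' @param n_buckets number of buckets (default 25).
#' @return ascending numeric vector of `n_buckets - 1` cutoffs.
#' @export
compute_cutoffs <- function(gc_values, n_buckets = GC_N_BUCKETS) {
  x <- gc_values[!is.na(gc_values)]
  n <- length(x)
  if (n < n_buckets) stop("need at least n_buckets non-missing values")
  # cutoff k = the ceil(k*n/n_buckets)-th smallest value (type-1 empirical
  # quantile), in exact integer arithmetic
  idx <- (seq_len(n_buckets - 1) * n + n_buckets - 1L) %/% n_buckets
  sort(x)[idx]
}

#' Assign GC values to buckets
#'
#' Bucket k is the half-open quantile interval `(cutoff[k], cutoff[k+1]]`:
#' a value equal to a cutoff belongs to the lower bucket; values at or below
#' the first cutoff get bucket 0; values above the last get the top bucket.
#'
#' @param gc numeric vector of GC fractions; `NA` stays `NA` (masked).
#' @param cutoffs ascending cutoffs from [compute_cutoffs()].
#' @return integer bucket indices in `0:(length(cutoffs))`.
#' @export
assign_bucket <- function(gc, cutoffs) {
  out <- findInterval(gc, cutoffs, left.open = TRUE)
  out[is.na(gc)] <- NA_integer_
  as.integer(out)
}

#' Build a %GC bucket map from a reference FASTA
#'
#' Splits each sequence into fixed-size bins (default 1 kb), computes the GC
#' fraction of each, derives rank-based cutoffs over the requested training
#' set and assigns every bin a bucket. Bins with more than half N are masked
#' and excluded from cutoff training.
#'
#' @param fasta path to a reference FASTA, or a named `DNAStringSet`.
#' @param bin_size bin width in bases.
#' @param n_buckets number of %GC strata.
#' @param autosomes_only logical; train cutoffs on autosomal bins only
#'   (chromosomes other than X/Y/M/MT). All bins are still assigned.
#' @param cutoffs optional preset cutoffs (e.g. a published set); when given
#'   no cutoffs are trained.
#' @return a `GCBucketMap`: list with `bin_size`, `n_buckets`, `cutoffs` and
#'   `bins` (data.frame `chrom`, `start` 0-based, `end`, `gc`, `bucket`).
#' @export
gc_bucket_map <- function(fasta, bin_size = GC_BIN_SIZE, n_buckets = GC_N_BUCKETS,
                          autosomes_only = FALSE, cutoffs = NULL) {
  seqs <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta) else fasta
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bins <- list()
  for (chr in names(seqs)) {
    len <- length(seqs[[chr]])
    starts <- seq.int(1L, len, by = bin_size)
    ends <- pmin(starts + bin_size - 1L, len)
    v <- Biostrings::Views(seqs[[chr]], start = starts, end = ends)
    gc <- gc_fraction(methods::as(v, "DNAStringSet"))
    bins[[chr]] <- data.frame(chrom = chr, start = starts - 1L, end = ends,
                              gc = gc)
  }
  bins <- do.call(rbind, bins)
  rownames(bins) <- NULL
  if (is.null(cutoffs)) {
    train <- bins$gc
    if (autosomes_only) train <- bins$gc[!is_sex_or_mito(bins$chrom)]
    cutoffs <- compute_cutoffs(train, n_buckets)
  } else {
    if (length(cutoffs) != n_buckets - 1L || is.unsorted(cutoffs)) {
      stop("preset cutoffs must be ", n_buckets - 1L, " ascending values")
    }
  }
  bins$bucket <- assign_bucket(bins$gc, cutoffs)
  structure(list(bin_size = bin_size, n_buckets = n_buckets,
                 cutoffs = cutoffs, bins = bins),
            class = "GCBucketMap")
}

#' @export
print.GCBucketMap <- function(x, ...) {
  cat("GCBucketMap:", nrow(x$bins), "bins of", x$bin_size, "bp in",
      x$n_buckets, "buckets;", sum(is.na(x$bins$gc)), "masked\n")
  cat("cutoffs (%):", paste(sprintf("%.1f", 100 * x$cutoffs), collapse = ", "), "\n")
  invisible(x)
}

is_sex_or_mito <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "Y", "M", "MT")
}

#' Published GRCh37 %GC cutoffs
#'
#' The 24 GC-percentage cutoffs reported for GRCh37 at 1-kb resolution,
#' usable as a preset for [gc_bucket_map()]. One adjacent pair in the
#' published list is transposed (non-monotone as printed); the preset
#' restores ascending order. Cutoffs should normally be recomputed from the
#' reference actually in use.
#'
#' @return ascending numeric vector of 24 GC fractions.
#' @export
grch37_gc_cutoffs <- function() {
  sort(c(30.1, 31.7, 32.9, 33.9, 34.8, 35.6, 36.3, 37.0, 37.7, 38.3, 39.8,
         39.6, 40.3, 41.0, 41.8, 42.6, 43.4, 44.4, 45.4, 46.5, 47.9, 49.5,
         51.9, 56.0)) / 100
}

#' Write / read a bucket map as BED-like TSV
#'
#' Columns: chrom, start, end (0-based half-open), gc, bucket; a `#cutoffs`
#' header line preserves the trained cutoffs.
#'
#' @param map a `GCBucketMap`.
#' @param path file path.
#' @return `path` invisibly; [read_gc_map()] returns a `GCBucketMap`.
#' @export
write_gc_map <- function(map, path) {
  writeLines(paste0("#cutoffs\t", paste(format(map$cutoffs, digits = 17), collapse = ",")), path)
  data.table::fwrite(map$bins, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gc_map
#' @export
read_gc_map <- function(path) {
  hdr <- readLines(path, n = 1)
  cutoffs <- as.numeric(strsplit(sub("^#cutoffs\t", "", hdr), ",")[[1]])
  bins <- as.data.frame(data.table::fread(
    path, skip = 1, header = FALSE,
    col.names = c("chrom", "start", "end", "gc", "bucket")))
  bs <- if (nrow(bins)) max(bins$end - bins$start) else GC_BIN_SIZE
  structure(list(bin_size = bs, n_buckets = length(cutoffs) + 1L,
                 cutoffs = cutoffs, bins = bins),
            class = "GCBucketMap")
}
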