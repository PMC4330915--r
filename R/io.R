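# Plain-text interchange: bedGraph for binned profiles, BED-like TSV for
# segments and annotations, TSV pedigrees.

#' Write / read a binned profile as bedGraph
#'
#' One line per 1-kb bin: chrom, start, end (0-based half-open), value.
#' Masked bins are written with value `NA` and read back masked.
#'
#' @param profile data.frame `chrom`, `start`, `end`, `value`.
#' @param path file path.
#' @return `path` invisibly; [read_bedgraph()] returns the data.frame.
#' @export
write_bedgraph <- function(profile, path) {
  data.table::fwrite(profile[c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  as.data.frame(data.table::fread(path, header = FALSE, na.strings = "NA",
                                  col.names = c("chrom", "start", "end", "value")))
}

#' Write / read copy-number segments as BED5+
#'
#' Columns: chrom, start, end, state, n_bins, median_ncp and, when present,
#' genotype_freq and allele_freq.
#'
#' @param segments segment data.frame.
#' @param path file path.
#' @return `path` invisibly; [read_segments()] returns the data.frame.
#' @export
write_segments <- function(segments, path) {
  data.table::fwrite(segments, path, sep = "\t", col.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  dt <- as.data.frame(data.table::fread(path, header = FALSE, na.strings = "NA"))
  names(dt) <- c("chrom", "start", "end", "state", "n_bins", "median_ncp",
                 "genotype_freq", "allele_freq")[seq_len(ncol(dt))]
  dt
}

#' Read a BED interval file
#'
#' First three columns chrom/start/end (0-based half-open); an optional
#' fourth column is kept as `name` (e.g. a gene symbol).
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end` and optionally `name`.
#' @export
read_bed <- function(path) {
  dt <- as.data.frame(data.table::fread(path, header = FALSE))
  names(dt) <- c("chrom", "start", "end", "name")[seq_len(min(ncol(dt), 4L))]
  dt[seq_len(min(ncol(dt), 4L))]
}

#' Read a pedigree file
#'
#' Tab-separated `family child father mother` (header optional).
#'
#' @param path file path.
#' @return data.frame `family`, `child`, `father`, `mother`.
#' @export
read_pedigree <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- identical(tolower(first[1]), "family")
  dt <- as.data.frame(data.table::fread(path, header = has_header))
  names(dt) <- c("family", "child", "father", "mother")
  dt
}
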