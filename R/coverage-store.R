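#' @importFrom stats median cor mad quantile rnorm rpois rbinom runif dnorm sd setNames
#' @importFrom utils head tail
#' @import data.table
NULL

# Encoding constants for the condensed one-byte-per-window representation.
# Values <= IDENTITY_LIMIT are stored verbatim; values up to OVERFLOW_LIMIT
# are square-root compressed; anything >= OVERFLOW_LIMIT goes to the sidecar.
IDENTITY_LIMIT <- 200
OVERFLOW_LIMIT <- 2700
OVERFLOW_SENTINEL <- 255L
WINDOW_SIZE <- 20L

round_half_up <- function(x) floor(x + 0.5)

#' Encode mean window coverage into one byte
#'
#' Coverage up to 200-fold is stored unmodified; coverage between 200 and
#' 2700 is square-root compressed as `int(sqrt(coverage - 200) + 200)`;
#' coverage of 2700-fold or more cannot be represented in one byte and is
#' flagged for full-resolution storage in the overflow sidecar (the byte
#' holds the sentinel 255). Bytes 251-254 are reserved.
#'
#' @param coverage numeric vector of non-negative mean window coverages.
#' @return list with integer vector `byte` (0-255) and logical vector
#'   `overflow` marking values that must be kept in the sidecar.
#' @examples
#' encode_coverage(c(0, 150, 2699, 3000))
#' @export
encode_coverage <- function(coverage) {
  if (any(is.na(coverage)) || any(coverage < 0)) {
    stop("coverage must be non-negative and non-missing")
  }
  byte <- integer(length(coverage))
  overflow <- coverage >= OVERFLOW_LIMIT
  lo <- coverage <= IDENTITY_LIMIT
  mid <- !lo & !overflow
  byte[lo] <- as.integer(round_half_up(coverage[lo]))
  byte[mid] <- as.integer(floor(sqrt(coverage[mid] - IDENTITY_LIMIT)) + IDENTITY_LIMIT)
  byte[overflow] <- OVERFLOW_SENTINEL
  list(byte = byte, overflow = overflow)
}

#' Decode one-byte coverage values
#'
#' Inverts [encode_coverage()]. Bytes in the identity regime decode to
#' themselves; square-root-compressed bytes decode to the midpoint of their
#' integer preimage interval (minimizing worst-case absolute error); the
#' sentinel byte requires the full-resolution overflow value.
#'
#' @param byte integer vector in 0-255.
#' @param overflow_value numeric vector; full-resolution values for sentinel
#'   bytes (ignored elsewhere). May be `NULL` when no byte is the sentinel.
#' @return numeric vector of approximate mean coverages.
#' @export
decode_coverage <- function(byte, overflow_value = NULL) {
  if (any(byte < 0 | byte > 255)) stop("byte values must be in [0, 255]")
  if (any(byte > 250 & byte < 255)) stop("bytes 251-254 are reserved")
  out <- as.numeric(byte)
  mid <- byte > IDENTITY_LIMIT & byte <= 250
  if (any(mid)) {
    b <- byte[mid]
    lo <- (b - 200)^2 + 200
    hi <- (b - 199)^2 + 199
    out[mid] <- (lo + hi) / 2
  }
  sent <- byte == OVERFLOW_SENTINEL
  if (any(sent)) {
    if (is.null(overflow_value) || any(is.na(overflow_value[sent]))) {
      stop("sentinel byte without an overflow record")
    }
    out[sent] <- overflow_value[sent]
  }
  out
}

#' Condense per-base depth into a one-byte-per-20-bp track
#'
#' Averages depth over non-overlapping 20-bp windows (absent positions count
#' as depth 0; a terminal partial window averages over the bases that exist),
#' rounds the mean half-up to an integer and encodes it in one byte. Windows
#' whose mean reaches 2700-fold are stored at full (unrounded) resolution in
#' the overflow sidecar and marked with the sentinel byte.
#'
#' @param depth a data.frame with columns `chrom`, `pos` (1-based), `depth`,
#'   sorted by position within chromosome, or a path to a tab-separated file
#'   of the same three columns (see [read_depth()]).
#' @param chrom_lengths named integer vector of chromosome lengths in bases.
#' @return a `CondensedTrack`: list with `window_size`, `chrom_lengths`,
#'   `bytes` (named list of integer vectors, one byte per window) and
#'   `overflow` (data.frame `chrom`, `window_start` 0-based, `value`).
#' @examples
#' d <- data.frame(chrom = "chr1", pos = 1:40, depth = 7)
#' condense(d, c(chr1 = 40L))$bytes$chr1
#' @export
condense <- function(depth, chrom_lengths) {
  if (is.character(depth)) depth <- read_depth(depth)
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depth)))
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector")
  }
  dt <- data.table::as.data.table(depth)
  bad <- setdiff(unique(dt$chrom), names(chrom_lengths))
  if (length(bad)) stop("depth refers to unknown chromosome(s): ", paste(bad, collapse = ", "))
  if (dt[, any(pos < 1L | pos > chrom_lengths[chrom]), ]) {
    stop("position beyond chromosome length")
  }
  if (dt[, any(diff(pos) <= 0), by = chrom][, any(V1)]) {
    stop("per-base depth must be sorted by position within chromosome")
  }

  bytes <- vector("list", length(chrom_lengths))
  names(bytes) <- names(chrom_lengths)
  ov <- list()
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    n_win <- as.integer(ceiling(len / WINDOW_SIZE))
    sums <- numeric(n_win)
    sub <- dt[chrom == chr]
    if (nrow(sub)) {
      win <- (sub$pos - 1L) %/% WINDOW_SIZE + 1L
      agg <- rowsum(as.numeric(sub$depth), win)
      sums[as.integer(rownames(agg))] <- agg[, 1L]
    }
    width <- rep(WINDOW_SIZE, n_win)
    width[n_win] <- len - (n_win - 1L) * WINDOW_SIZE
    means <- sums / width
    enc <- encode_coverage(round_half_up(means))
    bytes[[chr]] <- enc$byte
    if (any(enc$overflow)) {
      ov[[chr]] <- data.frame(
        chrom = chr,
        window_start = (which(enc$overflow) - 1L) * WINDOW_SIZE,
        value = means[enc$overflow]
      )
    }
  }
  overflow <- if (length(ov)) do.call(rbind, ov) else {
    data.frame(chrom = character(), window_start = integer(), value = numeric())
  }
  rownames(overflow) <- NULL
  structure(
    list(window_size = WINDOW_SIZE, chrom_lengths = chrom_lengths,
         bytes = bytes, overflow = overflow),
    class = "CondensedTrack"
  )
}

#' @export
print.CondensedTrack <- function(x, ...) {
  cat("CondensedTrack:", length(x$bytes), "chromosome(s),",
      sum(lengths(x$bytes)), "windows of", x$window_size, "bp,",
      nrow(x$overflow), "overflow site(s)\n")
  invisible(x)
}

# Decoded per-window values for one chromosome, with overflow substitution.
decode_chrom <- function(track, chrom) {
  b <- track$bytes[[chrom]]
  if (is.null(b)) stop("unknown chromosome: ", chrom)
  ovv <- rep(NA_real_, length(b))
  ov <- track$overflow[track$overflow$chrom == chrom, , drop = FALSE]
  if (nrow(ov)) ovv[ov$window_start %/% track$window_size + 1L] <- ov$value
  decode_coverage(b, ovv)
}

#' Query decoded coverage over a region
#'
#' Returns one decoded value per 20-bp window overlapping the 0-based
#' half-open interval `[start, end)`. Sentinel windows are substituted with
#' their full-resolution overflow value. Access is by computed window
#' offsets, never by scanning the chromosome.
#'
#' @param track a `CondensedTrack`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @return numeric vector of decoded per-window coverages (empty when the
#'   interval is empty).
#' @export
query_track <- function(track, chrom, start, end) {
  b <- track$bytes[[chrom]]
  if (is.null(b)) stop("unknown chromosome: ", chrom)
  len <- track$chrom_lengths[[chrom]]
  if (start < 0 || end > len) stop("region out of chromosome bounds")
  if (end <= start) return(numeric(0))
  w0 <- start %/% track$window_size + 1L
  w1 <- (end - 1L) %/% track$window_size + 1L
  idx <- w0:w1
  byte <- b[idx]
  ovv <- rep(NA_real_, length(idx))
  if (any(byte == OVERFLOW_SENTINEL)) {
    ov <- track$overflow[track$overflow$chrom == chrom, , drop = FALSE]
    m <- match((idx - 1L) * track$window_size, ov$window_start)
    ovv <- ov$value[m]
  }
  decode_coverage(byte, ovv)
}

#' Lag-wise autocorrelation of a coverage series
#'
#' Pearson correlation between the series and its lag-k shift, for
#' k = 1..max_lag (lag 0 is 1 by definition and not returned). Used to choose
#' and justify the 20-bp compression window: read length sets the distance
#' over which depth is strongly autocorrelated.
#'
#' @param values equally spaced numeric series (e.g. per-base or per-window
#'   depth along a region).
#' @param max_lag largest lag, strictly less than `length(values)`.
#' @return numeric vector of length `max_lag`; `NA` where the correlation is
#'   undefined (zero variance).
#' @export
coverage_autocorr <- function(values, max_lag) {
  n <- length(values)
  if (max_lag >= n) stop("series must be longer than max_lag")
  vapply(seq_len(max_lag), function(k) {
    a <- values[seq_len(n - k)]
    b <- values[seq_len(n - k) + k]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
}

#' Read per-base depth text
#'
#' Reads the three-column output of `samtools depth` and similar tools:
#' `chrom<TAB>pos<TAB>depth` with a 1-based position. For generic
#' tab-separated coverage reports with named columns (e.g. a
#' GC-corrected-coverage column), name the columns to use.
#'
#' @param path file path.
#' @param chrom_col,pos_col,depth_col column names when the file has a
#'   header; by default the file is read headerless as chrom/pos/depth.
#' @return data.frame with columns `chrom`, `pos`, `depth`.
#' @export
read_depth <- function(path, chrom_col = NULL, pos_col = NULL, depth_col = NULL) {
  if (is.null(depth_col)) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "pos", "depth"))
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    cols <- c(chrom_col %||% "chrom", pos_col %||% "pos", depth_col)
    if (!all(cols %in% names(dt))) {
      stop("columns not found: ", paste(setdiff(cols, names(dt)), collapse = ", "))
    }
    dt <- dt[, cols, with = FALSE]
    data.table::setnames(dt, c("chrom", "pos", "depth"))
  }
  as.data.frame(dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a condensed track to disk
#'
#' Binary layout: magic "RCPC", format version, window size, chromosome
#' table (name, length, byte offset), then the concatenated per-chromosome
#' byte arrays; one byte per 20-bp window, so the payload is genome length /
#' 20 bytes. The overflow sidecar is written beside it as tab-separated
#' `chrom<TAB>window_start<TAB>value` (0-based window start, full-resolution
#' value).
#'
#' @param track a `CondensedTrack`.
#' @param path output path for the binary track; the sidecar goes to
#'   `paste0(path, ".overflow.tsv")`.
#' @return `path`, invisibly.
#' @export
write_condensed <- function(track, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RCPC", con, 4, eos = NULL)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(as.integer(track$window_size), con, size = 4, endian = "little")
  writeBin(length(track$bytes), con, size = 4, endian = "little")
  for (chr in names(track$bytes)) {
    nm <- charToRaw(chr)
    writeBin(length(nm), con, size = 4, endian = "little")
    writeBin(nm, con)
    writeBin(as.numeric(track$chrom_lengths[[chr]]), con, size = 8, endian = "little")
  }
  for (chr in names(track$bytes)) {
    writeBin(as.raw(track$bytes[[chr]]), con)
  }
  ovp <- paste0(path, ".overflow.tsv")
  data.table::fwrite(track$overflow, ovp, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a condensed track, optionally only one region
#'
#' With `chrom` given, seeks directly to the requested windows using the
#' offsets in the header instead of reading the whole payload.
#'
#' @param path path written by [write_condensed()].
#' @param chrom,start,end optional region (0-based half-open); when given,
#'   returns the decoded per-window values for that region only.
#' @return a `CondensedTrack`, or a numeric vector when a region is given.
#' @export
read_condensed <- function(path, chrom = NULL, start = NULL, end = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "RCPC")) stop("not a condensed coverage track: ", path)
  version <- readBin(con, integer(), size = 4, endian = "little")
  ws <- readBin(con, integer(), size = 4, endian = "little")
  n_chr <- readBin(con, integer(), size = 4, endian = "little")
  names_ <- character(n_chr); lens <- numeric(n_chr)
  for (i in seq_len(n_chr)) {
    nl <- readBin(con, integer(), size = 4, endian = "little")
    names_[i] <- rawToChar(readBin(con, raw(), nl))
    lens[i] <- readBin(con, numeric(), size = 8, endian = "little")
  }
  n_win <- ceiling(lens / ws)
  chrom_lengths <- stats::setNames(as.integer(lens), names_)
  payload_at <- seek(con)
  ovp <- paste0(path, ".overflow.tsv")
  overflow <- if (file.exists(ovp) && file.size(ovp) > 0) {
    as.data.frame(data.table::fread(
      ovp, header = FALSE, col.names = c("chrom", "window_start", "value")))
  } else {
    data.frame(chrom = character(), window_start = integer(), value = numeric())
  }
  if (!is.null(chrom)) {
    i <- match(chrom, names_)
    if (is.na(i)) stop("unknown chromosome: ", chrom)
    if (end <= start) return(numeric(0))
    w0 <- start %/% ws; w1 <- (end - 1L) %/% ws
    seek(con, payload_at + sum(head(n_win, i - 1L)) + w0)
    byte <- as.integer(readBin(con, raw(), w1 - w0 + 1L))
    ovv <- rep(NA_real_, length(byte))
    ov <- overflow[overflow$chrom == chrom, , drop = FALSE]
    if (nrow(ov)) ovv <- ov$value[match((w0:w1) * ws, ov$window_start)]
    return(decode_coverage(byte, ovv))
  }
  bytes <- vector("list", n_chr)
  names(bytes) <- names_
  for (i in seq_len(n_chr)) bytes[[i]] <- as.integer(readBin(con, raw(), n_win[i]))
  structure(
    list(window_size = ws, chrom_lengths = chrom_lengths,
         bytes = bytes, overflow = overflow),
    class = "CondensedTrack"
  )
}
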