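# Mendelian evaluation of copy-number state tracks in father-mother-child
# trios. Each parent transmits one haplotype; under a parsimonious
# haplotype model a parent in state s carries the most balanced split of s
# copies across its two haplotypes, so the transmissible per-haplotype
# copies are: state 0 -> {0}, 1 -> {0,1}, 2 -> {1}, 3 -> {1,2},
# 4 ("four or more") -> {2,3}. The child's expected states are all pairwise
# sums, capped at state 4.

TRANSMISSIBLE <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L,
                      `3` = c(1L, 2L), `4` = c(2L, 3L))

#' Expected child states given the parents' states
#'
#' All copy-number states a child can inherit from parents in the given
#' states under the parsimonious haplotype model, e.g. parents in states 1
#' and 2 yield an expected child set of \{1, 2\}.
#'
#' @param father_state,mother_state integer states 0-4.
#' @return sorted integer vector of expected child states.
#' @export
expected_child_states <- function(father_state, mother_state) {
  stopifnot(father_state %in% 0:4, mother_state %in% 0:4)
  f <- TRANSMISSIBLE[[father_state + 1L]]
  m <- TRANSMISSIBLE[[mother_state + 1L]]
  sort(unique(pmin(as.vector(outer(f, m, `+`)), 4L)))
}

# 5x5x5 lookup: concordant[f+1, m+1, c+1]
concordance_table <- function() {
  arr <- array(FALSE, c(5, 5, 5))
  for (f in 0:4) for (m in 0:4) {
    arr[f + 1L, m + 1L, expected_child_states(f, m) + 1L] <- TRUE
  }
  arr
}

#' Trio concordance of copy-number state tracks
#'
#' Per analyzed bin, the child is concordant when its state is in
#' [expected_child_states()] of the parents' states. The loose metric is
#' the concordant fraction of all analyzed bins; since most of the genome
#' is diploid in everyone, a strict metric restricts the denominator to
#' bins where not all three members are state 2. Bins on the excluded
#' chromosomes (X, Y, M by default), bins overlapping reference gaps, and
#' bins in the recurrent-discordance mask are not analyzed; a bin with any
#' missing state is never counted discordant.
#'
#' @param child,father,mother state tracks (data.frames `chrom`, `start`,
#'   `end`, `state`) sharing their binning.
#' @param mask optional `DiscordanceMask` from
#'   [recurrent_discordance_mask()], or a logical per-bin vector.
#' @param gaps optional data.frame `chrom`, `start`, `end` of reference
#'   gaps (0-based half-open); overlapping bins are excluded.
#' @param excluded_chroms chromosome names (with or without a "chr" prefix)
#'   excluded from analysis.
#' @return list of class `TrioResult`: `loose`, `strict` (fractions, `NA`
#'   when the denominator is empty), `analyzed_span`, `discordant_span`
#'   (bases), and `discordant` (logical per analyzed-or-not bin, `NA`
#'   outside the analyzed set).
#' @export
trio_concordance <- function(child, father, mother, mask = NULL, gaps = NULL,
                             excluded_chroms = c("X", "Y", "M", "MT")) {
  bins <- child[c("chrom", "start", "end")]
  for (p in list(father, mother)) {
    if (!identical(p$chrom, bins$chrom) || !identical(p$start, bins$start)) {
      stop("trio tracks do not share a common binning")
    }
  }
  analyzed <- !(sub("^chr", "", bins$chrom) %in%
                  sub("^chr", "", excluded_chroms))
  if (!is.null(gaps)) {
    for (i in seq_len(nrow(gaps))) {
      analyzed <- analyzed & !(bins$chrom == gaps$chrom[i] &
                                 bins$start < gaps$end[i] &
                                 bins$end > gaps$start[i])
    }
  }
  if (!is.null(mask)) {
    m <- if (is.list(mask) && !is.null(mask$masked)) mask$masked else mask
    analyzed <- analyzed & !m
  }
  if (!any(analyzed)) {
    return(structure(list(loose = NA_real_, strict = NA_real_,
                          analyzed_span = 0, discordant_span = 0,
                          discordant = rep(NA, nrow(bins))),
                     class = "TrioResult"))
  }
  f <- father$state; m <- mother$state; c_ <- child$state
  complete <- !is.na(f) & !is.na(m) & !is.na(c_)
  conc <- rep(TRUE, nrow(bins))          # missing state: never discordant
  tab <- concordance_table()
  i <- complete
  conc[i] <- tab[cbind(f[i] + 1L, m[i] + 1L, c_[i] + 1L)]
  widths <- bins$end - bins$start
  a <- analyzed
  loose <- sum(widths[a & conc]) / sum(widths[a])
  strict_set <- a & complete & !(f == 2L & m == 2L & c_ == 2L)
  strict <- if (any(strict_set)) {
    sum(widths[strict_set & conc]) / sum(widths[strict_set])
  } else NA_real_
  discordant <- rep(NA, nrow(bins))
  discordant[a] <- !conc[a]
  structure(list(loose = loose, strict = strict,
                 analyzed_span = sum(widths[a]),
                 discordant_span = sum(widths[a & !conc]),
                 discordant = discordant),
            class = "TrioResult")
}

#' @export
print.TrioResult <- function(x, ...) {
  cat(sprintf("TrioResult: loose %.4f, strict %s; %d of %d kb discordant\n",
              x$loose,
              ifelse(is.na(x$strict), "NA", sprintf("%.4f", x$strict)),
              x$discordant_span %/% 1000, x$analyzed_span %/% 1000))
  invisible(x)
}

#' Recurrent-discordance mask
#'
#' Bins discordant in at least `threshold` trios are recurring false
#' positives (reference-sequence artifacts such as assembly compressions)
#' and are excluded from concordance computations. Adjacent masked bins are
#' merged into segments.
#'
#' @param discordant_bins list of per-trio logical vectors (as returned in
#'   `TrioResult$discordant`; `NA` counts as not discordant), all aligned
#'   to `bins`.
#' @param bins the shared binning (data.frame `chrom`, `start`, `end`).
#' @param threshold minimum number of discordant trios (default 100).
#' @return list of class `DiscordanceMask`: `masked` (logical per bin),
#'   `counts` (integer per bin), `segments` (merged masked spans).
#' @export
recurrent_discordance_mask <- function(discordant_bins, bins, threshold = 100L) {
  stopifnot(length(discordant_bins) >= 1)
  counts <- Reduce(`+`, lapply(discordant_bins, function(d) {
    as.integer(!is.na(d) & d)
  }))
  masked <- counts >= threshold
  segs <- list()
  for (chr in unique(bins$chrom)) {
    idx <- which(bins$chrom == chr)
    r <- rle(masked[idx])
    ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep)) {
      segs[[chr]] <- data.frame(chrom = chr,
                                start = bins$start[idx[starts_i[keep]]],
                                end = bins$end[idx[ends_i[keep]]])
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else {
    data.frame(chrom = character(), start = integer(), end = integer())
  }
  rownames(segments) <- NULL
  structure(list(masked = masked, counts = counts, segments = segments),
            class = "DiscordanceMask")
}

#' Shuffle trios into non-parental pairings
#'
#' Pairs each child with a randomly picked father and mother from the other
#' families, never its own parents: the null against which true-trio
#' concordance is judged (any concordance shuffled trios retain reflects
#' plain between-individual similarity, not inheritance).
#'
#' @param families data.frame with columns `child`, `father`, `mother`
#'   (IDs); at least two families.
#' @param seed integer seed; the same seed gives the same shuffle.
#' @return `families` with `father` and `mother` replaced by the shuffled
#'   assignments.
#' @export
shuffle_trios <- function(families, seed) {
  n <- nrow(families)
  if (n < 2) stop("need at least two families to shuffle")
  set.seed(seed)
  draw_derangement <- function() {
    for (attempt in 1:10000) {
      p <- sample.int(n)
      if (all(p != seq_len(n))) return(p)
    }
    stop("could not find a non-parental pairing")
  }
  out <- families
  out$father <- families$father[draw_derangement()]
  out$mother <- families$mother[draw_derangement()]
  out
}
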