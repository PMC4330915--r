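# Population context for copy-number segments: how often a reference panel
# of unrelated "founder" genomes shows the same state (genotype frequency),
# the implied deletion/duplication allele frequency, recurrent breakpoint
# (junction) clusters, and the gene impact of rare deletions.

#' Bundle per-individual state tracks into a panel
#'
#' @param state_profiles named list of per-individual state tracks, each a
#'   data.frame `chrom`, `start`, `end`, `state` (0-4 or `NA`), all sharing
#'   the same binning.
#' @return list of class `PanelStates`: `bins` (data.frame), `states`
#'   (bins x individuals integer matrix), `n_individuals`.
#' @export
panel_states <- function(state_profiles) {
  stopifnot(length(state_profiles) >= 1)
  bins <- state_profiles[[1]][c("chrom", "start", "end")]
  for (p in state_profiles[-1]) {
    if (!identical(p$chrom, bins$chrom) || !identical(p$start, bins$start)) {
      stop("panel tracks do not share a common binning")
    }
  }
  states <- matrix(vapply(state_profiles, function(p) as.integer(p$state),
                          integer(nrow(bins))),
                   nrow = nrow(bins))
  bad <- states[!is.na(states)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 4L)) {
    stop("states must be in 0..4 or NA")
  }
  structure(list(bins = bins, states = states,
                 n_individuals = ncol(states)),
            class = "PanelStates")
}

panel_overlap <- function(panel, chrom, start, end) {
  which(panel$bins$chrom == chrom & panel$bins$start < end &
          panel$bins$end > start)
}

#' Genotype frequency of a segment in a reference panel
#'
#' Per bin the segment overlaps, counts the panel individuals in the same
#' copy-number state as the segment; the genotype frequency is the median
#' of those counts divided by the panel size.
#'
#' @param segment one-row data.frame (or list) with `chrom`, `start`, `end`,
#'   `state`.
#' @param panel a `PanelStates`.
#' @return frequency in `[0, 1]`, or `NA` when the segment overlaps no
#'   panel bin.
#' @export
genotype_frequency <- function(segment, panel) {
  idx <- panel_overlap(panel, segment$chrom, segment$start, segment$end)
  if (!length(idx)) return(NA_real_)
  counts <- rowSums(panel$states[idx, , drop = FALSE] == segment$state,
                    na.rm = TRUE)
  stats::median(counts) / panel$n_individuals
}

#' Deletion or duplication allele frequency of a segment
#'
#' Integrates the panel's per-bin copy-number observations into an allele
#' count: for a deletion segment (state < 2) each individual contributes
#' `max(2 - state, 0)` deleted alleles; for a duplication segment
#' (state > 2), `max(min(state, 4) - 2, 0)` duplicated alleles (state 4
#' counted as exactly four copies). Per bin the count is divided by `2n`
#' chromosomes; the segment value is the median over its bins.
#'
#' @inheritParams genotype_frequency
#' @return allele frequency in `[0, 1]`; `NA` for a diploid (state-2)
#'   segment or no overlap.
#' @export
allele_frequency <- function(segment, panel) {
  if (segment$state == 2L) return(NA_real_)
  idx <- panel_overlap(panel, segment$chrom, segment$start, segment$end)
  if (!length(idx)) return(NA_real_)
  S <- panel$states[idx, , drop = FALSE]
  dosage <- if (segment$state < 2L) pmax(2L - S, 0L) else pmax(pmin(S, 4L) - 2L, 0L)
  af_bin <- rowSums(dosage, na.rm = TRUE) / (2 * panel$n_individuals)
  stats::median(af_bin)
}

#' Annotate segments with population frequencies
#'
#' Adds `genotype_freq` and `allele_freq` columns.
#'
#' @param segments data.frame from [state_segments()].
#' @param panel a `PanelStates`.
#' @return `segments` with the two frequency columns appended.
#' @export
annotate_segments <- function(segments, panel) {
  segments$genotype_freq <- vapply(seq_len(nrow(segments)), function(i) {
    genotype_frequency(segments[i, ], panel)
  }, numeric(1))
  segments$allele_freq <- vapply(seq_len(nrow(segments)), function(i) {
    allele_frequency(segments[i, ], panel)
  }, numeric(1))
  segments
}

#' Cluster recurrent structural-variant junctions
#'
#' Single-linkage chaining along each chromosome: consecutive sorted
#' junction coordinates at most `cutoff` apart join one cluster. Each
#' cluster's panel frequency is the fraction of assemblies with at least
#' one junction in the cluster range (an assembly counts once per cluster).
#' Recurrent junctions flag either common polymorphisms or systematic
#' calling artifacts; both motivate filtering.
#'
#' @param junctions data.frame `assembly`, `chrom`, `pos`.
#' @param cutoff single-linkage distance cutoff in bases (default 400).
#' @param n_assemblies panel size for the frequency denominator; defaults
#'   to the number of distinct assemblies present.
#' @return data.frame `chrom`, `start`, `end` (coordinate range), `n`
#'   (member junctions), `n_assemblies` (distinct), `frequency`.
#' @export
cluster_junctions <- function(junctions, cutoff = 400,
                              n_assemblies = length(unique(junctions$assembly))) {
  if (!nrow(junctions)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n = integer(), n_assemblies = integer(),
                      frequency = numeric()))
  }
  denom <- n_assemblies
  dt <- data.table::as.data.table(junctions)
  data.table::setorder(dt, chrom, pos)
  dt[, cluster := cumsum(c(1L, (diff(pos) > cutoff) |
                             (head(chrom, -1) != tail(chrom, -1))))]
  out <- dt[, .(chrom = chrom[1], start = min(pos), end = max(pos),
                n = .N, n_assemblies = length(unique(assembly))),
            by = cluster]
  out[, frequency := n_assemblies / denom]
  as.data.frame(out[, !"cluster"])
}

#' Select rare deletion segments
#'
#' Keeps hemizygous (state 1) and nullizygous (state 0) segments at least
#' `min_len` long with population genotype frequency below `max_freq`.
#'
#' @param segments annotated segments (with `genotype_freq`).
#' @param min_len minimum length in bases (default 3000).
#' @param max_freq genotype frequency bound (default 0.01, exclusive).
#' @return the retained rows.
#' @export
filter_rare_deletions <- function(segments, min_len = 3000, max_freq = 0.01) {
  keep <- segments$state %in% c(0L, 1L) &
    (segments$end - segments$start) >= min_len &
    !is.na(segments$genotype_freq) & segments$genotype_freq < max_freq
  segments[keep, , drop = FALSE]
}

#' Gene impact of rare deletions
#'
#' A gene is "affected" when at least one annotated exon overlaps (fully or
#' partially) the span of a hemizygous (state-1) deletion, and "knocked
#' out" when an exon overlaps a nullizygous (state-0) deletion. Because
#' segment boundaries are only bin-resolution, the first and last bin of
#' each deletion are trimmed before overlapping, so that a counted exon is
#' confidently inside the event; deletions of two bins or fewer trim to
#' nothing.
#'
#' @param deletions rare deletion segments ([filter_rare_deletions()]);
#'   an optional `individual` column enables per-individual counts.
#' @param exons data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `gene`.
#' @param bin_size trim width at each end, in bases (default 1000).
#' @return list with `genes` (data.frame `gene`, `affected`, `knocked_out`)
#'   and, when individuals are given, `individuals` (data.frame
#'   `individual`, `n_affected`, `n_knocked_out`).
#' @export
gene_impact <- function(deletions, exons, bin_size = GC_BIN_SIZE) {
  del <- deletions
  del$start <- del$start + bin_size
  del$end <- del$end - bin_size
  del <- del[del$end > del$start, , drop = FALSE]
  hits <- list()
  for (chr in unique(del$chrom)) {
    d <- del[del$chrom == chr, , drop = FALSE]
    e <- exons[exons$chrom == chr, , drop = FALSE]
    if (!nrow(d) || !nrow(e)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = e$start + 1L, end = e$end),
      IRanges::IRanges(start = d$start + 1L, end = d$end))
    if (!length(ov)) next
    hits[[chr]] <- data.frame(
      gene = e$gene[S4Vectors::queryHits(ov)],
      state = d$state[S4Vectors::subjectHits(ov)],
      individual = if ("individual" %in% names(d)) {
        d$individual[S4Vectors::subjectHits(ov)]
      } else NA_character_)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else {
    data.frame(gene = character(), state = integer(),
               individual = character())
  }
  genes <- data.frame(gene = sort(unique(exons$gene)))
  genes$affected <- genes$gene %in% hits$gene[hits$state == 1L]
  genes$knocked_out <- genes$gene %in% hits$gene[hits$state == 0L]
  out <- list(genes = genes)
  if ("individual" %in% names(deletions)) {
    inds <- sort(unique(deletions$individual))
    out$individuals <- data.frame(
      individual = inds,
      n_affected = vapply(inds, function(i) {
        length(unique(hits$gene[hits$individual == i & hits$state == 1L]))
      }, integer(1)),
      n_knocked_out = vapply(inds, function(i) {
        length(unique(hits$gene[hits$individual == i & hits$state == 0L]))
      }, integer(1)))
    rownames(out$individuals) <- NULL
  }
  out
}
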