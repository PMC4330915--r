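# End-to-end plumbing: condensed tracks -> %GC map -> scaled profiles ->
# RCP -> per-genome CNV calls, plus truth-based scoring for synthetic
# cohorts.

#' %GC bucket map from a synthetic reference model
#'
#' Uses the model's per-bin %GC directly (no sequence round trip); cutoffs
#' and buckets are the model's own.
#'
#' @param ref a `SyntheticReference`.
#' @return a `GCBucketMap`.
#' @export
gc_map_from_reference <- function(ref) {
  structure(list(bin_size = ref$bin_size, n_buckets = GC_N_BUCKETS,
                 cutoffs = ref$cutoffs,
                 bins = ref$bins[c("chrom", "start", "end", "gc", "bucket")]),
            class = "GCBucketMap")
}

#' Scale a set of condensed tracks to a common cohort target
#'
#' Fingerprints every track, builds the cohort target vector and returns
#' the per-genome scaled kilobase profiles.
#'
#' @param tracks named list of `CondensedTrack`s.
#' @param map a `GCBucketMap`.
#' @param autosomes passed to [characteristic_vector()].
#' @return list with `scaled` (named list of profiles), `vectors` (matrix,
#'   genomes x buckets) and `target`.
#' @export
cohort_scale <- function(tracks, map, autosomes = NULL) {
  vectors <- t(vapply(tracks, characteristic_vector, numeric(map$n_buckets),
                      map = map, autosomes = autosomes))
  target <- target_vector(vectors)
  scaled <- lapply(tracks, function(tr) {
    own <- characteristic_vector(tr, map, autosomes)
    scale_profile(aggregate_to_kb(tr, map$bin_size), map, own, target)
  })
  list(scaled = scaled, vectors = vectors, target = target)
}

#' True non-diploid segments of a cohort member
#'
#' Maximal runs of constant non-diploid true state, for scoring calls.
#'
#' @param cohort a `SyntheticCohort`.
#' @param id individual ID.
#' @return data.frame `chrom`, `start`, `end`, `state`.
#' @export
true_cnv_segments <- function(cohort, id) {
  st <- true_states(cohort, id)
  seg <- state_segments(st$state, data.frame(st[c("chrom", "start", "end")],
                                             value = NA_real_))
  seg <- seg[seg$state != 2L, c("chrom", "start", "end", "state")]
  rownames(seg) <- NULL
  seg
}

#' Score CNV calls against known truth
#'
#' A true event is recalled when a called non-diploid segment has the same
#' state and both boundaries within `tol_bins` bins; a called non-diploid
#' segment is a true positive when it matches a true event the same way.
#'
#' @param segments called segments ([state_segments()]).
#' @param truth true segments ([true_cnv_segments()]).
#' @param tol_bins boundary tolerance in bins (default 2).
#' @param bin_size bin width in bases (default 1000).
#' @return list with `recall`, `precision`, `n_true`, `n_called`.
#' @export
evaluate_cnv_calls <- function(segments, truth, tol_bins = 2L,
                               bin_size = GC_BIN_SIZE) {
  called <- segments[segments$state != 2L, , drop = FALSE]
  tol <- tol_bins * bin_size
  matches <- function(a, b) {
    a$chrom == b$chrom & a$state == b$state &
      abs(a$start - b$start) <= tol & abs(a$end - b$end) <= tol
  }
  recalled <- vapply(seq_len(nrow(truth)), function(i) {
    any(matches(called, truth[i, ]))
  }, logical(1))
  tp <- vapply(seq_len(nrow(called)), function(i) {
    any(matches(truth, called[i, ]))
  }, logical(1))
  list(recall = if (nrow(truth)) mean(recalled) else NA_real_,
       precision = if (nrow(called)) mean(tp) else NA_real_,
       n_true = nrow(truth), n_called = nrow(called))
}
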