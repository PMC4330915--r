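# Copy-number calling: divide a genome's scaled coverage by the RCP to get
# the Normalized Coverage Profile (NCP, in percent of diploid: 100 =
# diploid, 50 = hemizygous, 0 = nullizygous), then decode the most probable
# copy-number state path with a five-state Gaussian HMM and merge
# consecutive bins of equal state into segments.

#' Normalize scaled coverage to a Reference Coverage Profile
#'
#' `ncp(bin) = 100 * scaled(bin) / level(bin)`. Bins whose RCP is masked, or
#' whose level is below `floor_frac` of the genome-wide median level
#' (dropout regions, where the ratio would blow up), are masked.
#'
#' @param scaled a scaled profile from [scale_profile()].
#' @param rcp a `ReferenceCoverageProfile` sharing the binning.
#' @param floor_frac RCP level floor, as a fraction of the genome-wide
#'   median level (default 0.1).
#' @return data.frame `chrom`, `start`, `end`, `value` with the NCP in
#'   percent of diploid; masked bins are `NA`.
#' @export
normalize_profile <- function(scaled, rcp, floor_frac = 0.1) {
  key <- match(paste(scaled$chrom, scaled$start), paste(rcp$chrom, rcp$start))
  if (all(is.na(key))) stop("scaled profile and RCP share no bins")
  level <- rcp$level[key]
  floor_level <- floor_frac * stats::median(level, na.rm = TRUE)
  level[!is.na(level) & level < floor_level] <- NA_real_
  out <- scaled
  out$value <- 100 * scaled$value / level
  out
}

#' Five-state copy-number HMM parameters
#'
#' States 0-4 are observed copy counts: nullizygous, hemizygous, diploid,
#' one extra copy, and four or more copies, with emission means fixed at 0,
#' 50, 100, 150 and 200 percent of diploid. Emissions are Gaussian; the
#' state-4 sd is widest because that state is open-ended upward.
#'
#' @param emission_sds per-state emission standard deviations, in percent.
#' @param self_prob self-transition probability; the remainder is split
#'   equally among the other four states.
#' @param initial initial state distribution.
#' @return list of class `HMMParams` with `means`, `sds`, `transition`
#'   (5x5, rows = from), `initial`.
#' @export
hmm_params <- function(emission_sds = c(12, 12, 12, 18, 30),
                       self_prob = 1 - 1e-4,
                       initial = c(0.001, 0.01, 0.978, 0.01, 0.001)) {
  S <- 5L
  stopifnot(length(emission_sds) == S, all(emission_sds > 0),
            self_prob > 0, self_prob < 1, length(initial) == S)
  trans <- matrix((1 - self_prob) / (S - 1), S, S)
  diag(trans) <- self_prob
  p <- list(means = c(0, 50, 100, 150, 200), sds = emission_sds,
            transition = trans, initial = initial / sum(initial))
  class(p) <- "HMMParams"
  p
}

validate_hmm <- function(params) {
  S <- length(params$means)
  if (!is.matrix(params$transition) || any(dim(params$transition) != S) ||
      any(abs(rowSums(params$transition) - 1) > 1e-8) ||
      any(params$transition < 0)) {
    stop("transition matrix rows must be non-negative and sum to 1")
  }
  if (abs(sum(params$initial) - 1) > 1e-8 || any(params$initial < 0)) {
    stop("initial distribution must be non-negative and sum to 1")
  }
  invisible(params)
}

#' Most probable state path (Viterbi)
#'
#' Log-space dynamic program over one chromosome's NCP values. Masked bins
#' (`NA`) emit uniformly in every state, so the path bridges them on
#' transition structure alone. Ties break toward the lower state index.
#'
#' @param values NCP values of consecutive bins (percent; `NA` = masked).
#' @param params an `HMMParams`.
#' @return integer vector of states 0-4.
#' @export
viterbi_states <- function(values, params = hmm_params()) {
  validate_hmm(params)
  n <- length(values)
  if (n == 0) return(integer(0))
  S <- length(params$means)
  obs <- !is.na(values)
  emit <- matrix(0, n, S)
  for (s in seq_len(S)) {
    emit[obs, s] <- stats::dnorm(values[obs], params$means[s], params$sds[s],
                                 log = TRUE)
  }
  logA <- log(params$transition)
  delta <- log(params$initial) + emit[1, ]
  psi <- matrix(0L, n, S)
  if (n > 1) {
    for (t in 2:n) {
      cand <- delta + logA          # cand[i, j]: from state i into state j
      best_from <- max.col(t(cand), ties.method = "first")
      psi[t, ] <- best_from
      delta <- cand[cbind(best_from, seq_len(S))] + emit[t, ]
    }
  }
  states <- integer(n)
  states[n] <- which.max(delta)
  if (n > 1) for (t in n:2) states[t - 1L] <- psi[t, states[t]]
  states - 1L
}

#' Posterior-decoded state path (forward-backward)
#'
#' Alternative to [viterbi_states()]: the marginally most probable state per
#' bin rather than the jointly most probable path.
#'
#' @inheritParams viterbi_states
#' @return integer vector of states 0-4.
#' @export
posterior_states <- function(values, params = hmm_params()) {
  validate_hmm(params)
  n <- length(values)
  if (n == 0) return(integer(0))
  S <- length(params$means)
  obs <- !is.na(values)
  emit <- matrix(0, n, S)
  for (s in seq_len(S)) {
    emit[obs, s] <- stats::dnorm(values[obs], params$means[s], params$sds[s],
                                 log = TRUE)
  }
  A <- params$transition
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  fwd <- matrix(-Inf, n, S)
  bwd <- matrix(0, n, S)
  fwd[1, ] <- log(params$initial) + emit[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (j in seq_len(S)) fwd[t, j] <- lse(fwd[t - 1, ] + log(A[, j])) + emit[t, j]
    }
    for (t in (n - 1):1) {
      for (i in seq_len(S)) bwd[t, i] <- lse(log(A[i, ]) + emit[t + 1, ] + bwd[t + 1, ])
    }
  }
  max.col(fwd + bwd, ties.method = "first") - 1L
}

#' Merge consecutive equal-state bins into segments
#'
#' @param states integer states 0-4, aligned to `ncp` bins.
#' @param ncp NCP data.frame (`chrom`, `start`, `end`, `value`).
#' @return data.frame `chrom`, `start`, `end`, `state`, `n_bins`,
#'   `median_ncp` (median of the segment's unmasked bins).
#' @export
state_segments <- function(states, ncp) {
  if (!length(states)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      state = integer(), n_bins = integer(),
                      median_ncp = numeric()))
  }
  stopifnot(length(states) == nrow(ncp))
  res <- list()
  for (chr in unique(ncp$chrom)) {
    idx <- which(ncp$chrom == chr)
    r <- rle(states[idx])
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    res[[chr]] <- data.frame(
      chrom = chr,
      start = ncp$start[idx[starts_i]],
      end = ncp$end[idx[ends_i]],
      state = r$values,
      n_bins = r$lengths,
      median_ncp = vapply(seq_along(r$values), function(s) {
        stats::median(ncp$value[idx[starts_i[s]:ends_i[s]]], na.rm = TRUE)
      }, numeric(1)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Segment a normalized coverage profile into copy-number states
#'
#' Runs the HMM per chromosome (chromosomes are independent) and merges the
#' state path into segments.
#'
#' @param ncp NCP from [normalize_profile()].
#' @param params an `HMMParams`.
#' @param decoding `"viterbi"` (most probable path, default) or
#'   `"posterior"` (per-bin marginal).
#' @return list with `states` (integer per bin) and `segments`
#'   (see [state_segments()]).
#' @export
segment_profile <- function(ncp, params = hmm_params(),
                            decoding = c("viterbi", "posterior")) {
  decoding <- match.arg(decoding)
  decode <- if (decoding == "viterbi") viterbi_states else posterior_states
  states <- integer(nrow(ncp))
  for (chr in unique(ncp$chrom)) {
    idx <- which(ncp$chrom == chr)
    states[idx] <- decode(ncp$value[idx], params)
  }
  list(states = states, segments = state_segments(states, ncp))
}

#' Median NCP over a genomic interval
#'
#' The representative normalized coverage of an externally supplied event
#' (e.g. a published deletion call): the median NCP over the unmasked bins
#' the interval overlaps. A caller can then classify the event against a
#' cutoff such as 75% of diploid.
#'
#' @param ncp NCP data.frame.
#' @param chrom,start,end interval (0-based half-open).
#' @return the median NCP, or `NA` when no unmasked bin is overlapped.
#' @export
median_event_ncp <- function(ncp, chrom, start, end) {
  hit <- ncp$chrom == chrom & ncp$start < end & ncp$end > start
  v <- ncp$value[hit]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  stats::median(v)
}

#' Call CNVs for one genome against an RCP
#'
#' Convenience wrapper: normalize then segment.
#'
#' @inheritParams normalize_profile
#' @inheritParams segment_profile
#' @return list with `ncp`, `states`, `segments`.
#' @export
call_cnvs <- function(scaled, rcp, params = hmm_params(), floor_frac = 0.1,
                      decoding = "viterbi") {
  ncp <- normalize_profile(scaled, rcp, floor_frac = floor_frac)
  seg <- segment_profile(ncp, params, decoding = decoding)
  list(ncp = ncp, states = seg$states, segments = seg$segments)
}
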