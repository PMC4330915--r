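# Independent oracles used across tests.

# Exhaustive Viterbi: enumerate every state path and pick the best.
brute_force_viterbi <- function(values, params) {
  S <- length(params$means)
  n <- length(values)
  obs <- !is.na(values)
  emit <- matrix(0, n, S)
  for (s in seq_len(S)) {
    emit[obs, s] <- dnorm(values[obs], params$means[s], params$sds[s], log = TRUE)
  }
  logA <- log(params$transition)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  sc <- log(params$initial)[paths[, 1]] + emit[1, ][paths[, 1]]
  if (n > 1) {
    for (t in 2:n) {
      sc <- sc + logA[cbind(paths[, t - 1], paths[, t])] + emit[t, ][paths[, t]]
    }
  }
  unname(paths[which.max(sc), ]) - 1L
}

# Rank-based cutoffs by explicit sort-and-index.
brute_force_cutoffs <- function(x, n_buckets) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  x[ceiling(seq_len(n_buckets - 1) * n / n_buckets)]
}

# Bucket of one value by scanning the quantile intervals.
brute_force_bucket <- function(gc, cutoffs) {
  for (k in seq_along(cutoffs)) if (gc <= cutoffs[k]) return(k - 1L)
  length(cutoffs)
}

# Quadratic single-linkage clustering of junction coordinates (one
# chromosome): repeated merging of any two clusters whose closest members
# are within the cutoff.
brute_force_single_linkage <- function(pos, cutoff) {
  groups <- as.list(seq_along(pos))
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        d <- min(abs(outer(pos[groups[[i]]], pos[groups[[j]]], `-`)))
        if (d <= cutoff) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  # canonical form: sorted members, clusters ordered by minimum position
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, function(g) min(pos[g]), numeric(1)))]
}

# Transmissible per-haplotype copies by enumerating balanced splits of the
# total copy count (state 4 is open-ended: four or five copies).
oracle_transmissible <- function(state) {
  totals <- if (state == 4L) c(4L, 5L) else state
  sort(unique(unlist(lapply(totals, function(t) c(t %/% 2L, t - t %/% 2L)))))
}

oracle_child_states <- function(f, m) {
  sort(unique(pmin(as.vector(outer(oracle_transmissible(f),
                                   oracle_transmissible(m), `+`)), 4L)))
}

# A flat binned profile data.frame.
flat_profile <- function(n_bins, value, chrom = "chr1", bin_size = 1000L) {
  start <- (seq_len(n_bins) - 1L) * bin_size
  data.frame(chrom = chrom, start = start, end = start + bin_size,
             value = value)
}

# A state track data.frame.
state_track <- function(states, chrom = "chr1", bin_size = 1000L) {
  start <- (seq_along(states) - 1L) * bin_size
  data.frame(chrom = chrom, start = start, end = start + bin_size,
             state = as.integer(states))
}
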