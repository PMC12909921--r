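## CpG-aware Kimura 2-parameter divergence of TE copies to their family
## consensus, and classification of family divergence landscapes.
##
## CpG dinucleotides in the consensus deaminate fast, so transitions observed
## at consensus CpG columns overweight genuine age; they are down-weighted by
## w_cpg (default 1/10) before computing the K2P distance. w_cpg = 1 recovers
## the plain unweighted counts.

#' Count substitution site patterns in a copy/consensus alignment
#'
#' Columns where either sequence has a gap or an ambiguity code are skipped
#' entirely. Transitions (A<->G, C<->T) at consensus CpG columns count
#' `w_cpg` instead of 1; transversions always count 1. `n_sites` is the
#' unweighted number of evaluable columns, so `p = p_count / n_sites` and
#' `q = q_count / n_sites`.
#'
#' @param consensus_aln,copy_aln Aligned sequences of equal length (gap
#'   character `-`).
#' @param w_cpg Transition weight at consensus CpG columns (default 1/10).
#' @return A list with `n_sites`, `p_count`, `q_count`, `p`, `q`.
#' @export
count_site_patterns <- function(consensus_aln, copy_aln, w_cpg = 0.1) {
  if (nchar(consensus_aln) != nchar(copy_aln))
    stopf("alignment length mismatch (%d vs %d)",
          nchar(consensus_aln), nchar(copy_aln))
  a <- strsplit(toupper(consensus_aln), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(copy_aln), "", fixed = TRUE)[[1]]
  valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  ## consensus CpG mask: C whose next non-gap consensus base is G
  cons_idx <- which(a != "-")
  cpg <- rep(FALSE, length(a))
  if (length(cons_idx) > 1L) {
    cc <- a[cons_idx]
    is_c <- cc == "C" & c(cc[-1] == "G", FALSE)
    cpg[cons_idx[is_c]] <- TRUE
  }
  ts <- valid & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                   (a == "C" & b == "T") | (a == "T" & b == "C"))
  diffpos <- valid & a != b
  tv <- diffpos & !ts
  n_sites <- sum(valid)
  p_count <- sum(ts * ifelse(cpg, w_cpg, 1))
  q_count <- sum(tv)
  list(n_sites = n_sites, p_count = p_count, q_count = q_count,
       p = if (n_sites) p_count / n_sites else NA_real_,
       q = if (n_sites) q_count / n_sites else NA_real_)
}

#' Kimura 2-parameter distance
#'
#' `KD = 100 * (-1/2 * ln((1 - 2p - q) * sqrt(1 - 2q)))`, in substitutions
#' per 100 sites. Outside the model's domain (`1 - 2p - q <= 0` or
#' `1 - 2q <= 0`) the distance is saturated and `NA` is returned (such
#' copies are excluded from histograms).
#'
#' @param p Transition proportion.
#' @param q Transversion proportion.
#' @return KD in percent, or `NA_real_` when saturated.
#' @export
kimura2p <- function(p, q) {
  out <- rep(NA_real_, length(p))
  ok <- is.finite(p) & is.finite(q) & (1 - 2 * p - q) > 0 & (1 - 2 * q) > 0
  out[ok] <- 100 * (-0.5 * log((1 - 2 * p[ok] - q[ok]) * sqrt(1 - 2 * q[ok])))
  out
}

#' Per-copy KD values for a table of alignments
#'
#' @param alignments `data.table` with `family_id`, `copy_id`,
#'   `consensus_aln`, `copy_aln`.
#' @param w_cpg Passed to [count_site_patterns()].
#' @return The input table with `n_sites`, `p`, `q` and `kd` columns
#'   (`kd = NA` for saturated copies).
#' @export
copy_kd <- function(alignments, w_cpg = 0.1) {
  alignments <- data.table::as.data.table(alignments)
  pats <- lapply(seq_len(nrow(alignments)), function(i)
    count_site_patterns(alignments$consensus_aln[i], alignments$copy_aln[i],
                        w_cpg = w_cpg))
  out <- alignments[, .(family_id, copy_id)]
  out[, n_sites := vapply(pats, `[[`, numeric(1), "n_sites")]
  out[, p := vapply(pats, `[[`, numeric(1), "p")]
  out[, q := vapply(pats, `[[`, numeric(1), "q")]
  out[, kd := kimura2p(p, q)]
  out[]
}

#' Histogram of a family's KD values
#'
#' Unit bins `[0,1) ... [49,50)`; finite KDs at or above 50 are clamped into
#' the last bin so counts stay a partition of the finite-KD copies.
#'
#' @param kd Numeric KD values (percent); `NA`s (saturated) are dropped.
#' @return Integer vector of length 50, names = bin left edges.
#' @export
kd_histogram <- function(kd) {
  kd <- kd[is.finite(kd)]
  bin <- pmin(floor(kd), 49)
  counts <- tabulate(bin + 1L, nbins = 50L)
  names(counts) <- 0:49
  counts
}

#' Classify a family's KD landscape
#'
#' The histogram is smoothed with a centred moving average (window
#' `smooth_window` bins); local maxima with prominence at least
#' `prominence_frac` of the copy count are modes. One mode below `low_cut`
#' means a recent expansion; one mode above `high_cut` means decayed
#' remnants; modes on both sides mean a mixed history; anything else
#' (including fewer than `min_copies` copies) is unresolved.
#'
#' @param histogram Output of [kd_histogram()].
#' @param low_cut,high_cut Mode-position cuts in KD percent (defaults 10
#'   and 20).
#' @param min_copies Minimum copies for a call (default 20).
#' @param smooth_window Moving-average window in bins (default 3).
#' @param prominence_frac Minimum mode prominence as a fraction of copy
#'   count (default 0.05).
#' @return A list with `shape_class` (one of `recent_expansion`, `remnant`,
#'   `mixed`, `unresolved`) and `modes` (bin centres).
#' @export
classify_kd_profile <- function(histogram, low_cut = 10, high_cut = 20,
                                min_copies = 20L, smooth_window = 3L,
                                prominence_frac = 0.05) {
  n <- sum(histogram)
  centers <- as.numeric(names(histogram)) + 0.5
  sm <- moving_average(as.numeric(histogram), smooth_window)
  modes <- centers[find_modes(sm, prominence = prominence_frac * n)]
  if (n < min_copies)
    return(list(shape_class = "unresolved", modes = modes))
  cls <- if (length(modes) == 1L) {
    if (modes < low_cut) "recent_expansion"
    else if (modes > high_cut) "remnant"
    else "unresolved"
  } else if (length(modes) >= 2L &&
             any(modes < low_cut) && any(modes > high_cut)) {
    "mixed"
  } else "unresolved"
  list(shape_class = cls, modes = modes)
}

moving_average <- function(x, window = 3L) {
  half <- (window - 1L) %/% 2L
  xp <- c(rep(0, half), x, rep(0, half))
  vapply(seq_along(x), function(i) mean(xp[i:(i + 2L * half)]), numeric(1))
}

## Local maxima with a simple topographic prominence: peak height minus the
## higher of the two valley minima separating it from taller terrain.
find_modes <- function(y, prominence) {
  n <- length(y)
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  is_peak <- vapply(seq_len(m), function(k) {
    left <- if (k > 1L) r$values[k - 1L] else -Inf
    right <- if (k < m) r$values[k + 1L] else -Inf
    r$values[k] > left && r$values[k] > right
  }, logical(1))
  ## a plateau peak is represented by its first bin
  peaks <- starts[is_peak]
  peaks <- peaks[y[peaks] > 0]
  keep <- logical(length(peaks))
  for (k in seq_along(peaks)) {
    i <- peaks[k]
    left <- if (any(y[seq_len(i - 1)] > y[i])) {
      j <- max(which(y[seq_len(i - 1)] > y[i]))
      min(y[j:i])
    } else 0
    right <- if (i < n && any(y[(i + 1):n] > y[i])) {
      j <- i + min(which(y[(i + 1):n] > y[i]))
      min(y[i:j])
    } else 0
    keep[k] <- (y[i] - max(left, right)) >= prominence
  }
  peaks[keep]
}

#' KD profiles for all families
#'
#' @param kds Output of [copy_kd()].
#' @inheritParams classify_kd_profile
#' @return A `data.table` per family: `n_copies` (finite KD), `median_kd`,
#'   `shape_class`, `modes` (comma-joined bin centres).
#' @export
kd_profiles <- function(kds, low_cut = 10, high_cut = 20, min_copies = 20L) {
  kds <- data.table::as.data.table(kds)
  kds[, {
    h <- kd_histogram(kd)
    cl <- classify_kd_profile(h, low_cut = low_cut, high_cut = high_cut,
                              min_copies = min_copies)
    .(n_copies = sum(is.finite(kd)),
      median_kd = median(kd[is.finite(kd)]),
      shape_class = cl$shape_class,
      modes = paste(cl$modes, collapse = ","))
  }, by = family_id]
}
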