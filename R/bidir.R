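# Bidirectional (eRNA) origin detection. Divergent transcription leaves a
# signature of minus-strand signal immediately upstream and plus-strand
# signal immediately downstream of a shared origin. The detector pairs
# strand-specific local maxima of smoothed 5'-end coverage; it is a
# deliberately simple, certified-on-synthetic-truth stand-in for full
# probabilistic models of polymerase loading.

#' Detect bidirectional transcription origins on one chromosome
#'
#' Coverage on each strand is smoothed with a moving average
#' (`smooth_bins` bins); local maxima above a noise floor (95th percentile
#' of nonzero smoothed bins on that strand) are candidate summits. A call
#' is made where a minus-strand summit lies at most `max_pair_distance`
#' bases LEFT of a plus-strand summit. The call center is the midpoint of
#' the paired summits, the interval `center +/- flank` (clipped), and the
#' strength the summed RPM inside the interval. Overlapping candidates are
#' resolved greedily by strength, keeping call centers at least
#' `max_pair_distance` apart.
#'
#' @param track A stranded [coverage_track] (one chromosome).
#' @param min_strength Minimum summed RPM within the call.
#' @param max_pair_distance Maximum summit separation (bases).
#' @param flank Half-width of the reported interval (bases).
#' @param smooth_bins Moving-average window (bins, odd).
#' @return ROI-style data.frame: `chrom`, `start`, `end`, `center`,
#'   `support`, plus `strength` and `asymmetry` (fraction of plus-strand
#'   signal right of center).
#' @export
detect_bidirectionals <- function(track, min_strength = 1,
                                  max_pair_distance = 600L, flank = 750L,
                                  smooth_bins = 5L) {
  stopifnot(inherits(track, "coverage_track"), min_strength > 0,
            max_pair_distance > 0, flank > 0, smooth_bins >= 1)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), center = integer(),
                      support = integer(), strength = numeric(),
                      asymmetry = numeric())
  bs <- track$bin_size
  chrom_len <- length(track$values_plus) * bs
  sp <- smooth_ma(track$values_plus, smooth_bins)
  sm <- smooth_ma(track$values_minus, smooth_bins)
  peaks_p <- strand_summits(sp)
  peaks_m <- strand_summits(sm)
  if (!length(peaks_p) || !length(peaks_m)) return(empty)

  max_gap_bins <- ceiling(max_pair_distance / bs)
  cand <- list()
  for (ip in peaks_p) {
    left <- peaks_m[peaks_m <= ip & ip - peaks_m <= max_gap_bins]
    if (!length(left)) next
    im <- left[which.max(sm[left])]
    center <- as.integer(round(((im - 0.5) + (ip - 0.5)) / 2 * bs))
    lo <- max(0L, center - as.integer(flank))
    hi <- min(chrom_len, center + as.integer(flank))
    b1 <- lo %/% bs + 1L
    b2 <- min(length(sp), max(b1, (hi - 1L) %/% bs + 1L))
    strength <- sum(track$values_plus[b1:b2]) +
      sum(track$values_minus[b1:b2])
    if (strength < min_strength) next
    cbin <- center %/% bs + 1L
    plus_total <- sum(track$values_plus[b1:b2])
    plus_right <- if (cbin <= b2) {
      sum(track$values_plus[max(b1, cbin):b2])
    } else 0
    asym <- if (plus_total > 0) plus_right / plus_total else 0
    cand[[length(cand) + 1L]] <- data.frame(
      chrom = track$chrom, start = lo, end = hi, center = center,
      support = 1L, strength = strength, asymmetry = asym
    )
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$strength), , drop = FALSE]
  keep <- logical(nrow(cand))
  accepted <- integer()
  for (i in seq_len(nrow(cand))) {
    if (!length(accepted) ||
        all(abs(cand$center[i] - accepted) > max_pair_distance)) {
      keep[i] <- TRUE
      accepted <- c(accepted, cand$center[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

smooth_ma <- function(v, w) {
  if (w <= 1L) return(v)
  as.numeric(stats::filter(v, rep(1 / w, w), sides = 2) |>
               (\(x) { x[is.na(x)] <- 0; x })())
}

# local maxima above the per-strand noise floor (95th percentile of
# nonzero smoothed bins); plateaus keep their leftmost bin
strand_summits <- function(v) {
  nz <- v[v > 0]
  if (!length(nz)) return(integer())
  floor_v <- stats::quantile(nz, 0.95, names = FALSE)
  n <- length(v)
  left <- c(-Inf, v[-n])
  right <- c(v[-1L], -Inf)
  which(v >= floor_v & v > left & v >= right)
}
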