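# Accessibility peak calling against a local Poisson background: per-bin
# Poisson p-values with lambda the maximum over local windows and the
# genome-wide mean, BH-adjusted, significant bins merged into peaks.
# Local lambdas are computed in two passes: bins that look enriched
# against the genome-wide rate (relaxed p < mask_p) are masked out of the
# local windows, so a peak can neither inflate its own background nor
# that of its immediate neighborhood.

#' Call accessibility peaks on one chromosome
#'
#' Works on raw per-bin counts (an unstranded [coverage_track]); per bin
#' the background rate is the maximum of running means over
#' `lambda_windows` and the chromosome-wide mean. Bins with BH q-value at
#' most `q_max` are merged (gap up to `merge_gap_bins` bins) into peaks;
#' a peak's fold change is `log2(sum(signal) / sum(lambda))` over its
#' bins and the summit the center of its maximal bin. Peaks failing
#' `min_log2fc` (strict) or `q_max` are dropped.
#'
#' @param track Unstranded [coverage_track] of raw counts.
#' @param lambda_windows Local background window sizes in bases.
#' @param min_log2fc Minimum log2 fold change above background.
#' @param q_max Maximum BH q-value.
#' @param merge_gap_bins Bins of allowed gap inside one peak.
#' @param mask_p Relaxed Poisson p-value (vs the genome-wide rate) above
#'   which a bin is considered background when local lambdas are
#'   estimated.
#' @return data.frame of peak calls: `chrom`, `start`, `end`, `summit`,
#'   `fold_change`, `pvalue`, `qvalue`.
#' @export
call_peaks <- function(track, lambda_windows = c(1000L, 10000L),
                       min_log2fc = 1, q_max = 1e-5,
                       merge_gap_bins = 2L, mask_p = 1e-3) {
  stopifnot(inherits(track, "coverage_track"), length(lambda_windows) >= 1)
  v <- track_values(track)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      fold_change = numeric(), pvalue = numeric(),
                      qvalue = numeric())
  if (all(v == 0)) return(empty)
  bs <- track$bin_size
  nbin <- length(v)
  gmean <- mean(v)
  bgmask <- stats::ppois(v - 1, gmean, lower.tail = FALSE) >= mask_p
  lam <- rep(gmean, nbin)
  for (wbase in lambda_windows) {
    wbin <- max(1L, round(wbase / bs))
    lam <- pmax(lam, running_mean_masked(v, wbin, bgmask))
  }
  lam <- pmax(lam, 1e-9)
  pvals <- stats::ppois(v - 1, lam, lower.tail = FALSE)
  qvals <- stats::p.adjust(pvals, "BH")
  sig <- which(qvals <= q_max)
  if (!length(sig)) return(empty)
  # peak extent: the contiguous run of relaxed-candidate bins (gap up to
  # merge_gap_bins) around each significant seed, so a peak is not
  # clipped to only its most extreme bins
  cand <- sort(unique(c(sig, which(!bgmask))))
  cgrp <- cumsum(c(1L, diff(cand) > merge_gap_bins + 1L))
  runs <- split(cand, cgrp)
  runs <- runs[vapply(runs, function(b) any(b %in% sig), logical(1L))]
  peaks <- lapply(runs, function(bins) {
    b1 <- min(bins); b2 <- max(bins)
    fold <- log2(sum(v[b1:b2]) / sum(lam[b1:b2]))
    smax <- b1 - 1L + which.max(v[b1:b2])
    data.frame(
      chrom = track$chrom,
      start = (b1 - 1L) * bs, end = b2 * bs,
      summit = as.integer((smax - 0.5) * bs),
      fold_change = fold,
      pvalue = min(pvals[b1:b2]),
      qvalue = min(qvals[b1:b2])
    )
  })
  out <- do.call(rbind, peaks)
  out <- out[out$fold_change > min_log2fc & out$qvalue <= q_max, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# centered running mean over w bins using only bins where keep is TRUE;
# windows with no kept bin fall back to the global mean of kept bins
running_mean_masked <- function(v, w, keep) {
  n <- length(v)
  vk <- ifelse(keep, v, 0)
  fallback <- if (any(keep)) sum(vk) / sum(keep) else mean(v)
  if (w >= n) return(rep(fallback, n))
  half <- w %/% 2L
  cs <- cumsum(c(0, vk))
  ck <- cumsum(c(0L, as.integer(keep)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  nkeep <- ck[hi + 1L] - ck[lo]
  out <- rep(fallback, n)
  ok <- nkeep > 0L
  out[ok] <- (cs[hi + 1L] - cs[lo])[ok] / nkeep[ok]
  out
}

#' Presence matrix of consensus peaks across time points
#'
#' Consensus peaks are the merged union over all time points; presence at
#' a time point means an overlap of at least `min_overlap` bases with a
#' peak called there.
#'
#' @param peak_sets Named list of peak data.frames (`chrom`, `start`,
#'   `end`), one per time point.
#' @param min_overlap Minimum overlap (bases).
#' @return data.frame of consensus peaks with one logical column per time
#'   point.
#' @export
peak_presence <- function(peak_sets, min_overlap = 1L) {
  stopifnot(is.list(peak_sets), !is.null(names(peak_sets)),
            min_overlap >= 1)
  pooled <- do.call(rbind, lapply(peak_sets, function(s)
    as.data.frame(s)[, c("chrom", "start", "end")]))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer())
    for (nm in names(peak_sets)) out[[nm]] <- logical()
    return(out)
  }
  consensus <- merge_intervals(as_gintervals(pooled), gap = 0L)
  out <- data.frame(chrom = consensus$chrom, start = consensus$start,
                    end = consensus$end)
  for (nm in names(peak_sets)) {
    out[[nm]] <- overlaps_by(consensus, as_gintervals(peak_sets[[nm]]),
                             min_overlap)
  }
  out
}

#' Write peaks in narrowPeak-style BED6+4
#' @param peaks Peak data.frame from [call_peaks()].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_peaks <- function(peaks, path) {
  dt <- data.table::data.table(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak_%05d", seq_len(nrow(peaks))),
    score = round(pmin(1000, -10 * log10(pmax(peaks$qvalue, 1e-100)))),
    strand = ".",
    fold_change = peaks$fold_change,
    neglog10p = -log10(pmax(peaks$pvalue, 1e-300)),
    neglog10q = -log10(pmax(peaks$qvalue, 1e-300)),
    summit_offset = peaks$summit - peaks$start
  )
  writeLines(paste0("#", paste(names(dt), collapse = "\t")), path)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     append = TRUE)
  invisible(path)
}
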