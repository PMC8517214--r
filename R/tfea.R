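# Motif-displacement enrichment. For each ranked ROI the sequence around
# its center is scanned for motif matches; matches concentrated near the
# centers of the most differentially active ROIs produce a positive
# rank-weighted enrichment score. GC correction and Z / permutation
# p-values follow.

#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a named character vector of sequences as FASTA
#' @param genome Named character vector.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Motif hits around ROI centers
#'
#' Scans `center +/- half_width` (clipped to the chromosome) of every ROI
#' with one PWM. Displacement is the signed distance from the hit
#' midpoint to the ROI center (hit of width w starting at genomic p has
#' midpoint `p + (w - 1) / 2`). Per ROI the best hit (maximal score, ties
#' to the smallest |displacement|) is flagged `best` for enrichment
#' scoring; all hits feed displacement distributions.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param rois ROI data.frame (`chrom`, `center`, `name`).
#' @param p A [pwm].
#' @param half_width Scan half-width in bases (default 1500, i.e. the
#'   3-kb window).
#' @param threshold Log-odds threshold; default
#'   `score_threshold(p, p_cutoff)`.
#' @param p_cutoff Match p-value used when `threshold` is NULL.
#' @param coded Optional precomputed integer-coded chromosomes (named
#'   list, as from `encode_dna`) to amortize encoding across motifs.
#' @return data.frame: `roi_id`, `motif_id`, `position` (genomic,
#'   0-based), `strand`, `score`, `displacement`, `best`.
#' @export
hits_around_centers <- function(genome, rois, p, half_width = 1500L,
                                threshold = NULL, p_cutoff = 1e-5,
                                coded = NULL) {
  stopifnot(inherits(p, "pwm"))
  rois <- as.data.frame(rois)
  miss <- setdiff(unique(rois$chrom), names(genome))
  if (length(miss)) {
    stop("chromosome(s) missing from genome: ",
         paste(miss, collapse = ", "))
  }
  if (is.null(threshold)) threshold <- score_threshold(p, p_cutoff)
  # scan each chromosome once, then assign sparse hits to ROI windows
  if (is.null(coded)) {
    coded <- lapply(genome[unique(rois$chrom)], encode_dna)
  }
  w <- p$width
  res <- vector("list", length(coded))
  for (chrom in names(coded)) {
    code <- coded[[chrom]]
    clen <- length(code)
    fwd <- score_windows_cpp(code, p$lod)
    rc_lod <- p$lod[4:1, w:1, drop = FALSE]
    rev_ <- score_windows_cpp(code, rc_lod)
    hp <- which(!is.na(fwd) & fwd >= threshold - 1e-12)
    hm <- which(!is.na(rev_) & rev_ >= threshold - 1e-12)
    pos <- c(hp, hm) - 1L
    strand <- rep(c("+", "-"), c(length(hp), length(hm)))
    score <- c(fwd[hp], rev_[hm])
    o <- order(pos)
    pos <- pos[o]; strand <- strand[o]; score <- score[o]
    ridx <- which(rois$chrom == chrom)
    per_roi <- vector("list", length(ridx))
    for (k in seq_along(ridx)) {
      i <- ridx[k]
      center <- rois$center[i]
      lo <- max(0L, center - half_width)
      hi <- min(clen, center + half_width)
      sel <- which(pos >= lo & pos <= hi - w)
      if (!length(sel)) next
      disp <- pos[sel] + (w - 1) / 2 - center
      best <- order(-score[sel], abs(disp))[1L]
      per_roi[[k]] <- data.frame(
        roi_id = rois$name[i], motif_id = p$motif_id,
        position = pos[sel], strand = strand[sel], score = score[sel],
        displacement = disp, best = seq_along(sel) == best
      )
    }
    res[[chrom]] <- do.call(rbind, per_roi)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(roi_id = character(), motif_id = character(),
                      position = integer(), strand = character(),
                      score = numeric(), displacement = numeric(),
                      best = logical())
  }
  rownames(out) <- NULL
  out
}

#' Motif displacement distribution
#'
#' Histogram of all hit displacements over `[-half_width, half_width]`,
#' normalized to sum to 1 across bins (the column of a motif-displacement
#' heat map).
#'
#' @param hits Hit data.frame from [hits_around_centers()].
#' @param n_bins Number of bins (even, `>= 2`).
#' @param half_width Histogram half-range (bases).
#' @return List: `motif_id`, `bin_edges` (length `n_bins + 1`),
#'   `fractions` (length `n_bins`; all zero with `has_hits = FALSE` when
#'   no hits).
#' @export
md_distribution <- function(hits, n_bins = 100L, half_width = 1500L) {
  stopifnot(n_bins >= 2L, n_bins %% 2L == 0L)
  edges <- seq(-half_width, half_width, length.out = n_bins + 1L)
  motif_id <- if (nrow(hits)) hits$motif_id[1L] else NA_character_
  d <- hits$displacement
  d <- d[d >= -half_width & d <= half_width]
  if (!length(d)) {
    return(list(motif_id = motif_id, bin_edges = edges,
                fractions = rep(0, n_bins), has_hits = FALSE))
  }
  idx <- pmin(pmax(findInterval(d, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  list(motif_id = motif_id, bin_edges = edges,
       fractions = counts / sum(counts), has_hits = TRUE)
}

#' Rank-weighted motif enrichment score
#'
#' With ROIs ranked 1..N (rank 1 = most significant upregulation) and at
#' most one best hit per ROI, the normalized rank is
#' `r_i = (i - 0.5) / N` and each hit-bearing ROI gets weight
#' `w_i = exp(-|displacement_i| / sigma)`. The score is
#' `e = sum(w_i * (1 - 2 r_i)) / sum(w_i)`, bounded in `[-1, 1]`:
#' positive when motif hits near centers concentrate at the top of the
#' ranking, negative at the bottom, 0 when hits spread evenly (or when
#' there are no hits, flagged via `n_hit_rois = 0`).
#'
#' @param ranked_ids Character vector of ROI ids in rank order.
#' @param best_hits data.frame with `roi_id` and `displacement` (best hit
#'   per ROI; extra rows with `best == FALSE` are dropped if present).
#' @param sigma Displacement decay scale in bases.
#' @return List: `e_raw`, `n_hit_rois`.
#' @export
enrichment_score <- function(ranked_ids, best_hits, sigma = 150) {
  n <- length(ranked_ids)
  if (n < 10L) stop("need >= 10 ranked ROIs for a stable score")
  stopifnot(sigma > 0)
  bh <- as.data.frame(best_hits)
  if ("best" %in% names(bh)) bh <- bh[bh$best, , drop = FALSE]
  if (anyDuplicated(bh$roi_id)) stop("more than one best hit per ROI")
  idx <- match(bh$roi_id, ranked_ids)
  bh <- bh[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(list(e_raw = 0, n_hit_rois = 0L))
  r <- (idx - 0.5) / n
  w <- exp(-abs(bh$displacement) / sigma)
  list(e_raw = sum(w * (1 - 2 * r)) / sum(w), n_hit_rois = length(idx))
}

#' GC-content correction of enrichment scores
#'
#' Ordinary least squares of `e_raw` on motif GC fraction across the
#' motif set; the corrected score is the residual. With (near-)constant
#' GC the correction degenerates to mean-centering; with fewer than 5
#' motifs no correction is applied (warning).
#'
#' @param results data.frame with `motif_id`, `e_raw`, `gc_fraction`.
#' @return `results` with an `e_corrected` column.
#' @export
gc_correct <- function(results) {
  results <- as.data.frame(results)
  n <- nrow(results)
  if (n < 5L) {
    warning("fewer than 5 motifs; skipping GC correction")
    results$e_corrected <- results$e_raw
    return(results)
  }
  if (stats::var(results$gc_fraction) < 1e-6) {
    results$e_corrected <- results$e_raw - mean(results$e_raw)
    return(results)
  }
  fit <- stats::lm(e_raw ~ gc_fraction, data = results)
  results$e_corrected <- stats::residuals(fit)
  results
}

#' Motif p-values by Z score or rank permutation
#'
#' Z mode standardizes `e_corrected` across the motif set and applies a
#' two-sided normal p-value. Permutation mode shuffles the ROI ranking
#' `n_perm` times (one shared set of permutations, fixed by `seed`),
#' recomputes each motif's raw score, and reports the two-sided empirical
#' p with add-one smoothing. BH adjusts across motifs in both modes.
#'
#' @param results data.frame with `motif_id`, `e_raw`, `e_corrected`,
#'   `n_hit_rois`.
#' @param ranked_ids ROI ids in rank order (permutation mode).
#' @param best_hits_list Named list (by motif id) of best-hit data.frames
#'   (permutation mode).
#' @param mode `"z"` or `"permutation"`.
#' @param n_perm Number of permutations (`>= 100`).
#' @param seed Integer seed fixing the permutations.
#' @param sigma Displacement decay scale (must match the scores).
#' @return `results` with `z`, `pvalue`, `padj` columns.
#' @export
motif_pvalues <- function(results, ranked_ids = NULL,
                          best_hits_list = NULL,
                          mode = c("z", "permutation"), n_perm = 200L,
                          seed = 1L, sigma = 150) {
  mode <- match.arg(mode)
  results <- as.data.frame(results)
  if (mode == "z") {
    s <- stats::sd(results$e_corrected)
    if (!is.finite(s) || s == 0) {
      stop("zero spread across motifs; Z mode unavailable, ",
           "use mode = 'permutation'")
    }
    results$z <- (results$e_corrected - mean(results$e_corrected)) / s
    results$pvalue <- pmax(2 * stats::pnorm(-abs(results$z)), 1e-300)
  } else {
    stopifnot(n_perm >= 100L, !is.null(ranked_ids),
              !is.null(best_hits_list))
    n <- length(ranked_ids)
    set.seed(seed)
    perms <- vapply(seq_len(n_perm), function(i) sample.int(n),
                    integer(n))
    pv <- numeric(nrow(results))
    for (k in seq_len(nrow(results))) {
      bh <- best_hits_list[[results$motif_id[k]]]
      if (is.null(bh)) bh <- data.frame(roi_id = character(),
                                        displacement = numeric())
      bh <- as.data.frame(bh)
      if ("best" %in% names(bh)) bh <- bh[bh$best, , drop = FALSE]
      idx <- match(bh$roi_id, ranked_ids)
      keep <- !is.na(idx)
      idx <- idx[keep]
      if (!length(idx)) { pv[k] <- 1; next }
      w <- exp(-abs(bh$displacement[keep]) / sigma)
      e_obs <- sum(w * (1 - 2 * (idx - 0.5) / n)) / sum(w)
      # permuted rank of hit i is perms[idx[i], j] for permutation j
      pr <- perms[idx, , drop = FALSE]
      e_perm <- colSums(w * (1 - 2 * (pr - 0.5) / n)) / sum(w)
      pv[k] <- (1 + sum(abs(e_perm) >= abs(e_obs) - 1e-12)) / (n_perm + 1)
    }
    results$pvalue <- pv
    results$z <- stats::qnorm(pmax(pmin(1 - pv / 2, 1 - 1e-16), 0.5)) *
      sign(results$e_corrected)
  }
  results$padj <- pmax(stats::p.adjust(results$pvalue, "BH"),
                       results$pvalue)
  results
}

#' Full motif enrichment analysis for one ranking
#'
#' Convenience wrapper: scans every motif around the ranked ROI centers,
#' computes raw scores, GC-corrects across the motif set, and attaches
#' p-values.
#'
#' @param genome Named character vector of sequences.
#' @param rois ROI data.frame with `chrom`, `center`, `name`.
#' @param ranked_ids ROI ids in rank order (must all exist in `rois`).
#' @param pwms List of [pwm] objects.
#' @param half_width,p_cutoff,sigma Scan and scoring parameters.
#' @param mode,n_perm,seed Passed to [motif_pvalues()].
#' @return List: `results` (per-motif enrichment table), `hits` (all
#'   hits), `md` (bin x motif fraction matrix).
#' @export
run_tfea <- function(genome, rois, ranked_ids, pwms, half_width = 1500L,
                     p_cutoff = 1e-5, sigma = 150, mode = "z",
                     n_perm = 200L, seed = 1L) {
  hits_all <- list()
  best_list <- list()
  rows <- list()
  mdm <- NULL
  coded <- lapply(genome[unique(as.data.frame(rois)$chrom)], encode_dna)
  for (p in pwms) {
    h <- hits_around_centers(genome, rois, p, half_width,
                             p_cutoff = p_cutoff, coded = coded)
    hits_all[[p$motif_id]] <- h
    best <- h[h$best, , drop = FALSE]
    best_list[[p$motif_id]] <- best
    es <- enrichment_score(ranked_ids, best, sigma)
    rows[[p$motif_id]] <- data.frame(
      motif_id = p$motif_id, e_raw = es$e_raw,
      gc_fraction = p$gc_fraction, n_hit_rois = es$n_hit_rois
    )
    md <- md_distribution(h, half_width = half_width)
    if (is.null(mdm)) {
      mdm <- matrix(0, nrow = length(md$fractions), ncol = 0)
    }
    mdm <- cbind(mdm, md$fractions)
    colnames(mdm)[ncol(mdm)] <- p$motif_id
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  results <- gc_correct(results)
  results <- motif_pvalues(results, ranked_ids, best_list, mode = mode,
                           n_perm = n_perm, seed = seed, sigma = sigma)
  list(results = results, hits = do.call(rbind, hits_all), md = mdm)
}
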