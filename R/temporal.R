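# Temporal clustering of induction responses across a three-point time
# course (vehicle, early, late) from the three pairwise contrasts.

#' Classify features into temporal induction clusters
#'
#' Using contrasts early-vs-vehicle (`d30v0`), late-vs-vehicle
#' (`d120v0`) and late-vs-early (`d120v30`), with "up"/"down" meaning
#' significant (`padj < alpha`) with positive/negative `log2fc`:
#'
#' * `early_peak`: up at 30 vs 0 AND down at 120 vs 30;
#' * `early_plateau`: up at 30 vs 0 AND up at 120 vs 0 AND NOT down at
#'   120 vs 30;
#' * `late`: up at 120 vs 0 AND up at 120 vs 30;
#' * otherwise `unclassified`.
#'
#' The raw cluster definitions can overlap; precedence
#' `early_peak > early_plateau > late` (plus the NOT-down guard on
#' plateau) makes labels mutually exclusive. Only induction clusters are
#' labelled by default; `mirror = TRUE` classifies repression symmetric-ly
#' (swap up/down throughout).
#'
#' @param d30v0,d120v0,d120v30 Differential records (`feature_id`,
#'   `log2fc`, `padj`) for the three contrasts; all features must appear
#'   in all three.
#' @param alpha Adjusted-p significance cutoff in (0, 1).
#' @param mirror Classify downregulation clusters instead.
#' @return data.frame: `feature_id`, `label`, and the six evidence
#'   columns `lfc_30v0`, `padj_30v0`, `lfc_120v0`, `padj_120v0`,
#'   `lfc_120v30`, `padj_120v30`.
#' @export
classify_transcript_clusters <- function(d30v0, d120v0, d120v30,
                                         alpha = 0.05, mirror = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  d1 <- as.data.frame(d30v0); d2 <- as.data.frame(d120v0)
  d3 <- as.data.frame(d120v30)
  ids <- d1$feature_id
  for (d in list(d2, d3)) {
    miss <- setdiff(ids, d$feature_id)
    miss2 <- setdiff(d$feature_id, ids)
    if (length(miss) || length(miss2)) {
      stop("contrast missing feature(s): ",
           paste(utils::head(c(miss, miss2), 5L), collapse = ", "))
    }
  }
  d2 <- d2[match(ids, d2$feature_id), ]
  d3 <- d3[match(ids, d3$feature_id), ]
  sgn <- if (mirror) -1 else 1
  up <- function(d) d$padj < alpha & sgn * d$log2fc > 0
  down <- function(d) d$padj < alpha & sgn * d$log2fc < 0
  early_peak <- up(d1) & down(d3)
  early_plateau <- up(d1) & up(d2) & !down(d3)
  late <- up(d2) & up(d3)
  label <- rep("unclassified", length(ids))
  label[late] <- "late"
  label[early_plateau] <- "early_plateau"
  label[early_peak] <- "early_peak"
  data.frame(
    feature_id = ids, label = label,
    lfc_30v0 = d1$log2fc, padj_30v0 = d1$padj,
    lfc_120v0 = d2$log2fc, padj_120v0 = d2$padj,
    lfc_120v30 = d3$log2fc, padj_120v30 = d3$padj,
    row.names = NULL
  )
}

#' Classify accessibility peaks by presence/absence across time points
#'
#' Consensus peaks are the merged union of all three sets; presence at a
#' time point means an overlap of at least `min_overlap` bases with any
#' peak called there. Labels: `early_peak` = present only at 30,
#' `early_plateau` = absent in vehicle, present at 30 and 120, `late` =
#' present only at 120; anything else `unclassified`.
#'
#' @param peaks_veh,peaks_30,peaks_120 [gintervals] peak sets.
#' @param min_overlap Minimum overlap in bases (`>= 1`).
#' @return data.frame of consensus peaks with `label` and logical
#'   `present_veh`, `present_30`, `present_120`.
#' @export
classify_peak_clusters <- function(peaks_veh, peaks_30, peaks_120,
                                   min_overlap = 1L) {
  stopifnot(min_overlap >= 1)
  sets <- list(veh = as_gintervals(peaks_veh),
               t30 = as_gintervals(peaks_30),
               t120 = as_gintervals(peaks_120))
  pooled <- do.call(rbind, lapply(sets, function(s)
    as.data.frame(s)[, c("chrom", "start", "end")]))
  if (nrow(pooled) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      present_veh = logical(), present_30 = logical(),
                      present_120 = logical()))
  }
  consensus <- merge_intervals(as_gintervals(pooled), gap = 0L)
  pres <- vapply(sets, function(s)
    overlaps_by(consensus, s, min_overlap), logical(nrow(consensus)))
  pres <- matrix(pres, nrow = nrow(consensus),
                 dimnames = list(NULL, names(sets)))
  label <- rep("unclassified", nrow(consensus))
  label[!pres[, "veh"] & pres[, "t30"] & !pres[, "t120"]] <- "early_peak"
  label[!pres[, "veh"] & pres[, "t30"] & pres[, "t120"]] <- "early_plateau"
  label[!pres[, "veh"] & !pres[, "t30"] & pres[, "t120"]] <- "late"
  data.frame(
    chrom = consensus$chrom, start = consensus$start, end = consensus$end,
    label = label,
    present_veh = pres[, "veh"], present_30 = pres[, "t30"],
    present_120 = pres[, "t120"], row.names = NULL
  )
}

# TRUE per query interval when any subject interval overlaps >= min_ov bases
overlaps_by <- function(query, subject, min_ov) {
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  q <- data.table::data.table(chrom = query$chrom, start = query$start,
                              end = query$end, qidx = seq_len(nrow(query)))
  s <- data.table::data.table(chrom = subject$chrom, start = subject$start,
                              end = subject$end)
  data.table::setkey(s, chrom, start, end)
  ov <- data.table::foverlaps(q, s, type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) return(rep(FALSE, nrow(query)))
  ov[, bases := pmin(end, i.end) - pmax(start, i.start)]
  hit <- unique(ov[bases >= min_ov, qidx])
  seq_len(nrow(query)) %in% hit
}

#' Flag features for volcano-plot significance
#'
#' @param records Differential records.
#' @param alpha Adjusted-p cutoff.
#' @param lfc_min Absolute log2 fold-change gate (strict `>`).
#' @return Character vector, `"both"` when `padj < alpha` and
#'   `|log2fc| > lfc_min`, else `"other"`.
#' @export
volcano_flags <- function(records, alpha = 0.05, lfc_min = 1) {
  stopifnot(alpha > 0, alpha < 1, lfc_min >= 0)
  records <- as.data.frame(records)
  ifelse(records$padj < alpha & abs(records$log2fc) > lfc_min,
         "both", "other")
}
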