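#' @useDynLib tfdynamics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# All coordinates in this package are 0-based half-open (BED convention).
# 1-based formats are converted at the I/O boundary, never internally.

VALID_STRANDS <- c("+", "-", ".")

#' Construct a set of genomic intervals
#'
#' Intervals are plain data.frames (class `gintervals`) with BED-style
#' columns `chrom`, `start`, `end`, `name`, `score`, `strand`, using 0-based
#' half-open coordinates throughout.
#'
#' @param chrom Chromosome names (non-empty character).
#' @param start 0-based start positions (`start >= 0`).
#' @param end Exclusive end positions (`end > start`).
#' @param name Optional labels; default `"."`.
#' @param score Optional numeric scores; default 0.
#' @param strand One of `"+"`, `"-"`, `"."`; default `"."`.
#' @return A `gintervals` data.frame.
#' @export
#' @examples
#' gintervals("chr1", c(100, 300), c(200, 400))
gintervals <- function(chrom, start, end, name = ".", score = 0, strand = ".") {
  x <- data.table(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand)
  )
  validate_gintervals(x)
  setDF(x)
  class(x) <- c("gintervals", "data.frame")
  x
}

validate_gintervals <- function(x, context = "intervals") {
  if (nrow(x) == 0L) return(invisible(x))
  bad <- which(is.na(x$chrom) | !nzchar(x$chrom))
  if (length(bad)) stop(context, ": empty chromosome name at row ", bad[1L])
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0L | x$end <= x$start)
  if (length(bad)) {
    stop(context, ": invalid coordinates at row ", bad[1L],
         " (need 0 <= start < end; got start=", x$start[bad[1L]],
         ", end=", x$end[bad[1L]], ")")
  }
  bad <- which(!x$strand %in% VALID_STRANDS)
  if (length(bad)) stop(context, ": invalid strand at row ", bad[1L])
  invisible(x)
}

as_gintervals <- function(x) {
  x <- as.data.frame(x)
  if (is.null(x$name)) x[["name"]] <- rep(".", nrow(x))
  if (is.null(x$score)) x[["score"]] <- rep(0, nrow(x))
  if (is.null(x$strand)) x[["strand"]] <- rep(".", nrow(x))
  class(x) <- c("gintervals", "data.frame")
  x
}

#' Read a BED3-BED6 file
#'
#' Lines beginning with `#`, `track` or `browser` are skipped. Missing
#' columns take defaults (`name = "."`, `score = 0`, `strand = "."`).
#'
#' @param path Path to a BED file.
#' @return A [gintervals] data.frame in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(gintervals(character(), integer(), integer()))
  }
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(fields) < 3L) {
    stop("BED parse error at line ", lineno[1L], ": fewer than 3 columns")
  }
  start <- suppressWarnings(as.integer(fields[[2L]]))
  end <- suppressWarnings(as.integer(fields[[3L]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1L]],
         ": non-integer coordinates")
  }
  bad <- which(end <= start | start < 0L)
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1L]],
         ": end <= start or negative start")
  }
  n <- length(lines)
  name <- if (length(fields) >= 4L) fields[[4L]] else rep(".", n)
  name[is.na(name)] <- "."
  score <- if (length(fields) >= 5L) {
    suppressWarnings(as.numeric(fields[[5L]]))
  } else rep(0, n)
  score[is.na(score)] <- 0
  strand <- if (length(fields) >= 6L) fields[[6L]] else rep(".", n)
  strand[is.na(strand) | !strand %in% VALID_STRANDS] <- "."
  gintervals(fields[[1L]], start, end, name, score, strand)
}

#' Write intervals as BED6
#'
#' Round-trips with [read_bed()] field-for-field.
#'
#' @param x A [gintervals] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_gintervals(x)
  validate_gintervals(x)
  out <- data.table(
    chrom = x$chrom, start = x$start, end = x$end,
    name = x$name, score = x$score, strand = x$strand
  )
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge intervals closer than a gap
#'
#' Intervals on the same chromosome separated by at most `gap` bases
#' (half-open: `next_start - prev_end <= gap`) are unioned, transitively.
#' Strand is ignored; the default `gap = 60` matches common practice for
#' aggregating bidirectional calls across samples.
#'
#' @param x A [gintervals] data.frame.
#' @param gap Maximum separation (bases, `>= 0`) still merged.
#' @return Merged [gintervals], sorted by `(chrom, start)`, with `name`
#'   the count of member intervals stored in `score`.
#' @export
merge_intervals <- function(x, gap = 60L) {
  stopifnot(gap >= 0)
  x <- as_gintervals(x)
  validate_gintervals(x)
  if (nrow(x) == 0L) return(gintervals(character(), integer(), integer()))
  dt <- as.data.table(x)[, .(chrom, start, end)]
  setorder(dt, chrom, start, end)
  dt[, grp := {
    cm <- cummax(shift(end, fill = end[1L]))
    cumsum(start > cm + gap)
  }, by = chrom]
  out <- dt[, .(start = min(start), end = max(end), n = .N),
            by = .(chrom, grp)]
  setorder(out, chrom, start)
  gintervals(out$chrom, out$start, out$end, score = out$n)
}

#' Build consensus regions of interest across samples
#'
#' Per-sample calls (each with a `center`) that overlap or lie within `gap`
#' bases of each other are unioned into one consensus ROI. The consensus
#' center is the support-weighted mean of member centers, rounded down
#' (ties at .5 fall to the lower coordinate), and support counts the
#' contributing calls. This is a deliberately simple stand-in for
#' probabilistic consensus tools: with jittered per-sample calls around a
#' true origin it recovers the origin to within the jitter scale.
#'
#' @param roi_sets Named list (one element per sample) of ROI data.frames
#'   with columns `chrom`, `start`, `end`, `center` and optionally
#'   `support` (default 1 per call).
#' @param gap Maximum separation merged (bases).
#' @return A data.frame of class `rois`: `chrom`, `start`, `end`,
#'   `center`, `support`, `name`, sorted by `(chrom, start)`.
#' @export
consensus_rois <- function(roi_sets, gap = 60L) {
  stopifnot(is.list(roi_sets), gap >= 0)
  pooled <- rbindlist(lapply(roi_sets, function(r) {
    r <- as.data.table(as.data.frame(r))
    if (is.null(r$support)) r$support <- 1L
    stopifnot(all(r$start <= r$center), all(r$center < r$end))
    r[, .(chrom, start, end, center, support)]
  }))
  if (nrow(pooled) == 0L) {
    return(new_rois(data.table(chrom = character(), start = integer(),
                               end = integer(), center = integer(),
                               support = integer())))
  }
  setorder(pooled, chrom, start, end)
  pooled[, grp := {
    cm <- cummax(shift(end, fill = end[1L]))
    cumsum(start > cm + gap)
  }, by = chrom]
  out <- pooled[, .(
    start = min(start), end = max(end),
    center = as.integer(floor(sum(as.numeric(center) * support) / sum(support))),
    support = sum(support)
  ), by = .(chrom, grp)][, grp := NULL]
  setorder(out, chrom, start)
  new_rois(out)
}

new_rois <- function(dt) {
  dt <- as.data.table(dt)
  dt[, name := sprintf("roi_%05d", seq_len(.N))]
  setDF(dt)
  class(dt) <- c("rois", "data.frame")
  dt
}

#' Count reads overlapping regions
#'
#' A read counts toward every region it overlaps by at least one base
#' (half-open arithmetic); strand is ignored by default. Reads on
#' chromosomes absent from `regions` contribute nothing (with a warning).
#'
#' @param reads A data.frame of stranded reads: `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`) and `sample` (sample label).
#' @param regions A [gintervals] data.frame; feature ids come from `name`
#'   when non-trivial, else `chrom:start-end`.
#' @param samples Optional character vector fixing column order (defaults
#'   to sorted unique `reads$sample`).
#' @param stranded If `TRUE`, only reads matching the region strand count.
#' @return A [count_matrix].
#' @export
count_reads_in_regions <- function(reads, regions, samples = NULL,
                                   stranded = FALSE) {
  regions <- as_gintervals(regions)
  validate_gintervals(regions)
  reads <- as.data.table(as.data.frame(reads))
  stopifnot(all(c("chrom", "start", "end", "strand", "sample") %in%
                  names(reads)))
  if (nrow(reads) && !all(reads$strand %in% c("+", "-"))) {
    stop("reads must be stranded (+ or -)")
  }
  if (is.null(samples)) samples <- sort(unique(reads$sample))
  feat_id <- ifelse(is.na(regions$name) | regions$name == ".",
                    sprintf("%s:%d-%d", regions$chrom, regions$start,
                            regions$end),
                    regions$name)
  counts <- matrix(0L, nrow = nrow(regions), ncol = length(samples),
                   dimnames = list(feat_id, samples))
  if (nrow(reads)) {
    unknown <- setdiff(unique(reads$chrom), unique(regions$chrom))
    if (length(unknown)) {
      warning("reads on chromosome(s) absent from regions counted as zero: ",
              paste(unknown, collapse = ", "))
    }
    reg <- data.table(chrom = regions$chrom, start = regions$start,
                      end = regions$end - 1L, ridx = seq_len(nrow(regions)),
                      rstrand = regions$strand)
    rd <- reads[, .(chrom, start, end = end - 1L, strand, sample)]
    setkey(reg, chrom, start, end)
    ov <- foverlaps(rd, reg, type = "any", nomatch = NULL)
    if (stranded) ov <- ov[rstrand == "." | rstrand == strand]
    if (nrow(ov)) {
      tab <- ov[, .N, by = .(ridx, sample)]
      tab <- tab[sample %in% samples]
      counts[cbind(tab$ridx, match(tab$sample, samples))] <- tab$N
    }
  }
  count_matrix(counts, data.frame(sample = samples))
}

#' Construct a count matrix with sample metadata
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @param sample_info data.frame with one row per column of `counts`;
#'   must contain `sample` and may carry `condition` and `time` labels.
#' @return An object of class `count_matrix` (list with `counts` and
#'   `samples`).
#' @export
count_matrix <- function(counts, sample_info) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0L)) {
    stop("counts must be non-negative integers")
  }
  sample_info <- as.data.frame(sample_info)
  if (!"sample" %in% names(sample_info)) stop("sample_info needs a 'sample' column")
  if (nrow(sample_info) != ncol(counts)) {
    stop("sample_info rows (", nrow(sample_info),
         ") must match count columns (", ncol(counts), ")")
  }
  if (is.null(colnames(counts))) colnames(counts) <- sample_info$sample
  if (!identical(colnames(counts), as.character(sample_info$sample))) {
    stop("column names of counts must equal sample_info$sample")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("feature_%05d", seq_len(nrow(counts)))
  }
  structure(list(counts = counts, samples = sample_info),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  if ("condition" %in% names(x$samples)) {
    cat("conditions:", paste(unique(x$samples$condition), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write / read a count matrix with a JSON sample-metadata sidecar
#'
#' The matrix is tab-separated with a `# feature_id` header line; sample
#' metadata goes to `<path>.samples.json`.
#'
#' @param x A [count_matrix].
#' @param path Output path for the matrix.
#' @return `path` invisibly ([write_count_matrix()]); a [count_matrix]
#'   ([read_count_matrix()]).
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  dt <- data.table(feature_id = rownames(x$counts))
  for (j in colnames(x$counts)) dt[[j]] <- x$counts[, j]
  header <- paste0("#", paste(names(dt), collapse = "\t"))
  writeLines(header, path)
  fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  jsonlite::write_json(x$samples, paste0(path, ".samples.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  dt <- fread(path, sep = "\t", skip = 1L, header = FALSE,
              col.names = cols)
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  info <- jsonlite::read_json(paste0(path, ".samples.json"),
                              simplifyVector = TRUE)
  count_matrix(m, info)
}
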