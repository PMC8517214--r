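# Strand-resolved binned coverage. Nascent run-on reads are reduced to
# their 5' end (the polymerase position); each read lands in exactly one
# bin on its own strand.

#' Construct a coverage track
#'
#' @param chrom Chromosome name.
#' @param bin_size Bases per bin (`>= 1`).
#' @param values_plus,values_minus Non-negative per-bin signal, equal
#'   length. For unstranded data put everything on `values_plus` and pass
#'   zeros for `values_minus`.
#' @param normalized Logical; `TRUE` when values are reads-per-million.
#' @param library_size Total mapped reads behind the track.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(chrom, bin_size, values_plus, values_minus,
                           normalized = FALSE, library_size = NA_real_) {
  stopifnot(length(chrom) == 1L, bin_size >= 1,
            length(values_plus) == length(values_minus),
            all(values_plus >= 0), all(values_minus >= 0))
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 values_plus = as.numeric(values_plus),
                 values_minus = as.numeric(values_minus),
                 normalized = isTRUE(normalized),
                 library_size = library_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track", x$chrom, "-", length(x$values_plus), "bins x",
      x$bin_size, "bp,", if (x$normalized) "RPM" else "raw", "\n")
  invisible(x)
}

track_values <- function(track) track$values_plus + track$values_minus

bin_centers <- function(track) {
  (seq_along(track$values_plus) - 0.5) * track$bin_size
}

#' Build strand-resolved 5'-end coverage from reads
#'
#' Each read contributes its 5' end (start for `+`, `end - 1` for `-`)
#' to one bin on its strand; values are scaled to reads per million using
#' `library_size`.
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand`.
#' @param bin_size Bases per bin.
#' @param library_size Total mapped reads (`> 0`); defaults to
#'   `nrow(reads)`.
#' @param chrom_lengths Optional named vector fixing track extents.
#' @return Named list of [coverage_track] objects, one per chromosome.
#' @export
build_coverage <- function(reads, bin_size = 15L, library_size = NULL,
                           chrom_lengths = NULL) {
  reads <- as.data.frame(reads)
  if (is.null(library_size)) library_size <- nrow(reads)
  if (is.na(library_size) || library_size <= 0) {
    stop("library_size must be > 0")
  }
  stopifnot(all(reads$strand %in% c("+", "-")))
  pos5 <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  dt <- data.table::data.table(chrom = reads$chrom, pos = pos5,
                               strand = reads$strand)
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    sort(unique(dt$chrom))
  scale <- 1e6 / library_size
  out <- lapply(chroms, function(ch) {
    sub <- dt[chrom == ch]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      if (nrow(sub)) max(sub$pos) + 1L else bin_size
    nbin <- ceiling(len / bin_size)
    vp <- tabulate(sub[strand == "+", pos] %/% bin_size + 1L, nbins = nbin)
    vm <- tabulate(sub[strand == "-", pos] %/% bin_size + 1L, nbins = nbin)
    coverage_track(ch, bin_size, vp * scale, vm * scale,
                   normalized = TRUE, library_size = library_size)
  })
  names(out) <- chroms
  out
}

#' Export a coverage track as bedGraph
#'
#' Writes one file per strand suffix when the track is stranded.
#'
#' @param track A [coverage_track].
#' @param path Output path (strand suffixes `.pos`/`.neg` are appended
#'   before the extension when both strands carry signal).
#' @return Paths written, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  write_one <- function(values, p) {
    nz <- which(values != 0)
    dt <- data.table::data.table(
      chrom = track$chrom,
      start = (nz - 1L) * track$bin_size,
      end = nz * track$bin_size,
      value = values[nz]
    )
    writeLines(paste0("#chrom\tstart\tend\tvalue"), p)
    data.table::fwrite(dt, p, sep = "\t", col.names = FALSE, append = TRUE)
    p
  }
  if (any(track$values_minus != 0)) {
    p1 <- sub("(\\.[^.]*)?$", ".pos\\1", path)
    p2 <- sub("(\\.[^.]*)?$", ".neg\\1", path)
    invisible(c(write_one(track$values_plus, p1),
                write_one(track$values_minus, p2)))
  } else {
    invisible(write_one(track$values_plus, path))
  }
}
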