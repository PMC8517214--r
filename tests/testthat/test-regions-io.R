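test_that("read_bed parses BED3-BED6 and rejects malformed lines", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "chr1\t100\t200",
               "chr1\t100\t200\tx\t0\t-"), f)
  x <- read_bed(f)
  expect_equal(x$chrom, c("chr1", "chr1"))
  expect_equal(x$start, c(100L, 100L))
  expect_equal(x$end, c(200L, 200L))
  expect_equal(x$strand, c(".", "-"))
  expect_equal(x$name, c(".", "x"))

  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines("chr1\tabc\t200", f)
  expect_error(read_bed(f), "non-integer")
})

test_that("gintervals validates its invariants", {
  expect_error(gintervals("chr1", -1, 5), "invalid coordinates")
  expect_error(gintervals("chr1", 5, 5), "invalid coordinates")
  expect_error(gintervals("", 1, 5), "empty chromosome")
  expect_error(gintervals("chr1", 1, 5, strand = "x"), "strand")
  expect_silent(gintervals(character(), integer(), integer()))
})

test_that("write_bed/read_bed round-trips random intervals exactly", {
  set.seed(101)
  x <- random_intervals(100)
  f <- withr::local_tempfile()
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(as.data.frame(y), as.data.frame(x))
  write_bed(gintervals(character(), integer(), integer()), f)
  expect_equal(nrow(read_bed(f)), 0L)
})

test_that("merge_intervals honors the gap rule at the boundary", {
  a <- merge_intervals(gintervals("chr1", c(100, 250), c(200, 300)),
                       gap = 60)
  expect_equal(nrow(a), 1L)
  expect_equal(c(a$start, a$end), c(100L, 300L))
  b <- merge_intervals(gintervals("chr1", c(100, 261), c(200, 300)),
                       gap = 60)
  expect_equal(nrow(b), 2L)
})

test_that("merge_intervals equals the brute-force oracle and is idempotent", {
  set.seed(7)
  for (rep in 1:5) {
    x <- random_intervals(60)
    strip <- function(m) {
      out <- as.data.frame(m)[, c("chrom", "start", "end")]
      out$start <- as.integer(out$start); out$end <- as.integer(out$end)
      class(out) <- "data.frame"
      out
    }
    for (gap in c(0, 60, 500)) {
      got <- merge_intervals(x, gap)
      want <- brute_merge(x, gap)
      want$start <- as.integer(want$start)
      want$end <- as.integer(want$end)
      expect_equal(strip(got), want)
      expect_equal(strip(merge_intervals(got, gap)), want)
      # order invariance
      perm <- x[sample.int(nrow(x)), , drop = FALSE]
      expect_equal(strip(merge_intervals(perm, gap)), want)
    }
  }
})

test_that("consensus_rois averages centers weighted by support", {
  r1 <- data.frame(chrom = "chr1", start = 900, end = 1100, center = 1000)
  r2 <- data.frame(chrom = "chr1", start = 910, end = 1110, center = 1010)
  cc <- consensus_rois(list(s1 = r1, s2 = r2), gap = 60)
  expect_equal(cc$center, 1005L)
  expect_equal(cc$support, 2L)
  expect_equal(cc$start, 900L)
  expect_equal(cc$end, 1110L)
  # single sample: identity with support 1
  one <- consensus_rois(list(s1 = r1), gap = 60)
  expect_equal(one$center, 1000L)
  expect_equal(one$support, 1L)
  # .5 ties round down
  r3 <- data.frame(chrom = "chr1", start = 900, end = 1100, center = 1001)
  tie <- consensus_rois(list(a = r1, b = r3), gap = 0)
  expect_equal(tie$center, 1000L)
})

test_that("consensus_rois recovers jittered origins near the truth", {
  set.seed(11)
  truth <- sort(sample(seq(5000L, 995000L, by = 4000L), 50L))
  jitter_sd <- 40
  sets <- lapply(1:3, function(s) {
    centers <- as.integer(round(truth + stats::rnorm(50, 0, jitter_sd)))
    data.frame(chrom = "chrS", start = centers - 500L,
               end = centers + 500L, center = centers)
  })
  names(sets) <- paste0("s", 1:3)
  cc <- consensus_rois(sets, gap = 60)
  expect_equal(nrow(cc), 50L)
  expect_true(all(abs(cc$center - truth) <= 3 * jitter_sd / sqrt(3)))
  expect_true(all(cc$support == 3L))
  # identical replicates reproduce single-sample centers
  dup <- consensus_rois(list(a = sets[[1]], b = sets[[1]]), gap = 60)
  expect_equal(dup$center, sort(sets[[1]]$center))
})

test_that("count_reads_in_regions uses half-open >=1-base overlap", {
  regions <- gintervals("chr1", 100, 200, name = "r1")
  mk <- function(start, end) data.frame(chrom = "chr1", start = start,
                                        end = end, strand = "+",
                                        sample = "s1")
  expect_equal(unname(count_reads_in_regions(mk(150, 180), regions)$counts[1, 1]), 1L)
  expect_equal(unname(count_reads_in_regions(mk(199, 250), regions)$counts[1, 1]), 1L)
  expect_equal(unname(count_reads_in_regions(mk(200, 250), regions)$counts[1, 1]), 0L)
  expect_warning(count_reads_in_regions(
    data.frame(chrom = "chrX", start = 1, end = 10, strand = "-",
               sample = "s1"), regions), "absent")
})

test_that("read counts are conserved over a disjoint tiling", {
  set.seed(13)
  reads <- data.frame(chrom = "chr1",
                      start = sample.int(900L, 400L, replace = TRUE),
                      end = 0L, strand = sample(c("+", "-"), 400L, TRUE),
                      sample = sample(c("s1", "s2"), 400L, TRUE))
  reads$end <- reads$start + 20L
  tiles <- gintervals("chr1", seq(0L, 900L, by = 100L),
                      seq(100L, 1000L, by = 100L))
  cm <- count_reads_in_regions(reads, tiles)
  whole <- count_reads_in_regions(reads, gintervals("chr1", 0L, 1000L))
  # a read overlapping a tile boundary counts in both tiles
  boundary <- sapply(c("s1", "s2"), function(s) {
    r <- reads[reads$sample == s, ]
    sum((r$start %/% 100L) != ((r$end - 1L) %/% 100L))
  })
  expect_equal(colSums(cm$counts), whole$counts[1, ] + boundary)
})

test_that("count_matrix writes and reads back with its sidecar", {
  m <- matrix(0:5, 2, 3,
              dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  cm <- count_matrix(m, data.frame(sample = c("a", "b", "c"),
                                   condition = c("x", "x", "y")))
  f <- file.path(withr::local_tempdir(), "counts.tsv")
  write_count_matrix(cm, f)
  back <- read_count_matrix(f)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$samples$condition, c("x", "x", "y"))
  expect_error(count_matrix(m - 1L, data.frame(sample = c("a", "b", "c"))),
               "non-negative")
})
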