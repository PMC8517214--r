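test_that("hits_around_centers reports displacement from hit midpoint", {
  # motif embedded exactly at a center
  left <- random_dna(2000)
  word <- "ACGTACGG"
  set.seed(601)
  genome <- c(chrA = paste0(substr(left, 1, 996), word,
                            random_dna(1000)))
  # word occupies 0-based [996, 1004): midpoint 999.5 -> displacement -0.5
  rois <- data.frame(chrom = "chrA", center = 1000L, name = "r1")
  p <- word_pwm("w", word)
  h <- suppressWarnings(hits_around_centers(genome, rois, p,
                                            half_width = 500L))
  expect_gte(nrow(h), 1L)
  best <- h[h$best, ]
  expect_equal(best$position, 996L)
  expect_equal(best$displacement, -0.5)
  expect_error(hits_around_centers(genome,
                                   data.frame(chrom = "chrB",
                                              center = 10L, name = "x"),
                                   p), "chrB")
})

test_that("embedded displacement spread is recovered by the scanner", {
  cfg <- sim_config(seed = 603, genome_length = 3e6L)
  centers <- as.integer(seq(2000, 3e6 - 2000, length.out = 500))
  p <- word_pwm("t", "TGACGTCAT")
  gg <- generate_genome(cfg, centers, list(p), embed_prob = 1,
                        displacement_sd = 150)
  rois <- data.frame(chrom = "chrS", center = centers,
                     name = sprintf("r%03d", seq_along(centers)))
  h <- hits_around_centers(gg$genome, rois, p)
  best <- h[h$best, ]
  expect_gte(nrow(best), 450L)
  expect_lt(abs(stats::sd(best$displacement) - 150) / 150, 0.2)
})

test_that("md_distribution normalizes displacement histograms", {
  hits <- data.frame(motif_id = "m", displacement = rep(0, 7))
  md <- md_distribution(hits, n_bins = 100L)
  expect_equal(sum(md$fractions), 1)
  expect_equal(md$fractions[51], 1)  # displacement 0 falls in [0, 30)
  none <- md_distribution(hits[0, ], n_bins = 10L)
  expect_false(none$has_hits)
  expect_equal(none$fractions, rep(0, 10))
  set.seed(604)
  u <- data.frame(motif_id = "m",
                  displacement = stats::runif(10000, -1500, 1500))
  mdu <- md_distribution(u, n_bins = 10L)
  expect_equal(sum(mdu$fractions), 1, tolerance = 1e-9)
  expect_lte(max(mdu$fractions), 3 / 10)
  expect_error(md_distribution(hits, n_bins = 7L))
})

test_that("enrichment_score evaluates the stated formula", {
  ids <- sprintf("r%02d", 1:10)
  # hand evaluation at N = 10: hits with displacement 0 at ranks 1, 2
  bh <- data.frame(roi_id = ids[1:2], displacement = c(0, 0))
  es <- enrichment_score(ids, bh, sigma = 150)
  r <- (c(1, 2) - 0.5) / 10
  expect_equal(es$e_raw, mean(1 - 2 * r))
  expect_equal(es$n_hit_rois, 2L)
  # equal-weight hits everywhere -> 0 by symmetry
  all_bh <- data.frame(roi_id = ids, displacement = 0)
  expect_equal(enrichment_score(ids, all_bh)$e_raw, 0, tolerance = 1e-12)
  # reversal negates; relabeling invariance; bounds
  set.seed(605)
  some <- data.frame(roi_id = sample(ids, 5),
                     displacement = stats::rnorm(5, 0, 200))
  e1 <- enrichment_score(ids, some)$e_raw
  e2 <- enrichment_score(rev(ids), some)$e_raw
  expect_equal(e1, -e2)
  expect_true(abs(e1) <= 1)
  expect_equal(enrichment_score(ids, some)$e_raw, e1)
  # no hits -> 0 flagged; N < 10 errors
  expect_equal(enrichment_score(ids, some[0, ])$e_raw, 0)
  expect_error(enrichment_score(ids[1:4], some), ">= 10")
  expect_error(enrichment_score(ids, rbind(some, some)), "more than one")
})

test_that("gc_correct removes a linear GC trend", {
  res <- data.frame(motif_id = sprintf("m%d", 1:8),
                    gc_fraction = seq(0.2, 0.9, length.out = 8))
  res$e_raw <- 0.3 + 0.5 * res$gc_fraction
  out <- gc_correct(res)
  expect_equal(out$e_corrected, rep(0, 8), tolerance = 1e-12)
  # constant GC degenerates to mean-centering
  res2 <- res; res2$gc_fraction <- 0.5
  res2$e_raw <- stats::rnorm(8)
  out2 <- gc_correct(res2)
  expect_equal(out2$e_corrected, res2$e_raw - mean(res2$e_raw))
  # residuals sum to zero in the regression case
  res3 <- res; res3$e_raw <- res3$e_raw + stats::rnorm(8, 0, 0.1)
  expect_equal(sum(gc_correct(res3)$e_corrected), 0, tolerance = 1e-10)
  expect_warning(out4 <- gc_correct(res[1:3, ]), "fewer than 5")
  expect_equal(out4$e_corrected, out4$e_raw)
})

test_that("motif p-values: permutation mode is seeded and sane", {
  ids <- sprintf("r%03d", 1:100)
  set.seed(606)
  bhl <- list(
    top = data.frame(roi_id = ids[1:15], displacement = rnorm(15, 0, 50)),
    none = data.frame(roi_id = character(), displacement = numeric()),
    spread = data.frame(roi_id = sample(ids, 30),
                        displacement = rnorm(30, 0, 400))
  )
  res <- data.frame(motif_id = names(bhl),
                    e_raw = vapply(bhl, function(b)
                      enrichment_score(ids, b)$e_raw, numeric(1)))
  res$e_corrected <- res$e_raw
  res$n_hit_rois <- vapply(bhl, nrow, integer(1))
  p1 <- motif_pvalues(res, ids, bhl, mode = "permutation",
                      n_perm = 200, seed = 9)
  p2 <- motif_pvalues(res, ids, bhl, mode = "permutation",
                      n_perm = 200, seed = 9)
  expect_identical(p1$pvalue, p2$pvalue)  # bit-identical given the seed
  expect_equal(p1$pvalue[p1$motif_id == "none"], 1)
  expect_lt(p1$pvalue[p1$motif_id == "top"], 0.05)
  expect_true(all(p1$padj >= p1$pvalue))
  # Z mode requires spread
  flat <- res; flat$e_corrected <- 0.2
  expect_error(motif_pvalues(flat, mode = "z"), "permutation")
  pz <- motif_pvalues(res, mode = "z")
  expect_equal(sum(pz$z), 0, tolerance = 1e-9)
})
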