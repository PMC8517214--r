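test_that("size_factors reproduce hand-computed median-of-ratios", {
  m <- matrix(c(10L, 20L, 40L, 100L,
                20L, 40L, 80L, 200L), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  cm <- count_matrix(m, data.frame(sample = c("a", "b")))
  sf <- size_factors(cm)
  # B = 2A everywhere: after geometric-mean centering (1/sqrt2, sqrt2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  # identical samples
  cm2 <- count_matrix(m[, c(1, 1), drop = FALSE] |>
                        (\(x) { colnames(x) <- c("a", "b"); x })(),
                      data.frame(sample = c("a", "b")))
  expect_equal(unname(size_factors(cm2)), c(1, 1))
  # all-zero matrix errors; no common nonzero feature warns
  zero <- count_matrix(matrix(0L, 2, 2,
                              dimnames = list(NULL, c("a", "b"))),
                       data.frame(sample = c("a", "b")))
  expect_error(size_factors(zero), "all-zero")
  sparse <- count_matrix(matrix(c(5L, 0L, 0L, 7L), 2,
                                dimnames = list(NULL, c("a", "b"))),
                         data.frame(sample = c("a", "b")))
  expect_warning(size_factors(sparse), "total-count")
})

test_that("nb_differential basic contracts hold", {
  set.seed(301)
  cm <- nb_fixture(500, 100, 100, 0.05)
  expect_error(nb_differential(cm, "A1", paste0("B", 1:3)),
               "pooled")
  d <- nb_differential(cm, paste0("A", 1:3), paste0("B", 1:3))
  expect_true(all(d$pvalue > 0 & d$pvalue <= 1))
  expect_true(all(d$padj >= d$pvalue))
  expect_true(all(is.finite(d$log2fc)))
  # identical counts in every sample -> log2fc 0
  flat <- count_matrix(matrix(50L, 3, 6,
                              dimnames = list(NULL,
                                              c(paste0("A", 1:3),
                                                paste0("B", 1:3)))),
                       data.frame(sample = c(paste0("A", 1:3),
                                             paste0("B", 1:3))))
  df <- nb_differential(flat, paste0("A", 1:3), paste0("B", 1:3))
  expect_equal(df$log2fc, rep(0, 3))
  # BH monotonicity along sorted p
  o <- order(d$pvalue)
  expect_true(all(diff(d$padj[o]) >= -1e-12))
})

test_that("nb_differential is antisymmetric under group swap and stable
           under within-group relabeling", {
  set.seed(302)
  cm <- nb_fixture(300, 150, 150, 0.05)
  gA <- paste0("A", 1:3); gB <- paste0("B", 1:3)
  d1 <- nb_differential(cm, gA, gB)
  d2 <- nb_differential(cm, gB, gA)
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-12)
  expect_equal(d1$pvalue, d2$pvalue, tolerance = 1e-12)
  d3 <- nb_differential(cm, gA[c(2, 3, 1)], gB[c(3, 1, 2)])
  expect_equal(d1$pvalue, d3$pvalue)
})

test_that("null calibration and power match the simulated world", {
  set.seed(303)
  n <- 2000
  cm_null <- nb_fixture(n, 100, 100, 0.05)
  d0 <- nb_differential(cm_null, paste0("A", 1:3), paste0("B", 1:3))
  expect_gte(mean(d0$pvalue < 0.05), 0.03)
  expect_lte(mean(d0$pvalue < 0.05), 0.07)
  # signal features embedded among nulls (a global shift would be
  # absorbed by normalization, as for any ratio-based method)
  sig <- seq_len(200)
  muB <- rep(100, n); muB[sig] <- 400
  cm_sig <- nb_fixture(n, 100, muB, 0.05)
  d1 <- nb_differential(cm_sig, paste0("A", 1:3), paste0("B", 1:3))
  expect_gte(mean(d1$padj[sig] < 0.05), 0.95)
  expect_equal(mean(d1$log2fc[sig]), 2, tolerance = 0.1)
})

test_that("representative isoform keeps highest density, then length", {
  iso <- data.frame(
    gene = c("g1", "g1", "g2", "g2", "g3"),
    isoform = c("i1", "i2", "i3", "i4", "i5"),
    length = c(1000, 2000, 1000, 2000, 500),
    count = c(100, 150, 100, 200, 7)
  )
  keep <- select_representative_isoform(iso)
  expect_equal(keep$isoform[keep$gene == "g1"], "i1")  # 0.1 > 0.075
  expect_equal(keep$isoform[keep$gene == "g2"], "i4")  # tie -> longer
  expect_equal(keep$isoform[keep$gene == "g3"], "i5")  # identity
  # lexicographic final tie-break
  iso2 <- data.frame(gene = "g", isoform = c("b", "a"),
                     length = c(100, 100), count = c(10, 10))
  expect_equal(select_representative_isoform(iso2)$isoform, "a")
})

test_that("rank_regions orders by signed significance with total ties", {
  rec <- data.frame(
    feature_id = c("up_weak", "dn_strong", "up_strong", "dn_weak", "zero"),
    log2fc = c(1, -2, 2, -1, 0),
    pvalue = c(1e-3, 1e-8, 1e-10, 1e-2, 0.5),
    padj = c(1e-2, 1e-7, 1e-9, 5e-2, 0.6),
    mean_norm = 10
  )
  rk <- rank_regions(rec)
  expect_equal(rk$feature_id,
               c("up_strong", "up_weak", "zero", "dn_weak", "dn_strong"))
  # identical records -> lexicographic ids, ranking is a bijection
  same <- data.frame(feature_id = c("c", "a", "b"), log2fc = 1,
                     pvalue = 0.01, padj = 0.02, mean_norm = 5)
  rk2 <- rank_regions(same)
  expect_equal(rk2$feature_id, c("a", "b", "c"))
  set.seed(304)
  rnd <- data.frame(feature_id = sprintf("f%03d", 1:50),
                    log2fc = round(stats::rnorm(50), 2),
                    pvalue = stats::runif(50), padj = stats::runif(50),
                    mean_norm = 1)
  r1 <- rank_regions(rnd)
  expect_setequal(r1$feature_id, rnd$feature_id)
  expect_equal(rank_regions(rnd[sample.int(50), ])$feature_id,
               r1$feature_id)
})

test_that("differential tables round-trip through their TSV format", {
  set.seed(305)
  cm <- nb_fixture(50, 80, 80, 0.05)
  d <- nb_differential(cm, paste0("A", 1:3), paste0("B", 1:3))
  f <- file.path(withr::local_tempdir(), "diff.tsv")
  write_differential(d, f)
  back <- read_differential(f)
  expect_equal(back$feature_id, d$feature_id)
  expect_equal(back$log2fc, d$log2fc, tolerance = 1e-12)
  expect_equal(back$padj, d$padj, tolerance = 1e-12)
})
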