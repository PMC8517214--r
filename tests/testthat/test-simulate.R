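test_that("generate_genome hits the configured GC and is seed-stable", {
  cfg <- sim_config(seed = 801, genome_length = 1e5L, gc_content = 0.5)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  bases <- strsplit(g1$genome[[1]], "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)
  # embedding probability 0 leaves only chance occurrences
  p <- word_pwm("w", "TTTTAAAATTTT")
  g3 <- generate_genome(cfg, centers = c(50000L), motifs = list(p),
                        embed_prob = 0)
  expect_false(any(g3$truth$embedded))
  expect_identical(g3$genome, g1$genome)
})

test_that("embedded words land at their recorded displacements", {
  cfg <- sim_config(seed = 802, genome_length = 2e5L)
  p <- word_pwm("w", "ACGTAGGCA")
  centers <- c(50000L, 100000L, 150000L)
  g <- generate_genome(cfg, centers, list(p), embed_prob = 1,
                       displacement_sd = 100)
  expect_true(all(g$truth$embedded))
  word <- pwm_consensus(p)
  for (i in seq_len(nrow(g$truth))) {
    mid <- g$truth$center[i] + g$truth$displacement[i]
    startpos <- round(mid - (nchar(word) - 1) / 2)
    expect_equal(substr(g$genome[[1]], startpos + 1,
                        startpos + nchar(word)), word)
    expect_lte(abs(g$truth$displacement[i]), 1400)
  }
})

test_that("nascent reads follow the stated strand/decay model", {
  cfg <- sim_config(seed = 803, genome_length = 2e5L,
                    origin_reads = 2000, decay_scale = 150,
                    background_rate = 0)
  origins <- data.frame(chrom = "chrS", center = 100000L)
  sim <- simulate_nascent_reads(cfg, origins, samples = "s1")
  r <- sim$reads
  expect_gt(nrow(r), 1800)
  plus <- r[r$strand == "+", ]
  minus <- r[r$strand == "-", ]
  # strand symmetry within 5 binomial SDs
  expect_lt(abs(nrow(plus) - nrow(minus)),
            5 * sqrt(nrow(r) * 0.25) + 1)
  # exponential 5'-offset means within 10%
  expect_lt(abs(mean(plus$start - 100000) - 150), 15)
  expect_lt(abs(mean(100000 - (minus$end - 1)) - 150), 15)
  expect_true(all(r$end - r$start == cfg$read_length))
  # zero-strength origin emits nothing
  o0 <- data.frame(chrom = "chrS", center = 50000L, strength.s1 = 0)
  expect_equal(nrow(simulate_nascent_reads(cfg, o0, "s1")$reads), 0L)
})

test_that("gene counts follow their archetype means and the seed", {
  cfg <- sim_config(seed = 804, n_genes = 2000L, n_replicates = 3L)
  g1 <- simulate_gene_counts(cfg)
  g2 <- simulate_gene_counts(cfg)
  expect_identical(g1$counts$counts, g2$counts$counts)
  cm <- g1$counts; truth <- g1$truth
  cond_mean <- function(arch, cond) {
    rows <- truth$archetype == arch
    cols <- cm$samples$condition == cond
    rowMeans(cm$counts[rows, cols, drop = FALSE]) /
      truth$baseline[rows]
  }
  # early_peak: 30 min ~ 4x vehicle, 120 min back at baseline
  expect_equal(mean(cond_mean("early_peak", "t30")), 4, tolerance = 0.2)
  expect_equal(mean(cond_mean("early_peak", "t120")), 1, tolerance = 0.1)
  expect_equal(mean(cond_mean("late", "t30")), 1, tolerance = 0.1)
  expect_equal(mean(cond_mean("late", "t120")), 4, tolerance = 0.2)
  expect_equal(mean(cond_mean("null", "t30")), 1, tolerance = 0.1)
})

test_that("atac tracks honor the schedule and the seed", {
  cfg <- sim_config(seed = 805, genome_length = 2e5L)
  sched <- data.frame(chrom = "chrS", center = 100000L,
                      vehicle = FALSE, t30 = TRUE, t120 = FALSE)
  s1 <- simulate_atac(cfg, sched)
  s2 <- simulate_atac(cfg, sched)
  expect_identical(s1$tracks$t30$values_plus, s2$tracks$t30$values_plus)
  bin <- cfg$atac_bin
  inside <- (100000 %/% bin + 1) + seq(-4, 4)
  expect_gt(mean(s1$tracks$t30$values_plus[inside]),
            4 * cfg$atac_background)
  expect_lt(mean(s1$tracks$vehicle$values_plus[inside]),
            2.5 * cfg$atac_background)
  expect_lt(mean(s1$tracks$t120$values_plus[inside]),
            2.5 * cfg$atac_background)
  # empty schedule -> plain Poisson
  s3 <- simulate_atac(cfg, sched[sched$vehicle, , drop = FALSE][0, ] |>
                        (\(x) rbind(x, data.frame(chrom = "chrS",
                                                  center = 1000L,
                                                  vehicle = FALSE,
                                                  t30 = FALSE,
                                                  t120 = FALSE)))())
  expect_lt(mean(s3$tracks$t30$values_plus), 1.2 * cfg$atac_background)
})

test_that("emitted files parse with the module readers", {
  dir <- withr::local_tempdir()
  cfg <- pipeline_config(seed = 806,
                         sim = sim_config(seed = 806,
                                          genome_length = 3e5L,
                                          n_origins = 10L,
                                          n_genes = 50L))
  stage_simulate(cfg, dir)
  genome <- read_genome(file.path(dir, "genome.fa"))
  expect_equal(nchar(genome[[1]]), 3e5L)
  motifs <- read_meme_motifs(file.path(dir, "motifs.meme"))
  expect_gte(length(motifs), 5L)
  reads <- read_bed(file.path(dir, "reads_vehicle_r1.bed"))
  expect_true(all(reads$strand %in% c("+", "-")))
  cm <- read_count_matrix(file.path(dir, "gene_counts.tsv"))
  expect_equal(dim(cm$counts), c(50L, 6L))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(names(truth), c("origins", "motif_embedding", "genes",
                                  "atac_schedule", "samples"))
  expect_length(truth$origins$center, 10L)  # column-oriented JSON
})
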