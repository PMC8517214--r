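# Synthetic-data generator. Everything the pipeline consumes can be
# produced here with known ground truth: a random genome with motif words
# embedded at controlled displacements, strand-specific nascent reads
# decaying exponentially from bidirectional origins, NB gene counts
# following temporal archetypes, and accessibility tracks with scheduled
# peaks. One seed fixes every output byte-for-byte.

#' Simulation configuration
#'
#' Defaults state the simulated world: duplicate libraries, origins
#' emitting ~2000 reads with an exponential 5'-end decay of 150 bases
#' (typical eRNA scale), NB dispersion 0.05 and |log2 effect| 2 for
#' non-null archetypes, and a 3-point exposure time course
#' (vehicle / 30 min / 120 min as metadata labels).
#'
#' @param seed Integer master seed.
#' @param genome_length Bases per simulated chromosome.
#' @param gc_content Fraction G+C of the background sequence.
#' @param n_origins Number of bidirectional origins.
#' @param decay_scale Exponential scale of read 5'-offsets (bases).
#' @param origin_reads Expected reads per origin per sample.
#' @param background_rate Uniform background reads per base per sample.
#' @param read_length Fixed read length (bases).
#' @param n_genes,n_replicates,nb_dispersion Gene-count simulation size.
#' @param archetype_effects Named log2 effects for `early_peak`,
#'   `early_plateau`, `late`, `null`.
#' @param archetype_props Named proportions of genes per archetype.
#' @param atac_bin,atac_background,atac_fold,atac_peak_width
#'   Accessibility track geometry: bin size (bases), Poisson background
#'   mean per bin, enrichment fold, flat-top peak width (bases).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 1e6L, gc_content = 0.45,
                       n_origins = 50L, decay_scale = 150,
                       origin_reads = 2000, background_rate = 0.002,
                       read_length = 30L, n_genes = 1000L,
                       n_replicates = 2L, nb_dispersion = 0.05,
                       archetype_effects = c(early_peak = 2,
                                             early_plateau = 2,
                                             late = 2, null = 0),
                       archetype_props = c(early_peak = 0.1,
                                           early_plateau = 0.1,
                                           late = 0.1, null = 0.7),
                       atac_bin = 50L, atac_background = 2,
                       atac_fold = 8, atac_peak_width = 500L) {
  stopifnot(gc_content > 0, gc_content < 1, decay_scale > 0,
            origin_reads >= 0, background_rate >= 0, n_replicates >= 2,
            nb_dispersion > 0, abs(sum(archetype_props) - 1) < 1e-9)
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              gc_content = gc_content, n_origins = as.integer(n_origins),
              decay_scale = decay_scale, origin_reads = origin_reads,
              background_rate = background_rate,
              read_length = as.integer(read_length),
              n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              nb_dispersion = nb_dispersion,
              archetype_effects = archetype_effects,
              archetype_props = archetype_props,
              atac_bin = as.integer(atac_bin),
              atac_background = atac_background, atac_fold = atac_fold,
              atac_peak_width = as.integer(atac_peak_width))
  class(cfg) <- "sim_config"
  cfg
}

TIMEPOINTS <- c("vehicle", "t30", "t120")

#' Evenly spaced origin centers with jitter
#'
#' Places `n_origins` centers on `chrom`, at least ~5 kb apart so
#' neighboring calls and scan windows cannot collide.
#'
#' @param config A [sim_config].
#' @param chrom Chromosome name.
#' @return data.frame `chrom`, `center`.
#' @export
simulate_origins <- function(config, chrom = "chrS") {
  n <- config$n_origins
  margin <- 5000L
  usable <- config$genome_length - 2L * margin
  stopifnot(usable > n * 5000L)
  set.seed(config$seed + 11L)
  base <- margin + round(seq(0, usable, length.out = n))
  jitter <- sample(-1000:1000, n, replace = TRUE)
  data.frame(chrom = chrom,
             center = as.integer(pmin(pmax(base + jitter, margin),
                                      config$genome_length - margin)))
}

#' Generate a random genome with embedded motif words
#'
#' Bases are i.i.d. at the configured GC content. For each motif and each
#' designated center, with probability `embed_prob` the motif's consensus
#' word is written in at a displacement drawn from
#' `Normal(0, displacement_sd)` (clipped to +/-1400 so it stays inside a
#' 3-kb scan window). Overlapping embeddings at one center are resampled
#' up to 100 times, then skipped with a warning.
#'
#' @param config A [sim_config].
#' @param centers Integer vector of embedding anchor positions (0-based,
#'   like every other coordinate in the package).
#' @param motifs List of [pwm] objects to embed (may be empty).
#' @param embed_prob Per-motif scalar or vector over centers: embedding
#'   probability at each center.
#' @param displacement_sd SD of the embedding displacement (bases).
#' @param chrom Chromosome name.
#' @return List: `genome` (named character vector) and `truth`
#'   (data.frame `motif_id`, `center`, `embedded`, `displacement`).
#' @export
generate_genome <- function(config, centers = integer(), motifs = list(),
                            embed_prob = 0, displacement_sd = 150,
                            chrom = "chrS") {
  set.seed(config$seed + 23L)
  gc <- config$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqv <- sample(names(probs), config$genome_length, replace = TRUE,
                 prob = probs)
  truth <- list()
  occupied <- logical(config$genome_length)  # embedded word positions
  for (p in motifs) {
    word <- strsplit(pwm_consensus(p), "")[[1L]]
    w <- length(word)
    pr <- rep_len(embed_prob, length(centers))
    for (ci in seq_along(centers)) {
      center <- centers[ci]
      emb <- stats::runif(1) < pr[ci]
      disp <- NA_real_
      if (emb) {
        placed <- FALSE
        for (try in 1:100) {
          d <- max(-1400, min(1400, stats::rnorm(1, 0, displacement_sd)))
          # 0-based word start; occupies [startpos, startpos + w)
          startpos <- round(center + d - (w - 1) / 2)
          if (startpos < 0 || startpos + w > config$genome_length) next
          span <- (startpos + 1L):(startpos + w)
          if (any(occupied[span])) next
          seqv[span] <- word
          occupied[span] <- TRUE
          disp <- startpos + (w - 1) / 2 - center
          placed <- TRUE
          break
        }
        if (!placed) {
          warning("could not place ", p$motif_id, " at center ", center)
          emb <- FALSE
        }
      }
      truth[[length(truth) + 1L]] <- data.frame(
        motif_id = p$motif_id, center = center, embedded = emb,
        displacement = disp
      )
    }
  }
  genome <- stats::setNames(paste(seqv, collapse = ""), chrom)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(motif_id = character(), center = integer(),
               embedded = logical(), displacement = numeric())
  list(genome = genome, truth = truth)
}

#' Simulate strand-specific nascent reads around bidirectional origins
#'
#' Per origin and sample the read count is Poisson with the origin's
#' strength; each read picks a strand with probability 1/2, its 5' end an
#' exponential offset (`decay_scale`) downstream (+) or upstream (-) of
#' the center, and spans `read_length` bases. Uniform background reads
#' are added at `background_rate` per base.
#'
#' @param config A [sim_config].
#' @param origins data.frame `chrom`, `center`, plus optional per-sample
#'   `strength.<sample>` columns (default `origin_reads` everywhere).
#' @param samples Character vector of sample names.
#' @return List: `reads` (data.frame `chrom`, `start`, `end`, `strand`,
#'   `sample`) and `truth` (`origins` with realized counts).
#' @export
simulate_nascent_reads <- function(config, origins,
                                   samples = c("veh_r1", "veh_r2")) {
  set.seed(config$seed + 37L)
  rl <- config$read_length
  glen <- config$genome_length
  out <- list()
  for (s in samples) {
    strength_col <- paste0("strength.", s)
    strength <- if (strength_col %in% names(origins)) {
      origins[[strength_col]]
    } else rep(config$origin_reads, nrow(origins))
    for (i in seq_len(nrow(origins))) {
      n <- stats::rpois(1L, strength[i])
      if (n == 0L) next
      strand <- sample(c("+", "-"), n, replace = TRUE)
      off <- stats::rexp(n, rate = 1 / config$decay_scale)
      p5 <- ifelse(strand == "+",
                   origins$center[i] + off,
                   origins$center[i] - off)
      p5 <- as.integer(round(pmin(pmax(p5, rl), glen - rl)))
      start <- ifelse(strand == "+", p5, p5 - rl + 1L)
      out[[length(out) + 1L]] <- data.frame(
        chrom = origins$chrom[i], start = as.integer(start),
        end = as.integer(start + rl), strand = strand, sample = s
      )
    }
    nbg <- stats::rpois(1L, config$background_rate * glen)
    if (nbg > 0L) {
      start <- sample.int(glen - rl, nbg, replace = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        chrom = origins$chrom[1L], start = as.integer(start),
        end = as.integer(start + rl),
        strand = sample(c("+", "-"), nbg, replace = TRUE), sample = s
      )
    }
  }
  reads <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), sample = character())
  list(reads = reads, truth = origins)
}

#' Simulate NB gene counts following temporal archetypes
#'
#' Baseline means are log-uniform in `[50, 5000]`. With effect
#' `f = 2^effect`: `early_peak` scales the 30-min mean by `f` (120 min
#' back at baseline), `early_plateau` scales 30 and 120 min by `f`,
#' `late` scales only 120 min, `null` leaves all conditions equal.
#' Counts are NB with the configured dispersion.
#'
#' @param config A [sim_config].
#' @return List: `counts` (a [count_matrix] with `condition`/`time`
#'   metadata) and `truth` (data.frame `feature_id`, `archetype`,
#'   `baseline`).
#' @export
simulate_gene_counts <- function(config) {
  set.seed(config$seed + 53L)
  n <- config$n_genes
  reps <- config$n_replicates
  arch <- sample(names(config$archetype_props), n, replace = TRUE,
                 prob = config$archetype_props)
  baseline <- exp(stats::runif(n, log(50), log(5000)))
  eff <- 2^config$archetype_effects[arch]
  mu <- cbind(
    vehicle = baseline,
    t30 = baseline * ifelse(arch %in% c("early_peak", "early_plateau"),
                            eff, 1),
    t120 = baseline * ifelse(arch %in% c("early_plateau", "late"), eff, 1)
  )
  samples <- data.frame(
    sample = paste0(rep(TIMEPOINTS, each = reps), "_r", seq_len(reps)),
    condition = rep(TIMEPOINTS, each = reps),
    time = rep(c(0L, 30L, 120L), each = reps)
  )
  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(sprintf("gene_%05d", seq_len(n)),
                                   samples$sample))
  for (j in seq_len(nrow(samples))) {
    counts[, j] <- stats::rnbinom(n, size = 1 / config$nb_dispersion,
                                  mu = mu[, samples$condition[j]])
  }
  list(counts = count_matrix(counts, samples),
       truth = data.frame(feature_id = rownames(counts), archetype = arch,
                          baseline = baseline))
}

#' Simulate accessibility coverage with scheduled peaks
#'
#' Each time point gets an independent Poisson background track; peaks
#' present at that time point add a flat-top enrichment of
#' `atac_fold * atac_background` per bin across `atac_peak_width` bases.
#'
#' @param config A [sim_config].
#' @param schedule data.frame `chrom`, `center`, and logical columns
#'   `vehicle`, `t30`, `t120` saying when each peak is open.
#' @return List: `tracks` (named list of unstranded [coverage_track]s)
#'   and `truth` (the schedule).
#' @export
simulate_atac <- function(config, schedule) {
  set.seed(config$seed + 71L)
  bs <- config$atac_bin
  nbin <- ceiling(config$genome_length / bs)
  half_bins <- max(1L, round(config$atac_peak_width / bs / 2))
  tracks <- list()
  for (tp in TIMEPOINTS) {
    mu <- rep(config$atac_background, nbin)
    open <- which(schedule[[tp]])
    for (i in open) {
      cb <- schedule$center[i] %/% bs + 1L
      b1 <- max(1L, cb - half_bins)
      b2 <- min(nbin, cb + half_bins - 1L)
      mu[b1:b2] <- config$atac_background * config$atac_fold
    }
    v <- stats::rpois(nbin, mu)
    tracks[[tp]] <- coverage_track(schedule$chrom[1L], bs, v,
                                   rep(0, nbin))
  }
  list(tracks = tracks, truth = schedule)
}

#' Write a truth table as JSON
#' @param truth Any truth object (data.frame or list of them).
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
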