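# End-to-end orchestration. One validated config drives every stage with
# fixed-name outputs so stages compose via files; all randomness flows
# from the single top-level seed through per-stage derived seeds.

#' Pipeline configuration
#'
#' Thresholds default to the analysis constants used throughout:
#' significance `alpha = 0.05` with `lfc_min = 1` for volcano flags,
#' motif match p `1e-5` over a 3-kb scan window (`half_width = 1500`),
#' bidirectional aggregation gap 60 bases, peak gates `log2fc > 1` and
#' `q <= 1e-5`, and displacement decay `sigma = 150` bases.
#'
#' @param seed Master seed (integer).
#' @param alpha,lfc_min,motif_p_cutoff,half_width,merge_gap,sigma,
#'   peak_min_log2fc,peak_q_max Numeric thresholds (see description).
#' @param bin_size,min_strength,max_pair_distance,flank Bidirectional
#'   detector geometry.
#' @param rank_metric `"pvalue"` (default) or `"padj"`.
#' @param pvalue_mode `"z"` or `"permutation"`; `n_perm` permutations.
#' @param stranded_counting Count reads per region strand-matched.
#' @param sim A [sim_config] for the synthetic run (NULL to consume
#'   existing inputs in the run directory).
#' @param ... Unknown keys are rejected.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, alpha = 0.05, lfc_min = 1,
                            motif_p_cutoff = 1e-5, half_width = 1500L,
                            merge_gap = 60L, sigma = 150,
                            peak_min_log2fc = 1, peak_q_max = 1e-5,
                            bin_size = 15L, min_strength = 10,
                            max_pair_distance = 600L, flank = 750L,
                            rank_metric = "pvalue", pvalue_mode = "z",
                            n_perm = 200L, stranded_counting = FALSE,
                            sim = sim_config(seed = seed), ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "))
  }
  check_in <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1L || x < lo || x > hi) {
      stop("config: ", nm, " must be in [", lo, ", ", hi, "]")
    }
  }
  check_in(alpha, 1e-12, 1 - 1e-12, "alpha")
  check_in(lfc_min, 0, 20, "lfc_min")
  check_in(motif_p_cutoff, 1e-16, 0.5, "motif_p_cutoff")
  check_in(half_width, 100, 1e5, "half_width")
  check_in(merge_gap, 0, 1e5, "merge_gap")
  check_in(sigma, 1, 1e5, "sigma")
  check_in(peak_min_log2fc, 0, 20, "peak_min_log2fc")
  check_in(peak_q_max, 1e-300, 0.5, "peak_q_max")
  if (!rank_metric %in% c("pvalue", "padj")) stop("bad rank_metric")
  if (!pvalue_mode %in% c("z", "permutation")) stop("bad pvalue_mode")
  cfg <- list(seed = as.integer(seed), alpha = alpha, lfc_min = lfc_min,
              motif_p_cutoff = motif_p_cutoff,
              half_width = as.integer(half_width),
              merge_gap = as.integer(merge_gap), sigma = sigma,
              peak_min_log2fc = peak_min_log2fc, peak_q_max = peak_q_max,
              bin_size = as.integer(bin_size),
              min_strength = min_strength,
              max_pair_distance = as.integer(max_pair_distance),
              flank = as.integer(flank), rank_metric = rank_metric,
              pvalue_mode = pvalue_mode, n_perm = as.integer(n_perm),
              stranded_counting = isTRUE(stranded_counting), sim = sim)
  class(cfg) <- "pipeline_config"
  cfg
}

# stage seeds: first 7 hex digits of the md5 of the stage name, XORed
# with the master seed (stays below 2^31)
stage_seed <- function(config, stage) {
  tf <- tempfile()
  writeLines(stage, tf)
  h <- strtoi(substr(tools::md5sum(tf), 1L, 7L), 16L)
  unlink(tf)
  bitwXor(as.integer(h), as.integer(config$seed))
}

config_hash <- function(config) {
  tf <- tempfile()
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  h
}

CONTRASTS <- list(d30v0 = c("vehicle", "t30"),
                  d120v0 = c("vehicle", "t120"),
                  d120v30 = c("t30", "t120"))

#' Generate the full set of synthetic pipeline inputs
#'
#' Writes, under `dir`: `genome.fa`, `motifs.meme`, one
#' `reads_<sample>.bed` per sample (3 conditions x 2 replicates),
#' `gene_counts.tsv` (+ sample sidecar), `atac_<timepoint>.tsv` count
#' tracks, and `truth.json`. Origins follow the temporal archetypes so
#' every downstream stage has signal; one motif ("XRE-like") is embedded
#' preferentially at early-peak origins, one at chance everywhere, and
#' two GC-contrast controls at chance.
#'
#' @param config A [pipeline_config].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
stage_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  sim$seed <- stage_seed(config, "simulate")
  origins <- simulate_origins(sim)
  set.seed(sim$seed + 101L)
  arch <- sample(names(sim$archetype_props), nrow(origins),
                 replace = TRUE, prob = sim$archetype_props)
  eff <- 2^sim$archetype_effects[arch]
  base <- sim$origin_reads
  samples <- paste0(rep(TIMEPOINTS, each = sim$n_replicates), "_r",
                    seq_len(sim$n_replicates))
  for (s in samples) {
    cond <- sub("_r\\d+$", "", s)
    mult <- switch(cond,
      vehicle = rep(1, length(arch)),
      t30 = ifelse(arch %in% c("early_peak", "early_plateau"), eff, 1),
      t120 = ifelse(arch %in% c("early_plateau", "late"), eff, 1))
    origins[[paste0("strength.", s)]] <- base * mult
  }
  motifs <- demo_motifs()
  # XRE-like motif at early-peak origins, background motif at chance
  prob_main <- ifelse(arch == "early_peak", 0.8, 0.05)
  gg <- generate_genome(sim, origins$center, motifs["XRE_like"],
                        embed_prob = prob_main, displacement_sd = 150)
  genome <- gg$genome
  reads <- simulate_nascent_reads(sim, origins, samples)
  genes <- simulate_gene_counts(sim)
  # accessibility: peaks open according to the origin archetypes
  schedule <- data.frame(chrom = origins$chrom, center = origins$center,
                         vehicle = arch == "null",
                         t30 = arch %in% c("null", "early_peak",
                                           "early_plateau"),
                         t120 = arch %in% c("null", "early_plateau",
                                            "late"))
  atac <- simulate_atac(sim, schedule)

  write_genome(genome, file.path(dir, "genome.fa"))
  write_meme_motifs(motifs, file.path(dir, "motifs.meme"))
  for (s in samples) {
    rd <- reads$reads[reads$reads$sample == s, , drop = FALSE]
    write_bed(gintervals(rd$chrom, rd$start, rd$end, strand = rd$strand),
              file.path(dir, paste0("reads_", s, ".bed")))
  }
  write_count_matrix(genes$counts, file.path(dir, "gene_counts.tsv"))
  for (tp in TIMEPOINTS) {
    tr <- atac$tracks[[tp]]
    utils::write.table(
      data.frame(bin = seq_along(tr$values_plus), count = tr$values_plus),
      file.path(dir, paste0("atac_", tp, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_truth(list(
    origins = cbind(origins[c("chrom", "center")], archetype = arch),
    motif_embedding = gg$truth, genes = genes$truth,
    atac_schedule = schedule,
    samples = data.frame(sample = samples,
                         condition = sub("_r\\d+$", "", samples))
  ), file.path(dir, "truth.json"))
  invisible(dir)
}

demo_motifs <- function() {
  peaked <- function(word, conc = 0.97) {
    m <- matrix((1 - conc) / 3, nrow = 4,
                ncol = nchar(word), dimnames = list(DNA_BASES, NULL))
    idx <- match(strsplit(word, "")[[1L]], DNA_BASES)
    m[cbind(idx, seq_along(idx))] <- conc
    m
  }
  list(
    XRE_like = pwm("XRE_like", peaked("TGCGTGCGA")),
    CTRL_AT = pwm("CTRL_AT", peaked("ATTAATTAT")),
    CTRL_GC = pwm("CTRL_GC", peaked("GCCGGCCGG")),
    CTRL_MIX = pwm("CTRL_MIX", peaked("ACGTACGTA")),
    CTRL_TA = pwm("CTRL_TA", peaked("TATATAAAT")),
    CTRL_CG = pwm("CTRL_CG", peaked("CGGCGCGTC"))
  )
}

read_sample_reads <- function(dir, samples) {
  out <- lapply(samples, function(s) {
    f <- file.path(dir, paste0("reads_", s, ".bed"))
    if (!file.exists(f)) {
      stop("missing ", f, "; run the 'simulate' stage first")
    }
    b <- read_bed(f)
    data.frame(chrom = b$chrom, start = b$start, end = b$end,
               strand = b$strand, sample = s)
  })
  do.call(rbind, out)
}

pipeline_samples <- function(config) {
  paste0(rep(TIMEPOINTS, each = config$sim$n_replicates), "_r",
         seq_len(config$sim$n_replicates))
}

#' Detect bidirectionals per sample and build consensus ROIs
#'
#' Consumes `reads_<sample>.bed`; writes `bidir_calls.tsv` (all
#' per-sample calls), `rois.tsv` and `rois.bed`.
#'
#' @param config A [pipeline_config].
#' @param dir Run directory.
#' @return The consensus ROI data.frame, invisibly.
#' @export
stage_detect <- function(config, dir) {
  samples <- pipeline_samples(config)
  reads <- read_sample_reads(dir, samples)
  glen <- config$sim$genome_length
  calls <- list()
  for (s in samples) {
    rd <- reads[reads$sample == s, , drop = FALSE]
    tracks <- build_coverage(rd, bin_size = config$bin_size,
                             chrom_lengths = stats::setNames(
                               glen, unique(rd$chrom)))
    for (tr in tracks) {
      cc <- detect_bidirectionals(tr, min_strength = config$min_strength,
                                  max_pair_distance = config$max_pair_distance,
                                  flank = config$flank)
      if (nrow(cc)) calls[[length(calls) + 1L]] <- cbind(sample = s, cc)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    stop("no bidirectional calls in any sample")
  utils::write.table(calls, file.path(dir, "bidir_calls.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  rois <- consensus_rois(split(calls, calls$sample), gap = config$merge_gap)
  utils::write.table(as.data.frame(rois), file.path(dir, "rois.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_bed(gintervals(rois$chrom, rois$start, rois$end, name = rois$name,
                       score = rois$support),
            file.path(dir, "rois.bed"))
  invisible(rois)
}

read_stage_tsv <- function(dir, file, producer) {
  f <- file.path(dir, file)
  if (!file.exists(f)) {
    stop("missing ", f, "; run the '", producer, "' stage first")
  }
  utils::read.table(f, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Differential activity for genes and ROIs across all three contrasts
#'
#' Consumes `gene_counts.tsv`, `rois.tsv` and the per-sample read files;
#' writes `diff_genes_<contrast>.tsv`, `diff_rois_<contrast>.tsv` and
#' `ranked_rois_<contrast>.tsv` for contrasts `d30v0`, `d120v0`,
#' `d120v30`.
#'
#' @param config A [pipeline_config].
#' @param dir Run directory.
#' @return Invisibly, a list of differential tables.
#' @export
stage_diff <- function(config, dir) {
  genes <- read_count_matrix(file.path(dir, "gene_counts.tsv"))
  rois <- read_stage_tsv(dir, "rois.tsv", "detect")
  samples <- pipeline_samples(config)
  reads <- read_sample_reads(dir, samples)
  roi_counts <- count_reads_in_regions(
    reads, gintervals(rois$chrom, rois$start, rois$end, name = rois$name),
    samples = samples, stranded = config$stranded_counting)
  roi_counts$samples$condition <- sub("_r\\d+$", "",
                                      roi_counts$samples$sample)
  write_count_matrix(roi_counts, file.path(dir, "roi_counts.tsv"))
  out <- list()
  for (cn in names(CONTRASTS)) {
    grpA <- genes$samples$sample[genes$samples$condition ==
                                   CONTRASTS[[cn]][1L]]
    grpB <- genes$samples$sample[genes$samples$condition ==
                                   CONTRASTS[[cn]][2L]]
    dg <- nb_differential(genes, grpA, grpB)
    write_differential(dg, file.path(dir, paste0("diff_genes_", cn,
                                                 ".tsv")))
    grpA <- roi_counts$samples$sample[roi_counts$samples$condition ==
                                        CONTRASTS[[cn]][1L]]
    grpB <- roi_counts$samples$sample[roi_counts$samples$condition ==
                                        CONTRASTS[[cn]][2L]]
    dr <- nb_differential(roi_counts, grpA, grpB)
    write_differential(dr, file.path(dir, paste0("diff_rois_", cn,
                                                 ".tsv")))
    rk <- rank_regions(dr, use_padj = config$rank_metric == "padj")
    utils::write.table(rk, file.path(dir, paste0("ranked_rois_", cn,
                                                 ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out[[cn]] <- list(genes = dg, rois = dr)
  }
  invisible(out)
}

#' Temporal cluster tables for transcripts and bidirectionals
#'
#' Consumes the six differential tables; writes
#' `clusters_transcripts.tsv` and `clusters_bidirectionals.tsv` plus
#' per-cluster BED exports of ROIs.
#'
#' @param config A [pipeline_config].
#' @param dir Run directory.
#' @return Invisibly, the transcript cluster table.
#' @export
stage_cluster <- function(config, dir) {
  transcripts <- NULL
  for (what in c("genes", "rois")) {
    d <- lapply(names(CONTRASTS), function(cn)
      read_differential(file.path(dir, paste0("diff_", what, "_", cn,
                                              ".tsv"))))
    cl <- classify_transcript_clusters(d[[1L]], d[[2L]], d[[3L]],
                                       alpha = config$alpha)
    out <- if (what == "genes") "clusters_transcripts.tsv" else
      "clusters_bidirectionals.tsv"
    utils::write.table(cl, file.path(dir, out), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (what == "genes") transcripts <- cl
    if (what == "rois") {
      rois <- read_stage_tsv(dir, "rois.tsv", "detect")
      for (lab in c("early_peak", "early_plateau", "late")) {
        ids <- cl$feature_id[cl$label == lab]
        sub <- rois[rois$name %in% ids, , drop = FALSE]
        if (nrow(sub)) {
          write_bed(gintervals(sub$chrom, sub$start, sub$end,
                               name = sub$name),
                    file.path(dir, paste0("cluster_", lab, ".bed")))
        }
      }
    }
  }
  invisible(transcripts)
}

#' Accessibility peak calls and presence/absence clusters
#'
#' Consumes `atac_<timepoint>.tsv` count tracks; writes
#' `peaks_<timepoint>.tsv` and `clusters_peaks.tsv`.
#'
#' @param config A [pipeline_config].
#' @param dir Run directory.
#' @return Invisibly, the peak cluster table.
#' @export
stage_peaks <- function(config, dir) {
  sets <- list()
  for (tp in TIMEPOINTS) {
    tab <- read_stage_tsv(dir, paste0("atac_", tp, ".tsv"), "simulate")
    tr <- coverage_track("chrS", config$sim$atac_bin, tab$count,
                         rep(0, nrow(tab)))
    pk <- call_peaks(tr, min_log2fc = config$peak_min_log2fc,
                     q_max = config$peak_q_max)
    write_peaks(pk, file.path(dir, paste0("peaks_", tp, ".tsv")))
    sets[[tp]] <- pk
  }
  cl <- classify_peak_clusters(sets$vehicle, sets$t30, sets$t120)
  utils::write.table(cl, file.path(dir, "clusters_peaks.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(cl)
}

#' Motif displacement enrichment per contrast
#'
#' Consumes `genome.fa`, `motifs.meme`, `rois.tsv` and the ranked ROI
#' tables; writes `enrichment_<contrast>.tsv`, `md_<contrast>.tsv` and
#' `hits_<contrast>.tsv`.
#'
#' @param config A [pipeline_config].
#' @param dir Run directory.
#' @return Invisibly, a list of enrichment tables by contrast.
#' @export
stage_enrich <- function(config, dir) {
  gf <- file.path(dir, "genome.fa")
  if (!file.exists(gf)) stop("missing ", gf,
                             "; run the 'simulate' stage first")
  genome <- read_genome(gf)
  pwms <- read_meme_motifs(file.path(dir, "motifs.meme"))
  rois <- read_stage_tsv(dir, "rois.tsv", "detect")
  out <- list()
  for (cn in names(CONTRASTS)) {
    f <- file.path(dir, paste0("ranked_rois_", cn, ".tsv"))
    if (!file.exists(f)) stop("missing ", f,
                              "; run the 'diff' stage first")
    ranked <- utils::read.table(f, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    res <- run_tfea(genome, rois, ranked$feature_id, pwms,
                    half_width = config$half_width,
                    p_cutoff = config$motif_p_cutoff,
                    sigma = config$sigma, mode = config$pvalue_mode,
                    n_perm = config$n_perm,
                    seed = stage_seed(config, paste0("enrich_", cn)))
    utils::write.table(res$results,
                       file.path(dir, paste0("enrichment_", cn, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(res$md),
                       file.path(dir, paste0("md_", cn, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$hits,
                       file.path(dir, paste0("hits_", cn, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out[[cn]] <- res$results
  }
  invisible(out)
}

#' Run the whole pipeline on synthetic inputs
#'
#' Executes simulate, detect, diff, cluster, peaks and enrich in order,
#' then writes `manifest.json` (config hash, seed, stage list). Any
#' stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
run_pipeline <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list(simulate = stage_simulate, detect = stage_detect,
                 diff = stage_diff, cluster = stage_cluster,
                 peaks = stage_peaks, enrich = stage_enrich)
  for (nm in names(stages)) {
    tryCatch(stages[[nm]](config, dir), error = function(e) {
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = names(stages),
                   package_version = as.character(
                     utils::packageVersion("tfdynamics")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Command-line entry point
#'
#' `tfdynamics <subcommand> --dir DIR [--config FILE] [--seed N]` with
#' subcommands `simulate`, `detect`, `diff`, `cluster`, `peaks`,
#' `enrich`, or `run` (everything). `--config` points to a JSON file of
#' [pipeline_config()] overrides.
#'
#' @param args Character vector (defaults to `commandArgs(TRUE)`).
#' @return Exit status 0 on success (invisibly).
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: tfdynamics <simulate|detect|diff|cluster|peaks|",
         "enrich|run> --dir DIR [--config FILE] [--seed N]")
  }
  cmd <- args[1L]
  get_opt <- function(flag) {
    i <- which(args == flag)
    if (length(i)) args[i[1L] + 1L] else NULL
  }
  dir <- get_opt("--dir")
  if (is.null(dir)) stop("--dir is required")
  overrides <- list()
  cf <- get_opt("--config")
  if (!is.null(cf)) {
    overrides <- jsonlite::read_json(cf, simplifyVector = TRUE)
  }
  sd <- get_opt("--seed")
  if (!is.null(sd)) overrides$seed <- as.integer(sd)
  if (!is.null(overrides$sim)) {
    overrides$sim <- do.call(sim_config, as.list(overrides$sim))
  }
  config <- do.call(pipeline_config, overrides)
  fn <- switch(cmd, simulate = stage_simulate, detect = stage_detect,
               diff = stage_diff, cluster = stage_cluster,
               peaks = stage_peaks, enrich = stage_enrich,
               run = run_pipeline,
               stop("unknown subcommand: ", cmd))
  fn(config, dir)
  invisible(0L)
}
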