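# tfdynamics

Temporal deconvolution of transcription factor activity from nascent
transcription and chromatin accessibility.

## The problem

Cells exposed to a complex stimulus — an air-pollution particle mix, a
cytokine cocktail, a drug with several active components — mount several
transcriptional programs at once. Nascent-transcription assays (PRO-seq)
and chromatin accessibility assays (ATAC-seq) taken at a few time points
after exposure carry enough information to pull those programs apart:
enhancer activity shows up as *bidirectional* (eRNA) transcription around
a shared origin, differential activity orders regions by response, the
sign pattern across pairwise time-point contrasts groups responses into
temporal classes, and the transcription factors driving each class
betray themselves by their binding motifs concentrating near the centers
of the most responsive regions.

`tfdynamics` implements that strategy end to end for a three-point
design (vehicle / early / late), together with a synthetic-data module
that generates every input with known ground truth, so the whole
pipeline is testable without any sequencing data.

## What is inside

| Stage | Function(s) | Method |
|---|---|---|
| Interval plumbing | `read_bed`, `merge_intervals`, `consensus_rois`, `count_reads_in_regions` | BED-convention (0-based half-open) intervals; gap-merge; support-weighted consensus centers |
| eRNA detection | `build_coverage`, `detect_bidirectionals` | strand-resolved 5′-end coverage; paired strand local maxima on smoothed signal |
| Differential activity | `size_factors`, `nb_differential`, `rank_regions` | median-of-ratios normalization; NB Wald test with trend-moderated moment dispersions; BH; signed-significance ranking |
| Temporal clusters | `classify_transcript_clusters`, `classify_peak_clusters`, `volcano_flags` | early-peak / early-plateau / late rules over three contrasts; presence/absence for peaks |
| Motif enrichment | `read_meme_motifs`, `score_threshold`, `scan_sequence`, `hits_around_centers`, `enrichment_score`, `gc_correct`, `motif_pvalues`, `run_tfea` | exact DP score-distribution thresholds (p ≤ 1e-5), 3-kb scans around region centers, rank-weighted displacement statistic, GC correction, Z / permutation p-values |
| Peak calling | `call_peaks`, `peak_presence` | local-lambda Poisson scan (masked two-pass background), q ≤ 1e-5 and log2 fold change > 1 |
| Synthetic data | `sim_config`, `generate_genome`, `simulate_nascent_reads`, `simulate_gene_counts`, `simulate_atac` | seeded generators for genome, motif embeddings, stranded reads, NB counts, accessibility tracks |
| Orchestration | `pipeline_config`, `run_pipeline`, `stage_*`, `pipeline_cli` | one config, fixed-name outputs, per-stage derived seeds |

The enrichment score for a motif with best hit displacement `d_i` at the
ROI of rank `i` (of `N`) is

    E = Σ_i w_i (1 − 2 r_i) / Σ_i w_i ,   r_i = (i − 0.5)/N ,
    w_i = exp(−|d_i| / σ),  σ = 150 b

bounded in [−1, 1]: positive when motif instances near region centers
concentrate at the top of the differential ranking.

## Worked example

```r
library(tfdynamics)
cfg <- pipeline_config(seed = 42)
dir <- file.path(tempdir(), "demo")
run_pipeline(cfg, dir)

cl <- read.table(file.path(dir, "clusters_transcripts.tsv"),
                 header = TRUE, sep = "\t")
table(cl$label)
#>    early_peak early_plateau          late  unclassified
#>            87           114            95           704
```

The simulated world has 1000 genes (10% per induction archetype, 70%
null); the pipeline recovers the three archetypes at close to their
simulated frequencies, with the remainder honestly unclassified. The
enrichment report for the early contrast (vehicle vs 30 min):

```r
read.table(file.path(dir, "enrichment_d30v0.tsv"), header = TRUE)
#>   motif_id   e_raw e_corrected      z pvalue  padj n_hit_rois
#> 1 XRE_like  0.7909      0.7118  1.906 0.0566 0.340          4
#> 2  CTRL_AT -0.2843     -0.1338 -0.358 0.7201 0.806          4
#> 3  CTRL_GC  0.0000     -0.1939 -0.519 0.6035 0.806          0
#> ...
```

`XRE_like` — the motif the generator embeds preferentially at early-peak
origins — tops the ranking (E = 0.79); the embedded-at-chance controls
sit near zero. With only six motifs the across-motif Z test is
deliberately weak; `pvalue_mode = "permutation"` gives sharper,
calibrated inference and is what the acceptance tests exercise.

A command-line entry point mirrors the stages:

```sh
Rscript exec/tfdynamics run --dir out/ --seed 42
Rscript exec/tfdynamics simulate --dir out/ --config config.json
```

## Reanalysing real data

The package never downloads data. To run on real material, provide
strand-specific reads as BED6 (one file per sample, e.g. converted from
BAM with `bedtools bamtobed`), a genome FASTA, and a MEME-format motif
library, then call the stage functions directly; the study this design
follows is deposited as GEO GSE167372.
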