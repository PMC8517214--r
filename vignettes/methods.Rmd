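---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tfdynamics)
```

This vignette records the models behind each stage, the parameters that
matter (with units and defaults), what the synthetic generator does and
does not emulate, and the choices made where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## Coordinates and interval plumbing

All coordinates are 0-based half-open (BED convention), everywhere.
1-based formats are converted at the I/O boundary only; this removes a
whole class of off-by-one drift. Interval merging unions intervals on a
chromosome whose separation is at most `gap` bases (default 60, the
conventional distance for aggregating per-sample bidirectional calls),
transitively. Consensus regions of interest (ROIs) across samples are a
deliberately simple stand-in for probabilistic consensus tools: calls
within `gap` are unioned, the consensus center is the support-weighted
mean of member centers rounded *down* (so x.5 ties resolve toward the
lower coordinate, deterministically), and support counts member calls.
With per-sample calls jittered around a true origin the consensus center
converges at the jitter scale over replicates, which is all the
downstream 3-kb scan needs.

Read counting is unstranded by default with a one-or-more-base overlap
rule, matching the default behavior of the standard multi-sample
counting tools; a `stranded` flag is exposed because published designs
do not always state which was used.

## Bidirectional (eRNA) origin detection

Divergent transcription puts minus-strand reads immediately upstream and
plus-strand reads immediately downstream of an origin. The detector is a
simplified, synthetic-certified stand-in for full finite-mixture models
of polymerase loading:

1. 5′-end coverage per strand in `bin_size = 15` b bins (nascent run-on
   reads mark the polymerase position at their 5′ end; full-read pileup
   would blur the origin);
2. moving-average smoothing over 5 bins;
3. candidate summits = local maxima above a noise floor, the 95th
   percentile of nonzero smoothed bins on that strand;
4. a call pairs a minus summit at most `max_pair_distance = 600` b LEFT
   of a plus summit; center = summit midpoint; interval = center ±
   `flank = 750` b (so calls fit inside the 3-kb scan window);
5. strength = summed RPM in the interval, gated by `min_strength`;
   overlapping candidates resolve greedily by strength with centers kept
   more than `max_pair_distance` apart.

Accuracy claims are made only against synthetic truth (the generator
below), never against any published call counts: at 2000 reads/origin
and decay scale 150 b the suite verifies exactly one call per origin
within 75 b. Wrong-order summit pairs are never emitted, detection
commutes with coordinate translation up to binning, and plus-only signal
yields nothing.

## Differential activity

Normalization is median-of-ratios with geometric-mean-centered factors
(falling back, with a warning, to total-count scaling when no feature is
nonzero everywhere). The test is a documented negative-binomial
stand-in, not a re-implementation of any published tool's internals:

* moment dispersion per feature from the pooled within-group variance
  (`Var ≈ μ + αμ²`);
* a parametric mean–dispersion trend `α(μ) = a₀ + a₁/μ` fitted by a
  gamma GLM across features (median fallback when degenerate);
* the working dispersion is the moment estimate *moderated toward the
  trend* with `prior_df = 6` pseudo-degrees of freedom and *floored* at
  the trend:
  `α = max(trend, (df·α̂ + prior_df·trend)/(df + prior_df))`.
  The floor alone (the obvious reading of "trend floor") keeps every
  noisy overestimate at 2 replicates and costs real power: archetype
  recovery sat below the design goal of 90% in our simulations, while
  symmetric moderation without the floor inflated the null fraction
  toward the top of the acceptable band. The asymmetric hybrid keeps the
  3 vs 3 null fraction near 0.05 and restores 2-replicate power; the
  acceptance suite pins both (null p<0.05 fraction in [0.03, 0.07];
  ≥95% of 4-fold features at padj < 0.05);
* Wald test on `log2fc = log2((μ_B + 0.5)/(μ_A + 0.5))` with
  delta-method standard error; p of exactly 0 clamped to 1e-300 so ranks
  and plots stay finite (published tables likewise print adjusted p that
  "round to 0"). BH adjustment across features.

A global fold change applied to *every* feature is absorbed by
ratio-based normalization — by design, as for any median-of-ratios
method — so power simulations embed signal features among nulls.

Ranking for enrichment is by signed significance: upregulated by
ascending p, then unchanged by descending p, then downregulated by
descending p (most significant downregulation last); ties break by
|log2fc| then feature id, making the order total and reproducible. Raw
p is the default metric (whether published rankings used raw or adjusted
p is typically unstated; `use_padj` flips it).

Isoform filtering keeps, per gene, the isoform with the highest read
density (count / annotated length), ties to the longer annotation, then
the lexicographically smallest id.

## Temporal clusters

With contrasts early-vs-vehicle, late-vs-vehicle and late-vs-early, and
"up"/"down" meaning `padj < 0.05` with the corresponding sign:

* early peak: up(30v0) AND down(120v30);
* early plateau: up(30v0) AND up(120v0) AND NOT down(120v30);
* late: up(120v0) AND up(120v30).

The raw definitions can overlap (a gene can satisfy the peak and plateau
conjunctions simultaneously); precedence early_peak > early_plateau >
late, plus the NOT-down guard encoding "plateau", makes labels mutually
exclusive — disjoint reporting is what the standard Venn presentation
implies. Only induction clusters are labelled by default; `mirror =
TRUE` provides the symmetric repression classification. Peak clusters
use presence/absence: a consensus peak present only early is early peak,
present early and late (never in vehicle) is early plateau, present only
late is late; presence means ≥ `min_overlap = 1` base of overlap
(simplest definition, configurable).

## Motif displacement enrichment

**Scanning.** PWMs are scored as log-odds in bits against an order-0
background. Match thresholds are exact: the per-position score
distributions are convolved by dynamic programming on a 1e-3-bit grid,
and the threshold is the smallest *attainable* score whose null tail
probability is at most the cutoff (default 1e-5, the conventional value
for 3-kb regulatory scans). Two numerical details: (i) the returned
threshold subtracts half a grid step per position so that every word the
DP counted as passing also passes a real-valued comparison — otherwise
accumulated rounding can push the grid threshold above the true score of
the best word and silently drop exact matches; (ii) when the cutoff is
below the probability of the single best word the exact maximal score is
returned with a warning. Windows containing `N` are skipped rather than
scored against the background, so assembly gaps cannot distort the
threshold. Both strands are scanned; the scanner and the DP are verified
against brute-force enumeration in the test suite.

**Scoring.** Each ROI contributes at most its best hit (maximal score,
ties to smallest |displacement|); all hits feed the displacement
histograms. With normalized rank `r_i = (i − 0.5)/N` and weight
`w_i = exp(−|d_i|/σ)`, `σ = 150` b (the scale of the displacement the
generator embeds, and of enhancer motif positioning generally),

&nbsp;&nbsp;&nbsp;&nbsp;`E = Σ w_i (1 − 2 r_i) / Σ w_i`.

The functional form is this package's documented choice — the field's
published tools name the calculation but not a formula — validated by
calibration (embedding independent of rank ⇒ uniform permutation p) and
power (embedding concentrated in the top decile ⇒ detection) rather than
by matching another tool's output. E is bounded in [−1, 1], zero for no
hits (flagged), antisymmetric under rank reversal, and invariant to ROI
relabeling.

**Correction and inference.** E is corrected for sequence content by
OLS of `e_raw` on motif GC fraction across the motif set (residuals;
mean-centering when GC is constant; skipped with a warning below 5
motifs). P-values come either from Z scores across the motif set
(cheap, the default, and the convention in the field) or from
permutations of the ROI ranking (`n_perm ≥ 100`, one shared seeded set
of permutations, add-one smoothing; bit-identical under a fixed seed).
Both modes are exposed because the field's described "Z score" p-values
are ambiguous between the two; permutation mode is the validation path.

## Accessibility peaks

A local-lambda Poisson scan on binned counts: per bin, lambda is the
maximum of running means over 1-kb and 10-kb windows and the
chromosome-wide mean; Poisson upper-tail p-values are BH-adjusted and
bins at q ≤ 1e-5 become seeds; a peak spans the contiguous run of
relaxed-candidate bins (enriched vs the genome-wide rate at p < 1e-3,
gaps ≤ 2 bins) containing a seed; peaks must clear log2 fold change > 1
over their summed local background. Two implementation points that a
naive reading gets wrong: local windows must *exclude* enriched bins
(two-pass masking) or a 500-b peak inflates its own 1-kb background and
nothing is ever called; and clipping peaks to only their q-significant
bins truncates them below any reciprocal-overlap criterion — extension
to the relaxed-candidate run restores honest peak extents. Duplicate
handling, fragment-model shifting and scaling of published callers are
out of scope; the caller is exercised only on synthetic tracks.

## The synthetic world

The generator states one fixed world (defaults in `sim_config`):

* genome: i.i.d. bases, GC 0.45, 1 Mb per chromosome;
* origins: 50, ≥ ~5 kb apart (jittered grid), 2000 expected reads per
  origin per sample, strand chosen fairly, 5′ offsets exponential with
  scale 150 b, read length 30 b, uniform background at 0.002
  reads/base;
* genes: 1000, baselines log-uniform in [50, 5000], NB dispersion 0.05,
  2 replicates, archetype effects |log2fc| = 2 with proportions
  10/10/10/70% (peak/plateau/late/null);
* motif embedding: the consensus (argmax) word written into the
  sequence at Normal(0, sd) displacements clipped to ±1400 b, with
  per-center probabilities; consensus rather than PWM-sampled embedding
  guarantees hits at the stated scan threshold so recovery tests are
  sharp (a sampled mode would blur threshold effects into embedding
  noise);
* accessibility: Poisson background 2/bin (50-b bins) with flat-top
  500-b peaks at 8-fold, opened per time point by a schedule.

One seed fixes every output byte-for-byte; the pipeline derives
per-stage seeds as (first 7 hex digits of the md5 of the stage name)
XOR seed, keeping stage outputs independent but jointly reproducible.

What the generator does *not* emulate — and therefore what a green test
does not establish: mappability and GC amplification bias, fragment-level
structure (paired ends, duplicates), chromatin context, correlated
noise between replicates, overlapping or weak origins, and real motif
redundancy/degeneracy. Green tests certify the pipeline's statistical
contracts on data matching its model assumptions, not performance on any
particular sequencing run.

## Degenerate inputs and tie-breaks

Empty interval sets, all-zero tracks and hitless motifs are legal and
return empty/flagged results; zero p-values clamp to 1e-300; weighted
centers round down on .5; equal-score hits prefer the smaller
|displacement|; equal-density isoforms prefer the longer annotation then
the smaller id; identical differential records rank lexicographically.
Single-replicate groups are refused unless `pooled_dispersion = TRUE`
(which over-estimates dispersion in the presence of real effects, i.e.
is conservative).

## Known limitations

The origin detector assumes well-separated origins and symmetric decay;
closely spaced enhancers merge into one call. The NB stand-in has no
shrinkage of fold changes, no Cox–Reid adjustment, and a delta-method
Wald test that is slightly conservative at very low means. The Z-mode
enrichment p-value is relative to the motif set analysed — with few or
correlated motifs it is weak, and permutation mode should be preferred.
The peak caller has no input-control track and models counts as Poisson
(no overdispersion); real accessibility data would need the NB route.
Config files are JSON rather than YAML (no YAML parser in the supported
dependency set).
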