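---
title: "Quantifying spatially structured phage-bacteria coevolution: methods and design"
author: "phagecoev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatially structured phage-bacteria coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagecoev)
```

# The system and the pipeline

When motile *E. coli* and a lytic phage such as T7 coevolve on soft-agar
swimming plates, the bacteria expand as traveling waves, phage infections
carve lysis zones into them, resistant mutants re-colonise the cleared
territory, and the process repeats. This package provides the complete
quantitative pipeline for such an experiment:

1. **spatiotemporal** -- growth--lysis cycle counting and dominance maps from
   dark-field time-lapse stacks;
2. **plaque scoring** -- per-spot infectivity and turbidity from
   cross-infection plate images;
3. **infection network** -- matrix assembly, control concordance, phenotypic
   classes, nestedness (NODF) and Barber modularity with an equiprobable
   permutation null;
4. **genotype encoding** -- mutation tables to predictor matrices, with
   interval-event segmentation and coverage-based CNV candidate reports;
5. **Lasso association** -- sparse regression of infectivity on joint
   phage x bacterium genotypes with 5-fold CV and the one-standard-error
   rule;
6. **adaptive evolution statistics** -- a dN/dS permutation test preserving
   transition/transversion classes, and a multiply-mutated-gene simulation;
7. **synthetic data** -- generators for every input with known ground truth.

Every stage can therefore be validated end to end without any external
data: a generator plants the truth, the analysis recovers it, and the test
suite asserts the match.

# Time-lapse quantification

The raw stacks are dark-field images where bacterial density is bright and
cleared agar is dark. Preprocessing subtracts the first frame from all
later frames (clamping negatives at zero), keeps the red channel -- the one
with the best signal-to-noise in this imaging mode -- and crops to the
plate. Pixels are then averaged over 10 x 10 px blocks, and each block
trace is smoothed with a trailing 4-frame (30 min at 10 min/frame) moving
average whose first positions use a shrinking window so that the trace
keeps its length and frame indices keep their acquisition times.

A growth--lysis cycle is one peak of the block trace. Peaks are local
maxima filtered by **topographic prominence** (at least 4 intensity units)
and minimum spacing (20 frames), the spacing filter applied greedily from
the highest peak down with ties to the earlier index. Two choices deserve
comment:

* *Plateaus*: runs of exactly equal values count as a single candidate at
  the run centre. Noiseless synthetic data produce such plateaus routinely.
* *Boundary contours*: walking away from a peak, a side that meets strictly
  higher terrain contributes the minimum of the walked stretch; prominence
  is the height above the higher such minimum. A side that runs off the end
  of the recording without meeting higher terrain places no bound, and for
  the global maximum the reference is the trace minimum. The consequence is
  that territory bacteria hold until the last frame still counts as a
  full-prominence peak. Without this rule, any trace that rises and then
  simply stays colonised would contain *no* detectable peak at all, because
  the flat tail would cap the prominence of its own maximum at roughly the
  noise amplitude.

The dominance map summarises each block by `etaFinal` (intensity in the
last frame; bacteria-held territory) and `etaDiff = etaMax - etaFinal`
(intensity lost after the maximum; phage-cleared territory). The
plate-wide median cycle count is taken only over blocks whose maximal
intensity exceeds an activity floor, 4 by default -- equal to the
prominence threshold -- because empty agar never colonised by the wave
would otherwise pull the median down. The floor and the pixel-to-mm scale
are configuration, not results: neither is derivable from the image alone.

The timelapse generator renders a left-to-right traveling wave (raised
cosine ramp to a plateau of 100) and plants lysis events as raised-cosine
dips of controllable depth followed by regrowth, so each event adds
exactly one peak of prominence equal to its depth. Planted counts are
recovered exactly at zero noise, and on more than 95% of active blocks at
noise sd 1 (the acceptance suite measures this on a 50 x 50-block,
300-frame stack, with events at least 50 frames apart and depth 20).

# Plaque-image scoring

Each cross-infection plate carries a 8 x 12 grid of phage spots. The image
is cut into 181 x 181 px squares centred on the spots (`L` odd so a centre
pixel exists), and each square is normalized so that all pixels at or
above its 90th intensity percentile map to 255: we rescale by `255/p90`
and clip. The rescale-then-clip form fixes the behaviour of pixels below
the percentile (monotone, idempotent) which a bare "set the top decile to
255" prescription leaves open. Scores are then closed forms on the
normalized square `V` with `Vmax = 255`:

$$\mathrm{phageFraction} = \frac{\mathrm{phageArea}}{L^2},\qquad
  \mathrm{clearance} = 1 - \overline{V^{\mathrm{isPhage}}/V_{\max}},\qquad
  \mathrm{Infectivity} = \mathrm{phageFraction}\times\mathrm{clearance},$$

$$\mathrm{Turbidity} = \frac{1}{V_{\max} L^2}\sum V .$$

The lysis mask marks pixels strictly below a threshold; the default
threshold is Otsu's method on the pooled normalized plate histogram
(per-spot overrides are accepted), since dark-field lysis and lawn
populations are strongly bimodal. A spot with an empty mask scores
clearance 0 and infectivity 0 by convention -- the mean over an empty
pixel set is undefined and a spot without lysis must score zero. Because
normalization is per-region, all scores are invariant to global
multiplicative illumination changes.

About a quarter of the spots on a real plate are phage-free by design;
`carryoverQC()` flags any such spot whose infectivity exceeds a tolerance,
catching spot-to-spot carryover.

The plate generator renders plaques as centred squares (so any area
fraction up to 1 fits inside the region) and records the ground truth on
the post-normalization scale using the realized pixel counts, which is why
`scorePlate()` reproduces it to numerical precision rather than "within a
pixel".

# Infection-network structure

Per-spot scores are assembled into a phage x bacteria matrix in [0, 1];
duplicate measurements of a pair are averaged and unmeasured pairs are
`NA`. Replicate wildtype controls are compared by squared Pearson
correlation over pairwise-complete profiles.

Isolates are clustered on Euclidean distances with complete linkage and
classes are cut at 40% of the maximum merge height; all classes at the cut
are counted, including singletons. When missing cells exist they are
imputed with the mean of the present values in their 5 x 5 neighbourhood
in the class-sorted matrix (truncated at edges); the matrix is clustered
raw when complete, and imputed-then-reclustered otherwise.

The binarized matrix (strictly positive scores become 1; the threshold is
configurable but any detectable lysis counts by default) is reduced by
removing empty rows and columns, then:

* **NODF** (0--1 scale): every unordered pair of rows and of columns
  contributes the overlap fraction of the sparser line when the marginal
  totals strictly differ, else 0; NODF is the mean contribution. This is
  permutation-invariant and matches `vegan::nestednodf` (which the tests
  use as an independent cross-check, never as the implementation).
* **Barber modularity** $Q_b = \frac{1}{m}\sum_{ij}(A_{ij} - k_i d_j/m)\,
  \delta(g_i, g_j)$, maximized by the BRIM recursion (alternating optimal
  reassignment of one side given the other) from deterministic plus seeded
  random starts. The all-one-module partition ($Q_b = 0$) is always
  included, so the search never returns a negative value. On every binary
  matrix up to 3 x 3 and on seeded samples of 4 x 4 instances the search
  attains the exhaustive set-partition maximum; full enumeration of all
  65,535 4 x 4 matrices against a 4,140-partition oracle is
  computationally disproportionate in this implementation, so the suite
  samples them (this is the one deliberate reduction of an oracle's
  domain, and it is seeded and reproducible).

Significance uses the **equiprobable null**: matrices of the same shape
with i.i.d. Bernoulli entries at the observed fill fraction, the same
empty-line rule applied to each draw (degenerate draws score 0), and the
add-one estimator $p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n)$
so that zero exceedances at $n = 10^4$ reports $p < 10^{-4}$ rather than
0. Because the null's fill is estimated from the observed matrix itself,
p-values under the null are uniform only up to that plug-in estimation;
the calibration test in the suite draws observed matrices from the same
Bernoulli law and verifies uniformity by Kolmogorov--Smirnov at
$\alpha = 0.01$.

# Genotype encoding

Mutation tables use 1-based inclusive coordinates (GenBank convention).
SNPs, insertions and IS elements become binary predictors; synonymous
SNPs are omitted. Deletions and amplifications are first segmented at the
union of all event endpoints within a type, so overlapping events across
isolates are cut into shared unique segments (internally half-open so
covered bases are conserved exactly -- a per-base oracle verifies this on
random interval sets). Amplification segments carry integer copy number
with ancestral value 1; they are never merged with co-occurring
predictors, whereas other predictors with identical carrier vectors are
joined into one compound label (`+`-concatenated in genomic order).
Coverage-based CNV candidates replace a manual curation step: coverage is
median-normalized within the isolate, then divided by the
median-normalized ancestral coverage, and runs at >= 1.5 or <= 0.5 over a
configurable span (default 100 bp) are reported for review.

Observations for regression are deduplicated: one row per distinct joint
genotype, response = mean infectivity over pooled pairs, weight = pooled
pair count (weights sum to the number of scored pairs). Weighted fitting
is available behind a flag but off by default -- the plain description of
the analysis averages phenotypes and fits unweighted.

# Lasso association

`fitLasso()` fits the infectivity model over a 200-point geometric penalty
grid anchored at the analytic critical penalty (the smallest lambda
nulling every coefficient) and spanning four decades below it; a fixed raw
penalty value would be meaningless after internal standardization, which
is why the grid-length reading of the tuning parameter is used. Folds are
assigned on a content-canonical ordering of the observations, so the
selected support does not depend on input row order, and the fit is
deterministic given the seed. Selection uses the one-standard-error rule:
the largest penalty whose CV mean squared error is within one SE of the
minimum.

A property worth knowing when interpreting selections: with strong
effects, the CV error keeps decreasing below the support-only penalty
because of lasso shrinkage bias, and at n = 500 observations with 5-fold
CV the one-SE band (about 2.5% of the minimum MSE) is narrower than that
bias. The selected set then contains, beyond the planted effects, a
variable number of spurious predictors whose coefficients are an order of
magnitude smaller than any true effect (typically below 0.02 against true
effects of 0.3 and larger). The tests therefore assert what the procedure
actually guarantees -- the planted effects are recovered with their signs
and dominate the selection -- rather than an exact support match, and
`reportAssociations()` returns coefficients sorted so that the dominant
associations are immediately visible. Debiased (relaxed) refits would
sharpen the support but are deliberately out of scope: the package
implements the plain cross-validated lasso its users expect.

# Adaptive-evolution statistics

`classifySnp()` translates the containing codon before and after the
substitution (reverse-complementing minus-strand ORFs); stop gains and
losses count as nonsynonymous, stop-to-stop as synonymous, and a position
inside overlapping ORFs is nonsynonymous if it is nonsynonymous in any of
them.

The **dN/dS permutation** excludes intergenic SNPs, then re-places each
intragenic event uniformly over all concatenated ORF nucleotide positions
(longer ORFs receive proportionally more placements -- no per-ORF
weighting is stated or assumed) and draws the alt allele to preserve the
event's own substitution class: a transition keeps its unique partner, a
transversion chooses uniformly between its two. Recurrent events are
counted once by default; a flag re-places them once per replicate plate
instead, since the verbal description of "accounting for" recurrences is
ambiguous. The simulated nonsynonymous count is compared with the observed
one and the add-one p-value reported. On toy genomes with analytically
known per-placement nonsynonymous probabilities (all-TGG: every change
nonsynonymous; fourfold-degenerate third positions: known synonymous
excess) the simulated counts match exact binomial tails within Monte-Carlo
error at 10,000 replicates.

The **multiply-mutated-gene simulation** keeps every mutation event with
all its properties except position, re-places it uniformly over the whole
genome (an event seen in *m* parallel replicate plates is drawn *m* times;
interval events mark every overlapped gene), and records each replicate's
maximal per-gene count. The significance threshold c* is the smallest
count attained by at most 5% of replicates -- a family-wise criterion,
chosen because the verbal rule thresholds where few simulations "reach the
experimental value"; a per-gene variant is available behind a flag.
Default replicate counts are 10,000 (dN/dS), 500 (bacterial multihit) and
5,000 (phage multihit).

# The synthetic-data module

The generators emulate the statistical structure each analysis stage
assumes, not the underlying biology: no chemotaxis PDEs, no phage
population genetics, no optics. Concretely:

* traveling waves are kinematic ramps, lysis events are raised-cosine dips
  with controllable prominence;
* plate images are flat lawns with square plaques and optional Gaussian
  pixel noise; ground truth is recorded on the post-normalization scale;
* infectivity matrices follow additive-then-clip:
  $\mathrm{clip}(\beta_0 + \sum_j \beta_j x_j + \varepsilon,\,0,\,1)$ with
  i.i.d. Bernoulli(0.35) carriers, baseline 0.5 (mid-scale, maximising the
  unclipped linear range), effect magnitudes 0.3--0.5, bacterial effects
  negative (resistance) and phage effects positive (infectivity), noise sd
  0.05. Clipping is biologically meaningful (complete resistance,
  saturated infection) but censors the linear model where several
  same-sign effects stack; tests that probe the regression itself
  therefore use balanced planted models where saturation is rare, and the
  recovery-rate figure reported by the acceptance script quantifies the
  procedure under the unbalanced default conditions honestly;
* toy genomes are built from designed codon compositions so the
  nonsynonymous placement probabilities are known by enumeration, with
  ORFs on either strand and round-trippable FASTA + GFF3 output.

All generators are pure functions of their parameters and seed:
bit-identical outputs on repeated calls.

# Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path while completing in minutes on a
single core: 50 x 50-block stacks with 300 frames for cycle recovery;
exhaustive oracle comparisons up to 3 x 3 with seeded 4 x 4 samples for the
bipartite statistics; 200 replicates of 1,000 null draws for calibration;
20 seeds of n = 500 / p = 50 for the regression; 10,000 permutation
replicates for dN/dS and 5,000 for the multihit simulation. Every stochastic
step takes an explicit integer seed and restores the caller's RNG state.

# Known limitations

* Spot centres must lie on a regular grid (or be supplied); free-form spot
  detection is out of scope, as are plaque morphology typing and
  fluorescence two-colour analyses.
* The pipeline starts from mutation tables; read alignment and variant
  calling belong upstream.
* Nestedness and modularity are computed on binarized matrices; weighted
  variants and alternative null models (fixed-degree, proportional) are
  not implemented.
* The BRIM search is exact on the small instances the tests enumerate but
  heuristic in general, as any modularity maximiser must be.
* The coverage CNV report flags candidates; it does not genotype
  breakpoints.
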