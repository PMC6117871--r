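---
title: "Methods: striatal interneuron taxonomy and PatchSeq analysis with striacell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: striatal interneuron taxonomy and PatchSeq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`striacell` implements the computational pipeline used to build a
single-cell taxonomy of striatal interneurons from UMI counts and to link
PatchSeq transcriptomes to that taxonomy and to intrinsic
electrophysiology: dataset-specific quality control, total-count
normalization, variable-gene selection, a pluggable clustering stage with
classifier-based robustness assessment, marker enrichment scoring and
gene-by-type specificity, a rank-1 negative-binomial latent factor model
for within-cluster gradients, Spearman and Wilcoxon screens with
Benjamini-Hochberg control, specificity-weighted bootstrap assignment of
query cells, and intrinsic-feature extraction from current-clamp sweeps.
Synthetic-data generators with exact ground truth accompany every stage,
so the whole pipeline is testable without any external download.

# Quality control and normalization

Three QC schemes are implemented with the inequalities exactly as their
thresholds are usually stated, strict where "more than"/"less than" is
meant:

* `qcDatasetA()`: cells pass with **more than** 1,500 molecules; genes
  with fewer than 25 molecules over the whole dataset are removed.
* `qcDatasetB()`: cells fail with fewer than 800 UMIs, a total-UMI to
  genes-detected ratio **strictly below** 1.2 (exactly 1.2 passes), or
  more than zero molecules of any configured non-neuronal marker
  (defaults: Mog, Mbp, Aqp4, Gja1, C1qc, Aif1, Fn1, Cldn5). Cells with no
  genes detected fail with a dedicated reason code since the ratio is
  undefined. The genes-detected denominator is computed on the full gene
  set, before any marker removal.
* `qcPatchseq()`: mitochondrial and rRNA genes are removed from both
  tallies; a cell passes with **more than** 2,000 molecules OR more than
  1,000 distinct genes (inclusive disjunction).

`normalizeTotal()` scales each cell to a 2,000-molecule total and, by
default, rounds to the closest integer. Rounding is half-away-from-zero;
on this arithmetic half-integers are rare and the choice only matters at
ties. Activity-dependent and mito/rRNA gene lists ship as editable
configuration (`geneListConfig()`, `readGeneList()`) because the original
lists are external; manual doublet exclusions can be supplied as a cell
list rather than being automated.

# Clustering scaffold

The discrete clustering brand used originally (a biclustering algorithm
published elsewhere) is deliberately not reimplemented: `clusterCells()`
is an explicit stand-in — log2(x+1) counts on the variable genes,
correlation distance, Ward agglomeration — and every downstream stage
accepts any `ClusterAssignment`, including one read from file. This keeps
the package's own computations independent of one clustering choice.

Variable genes come from the log(CV)-vs-log(mean) procedure: an ordinary
least-squares line in log10 space over genes with positive mean, genes
ranked by residual, with an epsilon guard (1e-8) so zero-variance genes
can never outrank genuinely dispersed ones. The selection is invariant to
global rescaling of the counts.

`assessRobustness()` holds out a stratified 20% of each cluster, trains a
random forest (200 trees by default; the ensemble choice is not critical
and any multi-class learner satisfies the contract) on log2 counts, and
reports per-cluster precision, recall and the held-out confusion
probability matrix, whose rows sum to one. One split is the default; the
split can be repeated and averaged since the original procedure does not
state a repetition count.

`clusterMeanDendrogram()` normalizes each cell to 10,000 molecules,
log2(x+1)-transforms, averages within clusters, and links with Ward on
correlation distance (`ward.D2`, which squares dissimilarities internally
and is the closest R analogue of the MATLAB Ward rule). Trees export as
Newick via `dendrogramNewick()`.

# Marker scores and specificity

For gene *i* and cluster *j*,

$$\mathrm{enrich}_{i,j} =
  \frac{\frac{1}{|j|}\sum_{k \in j} E_{i,k}}
       {\frac{1}{N}\sum_{k} E_{i,k}},\qquad
  \mathrm{posfrac}_{i,j} = \frac{1}{|j|}\sum_{k \in j} I(E_{i,k}>0),
  \qquad S_{i,j} = \mathrm{enrich}_{i,j}\cdot
  \mathrm{posfrac}_{i,j}^{\,\mathrm{power}}$$

with powers 0, 0.5 and 1 by default; the power sets the weight given to
the fraction of positive cells. Genes with zero global mean carry zero
enrichment by convention. Ranking ties break lexicographically by gene id
for determinism. Scores are usually computed on normalized counts; raw
counts are accepted.

Specificity follows the expression-weighted cell-type enrichment
convention: a gene's cluster mean divided by the sum of its cluster
means, so each expressed gene distributes exactly one unit of specificity
across types. The formula sits behind `SpecificityMatrix` so alternatives
can be swapped.

# PatchSeq mapping

A query cell's observed score for cluster *j* is
$\sum_{g \in G} x_g\, s_{g,j}$ over the variance-filtered marker panel
*G* (population SD of raw read counts at least 1; the boundary is kept).
The null re-draws $|G|$ genes uniformly without replacement from the
background universe (all reference genes with a nonzero profile), pairing
the *i*-th drawn gene's specificity with the *i*-th observed count —
counts keep their order, gene identity is randomized. Empirical p-values
use the add-one convention, $(1 + \#\{\mathrm{null} \ge
\mathrm{obs}\})/(B+1)$, so they live in $[1/(B+1), 1]$ and the pipeline is
bit-reproducible given the seed. A cell is assigned to the argmin-p
cluster when that minimum is below alpha (0.05), with ties reported as
"undefined"; no multiplicity correction is applied over the J clusters,
matching the original assignment rule. `mapDataset()` draws one shared
set of B null gene lists for all cells, which is statistically equivalent
per cell and much faster.

The reference is total-count-normalized before specificity is computed
(`normalize_reference = TRUE`): with raw counts, library-size noise tilts
cluster means and can generically inflate one cluster's scores for every
query cell. Query-side scores and the SD filter use raw read counts.

**Selection-effect caveat.** Because specificities sum to one across
clusters, the J observed scores of a cell sum to a constant shared with
every null draw; extremes are therefore anti-correlated across clusters,
and taking the minimum p over J = 7 clusters at alpha = 0.05 yields a
null (gene-permuted) assignment rate far above alpha — about 0.65 under
the default generator (it also reflects that the marker panel's
specificity values are more dispersed than random gene lists', inflating
marginal tails to ~0.10 per cluster). This is a property of the
uncorrected min-p rule itself, documented rather than corrected, and it
is why the package reports the null assignment rate in its acceptance
output instead of claiming per-cell calibration.

# Rank-1 negative-binomial latent factor

Within one cluster, filtered to genes with over three reads in over
eight cells, the model is

$$\log \mu_{ig} = \log s_i + a_g + f_i^{\top} c_g + w_g z_i$$

with NB observations (variance $\mu + \mu^2/\theta$, one shared
$\theta$), library-size offsets $s_i$ equalizing per-cell totals, and one
indicator column per plate except a reference plate. Fitting is block
coordinate ascent: per-gene IRLS regressions given z, a 1-D likelihood
maximization of $\theta$ on a log grid, and per-cell 1-D maximizations of
$z_i$ (the per-cell log-likelihood is concave in $z_i$ under the log
link). z is standardized after every sweep, with the scale re-absorbed
into weights and intercepts so the likelihood is untouched, and the
global sign is fixed so the gene with the largest |w| has positive
weight. The log-likelihood trace is non-decreasing by construction; the
fit stops at a relative change below 1e-6 or 200 outer sweeps.

Initialization is the first principal component of the log2-normalized
matrix, residualized on the covariate design. The residualization is the
package's own choice: the confounded direction (batch variance carried
either by $c_g$ or by $w_g z_i$) is likelihood-flat, so an initialization
inside it would never leave; starting orthogonal to the design lets the
covariates absorb batch structure, which is the point of including them.
A constant matrix returns a degenerate model with zero weights rather
than an error. This module is a self-contained reimplementation of
intent — the originally cited factor-analysis code's link, penalty and
dispersion handling are unpublished — so its real-data scores need not
match any previously printed factor value.

Associations: `factorGeneAssociation()` fits an NB GLM of a gene's counts
on z (offsets and design included; Wald p);
`factorEphysAssociation()` projects query expression as
$\sum_g w_g \log(x_{ig}+1)$ (at least 10 overlapping genes) and fits an
ordinary linear model of the electrophysiological parameter on the
projection.

The tSNE-gradient screen keeps genes detected in more than 10% of the
cluster's cells and less than 70% of all cells — "less abundant than 70%"
is read as a detection fraction — and reports Pearson correlations of
(log) expression with the x and y embedding coordinates. Embedding
coordinates are treated strictly as input; perplexity and related
settings belong to the external embedding tool.

# Screens

`bhAdjust()` validates inputs and applies the standard step-up
adjustment. `ranksumTest()` enumerates all group assignments of the
pooled average ranks when $n_A + n_B \le 10$ — exact even under ties —
and otherwise uses the tie-corrected normal approximation with continuity
correction. `wilcoxonDE()` runs per gene at the single-cell level over
genes detected in at least one cell of either group; fold change is
$(\bar{x}_A + \varepsilon)/(\bar{x}_B + \varepsilon)$ with
$\varepsilon = 0.01$ normalized molecules (the zero-handling is otherwise
undefined; $\varepsilon$ is a config knob), and significance requires
q < 0.05 and $|\log_2 \mathrm{FC}| \ge 1$. `spearmanScreen()` uses
average-rank ties, the t approximation (exhaustive rank permutation for
n of at most 9), BH over all testable genes except the target itself, and
classifies genes positive/negative at rho beyond ±0.15 with q < 0.05.
Spearman is computed on normalized counts by default — only tie patterns
can differ from raw counts.

# Electrophysiology

`detectAPs()` finds threshold crossings of dV/dt at 10 mV/ms (a
conventional criterion; configurable). The detection derivative is taken
on a ~0.25 ms boxcar-smoothed copy of the trace so recording noise cannot
push subthreshold transients over the slope criterion; every voltage
measurement (threshold, peak, widths) is then read off the raw trace.
Events must rise at least 10 mV above their threshold voltage;
half-width interpolates linearly at half amplitude; the AHP trough is
searched until the next event, and a second trough separated by at least
0.5 mV of recovery is reported as a biphasic AHP.

`extractFeatures()` computes: RMP (pre-stimulus baseline of the first
sweep); Rin from the steady-state deflection of the smallest
hyperpolarizing step; the membrane time constant from a profiled
least-squares single-exponential fit (free offset) to the onset decay;
sag as (peak − steady-state)/peak deflection on the largest
hyperpolarizing step, both relative to baseline, with the slow extrema
read off a 1-ms smoothed trace; rebound as the post-stimulus peak minus
baseline; rheobase as the smallest current eliciting an AP, with the
single-AP features and the latency to the first spike taken from that
sweep's first AP; and, scanning upward from rheobase until a silent sweep
(firing failure), the maximum firing frequency (APs per stimulus
duration), steady frequency over the last half of that sweep, adaptation
index $(\mathrm{ISI}_{last}-\mathrm{ISI}_{first})/(\mathrm{ISI}_{last}+
\mathrm{ISI}_{first})$ (named but not defined in the original; this
symmetric form is the package's choice) and mean inter-event interval.
Features that cannot be measured are NA and flagged. Recording-quality
exclusion removes cells with AP half-width strictly above 2 ms or
amplitude strictly below 40 mV; cells whose AP features are unmeasurable
are kept with a warning since the rule cannot be evaluated.

For the population analyses, parameters are signed-log transformed
($\mathrm{sign}(v)\log(1+|v|)$, since RMP and rebound can be negative)
and z-scored; PCA uses SVD with parameter-median imputation (imputed
cells are listed; pairwise tests never impute); group comparisons are
Welch t-tests with BH over parameters; hierarchical clustering uses
Euclidean distance with average linkage. The 19-parameter set is the
package's documented default (`ephysParameterSet()`); the 15-parameter
subset drops the biphasic-AHP and latency entries.

# Synthetic data: what it emulates, and what it does not

`simulateCounts()` draws NB counts (variance $\mu + \mu^2/\theta$,
$\theta = 2$) around log-normal baseline means with log-normal library
sizes (sdlog 0.3), K = 7 clusters of 100 cells by default, 28 exclusive
marker genes per cluster at 4-fold enrichment — so the default marker
panel is ~196 genes, the size of a realistic informative panel for this
many populations — optional per-gene plate effects, and an optional
rank-1 within-cluster gradient $\exp(w^*_g z^*_i)$ emulating the
continuum observed inside a discrete type. Defaults give roughly 2,000
total molecules per cell, matching the normalization target. It does not
emulate: transcriptome-wide gene counts, dropout structure beyond NB
sampling, doublets, ambient contamination, or correlated gene programs;
passing tests therefore demonstrate algorithmic correctness under the
stated model, not performance on real tissue.

`simulateSweeps()` is phenomenological by design: a leaky-integrator
membrane with a slow H-current-like gate (sag and rebound), a
spike-triggered adaptation current, depolarization block above a ceiling
current, and stereotyped triangular spike waveforms inserted at threshold
crossings — so every ground-truth feature is exactly controllable, which
conductance-based models do not allow. Ground truth comes from the
model's own constants (waveform geometry, threshold placement — rheobase
is exact by construction on the 1 pA protocol grid) and from the
noiseless deterministic trace and event log; Gaussian recording noise
(0.1 mV) is added only to the emitted traces. The late-spiking archetype
solves its drive ramp time constant so the first spike at rheobase lands
on the configured 150 ms latency. Five spiking archetypes mirror
fast-spiking, fast-spiking-like, late-spiking, bursting/low-threshold and
regular phenotypes; a passive archetype provides a pure RC benchmark.

# Numerical choices and problem sizes

Tolerances: latent factor 1e-6 relative log-likelihood; specificity rows
sum to 1 within 1e-9; marker scores reproduce a literal transcription of
their formulas to 1e-12. Tie-breaks are lexicographic wherever a ranking
is emitted. Degenerate inputs (constant matrices, zero-total cells,
all-zero genes, singleton clusters) are either flagged or rejected with
named errors, as documented per function. The test-suite problem sizes —
e.g. 20 latent-factor fits of 200 cells by 100 genes, 1,000 null query
cells at B = 1,000, 100 simulated recordings per archetype — were chosen
as the smallest sizes at which the recovery statistics stabilize.

# Known limitations

* The clustering stage is a stand-in; results depending on a specific
  clustering brand should load that brand's assignments from file.
* The latent factor is strictly rank-1 with a shared dispersion;
  multi-factor continua are out of scope.
* The bootstrap mapping's min-p assignment is uncorrected over clusters
  (see the selection-effect caveat above).
* The trace simulator is not conductance-based; it cannot produce
  subthreshold oscillations, spike-frequency phenomena beyond its single
  adaptation current, or realistic spike shapes beyond the planted
  geometry.
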