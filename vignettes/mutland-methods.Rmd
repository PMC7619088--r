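---
title: "Methods: variant classification and sensitivity segmentation in mutland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant classification and sensitivity segmentation in mutland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutland)
```

# Overview

`mutland` interprets the *mutational landscape* of a protein: the 19 × L
matrix of predicted effects of every single amino-acid substitution in a
query of length L, derived from a multiple sequence alignment (MSA). Raw
evolutionary scores are dimensionless, with more negative values indicating
stronger predicted functional impact. Around this matrix the package builds
four analyses:

1. **MSA quality control** — per-column gap content, substitution sampling
   and conservation; per-sequence identity to the query.
2. **Three-tier variant classification** — a three-component Gaussian
   mixture fitted to the pooled score distribution yields two thresholds
   separating *impactful*, *mild* and *neutral* variants, and residues are
   called *sensitive* or *tolerant*.
3. **Sensitivity-profile segmentation** — the per-residue mean of the 19
   substitution scores is segmented by exact penalised changepoint
   detection, highlighting peptides in disordered regions that evolve under
   locally stronger constraint than their background.
4. **Structure-aware modulation** — relative solvent accessibility (RSA)
   computed from a PDB structure rescales each score so buried, constrained
   positions are emphasised.

The package ships synthetic generators for all of its inputs, so every
claim in this vignette is exercised by the test suite on data with known
generating truth.

# Input conventions

MSAs are accepted in A2M, A3M or aligned FASTA. The first record is the
query and must be gap-free after normalisation; this is an error, not a
silent repair, because every downstream coordinate (positions 1..L,
1-based everywhere in user-facing output) is defined on the ungapped query.
In A2M/A3M, lowercase letters and dots are insertions relative to the query
and are removed; the three dialects therefore normalise to the same
rectangular alignment, which is a tested invariant.

`X` and other non-standard letters in homolog rows are treated as gap-like
in all column statistics: they carry no substitution identity, so counting
them as observations would overstate both conservation and substitution
sampling.

The conservation statistic is deliberately simple — the modal non-gap
amino-acid frequency of the column — and is exposed as a pluggable function
(`column_stats(..., conservation_fun = )`). Tree-aware conservation
measures are out of scope here.

# Scores: ingestion and the baseline scorer

External 19 × L score matrices (e.g. from an upstream evolutionary-score
predictor) are ingested from long-form or grid CSV, with wild-type letters
validated against the query. Wild-type cells are *masked*, not scored 0:
they are not variants, and including ~L zeros would visibly distort the
mixture fit. Missing substitution cells are tolerated — the sensitivity
profile averages over available cells and the affected variants are
reported as `unscored` — so partial matrices do not abort a run.

When no matrix is supplied, `baseline_scores()` computes column log-odds

$$ s(i, a) = \log\frac{c_i(a) + p}{c_i(\mathrm{wt}_i) + p} $$

with non-gap column counts $c_i$ and pseudocount $p$ (default 1). This is a
column-independent conservation score: no phylogeny, no epistasis, no
sequence reweighting. It exists so the toolkit is self-contained and
testable; it is labelled `"baseline"` in every output so it cannot be
mistaken for the output of a dedicated predictor. On a query-only MSA it
degenerates to the constant $\log(p/(1+p))$, a contract the tests pin down.

# Variant classification

The pooled finite scores of a protein are modelled as a mixture of three
Gaussians with free weights, means and variances. Fitting is by EM with

* 10 restarts — the first from deterministic quantile initialisation
  (means at the 1/6, 3/6, 5/6 quantiles), the rest from seeded jittered
  quantiles,
* convergence tolerance 1e-6 on the log-likelihood, at most 500 iterations,
* a variance floor of 1e-8, with collapsed restarts discarded,
* a hard minimum of 30 finite scores.

These settings trade a little speed for reproducibility: the same data and
seed always give the same fit, and on well-separated components any seed
reaches the same optimum. The fit is cross-checked in the test suite
against an independent mixture implementation (`mclust`) on the same data.

Components are sorted by mean ascending (most negative = impactful). Each
classification threshold is the **weighted-density crossover** between
adjacent components: the score where $w_j\,\phi(x;\mu_j,\sigma_j^2) =
w_{j+1}\,\phi(x;\mu_{j+1},\sigma_{j+1}^2)$, solved in closed form from the
quadratic in $x$, restricted to the open interval between the two means.
With equal weights and variances this is the midpoint; with unequal
weights it shifts toward the lighter component. If no crossing exists in
the interval (heavily overlapping components), the midpoint of the two
means is used and flagged in the output metadata. The crossover is the
point where the posterior flips between components, which is the natural
boundary the mixture itself defines.

Scores strictly below the lower threshold are *impactful*, scores at or
above the upper threshold *neutral*, the rest *mild*. A score exactly equal
to a threshold belongs to the milder class — a conservative tie-break for
pathogenicity calling, tested explicitly. A residue is *tolerant* when at
least 10 of its 19 substitutions (more than half) are neutral; unscored
substitutions count as non-neutral, since absence of evidence should not
manufacture tolerance.

The mixture is fitted on **all** finite scores, including positions later
flagged non-confident; confidence is reported alongside, not used as a
filter, so that flagging thresholds cannot silently change the
classification of other variants.

## Confidence flags

A position is non-confident when its 19 scores show low dispersion *and*
the column is poorly conserved *and* (the column is highly gapped *or* few
of the 19 substitutions are sampled). The logical shape of this rule is
fixed; the cut-offs are configuration with defaults

| parameter | meaning | default |
|---|---|---|
| `d_min` | score dispersion (sd of the 19 scores) below which a position is suspect | 0.2 |
| `c_min` | modal-frequency conservation below which a column is "poorly conserved" | 0.3 |
| `g_max` | gap fraction above which a column is "highly gapped" | 0.5 |
| `s_min` | minimum distinct substitutions observed in the column | 5 |

These defaults are declared choices, not values inferred from data; they
are deliberately permissive so the flag marks only clearly
information-poor positions. A position with no finite scores at all is
treated as dispersion 0, so it can only be flagged, never rescued, by the
dispersion clause. Tightening `g_max` or `c_min` can only shrink the
confident set, a monotonicity property the tests check.

# Sensitivity-profile segmentation

The mutational sensitivity of residue $i$ is the mean of its 19
substitution scores. The profile $y_1,\dots,y_n$ ($n = L$) is modelled as
piecewise constant with independent Gaussian noise of common variance
$\sigma^2$ and segment means $\mu_j$. The segmentation minimises

$$ \sum_j \sum_{i \in \mathrm{seg}_j} w_i\,(y_i - \mu_j)^2 \;+\;
   \beta\,(K - 1), \qquad \beta = \alpha\,\hat\sigma^2 \log n, $$

exactly, over all K and all segmentations, with $\alpha = 1.4$ by default.
$\alpha$ is the user-facing granularity knob: larger values merge segments.

**Noise variance.** $\hat\sigma^2$ is the Hall difference-based estimator
with the optimal fourth-order coefficients
$(0.1942, 0.2809, 0.3832, -0.8582)$. Because the coefficients sum to zero,
a piecewise-constant mean cancels except in the few windows straddling a
changepoint, so the estimator stays close to the noise variance even in the
presence of real segments (within 20% with 3σ jumps in the tests; the
published coefficients are rounded to four decimals, so a constant signal
yields ~1e-7 rather than exactly 0). The estimator is computed on the
*unweighted* profile: $\sigma^2$ is a property of the observation noise,
whereas the weights below encode trust, and mixing the two would couple the
penalty to the structure input. One global $\sigma^2$ is used per protein.

**Weights.** Residues in high-confidence structured regions (pLDDT
strictly above 70) receive weight 0.1, all others weight 1. Ordered regions
show larger sensitivity variance, which would otherwise cause
over-segmentation exactly where segment detection matters least; the
disordered regions keep full weight. Weights require the user to declare
the structure an AlphaFold-type model — experimental B-factors are never
interpreted as pLDDT. Without a structure (or for residues not aligned to
it) all weights are 1.

**Solver.** The minimiser is computed by optimal partitioning with
functional candidate tracking: for every candidate changepoint the cost of
the current segment is held as a quadratic in its mean and updated in O(1)
per observation, and candidates whose minimum exceeds the running optimum
plus the penalty are pruned. The result is the exact global optimum; the
test suite verifies equality (changepoints and penalised cost) with an
exhaustive O(n²) dynamic program on hundreds of random weighted instances.
Among equal-cost optima the most recent changepoint wins, so a zero
penalty returns n singleton segments with zero cost — the degenerate
contract used to test the penalty limits.

**Segment scores.** On the raw scale, lower mean = higher sensitivity. A
segment scores 2 when its mean is strictly below both flanking means, 1
when below exactly one, else 0. The direction is chosen so that "elevated
sensitivity versus both neighbours" is the top score; ties are not
elevated, and terminal segments, having one neighbour, score at most 1. A
segment is *highlighted* as a putative functional element when it scores at
least 1 and lies in a disordered region — majority of positions with pLDDT
below 70, with unaligned or structure-less positions counted as
unstructured (no structural evidence of order).

# Structural context

**Chain parsing.** The first model of a PDB file is read via `bio3d`;
waters are dropped, alternate locations resolve to the highest-occupancy
copy, and non-standard residues map to standard equivalents through a
curated dictionary (MSE→M, SEP→S, TPO→T, PTR→Y, MLY/M3L→K, HYP→P, and a
few more); unmapped residues are dropped. Per-residue B-factor is the mean
over the residue's atoms (for AlphaFold models all atoms of a residue share
the pLDDT, so the mean is exact).

**Sequence–structure mapping.** The query is globally aligned to the chain
sequence under match 1.0, mismatch −3.0, gap opening −2.5, gap extension
−2.0, with terminal gaps scored at the extension-only rate (−2.0 per
position). Ties are broken deterministically: diagonal over up over left.
The optimal score is verified against an independent affine-gap dynamic
program on hundreds of random pairs, and the mapping is strictly monotone
by construction. Runs where the aligned identity falls below 30% are
flagged in the run summary but not refused.

**Solvent accessibility.** Per-atom accessible surface area uses
Shrake–Rupley sphere sampling with probe radius 1.4 Å and 100 points per
atom on a Fibonacci lattice, summed per residue; RSA is the residue ASA as
a percentage of the theoretical maximum for its residue type from the
Tien et al. (2013) table (overridable, and named in the run metadata,
since RSA depends on this choice). For multimeric files both contexts are
computed: *complexed* (other chains occlude solvent) and *free* (chain in
isolation). Because occluders can only block sample points,
RSA(free) ≥ RSA(complexed) holds exactly, residue by residue. At 100
points each sample is 1% of an atom sphere, so per-residue RSA carries a
discretisation granularity of a few points; doubling the density from 200
to 400 points moves fixture RSAs by under 2 points.

**Score modulation.** For mapped positions,

$$ \mathrm{pred}^{RSA}_{evol} = \mathrm{pred}_{evol} \times
   \left(1 - \frac{\min(\mathrm{RSA}, 100)}{100}\right), $$

so a fully buried residue keeps its score and a fully exposed one is
zeroed; RSA is capped at 100% to absorb accessibilities above the
theoretical maximum. The multiplier lies in [0, 1], so the modulated score
never grows in magnitude and never changes sign. Unmapped query positions
get NaN in all 19 cells and are marked `unaligned` in exports — the CSV
writer deliberately preserves the NaN/NA distinction so unaligned (NaN)
and unscored (NA) stay distinguishable downstream. When a multimer is
supplied the complexed RSA feeds the modulation by default (binding
interfaces are then emphasised); both RSA columns are always exported.

# Synthetic data: what it does and does not emulate

The generators define the study conditions for all tests:

* `generate_synthetic_msa()` — conserved motifs (low-entropy columns)
  inside a divergent background (high-entropy columns, 5% gaps by
  default), query = consensus. It emulates the "island of constraint in a
  disordered background" situation; it does **not** emulate phylogenetic
  correlation between rows, realistic substitution matrices, or alignment
  errors.
* `generate_synthetic_landscape()` — scores drawn from a three-Gaussian
  mixture (defaults: means −8/−4/0, sd 0.5, weights 0.3/0.3/0.4) with
  optional segment-level mean shifts; returns the generating components,
  thresholds and changepoints as truth for recovery tests.
* `generate_piecewise_signal()` — piecewise-constant mean plus Gaussian
  noise, for changepoint and variance-estimator experiments.
* `generate_toy_structure()` — idealised helix/extended backbones with a
  CB placeholder, one or two chains (the second in contact to create a
  buried interface), optional synthetic pLDDT in the B-factor column. The
  geometry exercises parsing, alignment, accessibility and export code; it
  is not physically realistic.

Problem sizes in the tests (e.g. n = 300 signals over 100 seeds, 200
random instances against the exhaustive oracle, 500 alignment pairs,
L = 120 pipeline fixtures) were chosen to give stable pass/fail statistics
at interactive runtimes. Passing tests on these fixtures demonstrates the
correctness of the algorithms and their contracts; it does not certify
predictive accuracy on real proteins, which depends on the upstream score
matrix and alignment quality.

# Numerical and design notes

* All randomness flows through explicit integer seeds (`withr::with_seed`);
  identical config + seed gives byte-identical CSV outputs.
* The changepoint tie-break (latest changepoint wins) and the alignment
  tie-break (diagonal > up > left) are fixed so results are reproducible
  across platforms.
* Equal-cost alignment or segmentation optima are resolved by those
  tie-breaks; for continuous inputs exact ties have probability zero.
* The mixture thresholds use the closed-form quadratic; a dense grid search
  is used as the oracle in tests, not in production.
* Degenerate inputs have defined behaviour rather than errors where a
  sensible value exists: empty columns (gap fraction 1, conservation 0),
  query-only MSAs (constant baseline landscape), single-segment profiles
  (score 0), structures with zero mappable residues (error, since nothing
  downstream is computable).

# Known limitations

* The baseline scorer is a stand-in: it measures column conservation only
  and will not reproduce the accuracy of predictors that model phylogeny
  or epistasis. Bring an external matrix for real analyses.
* The confidence cut-offs are declared defaults, not calibrated values.
* Hall's estimator assumes roughly homoscedastic noise; strongly
  heteroscedastic profiles will mis-estimate the penalty scale (the pLDDT
  weighting mitigates the main known source, ordered-region variance).
* One chain is analysed per run; other chains enter only as occluders.
* mmCIF input is not parsed; convert to PDB first.
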