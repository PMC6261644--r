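---
title: "Methods: quantifying enhancer activity, shape and noise in synthetic STARR-seq screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying enhancer activity, shape and noise in synthetic STARR-seq screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synstarr)
```

# The assay and what the package computes

In a synthetic STARR-seq screen a designed oligo pool is cloned downstream
of a minimal promoter so that each candidate enhancer transcribes itself;
sequencing the reporter transcripts simultaneously identifies each variant
and measures its activity through its read count. The designs handled here
carry a glucocorticoid receptor (GR) binding sequence (GBS) — two imperfect
6 bp palindromic half sites around a 3 bp spacer — with degenerate (N)
positions either flanking the GBS (two 1024-variant flank libraries, 5 Ns)
or inside it (a 65,536-variant half-site library, 8 Ns spanning two spacer
positions and the downstream half site). Comparing read counts between
hormone-treated (dexamethasone) and vehicle-treated (ethanol) samples gives
a per-variant activity: the log2 fold change upon hormone treatment.

The package implements the full chain: template parsing and variant
enumeration, exact-match read counting, negative-binomial differential
activity testing and classification, sequence analytics (consensus motifs,
weighted activity logos, PWM motif weights), pentamer-based DNA shape
prediction with clustering and classifiers, and expression mean/noise from
two-channel single-cell fluorescence. A synthetic-data module generates
screens, reads and cell populations with the statistical structure the
analysis assumes, so every stage is testable end to end without downloads.

# Coordinates and position labels

All internal coordinates are 1-based closed indices, the R convention used
by every string and ranges dependency here. Published figure labels for
these designs (flank positions 6–12; spacer positions −1/0 and half-site
positions 1–6) have no stated origin, so the mapping between biological
labels and insert offsets is shipped as data on each template
(`position_labels`), not hard-coded into any computation; users can relabel
without touching results. The variant key is the concatenated bases at the
degenerate positions only — full inserts are reconstructed on demand —
which keeps a 65,536-row count matrix compact.

# Counting model

Only reads whose insert region matches a library insert exactly in length
and composition are counted; a single substitution anywhere in the insert
(fixed or degenerate positions) discards the read, and no deduplication is
performed because duplicate reads carry the quantitative signal. Two mate
modes exist: `strict` (default) requires both mates to report the same
insert, which avoids double-counting ambiguous pairs at the cost of a
recovery factor of roughly $(1-e)^{2L}$ at per-base error rate $e$;
`read1` uses read 1 alone ($(1-e)^{L}$). The half-site screen additionally
drops variants whose mean count across all samples is not strictly above
100 — the strict boundary follows the screen's wording ("above 100"), and
the flank libraries are analysed unfiltered since every flank variant was
recovered at high coverage.

# The negative-binomial activity test

Counts are modelled as NB with variance $\mu + \alpha\mu^2$. The workflow
is a reconstruction of the standard RNA-seq differential machinery,
implemented in this package (an external tool release is used only as an
independent cross-check in the tests):

1. **Size factors** by median-of-ratios over variants covered in every
   sample, rescaled to geometric mean 1.
2. **Dispersions**: per-variant maximum likelihood under condition-wise
   fitted means, using the Cox–Reid adjusted likelihood
   $\ell(\alpha) - \tfrac12\log\det(X^\top W X)$ — without the adjustment,
   dispersions at 3 + 3 samples are biased low and the Wald tails become
   anti-conservative (we measured empirical FDR near 0.13 at a nominal
   0.01 cutoff). A robust loess of log dispersion on log base mean gives a
   local trend; final dispersions maximise the likelihood under a normal
   prior on $\log\alpha$ centred at the trend. The prior variance is the
   spread of the log residuals in excess of the sampling variance
   $\psi_1((m-p)/2)$ of a log-dispersion estimate, floored at 0.25;
   estimates more than two residual SDs above the trend are kept raw
   (shrinking a genuine outlier would understate its variance).
3. **Wald test** on the condition coefficient of a per-variant NB GLM
   (log link, log size factors as offset, vehicle as reference), reported
   in log2. No fold-change shrinkage is applied.
4. **BH step-up** adjustment across tested variants; classification at
   padj < 0.01: flank mode labels enhancing (positive log2FC), blunting
   (negative) or neutral; half-site mode bins significant variants at the
   log2FC cutoffs 2 and −2 into activated / weak / repressed.

Two caveats are surfaced as warnings rather than buried: in flank mode
every construct carries a functional GBS, so median-of-ratios centring
makes weak variants look repressed — "blunting" is relative to the pool,
not absolute repression; and "repressed" half-site calls are flagged
unreliable because apparent repression in such screens has not been
reproducible for individually assayed variants.

On data simulated under this model at the study design (1024 variants,
3 vs 3 replicates, 5×10⁶ reads/sample, $\alpha = 0.05$, planted effects
of ±1 log2 on 15%/10% of variants), the tests measure sensitivity ≈ 0.80
at empirical FDR ≈ 0.03, and log2 fold changes agree with the reference
implementation to ~10⁻⁵.

# Sequence analytics

The **activity logo** asks, for every (position, base) cell, whether
variants carrying that base are more or less active than the rest: two
one-sided Mann–Whitney tests on the activity weights, normal approximation
with tie and continuity correction, no multiple-testing correction across
cells, raw p < 0.001 highlighted. These conventions are fixed here because
the weighted-logo tools leave them implicit; the tests verify the p-values
against `stats::wilcox.test` and their calibration under weight–sequence
independence. Cells whose base partition is empty are undefined and
flagged. **Consensus motifs** are plain position frequency matrices with
per-position information content in bits (no small-sample correction).
**Motif weight** is the maximal log-odds PWM score over offsets and both
strands, $\sum_i \log(p_\mathrm{motif}(b_i\,|\,i) / p_\mathrm{bg}(b_i))$,
with Laplace pseudocount 1 on the count matrix and a uniform order-0
background unless a Markov background (transition TSV) is supplied;
training a background on open-chromatin sequence is a user input, not a
package responsibility.

# DNA shape

Shape features come from a pentamer lookup table: minor groove width (Å)
and propeller twist (degrees) describe the central base of each 5-mer
window; roll and helix twist (degrees) describe the two steps adjacent to
the centre and are averaged where two overlapping windows cover the same
step, leaving two undefined positions (one step) at each end. Profiles are
computed on the insert context, not the bare key, so windows at the
degenerate-region edges are defined. The published pentamer table is not
bundled: analyses accept any table in the documented TSV layout, and the
package ships synthetic tables (constant, and random under the physical
strand-symmetry constraint value(p) = value(revcomp(p)) with mirrored step
features) that exist purely to make the machinery testable. Profile
clustering is best-of-restarts Lloyd k-means (default k = 4) on raw values
— Euclidean distance is meaningful because profiles within a run share
units; the published description of this step gives two conflicting
restart counts (20 and 100), so a single `n_init` parameter (default 100)
is exposed instead. Group comparisons are per-position two-sided Wilcoxon
rank-sum tests, reported per position without adjustment by default (BH
across positions behind a flag).

# Activity classifiers

Four models discriminate activity classes, evaluated by 10-fold
cross-validation: per-class positional frequency models scored by summed
log-likelihood ratio over mononucleotides or adjacent dinucleotides
(pseudocount 1), and 100-tree random forests on either the two-bit-coded
sequence (A = 00, C = 01, G = 10, T = 11) or the MGW profile. The
likelihood-ratio scorers, the binary coding and the CV/ROC harness are
implemented here; the forest is the standard `randomForest`
implementation behind the scorer interface. Folds are stratified (the
original description does not say; unstratified folds risk empty classes
at these class sizes) and held-out scores are pooled into a single ROC
whose trapezoidal AUC equals the Mann–Whitney concordance of the pooled
scores — an identity the acceptance tests check exactly.

# Expression noise

Per cell, reporter GFP is normalised by co-transfected mCherry; the
population statistics are the mean ratio and CV² = unbiased variance over
squared mean, computed on the per-cell ratio (normalising by the
population-mean mCherry instead is available behind a flag, since the
written description admits both readings). No log transform and no outlier
trimming are applied by default. Gates are user inputs (as in practice);
a helper suggests thresholds from a no-reporter control. The simulator
draws GFP from the steady-state gamma approximation of a two-state
promoter — shape = burst frequency $a$, scale = burst size $b$, so
mean $= ab$ and CV² $= 1/a$ — with extrinsic per-cell factors scaling both
channels (removed by ratio normalisation, and shown to be in the tests)
and independent multiplicative measurement noise per channel. An explicit
chemical-master-equation simulation of the two-state promoter is out of
scope; the gamma limit reproduces the mean–noise behaviour the analysis
interrogates: sweeping burst frequency at fixed size gives a log–log
mean–CV² slope of −1, sweeping burst size at fixed frequency leaves CV²
flat.

# Synthetic screens: what they emulate and what they do not

`simulate_screen()` draws plasmid-pool proportions from a lognormal
(default sdlog 0.5 — the real libraries' abundance skew is not published,
and this gives the mild right skew typical of cloned oligo pools), applies
optional dropout, and generates NB counts per replicate with planted log2
effects. Defaults are the study design: 3 + 3 replicates, 5×10⁶
reads/sample, dispersion 0.05, 15% enhancing at +1 and 10% blunting at −1.
`simulate_reads()` emits the realised oligo as read 1 and its reverse
complement as read 2 with iid substitution errors. Not modelled: PCR
amplification bias, indels, UMI structure, synthesis bias across
degenerate positions, cell-cycle or transfection-dose effects beyond the
shared extrinsic factor. Passing tests on these simulations therefore
demonstrate that the statistical machinery is correct and calibrated under
its stated model — not that real screens are free of the artefacts listed
above.

# Numerical choices and degenerate inputs

Dispersions are floored at 10⁻⁸ and optimised on the log scale over
[10⁻⁸, 30]. Variants that are all-zero are skipped with NA results;
variants all-zero in one condition are tested with the raw GLM but their
displayed log2FC uses a 0.5 pseudo-count (flagged `zero_condition`), since
the raw estimate is effectively infinite. Ranking ties break
lexicographically by key so output order is deterministic. ROC ties get
half credit (trapezoid over tied-score steps). Every simulator takes a
mandatory seed and touches no hidden global RNG state; k-means and forests
take explicit seeds. The analysis drivers use a fixed problem size
(1024-variant screens, 400-profile shape sets, 10⁵-cell noise
populations), chosen so each stage illustrates its behaviour at the
study's own scale while remaining quick to re-run.

# Known limitations

The NB reconstruction is faithful but simplified — no Cook's-distance
outlier replacement, no independent filtering beyond the documented
mean-count rule — so significance-based variant counts on real data are
expected to match an external tool's output closely but not to the last
variant. The shape stage is only as good as the supplied pentamer table.
The activity logo reports raw per-cell p-values; with ~20–32 cells per
logo, a 0.001 highlight threshold implies a small family-wise error that
users should keep in mind when reading single highlighted cells.
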