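---
title: "Methods: compositional analysis of cervicovaginal microbiome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional analysis of cervicovaginal microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervicomp)
```

cervicomp analyses genus-level cervicovaginal microbiome tables across four
diagnostic groups — Normal epithelium, low-grade (LSIL) and high-grade
(HSIL) squamous intraepithelial lesions, and invasive cervical carcinoma
(CCU). This vignette documents the statistical model behind each stage, the
parameters that matter, and the design choices made where the methods
literature leaves genuine freedom.

## Compositional substrate

Sequencing counts carry only relative information, so every multivariate
stage operates in log-ratio coordinates. A sample's composition $x$ is
mapped by the centered log-ratio (CLR) transform

$$\mathrm{clr}(x)_k = \ln\frac{x_k}{g(x)}, \qquad
  g(x) = \Big(\prod_k x_k\Big)^{1/K},$$

and beta diversity is the Aitchison distance — the Euclidean distance
between CLR vectors. CLR rows sum to zero, distances are invariant to
closure (scaling a sample's counts leaves them unchanged), and Aitchison
distance matrices are always Euclidean-embeddable, which principal
coordinates analysis exploits.

Zeros must be handled first. `replace_zeros()` adds a pseudocount of 0.5 to
every count before closing to proportions; tables already expressed as
proportions instead get multiplicative replacement with $\delta = 10^{-6}$
(zeros set to $\delta$, the non-zero parts rescaled by $1 - z\delta$).
Both constants are configurable and recorded in output provenance. The
choice matters quantitatively — absolute values of CLR coordinates, and
hence mean Aitchison distances and log-ratio index values, shift with the
pseudocount — but the orderings and tests the pipeline reports are stable
across reasonable values. Natural logarithms are used throughout; Shannon
diversity is therefore reported in nats.

## Permutation machinery

PERMANOVA partitions the squared-distance sums
($SS_\text{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2$, within-group terms
computed per group) and tests the pseudo-F by random relabelling. The
p-value convention includes the observed labelling,
$p = (1 + \#\{F_\pi \ge F_\text{obs}\})/(1 + P)$, which guarantees
$p \ge 1/(P+1)$; the permutation stream is seeded and the seed is an
explicit argument everywhere. Pairwise comparisons run on the restricted
distance sub-matrix with Benjamini–Hochberg correction across the six group
pairs.

PERMDISP embeds the samples by PCoA, takes each sample's distance to its
group **centroid** in that embedding as its dispersion, and permutes group
labels, recomputing centroids and dispersions for every permutation.
Published PERMDISP variants differ here (spatial medians, residual
permutation); the centroid variant was chosen because it is the most common
default and reproduces the qualitative dispersion gradient of interest —
dispersion rising from Normal to carcinoma communities.

The single-factor host screen runs one independent PERMANOVA per metadata
factor on the samples with non-missing values, treating every factor as
categorical; factors left with fewer than two levels of at least two
samples are skipped with a warning.

## Bias-corrected differential abundance

`bias_corrected_da()` implements a simplified estimator in the ANCOM-BC
family. Observed log counts are modelled as

$$y_{jk} = \ln(c_{jk} + 1) = \beta_{g(j),k} + d_j + \varepsilon_{jk},$$

where $d_j$ is the sample's unobserved sampling fraction (library-size
bias) and $\beta_{g,k}$ the group-level log abundance. Alternating least
squares estimates $\beta$ and $d$ (convergence tolerance $10^{-6}$, at most
100 iterations; the iteration converges geometrically because both updates
are linear projections). Each contrast's raw log-fold changes are then
centred by their median across genera — the bias-correction step, valid
under the assumption that most genera are non-differential. Wald tests use
the two-group standard error from per-genus residual variances; q-values
are BH within each contrast family and genera with $q \le 0.10$ are
flagged. The global test per genus combines all non-reference contrasts as
an independent-coordinate chi-square.

This is deliberately **not** a verbatim ANCOM-BC2 reimplementation:
structural-zero detection, sensitivity scores and mixed models are out of
scope, so results are comparable at the method-family level, not
coefficient-identical. The pseudocount inside the log (default 1) breaks
exact sampling-fraction invariance for genera with small counts; with
pseudocount 0 on strictly positive tables the invariance is exact, and the
test suite checks both regimes.

## Log-ratio indices and ROC

The predefined *Lactobacillus*-to-anaerobe index is
$\mathrm{clr}(\text{Lactobacillus}) - \overline{\mathrm{clr}}(\text{panel})$,
algebraically the log of Lactobacillus over the geometric mean of the panel
proportions. The default panel (Gardnerella, Prevotella, Dialister,
Anaerococcus, Peptoniphilus, Finegoldia, Fannyhessea, Fusobacterium,
Peptostreptococcus, Sneathia, Megasphaera, Hoylesella) is a curated set of
obligate anaerobes implicated in cervicovaginal dysbiosis; it is
intersected with the table's columns and fully configurable, since no
canonical membership exists.

The data-driven composite index contrasts genera consistently increased
versus decreased in CCU relative to Normal. "Consistently" is
operationalised as a mean CLR difference beyond $\pm\tau$ (default
$\tau = 1.0$ natural-log units) with prevalence $\ge 20\%$ in the enriched
group. Under the default cohort conditions the carcinoma group is small and
highly dispersed, so membership of borderline genera (Prevotella among
them) fluctuates between seeds; the depletion of Lactobacillus is recovered
essentially always. Both thresholds are exposed as arguments.

ROC evaluation uses the rank (Mann–Whitney) AUC with half credit for ties;
by default the positive class is CCU and *lower* index values indicate the
positive class. The rank formula is checked against trapezoidal integration
of the empirical curve in the tests.

## Co-occurrence networks

Within each diagnostic group, genera are filtered to within-group
prevalence $\ge 30\%$ ($\ge 40\%$ for the smaller CCU group) and non-zero
variance, capped at the 20 highest-abundance genera. Spearman correlations
(average ranks, $t$ approximation for p, pairs with constant vectors
excluded) are computed on CLR values, BH-corrected within the group, and
thresholded at $|\rho| \ge 0.60$ ($\ge 0.70$ for CCU) with $q < 0.05$.
Nodes include edge-less retained genera — necessary for density
($E / \binom{N}{2}$) and component counts to match published conventions.

## The synthetic cohort generator

Because per-sample data for such cohorts are rarely public, the package
ships a seeded generator whose defaults emulate a published cohort's
group-level summaries: per-genus mean relative abundance and prevalence per
group (17 genera plus a filler genus `"Other"` absorbing the remainder so
means sum to exactly 1), group sizes 25/23/24/10, and a dispersion gradient
implemented as Dirichlet concentrations 50 (Normal), 20 (LSIL), 20 (HSIL)
and 5 (CCU). Sampling is zero-inflated Dirichlet-multinomial: Bernoulli
presence per genus from the prevalence, a Dirichlet composition over the
present set with parameters $c_g \cdot m_{gk}$ renormalised, a lognormal
library size (log-mean $\ln 50{,}000$, log-sd 0.4 — a typical full-length
16S depth; the source summaries are silent on depth) rounded to an integer
of at least 100, then multinomial counts.

Two practical details. A profile cell can have a printed mean of 0.00% with
positive prevalence (the mean was rounded away); present genera are
therefore floored at a mean of 0.05% — below print resolution — before
renormalisation, so presence can materialise as reads. And a sample whose
Bernoulli draws all come up absent is re-drawn with Lactobacillus forced
present, with a warning.

What the generator does **not** emulate: read-level error, taxonomic
misclassification, genus-genus correlation structure beyond what the
Dirichlet induces, and host-factor effects. Passing tests on synthetic
cohorts therefore demonstrate that the pipeline recovers the group-level
structure it was pointed at — orderings, directions, separations — not that
it reproduces any real cohort's per-sample values. Published tables from
real data are used where they are recomputable (network densities and
component counts from printed node counts and edge lists, contingency
percentages from printed counts); those are reproduced exactly.

## Problem sizes and numerical choices

The test suite calibrates the permutation tests with 500 null replicates of
a 40-sample two-group design at 199 permutations, and checks structure
recovery over 100 seeded cohorts of the default 25/23/24/10 design at 299
permutations per pairwise test — sizes chosen so the whole suite runs in
about a minute while leaving the binomial noise on the checked rates well
inside the asserted bands. Interactive analyses should use the
pipeline default of 9999 permutations, matching standard practice.

Other numerical conventions: PCoA eigenvalues below $10^{-8}$ of the
leading eigenvalue are truncated (Aitchison matrices have no meaningful
negative eigenvalues); PERMANOVA errors on groups of size one and flags
zero within-group sums of squares as degenerate; Mann–Whitney switches from
exact enumeration to the tie/continuity-corrected normal approximation when
the smaller group exceeds 8 or ties are present; Cliff's delta magnitude
labels use the conventional 0.147 / 0.33 / 0.474 cut points.

## Limitations

The carcinoma group's small size (10) limits power in every per-genus
analysis, mirroring the situation in real cohorts of this design. The
differential-abundance estimator shares the ANCOM-BC assumption that most
genera are non-differential; in communities where the majority of taxa
shift in one direction the median bias correction absorbs part of the
signal. Absolute values of CLR-based quantities depend on the
zero-replacement constants, so cross-study comparisons should fix those
constants first.
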