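---
title: "Methods: multivariate evaluation of upland cotton germplasm quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate evaluation of upland cotton germplasm quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cottoneval)
```

## The evaluation problem

Cottonseed is simultaneously a protein, oil and fiber crop: a germplasm
panel of upland cotton (*Gossypium hirsutum* L.) accessions is typically
phenotyped for protein and oil content (% of kernel dry weight), the 16
amino acids, the 8 fatty acids (% of total fatty acids) and 8 fiber traits
(boll weight, lint percentage, seed index, fiber length / uniformity /
strength / micronaire / elongation). Breeders then need a single defensible
ranking that integrates all 34 traits, because individual traits disagree:
most notably, protein and oil content trade off strongly (panel-level
correlations near -0.95), while protein moves with the amino acids and with
the main fiber yield and quality traits.

`cottoneval` implements the full analysis chain for such a panel:
descriptive variation profiling (coefficients of variation), group
comparisons across geographic origin and breeding period (one-way ANOVA,
Tukey HSD, compact letter displays), the full Pearson correlation matrix
with significance stars, Ward clustering of accessions, and - at its core -
a principal-component / fuzzy-membership-function (PCA-FMF) composite score.

## The PCA-FMF composite

Given the accession-by-trait matrix, `pcafmf()` performs, in order:

1. **Standardization.** Each trait is z-scored (sample SD, $n-1$). Traits
   carry incommensurable units (%, g, mm, cN/tex), so all further algebra
   runs on the correlation matrix.
2. **PCA.** Eigendecomposition of the $34 \times 34$ correlation matrix;
   eigenvalues $\lambda_i$ (which sum to 34), loadings, and accession
   scores $X_i = Z v_i$. The contribution rate of component $i$ is
   $CR_i = \lambda_i / p$.
3. **Retention.** Components with $\lambda_i > 1$ (Kaiser rule, strict
   inequality; the threshold is a visible argument).
4. **Weights.** $W_i = CR_i / \sum_{j \in \text{retained}} CR_j
   = \lambda_i / \sum_{j} \lambda_j$. Whether $CR$ is defined against total
   or retained variance is irrelevant: the normalization cancels it.
5. **Fuzzy membership.** Per retained component,
   $U(X_i) = (X_i - X_{\min}) / (X_{\max} - X_{\min})$, so every component
   contributes on a common $[0,1]$ scale with the observed extremes at 0
   and 1 exactly.
6. **Composite and selection.** $F = \sum_i U_i W_i \in [0,1]$; accessions
   are ranked by $F$ descending (ties broken by accession id) and the top
   fraction (default 5%) selected with a ceiling rule, so a 259-accession
   panel yields exactly $\lceil 0.05 \times 259 \rceil = 13$ elites.

### The sign convention

A principal axis is defined only up to sign, but $F$ is **not**
sign-invariant: flipping component $i$ replaces $U_i$ by $1-U_i$. Any
implementation therefore embeds an orientation choice, usually silently.
Ours is explicit and deterministic: the trait registry assigns each trait a
desirability (`higher_better` for protein, the amino acids, C18:2/C18:3 and
the fiber yield/quality traits; `lower_better` for oil and the saturated
fatty acids; `neutral` for C16:1, C18:1, SI and FM), and each loading
column is flipped, when needed, so its loading sum on desirable traits
minus undesirable ones is non-negative. Exact ties fall back to making the
largest-magnitude loading positive. On panels generated with the default
configuration this orients the first component positively toward protein
and the amino acids and negatively toward oil - the orientation under which
"high F" reads as "good comprehensive quality". Oil is oriented downward
purely because of its hard trade-off with protein inside this composite,
not because oil is undesirable as a trait. A regression test pins the
convention: any change to it is a visible, deliberate API change.

Because standardization removes location and scale, $F$ is invariant to
positive per-trait affine transformations of the input - a property the
test suite asserts to $10^{-10}$, alongside equivalence (to $10^{-8}$)
with an independently coded SVD-based oracle on random small panels.

## Group comparison machinery

Per-trait one-way ANOVA is computed from the between/within sum-of-squares
definition (and cross-checked against `stats::aov`), with the degenerate
all-means-equal case defined as $F = 0, p = 1$. Post hoc pairwise tests use
the studentized range with the Tukey-Kramer unequal-$n$ correction via
`stats::TukeyHSD`; at $k = 2$ this reduces to the pooled two-sample t-test,
which the suite checks numerically. Letters come from the insert-absorb
algorithm: two levels share a letter exactly when their difference is not
significant, and letter order follows descending group means. No
multiple-testing correction is applied across traits - significant-trait
counts are reported the way germplasm surveys conventionally report them,
as raw per-trait tests.

## The synthetic germplasm generator

Per-accession phenotype tables for published panels typically live in
appendices that are not machine-readable, so the package ships a generator
whose defaults encode the published statistical structure of a
259-accession panel:

* **Marginals.** Printed trait means (protein 44.00, oil 32.46, Glu 8.19,
  Arg 5.02, Asp 3.60, C18:2 55.92, ...) and printed CVs where available.
  For traits with a printed range but no CV, the SD is set to range/6
  (protein: (53.48-35.32)/6, CV 6.88%). The 13 unprinted amino-acid means
  and minor fatty-acid means are fixed at typical cottonseed kernel values
  constrained so the saturated and unsaturated family sums equal the
  printed 26.73 and 73.12.
* **Fatty-acid labeling.** The printed panel statistics attach 22.88% to
  palmitoleic acid (C16:1), which is inconsistent with the same source's
  family arithmetic: the three major fatty acids C16:0 + C18:1 + C18:2 sum
  to 95.21% and the unsaturated family to 73.12%, which forces
  C16:0 = 95.21 - 16.41 - 55.92 = 22.88 exactly. The default
  (`fatty_acid_labeling = "consistent"`) uses the arithmetic-consistent
  assignment; `"as_printed"` preserves the literal labeling for users who
  want the published table verbatim. We deliberately expose both rather
  than silently "fixing" one.
* **A printed CV we keep as printed.** C18:2 carries CV 26.37% although its
  printed range (49.20-69.10%) implies roughly 6%. We follow the printed
  CV; only means and correlations are used as calibration targets, so the
  choice affects dispersion realism, not calibration.
* **Correlation structure.** Pinned pairwise anchors: protein-oil -0.947,
  protein-amino acid coefficients spanning 0.57-0.85 (assigned
  deterministically, strongest for Glu/Asp/Arg, weakest for the
  sulfur-containing Met), protein-LP 0.47, oil-SI 0.44, protein-C18:2
  0.26, protein-C18:3 0.25. Unspecified cells are filled by a
  single-factor rule: a protein-oil axis with loadings chosen so the
  rank-one base reproduces every anchor exactly (and is positive
  semi-definite by construction), overlaid with family blocks - amino-acid
  pairs floored at 0.65, within-SFA and within-UFA pairs floored at +0.3,
  SFA x UFA capped at -0.3. A naive fill (anchors + blocks + zeros
  elsewhere) is jointly infeasible - e.g. protein-oil -0.947 with oil-SI
  0.44 forces protein-SI near -0.42 - and projecting it to PSD visibly
  displaces the anchors; the factor-based fill avoids that failure mode.
* **PSD repair.** `repair_correlation()` projects by eigenvalue clipping at
  a floor of $10^{-8}$ with diagonal rescaling, iterated until PSD (the
  rescaling can reintroduce marginally negative eigenvalues). The default
  configuration additionally re-imposes the pinned anchors between repair
  sweeps (an anchor-preserving alternating projection), so the matrix
  actually sampled from carries the published coefficients to within
  ~1e-3. The repaired matrix is stored in the ground truth of every
  generated panel.
* **Group effects.** Additive origin and breeding-period shifts, centred
  to the size-weighted mean so the marginal means are untouched. Printed
  group means (NIR protein 45.65 / oil 30.75, FOR oil 35.58, NIR C18:2
  56.34) are encoded as desired group means; amino acids track protein's
  standardized shift at half strength; SI tracks oil and LP tracks protein
  at quarter strength, which both matches the reported cluster profiles
  (older high-oil groups carry larger seed index, newer high-protein
  groups better lint percentage) and keeps the panel-level oil-SI and
  protein-LP correlations at their pinned values despite the added
  between-group variance. Traits reported non-significant across origins
  (C14:0, C18:0, C16:1) or periods (C14:0, C18:1, C18:3) get zero shifts
  on that axis. Breeding period is assigned independently of origin with
  uniform proportions (the origin-by-period cross-table is not published).
* **Sampling.** Gaussian, via the eigen factor of the repaired correlation,
  scaled by per-trait SD = mean x CV/100; percentage traits are clipped to
  [0, 100] with the clip count recorded (under defaults only a handful of
  cells per 5000 accessions, in the heavy C18:2 tail). One master seed
  drives everything through a counter-based sub-seed split; identical
  configuration gives byte-identical written tables.

### What the generator does and does not emulate

It reproduces marginal means and dispersions, the pinned correlation
skeleton with plausible block fill, qualitative group orderings, and
origin-group sizes (40/95/28/58/15/23, scaled proportionally for other
panel sizes). It does **not** simulate assay error structure, genetic
relatedness or pedigree, the compositional closure of fatty-acid profiles
(columns are not renormalized to sum to 100, preserving the printed
pairwise correlations instead), origin-period dependence, or any
non-Gaussian tail behaviour. Passing recovery tests on generated panels
therefore validates the *pipeline machinery* - not distributional claims
about real cottonseed data.

## Numerical and design choices

* SD uses $n-1$ throughout; CV = 100 x sd/mean, undefined (with a warning)
  at zero mean.
* Normality screening is Shapiro-Wilk at $\alpha = 0.05$, advisory only.
  Histogram binning uses Freedman-Diaconis. Neither gates any stage.
* Correlation p-values use the exact t transform
  $t = r\sqrt{(n-2)/(1-r^2)}$; stars are `**` for $p<0.01$, `*` for
  $0.01 \le p < 0.05$, uncorrected across the 561 pairs.
* Component retention uses strict $\lambda > 1$; a panel where nothing
  exceeds the threshold raises an error advising an override rather than
  silently retaining the first component.
* Degenerate membership (a retained component with zero score range) is an
  error by default, with an explicit `degenerate = "half"` escape mapping
  it to 0.5.
* Elite count uses the ceiling rule (floor would select 12 from 259 at 5%).
  Rank ties break by accession id ascending, making rankings reproducible.
* Clustering is Ward (D2) on Euclidean distance over standardized traits,
  $k = 4$ by default; labels are canonicalized by decreasing cluster size
  (ties by smallest member id) so row order cannot change cluster
  identities. Linkage and distance are package choices - the published
  analysis names neither.
* Amino acids are treated as % of kernel dry weight (the interpretation
  consistent with the published per-kernel percentages), not per unit
  protein.

## Problem sizes used by the test suite

The suite exercises generator calibration at $n = 5000$ (means,
family sums and pinned correlations) and verifies the all-pairs
correlation recovery band (+-0.03 against the repaired target) at
$n = 20000$ with group effects disabled - at $n = 5000$ the union bound
over 561 pairs leaves no headroom for a 0.03 band, so the larger panel is
the honest size for an every-pair assertion. Statistical calibration uses
200 null replicates for the ANOVA type-I check; oracle equivalence uses 50
random 30 x 8 panels; planted-structure recovery uses 259-accession panels
mirroring the published design.

## Known limitations

* The composite depends on the sign convention; panels where a component is
  genuinely quality-ambiguous (desirability votes cancelling) fall back to
  a loading-magnitude rule that is deterministic but scientifically
  arbitrary.
* Published per-accession F values cannot be reproduced without the
  original raw data and its (unstated) orientation handling; the package
  reproduces the *procedure* and its scale, not individual published
  scores.
* `predict()` on accessions outside the fitted panel's score range returns
  memberships (and possibly F) outside $[0,1]$ by design, flagging
  extrapolation instead of clamping it.
* The generator's unpinned correlation cells are a modelling choice; any
  analysis sensitive to, say, amino-acid-fatty-acid cross-correlations
  beyond the factor fill should not lean on the defaults.
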