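---
title: "Cross-ome fingerprinting: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-ome fingerprinting: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics it implements:
what each stage assumes, which parameters matter and why their defaults are
what they are, what the synthetic generator does and does not emulate, and
where the genuinely open design decisions were made.

```{r setup, message = FALSE}
library(crossome)
```

## The analysis model

The input is a pair of log2-intensity matrices — proteins × samples and
lipids × samples — measured on the same panel of samples (typically a set
of mutant cell lines, each in replicate, plus a control line). The analysis
asks which lipids and proteins co-vary across the panel, groups them, and
summarises each group per genotype.

### Kendall tau-b association

Every lipid–protein pair is scored with the tie-corrected Kendall rank
correlation across the shared samples:

$$\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}},$$

where $C$ and $D$ count concordant and discordant sample pairs,
$n_0 = n(n-1)/2$, and $n_1$, $n_2$ count tied pairs in each vector. Rank
correlation is the right default here: LC-MS intensities are heavy-tailed
and occasionally contaminated, label-free ratios are only monotonically
related to true abundance, and tau responds to *any* monotone coupling.
The tie correction matters because quantified omics tables routinely
contain repeated values (imputation floors, quantised low-intensity
signals).

Missing values are dropped pairwise per feature pair, never imputed.
A tau value is reported missing when fewer than `min_overlap` complete
pairs remain (default **8**; rank correlations on fewer points are
dominated by noise) or when either vector is constant on the complete
positions (the statistic is undefined). The `n_pairs` matrix always
records the complete-pair count so downstream code can reason about
support.

Two correlation axes are supported. The default correlates replicate-level
columns, which retains within-genotype variation as signal-bearing
resolution; `aggregate = "genotype_mean"` first averages replicates within
genotype. Both are exposed because either convention is defensible for a
panel design and they can disagree at the margin.

### Degree filter

A feature survives only if at least `min_partners = 2` features on the
*other* ome correlate with it at `|tau| > 0.4` (strict inequality, absolute
value — a strong negative association is as informative as a positive one).
Both omes are evaluated against the **full** matrix and the two filters are
applied simultaneously in one pass. Iterative re-filtering (dropping a
feature, then re-evaluating its former partners) was deliberately rejected:
it makes retention order-dependent and can cascade into near-empty
matrices.

### Dual clustering

The filtered tau matrix is clustered on both axes. Each protein's profile
is its tau vector over the retained lipids, and vice versa; missing tau is
treated as 0 *for distances only* (absence of evidence of association),
never for the filter. Average-linkage hierarchical clustering on Euclidean
distances provides the heatmap leaf order; k-means with 25 restarts and a
fixed seed provides the labels (defaults `k_protein = 18`, `k_lipid = 13`).
Because k-means labels are arbitrary, clusters are renumbered by the
leaf-order position of each cluster's medoid, making the output a pure
function of the inputs and the seed.

The lipid default of 13 rather than 14 reflects a genuinely unresolved
choice between two internally reported values in the motivating analysis
style; both are a single argument away, and no claim is made that either
reproduces any particular published clustering.

### Enrichment

Protein clusters are tested against annotation terms (GMT input) and lipid
clusters against lipid classes parsed from shorthand names, with the same
machinery: a 2×2 Fisher's exact test per (cluster, term) pair over a
declared universe, two-sided by the probability-mass rule, with
Benjamini–Hochberg q-values across all tested pairs at once. The reported
odds ratio is the sample odds ratio $ad/bc$ (infinite when $bc = 0$ and
$ad > 0$), not the conditional MLE, because the counts themselves are part
of the output and the sample OR is what they imply.

Two knobs matter. The **universe** defaults to the degree-filtered features
— the population the clustering actually partitioned — and can be widened
to all quantified features; enrichment against the wider universe answers
a different question ("is this cluster unusual among everything we
measured?") and tends to inflate significance for any retained set.
`min_overlap_count` (default 2) excludes pairs whose in-cluster overlap is
below the floor *before* testing, keeping the BH family free of tests that
could never be informative.

### Genotype signatures

For each cluster and genotype, the package de-logs each feature's
within-genotype replicate mean (a geometric mean on the intensity scale),
sums over the cluster's features, and reports the log2 ratio to the same
sum in the control. Summing on the linear scale is deliberate: the target
quantity is the summed abundance of a functional group of molecules, and a
sum of log values would instead be a product of abundances. Features whose
mean is missing in either the genotype or the control are dropped pairwise,
and `n_features` records the count actually used, so a signature is always
a like-for-like ratio. Consequences worth knowing: the control against
itself is exactly 0, a uniform doubling of every cluster feature is exactly
+1, and a global rescaling of all intensities cancels.

### Outliers, networks, chain-length summaries

Per-feature genotype summaries are screened with a robust z-score,
$(x - \mathrm{median})/(1.4826\,\mathrm{MAD})$, flagged at
`z_threshold = 2.5`. The MAD is floored at `1e-9` so constant vectors give
z = 0 everywhere rather than 0/0; the floor triggers a warning because a
zero MAD usually means the summary was degenerate. At least 5 genotypes
are required — below that a median/MAD scale is meaningless.

Bipartite networks are extracted by scanning the tau submatrix between a
marker protein set and the lipids of named clusters, keeping edges with
`|tau|` above a threshold (default 0.4, matching the filter so extracted
edges are always inside the filtered support when thresholds agree).

Chain-length summaries rank lipids by log2 fold change (mid-rank ties, so
an all-zero vector puts every class at percentile ≈ 0.5) and split each
class at `carbon_cutoff = 20` total carbons; species whose carbon total
could not be parsed are excluded from the split and counted.

## Lipid name parsing

The parser accepts the common shorthand grammar
`CLASS [O-|P-] C:D [ _C:D | /C:D ]*` with bracket decorations
(`"Cer[NS] 18:1_24:0"`) and prose prefixes (`"Lyso-PC 18:1"`,
`"plasmanyl-PC 34:1"`, `"alkenyl-DG 36:2"`). `_` and `/` chain separators
are treated identically because only carbon/double-bond totals feed the
downstream summaries. Names outside the grammar are *kept* — class set to
the raw token, totals unknown — with a warning rather than an error,
because a real lipidomics export always contains a tail of odd identifiers
and dropping them silently would corrupt universe sizes. Class tokens are
case-preserved and may contain digits (GM3).

## The synthetic generator

`simulate_crossome()` emulates the study design the package targets:
33 genotypes × 4 replicate cultures, 2000 proteins, 600 lipids, and 5
planted cross-ome modules of 40 proteins + 15 lipids each. Each module has
one latent activity per sample,

$$z_{m,s} = \delta\,\mathbf{1}[\text{genotype}(s) \in A_m] + N(0, \sigma_z),$$

and each module feature reads
$\text{base}_f + \lambda_f z_{m,s} + N(0, \sigma_\epsilon)$ with positive
loadings $\lambda_f \sim U(0.5, 1.5)$, so within-module features co-vary
monotonically — exactly the structure Kendall correlation is designed to
see. Background features are independent noise. Entries are masked
completely at random at 5%.

Default magnitudes, chosen once as plausible for replicate-level label-free
data and then left alone:

| parameter | default | meaning |
|---|---|---|
| `noise_sd` | 0.3 | log2 measurement noise per entry |
| `genotype_effect` | 1.0 | log2 shift of an affected genotype's module activity |
| `latent_sd` | 0.5 | spread of the module driver across samples |
| `missing_rate` | 0.05 | missing-at-random fraction |
| module sizes | 40 / 15 | proteins / lipids per module |

`latent_sd` deserves its justification: the driver spread has to be large
enough that within-module pairs stay strongly rank-correlated (with these
defaults, pairwise correlations are ≈ 0.65–0.85, comfortably above the 0.4
retention threshold), yet small enough that a 1.0 log2 genotype effect
remains identifiable from quadruplicate replicate means — the per-genotype
mean of the driver fluctuates with sd $\sigma_z/2$, which at 0.5 leaves
summed-cluster signatures recoverable to within ±0.1 on average. A driver
spread of 1.0 would bury a 1-log2 effect in its own sampling noise at n=4,
making that recovery property unattainable for any estimator.

Each module is "affected" in 3 disjoint non-control genotypes (round-robin
assignment), the control is never affected, lipid identities carry a 70%
per-module class bias so class enrichment is recoverable, and protein
annotation terms mirror the modules alongside 10 random decoy terms.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: intensity-dependent missingness
(real MS missingness is left-censored, not MCAR), batch/run-order effects,
correlated background (housekeeping co-regulation), multi-module feature
membership, sign-mixed loadings, and any form of instrument drift. Recovery
results on this generator are a correctness check of the machinery, not a
sensitivity claim for any instrument.

## Numerical choices

- The tau kernel is compiled (Rcpp), enumerates all $O(n^2)$ sample pairs
  exactly, and accumulates counts in 64-bit integers; no large-sample
  approximation is used anywhere.
- Fisher p-values come from the exact hypergeometric distribution
  (`stats::fisher.test`), with equality of table probabilities judged at
  relative tolerance 1e-7, the standard convention.
- k-means ties are resolved by 25 restarts/best inertia under a fixed seed;
  hierarchical clustering inherits `stats::hclust` tie behaviour, which is
  deterministic for fixed input order.
- Top-partner ties at equal `|tau|` break lexicographically by protein id,
  so rankings are reproducible across platforms.
- Degenerate inputs are contracts, not accidents: constant vectors give
  missing tau; an empty retained set is a structured empty result with a
  warning; a cluster with no usable features yields a missing signature; a
  zero MAD floors to `1e-9`.

## Problem sizes used in the shipped checks

The test suite exercises most operations on a scaled-down preset
(8 genotypes × 3 replicates, 120 proteins, 60 lipids, 3 modules) where a
full run takes seconds, and validates the end-to-end recovery properties —
filter retention, clustering ARI, signature recovery over 20 seeds,
outlier calibration over 100 features, and the enrichment permutation null
over 200 permutations — at the full 33 × 4 design. These sizes are the
package's own verification design: small enough to run routinely,
large enough that the full-design properties are measured where they are
claimed.

## Known limitations

- Tau p-values are deliberately absent: the degree filter is a magnitude
  rule, and pretending per-pair significance across ~10^6 dependent tests
  would be worse than none. Partial correlations and within-ome networks
  are likewise out of scope.
- Enrichment treats terms as flat sets; no ontology-graph propagation.
- The robust-z outlier screen is a univariate rule per feature; it will
  not find genotypes that are only jointly unusual across features.
- `organelle_panel_kmeans` clusters a user-supplied curated panel; the
  package ships no curated organelle list of its own.
- With fewer than ~30 shared samples, the |tau| > 0.4 / ≥2-partner filter
  admits a visible tail of background features (the null sd of tau at
  n = 24 is ≈ 0.14); the defaults are tuned for panel-scale designs, and
  smaller studies should raise `tau_min` or `min_partners`.
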