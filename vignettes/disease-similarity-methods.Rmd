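---
title: "Quantifying similarity among muscle diseases from differential gene activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying similarity among muscle diseases from differential gene activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dganet)
```

## The problem

Diseases affecting human skeletal muscle — dystrophies, inflammatory
myopathies, metabolic and neuromuscular disorders — are heterogeneous in
etiology but often share downstream pathology. Given one case/control
transcriptome study per disease, `dganet` asks three questions:

1. Which diseases resemble each other in their *expression response*,
   and is that resemblance stronger than chance?
2. Is there a *common program of regulation* — sets of interacting
   proteins dysregulated across a majority of the diseases?
3. Do the answers point at *drug repurposing* opportunities?

Everything in the package operates on tabular objects (tibbles in and
out wherever the data is naturally long-form) and is driven either by
user files (expression TSVs, a STRING-style edge list, GMT gene sets,
drug-gene tables) or by a synthetic-data generator with planted ground
truth.

## Differential gene activity (DGA)

The unit of expression change is a variance-regularized two-sample
t-statistic per gene and disease. For each arm (disease, control) with
$n$ samples, sample mean $m$ and sample sd $s$, the arm variance is
shrunk toward a *background* variance $\sigma_{bg}^2$ estimated from
genes of similar expression level:

$$\tilde\sigma^2 = \frac{v_0\,\sigma_{bg}^2 + (n-1)\,s^2}{v_0 + n - 1},
\qquad
t = \frac{m_1 - m_2}{\sqrt{\tilde\sigma_1^2/n_1 + \tilde\sigma_2^2/n_2}}.$$

$\sigma_{bg}$ is the mean of per-gene sds over a window of `window`
genes (default 101, clamped at the extremes of the ranking so the
window always covers exactly `window` genes) centred on the gene's rank
by arm mean; ranking ties break deterministically by gene id. The prior
weight is $v_0 = \max(c - n, 0)$ with confidence $c = 10$
pseudo-observations per arm, so arms with ten or more replicates
receive no shrinkage and the score is exactly Welch's t — a property
the test suite checks against a textbook Welch implementation at
`1e-12`. The denominator $v_0 + n - 1$ is a deliberate, documented
variant of the classical regularized-t tool (whose published weighting
differs by one); it was chosen precisely so that the $v_0 = 0$ limit is
exact. Variances are regularized per arm, not pooled, because arm sizes
are routinely unbalanced in public case/control series.

DGA scores are computed on z-transformed expression (each gene row
standardized to mean 0, sd 1 across all samples of a study, `n-1`
denominator; constant rows become zeros and are flagged). The
t-statistic is invariant to per-gene affine rescaling, so the
z-transform does not distort it — it only makes matrices comparable
across studies. Batch structure is handled by a stand-in for empirical-
Bayes correction: per-batch gene-wise standardization, which removes
additive batch offsets exactly and is clearly labeled a stand-in (true
ComBat-style correction is out of scope). Probe-level inputs are
collapsed one-row-per-gene by the MaxMean rule (keep the probe with the
highest mean; ties to the lexicographically smallest probe id).

## Disease similarity and its null

Similarity between diseases $i$ and $j$ is the *partial* Pearson
correlation of their DGA columns, controlling for all other diseases:
with $\Omega$ the inverse of the disease-by-disease correlation matrix,

$$\rho_{ij\cdot rest} = -\frac{\Omega_{ij}}{\sqrt{\Omega_{ii}\Omega_{jj}}}.$$

Partialling factors out components common to every study (tissue,
platform, the shared dysregulation program), which plain correlation
would count as similarity. The implementation is checked against two
independent oracles: the first-order recursion formula at three
variables and correlations of least-squares residuals up to six.

Significance is purely permutation-based. Disease/control labels are
reshuffled independently within each study (arm sizes preserved — the
paper leaves the shuffling unit unstated; within-study was chosen
because labels are only exchangeable within a study), the whole DGA and
partial-correlation computation is repeated (default 100 times), and
all permuted pairwise correlations are pooled into one background
distribution — the pooled null, rather than per-pair nulls, because a
single background of disease correlations is being modeled and 100
permutations per pair would give a very coarse per-pair tail. The
p-value of an observed correlation is the one-sided upper-tail
exceedance with add-one smoothing,
$p = (1 + \#\{r^{null} \ge r^{obs}\})/(N+1)$: "similar" means
*high positive* partial correlation, and the smoothing keeps $p > 0$
with finite permutations (the raw-count variant is available via
`smooth = FALSE`).

Diseases are clustered by complete-linkage agglomeration on the
distance $1 - \rho$, with a deterministic lexicographic tie-break
(verified against `hclust` on tie-free instances). The dendrogram is
cut at $h^\ast = 1 - q_{1-\alpha}$ where $q_{1-\alpha}$ is the
$(1-\alpha)$ quantile of the pooled null correlations: a subtree sits
entirely below the cut exactly when its members' mutual similarities
are beyond the null at level $\alpha$, which is how "the cut
corresponds to p = 0.05" is made operational. Diseases left as
singletons are reported unclustered.

## Protein and functional module activity

A weighted protein-interaction network (edge confidence scores in
(0, 1], strictly greater than 0.85 by default — the high-confidence
regime; 0–1000-scaled files are auto-detected) is decomposed with the
Markov Cluster algorithm: the column-stochastic transition matrix is
alternately *expanded* (matrix power, default 2) and *inflated*
(entrywise power, default 2.0, followed by column renormalization and
pruning of entries below `1e-5`) until convergence. Clusters are read
from attractor rows and resolved into a partition (a node claimed by
two attractor systems goes to the larger converged weight, ties to the
lowest module id). Inflation 2.0 and self-loop weight 1 are the
conventional defaults; the source publication gives no MCL parameters,
and these settings recover planted partition modules (ARI ≥ 0.9 at
`p_within/p_between` = 18) while producing a broad module-size range.

Module activity — PMA for protein modules, FMA for curated functional
modules — is the arithmetic mean of the module genes' DGA scores in one
disease. Negative activity means coherent downregulation. Modules are
first filtered to the measured universe with a minimum surviving size
of 3. Significance is two-sided on $|$activity$|$ against a *matched*
permutation null (same module, same disease), not a pooled one, because
module size strongly controls the spread of a mean of t-statistics;
pooling across sizes would mis-calibrate small and large modules in
opposite directions.

The cross-disease **signature** is extracted in two steps: (1) modules
significant in strictly more than half the diseases; (2) of those, the
modules whose mean $|$activity$|$ over *all* diseases is at or above the
median of that summary ("upper 50th percentile of module expression").
The phrase behind step 2 is ambiguous about whether the mean is taken
before or after significance masking; the unmasked mean was chosen as
the default (it is the stabler statistic and uses the full activity
profile), with `summary_over = "significant"` as the alternative.

The same activity/significance machinery scores the curated catalog of
23 muscle functional modules (neuromuscular junction, excitation-
contraction coupling, calcium homeostasis, sarcomeric, mitochondrial,
inflammatory units, ...). The catalog is data, not code: a GMT file
supplied by the user. The file bundled under `inst/extdata/` is a
synthetic, non-authoritative stand-in for tests and demos. Functional-
module significance is two-sided, matching the protein-module
convention (the source is silent on sidedness); shared-FM reports per
disease pair carry a sign-concordance flag so that concordant and
opposed dysregulation of the same machinery can be distinguished.

## Association statistics and drugs

Disease-gene list overlap per disease pair is upper-tail
hypergeometric, exact, with no multiple-testing correction (the
reference analysis reports raw p < 0.05 counts); the default universe
is the union of the lists, configurable, since no universe is ever
stated for such analyses. Agreement between the expression-based and
gene-based significant-pair sets is a one-sided (enrichment) Fisher
exact test on the 2×2 cross-classification of all pairs. Both are
verified against brute-force enumeration on small universes.

Drug integration maps a drug–target table onto modules: druggable-
target over-representation in signature-module genes (same exact
hypergeometric code path), per-cluster associated modules (the
signature two-step rule restricted to a cluster's diseases, requiring
significance in *every* member by default, `rule = "majority"` to
relax), cluster-unique module sets by set difference, and candidate
drugs as those with at least one target inside the chosen modules'
genes (all module genes, not only druggable-category genes — the less
restrictive reading of an unstated choice), filtered to approved drugs
by default.

## The synthetic world

The generator states one world and the tests measure it; its defaults
are not tuned to outcomes. Per disease it draws a genes × samples
matrix of unit-variance Gaussian noise (marginal scale is irrelevant
after z-transformation), adds per-batch additive offsets (sd 0.5) to
exercise the batch stand-in, and shifts the disease arm by
`effect_size` (default 2 z-units — a strong but realistic microarray
effect) on the planted effect genes. Effect-gene programs are disjoint
gene sets: one per planted disease cluster, one per unclustered disease
(providing true-negative pairs), each with one coherent random
direction (a whole program is up or down, so mean-based module activity
is a sensible statistic and two-sidedness is exercised across
programs), plus an optional program shared by *all* diseases (default
15 genes) that emulates a cross-disease common signature. The default
world has 20 diseases in seven planted clusters of sizes 4 and 2 with
four unclustered diseases, 500 genes, and 10 samples per arm — sample
sizes are a free parameter in the source material, and 10/arm is
typical of the public muscle series the framework targets.

The interaction network is a planted-partition graph whose modules are
drawn from the effect programs (so module activity has something to
find), with within/between edge probabilities 0.9/0.05 and edge scores
uniform on (0.86, 1). Disease-gene lists share a configurable core
fraction (default 0.8) within a cluster, drawn from the cluster's
effect genes, with all other list genes disease-private — so
intra-cluster overlap is exact and inter-cluster overlap is zero by
construction. The drug table draws targets from the universe or, on
request, from planted module genes.

What the generator does *not* emulate: probe-level chemistry,
non-additive batch effects, correlated noise between genes, platform
differences, and the long-tailed module-size distribution of a real
interactome. A green recovery test therefore establishes that the
pipeline's inferential chain is correct and calibrated under its own
assumptions — not that any particular biological conclusion from real
compendia is reproduced.

## Numerical and degenerate-input choices

- All generators and the permutation machinery are pure functions of
  (config, seed); the pipeline seed fans out to per-stage child seeds
  so stages can be reproduced in isolation.
- Constant gene rows z-transform to zeros (flagged); a regularized t
  with both arm variances and backgrounds zero returns 0 with a
  degeneracy flag.
- Singular disease correlation matrices (duplicated DGA columns) raise
  an error naming the collinear columns rather than returning
  pseudo-inverse artifacts.
- MCL prunes entries below `1e-5` and renormalizes, keeps columns
  stochastic, warns (and returns the last iterate) if the cap of 100
  iterations is hit.
- Linkage heights are non-decreasing (complete linkage is monotone);
  merge ties break lexicographically; the signature and cluster-
  association thresholds use `>=` so an all-equal stage-1 set passes in
  full.
- Hashes in the run manifest serialize floats at 12 significant digits,
  making manifests comparable across platforms at documented precision.

## Limitations

- The batch stand-in removes additive offsets only; location-scale or
  covariate-dependent batch effects need a real empirical-Bayes tool
  upstream.
- The pooled pair null assumes pairs are exchangeable under the null;
  strongly heteroscedastic studies could make some pairs' nulls wider
  than the pool.
- With 100 permutations the smallest achievable p-value for module
  activity is 1/101; genome-scale multiplicity control over modules is
  deliberately out of scope.
- Partial correlation requires more genes than diseases (always true
  here) and no exactly collinear disease profiles.
- The interface consumes gene symbols as given; identifier mapping
  (e.g. ENSP to symbol) beyond a user-supplied table is out of scope.
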