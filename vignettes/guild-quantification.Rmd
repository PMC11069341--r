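---
title: "Quantifying microbial guilds: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microbial guilds: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`guildquant` scores the contribution of a group *s* of equivalent
metagenomic sequences — one taxon, one implementation (functional
sequence space of the reference tree), one environmental context — as

$$k_s = A_s \frac{d_{\mathrm{obs},s}}{d_{\mathrm{exp},s}} u_s,$$

with $A_s$ the summed TPM abundance, $d_{\mathrm{obs},s}$ the number of
unique member sequences, $u_s \in [0,1]$ the univocity of the group's
implementation (binary in this package: functional or not), and

$$d_{\mathrm{exp},s} = c\,A_s^{\gamma}$$

the richness expected from abundance alone. In metagenomic data richness
and abundance rise together — sampling a large, unsaturated pool of
distinct sequences yields a log–log-linear relationship — so the ratio
$d_{\mathrm{obs}}/d_{\mathrm{exp}}$ isolates *richness surprise*: groups
holding more distinct sequences than their abundance predicts are
rewarded, which matters because effector richness buffers a function
against environmental fluctuation.

Assumptions worth keeping in mind:

* One $(c, \gamma)$ pair is fitted **per gene**, pooled over all groups
  and contexts. Per-group constants would force
  $d_{\mathrm{obs}}/d_{\mathrm{exp}} \equiv 1$ and empty the model of
  content; per-context fits are possible by subsetting the group table
  but are not the default.
* The fit is ordinary least squares of $\log d$ on $\log A$. The internal
  log base is immaterial for the linear-scale constants and is recorded
  in the model object. Groups with $A = 0$ carry no information about the
  law; they are excluded and counted.
* Univocity is binary. Nothing in the interface forbids intermediate
  values (an efficiency-weighted $u$), but no such estimation is
  provided.
* Groups in undefined regions of the tree (`incertae`) get **no** $k$
  value (`NA`), deliberately distinct from $k = 0$ of a non-functional
  group: absence of evidence is not evidence of absence.

Fold changes between environments or implementations divide **summed**
$k$ values of two selections. An alternative mode (`mode = "pooled"`)
first merges each selection into a single sequence set (abundances and
richness summed) and re-evaluates the impact formula on the pooled set;
the two modes agree when groups sit exactly on the richness law and
differ slightly otherwise. Summing is the default because it is the
natural reading of "adding the $k$ of each implementation per layer";
pooling is exposed for sensitivity analysis.

# Discovering implementations on the reference tree

Where direct biochemical evidence exists, `assign_univocity()` propagates
sequence-level labels conservatively: each maximal monophyletic clade
whose evidenced leaves agree unanimously becomes a cluster ($u = 1$ or
$u = 0$); any clade containing contradictory evidence is never labeled,
and unevidenced regions stay `incertae`.

Where evidence is environmental (cultured species with known temperature,
salinity, pH preferences, motility, ...), `node_trait_enrichment()` tests
every internal node: the observed mean trait value of the node's
data-bearing leaves is compared to the null distribution obtained by
shuffling the trait values among **all** data-bearing leaves of the tree
(missing values are never permuted into existence). Parameters:

* `n_rand = 20000` randomizations by default (at least 1000 enforced).
  The null mean and SD converge quickly; 20 000 keeps the Monte-Carlo
  error of a 0.003-tail p-value near 10% relative.
* significance at $|z| \ge 3$ (`z_threshold = 3`), the operating point
  equivalent to a one-tailed permutation $P < 0.003$ under a normal
  null. Both tails are tested: a clade can be significantly *low*
  salinity as well as high.
* `min_leaves = 4`: a mean over fewer than four leaves is too unstable to
  interpret a 3-sigma call.
* p-values use the $(b+1)/(B+1)$ estimator, so a finite number of
  shuffles never reports $p = 0$; tie counting uses a relative tolerance
  of $10^{-9}$ so that permutations reproducing the observed subset are
  counted as ties rather than falling on either side by round-off.
* A constant trait, or a node subtending every data-bearing leaf, has a
  degenerate null (SD 0); such nodes report $z = 0$ and are never
  significant.

`select_general_nodes()` then keeps, per trait, the significant nodes
whose parent is not significant (the root qualifies if significant), and
`define_implementations()` converts the selection into the cluster map.
When different traits select overlapping but non-identical nodes, the
node covering more leaves wins; identical selections merge. Binary traits
are treated as 0/1 numerics under the same test.

**Localization caveat.** With the tree-wide shuffle null, an ancestor
that contains a strongly shifted clade plus a comparable number of
background leaves is itself significant — its observed mean is still far
above the permutation null. Localization to exactly the planted clade is
therefore only guaranteed when the clade is *maximal*, i.e. its parent
dilutes the signal across most of the tree (in the limit, the parent
subtends all data-bearing leaves and its mean is permutation-invariant).
The package's planted-clade power scenario is built that way: a 16-leaf
shifted clade against 48 background leaves, hanging directly off the
root. On a perfectly balanced tree the 2x-sized parent of a shifted clade
is expected to reach $|z| \ge 3$ too, and the most-general rule will
select the parent; this is a property of the method, not a bug of the
implementation.

# The divergence null model

To ask whether gene-tree divergence is just taxonomy, the package
compares node-wise mean *normalized patristic distances*. Distances are
normalized by each tree's diameter (maximum pairwise distance), bounding
them to $[0, 1]$ and making every statistic invariant to a global rescale
of branch lengths. For every internal node of the target gene tree with
at least two organisms present in both phylomarker trees, the mean over
organism pairs of the normalized distance is computed in marker 1,
marker 2, and the target. The marker-2-on-marker-1 regression (OLS, with
residual SD using $n - 2$ degrees of freedom) defines the expectation;
target nodes whose residual exceeds $3\sigma$ in either direction are
flagged — convergence below the line, excess divergence above it.

Choices made where the design was open:

* Organisms with several target-tree leaves (a gene can occur in multiple
  distant copies) contribute the **minimum** leaf-pair distance — the
  most convergent copy — configurable to the mean
  (`target_combine = "mean"`). Phylomarker trees combine multiple leaves
  by the mean.
* OLS of marker 2 on marker 1 rather than total least squares, matching
  the convention of plotting everything against the 16S axis.
* The band is the residual SD, not a prediction interval; at the
  $n \approx 60{-}100$ node counts typical here the difference is a few
  percent of $\sigma$.
* An absolute floor of $10^{-10}$ on the flagging threshold absorbs
  floating-point residuals when $\sigma = 0$ (identical trees), while any
  real departure still triggers at $\sigma = 0$.

A calibration caveat mirrors textbook expectations: the $0.3\%$
false-flag rate of a $3\sigma$ band assumes independent Gaussian
residuals. Node-wise distances on one tree are *not* independent —
nested nodes share organism pairs — so when entire trees are perturbed
by branch-rate noise the realized flag rate on an unrelated target
exceeds the nominal rate even without any convergence signal. The
package's calibration check is therefore performed at the point level
(independent residuals around the fitted line), while tree-level checks
use planted convergence events and exact agreement in the noise-free
limit.

# Placement ingestion and grouping

`read_jplace()` parses jplace v3 (the EPA-ng output format): edge numbers
are taken from the `{N}` tokens of the tree string and attached to the
node below each edge. Invariants enforced: all referenced edges exist,
and each query's like_weight_ratio (LWR) sums to at most $1 + 10^{-6}$.
Unknown field names produce a warning and are ignored; missing `tree`,
`fields` or `placements` keys are errors naming the key.

`assign_queries()` implements the best-hit rule: a query's LWR mass is
summed per cluster (an edge belongs to the cluster of the node below it;
edges above every cluster root are `incertae`) and the argmax cluster
wins. Ties are broken toward the cluster holding the single
best-supported edge, then lexicographically, and are logged. The
assignment confidence is the winning mass; taxonomy is the longest common
prefix of leaf taxonomies at the best edge (the consensus is computed
once per tree). Queries winning a $u = 0$ cluster are kept and flagged —
their impact will be zero — while `incertae` winners keep that label and
get no $k$ later.

`filter_low_quality()` discards assignments below a confidence threshold
(`min_confidence = 0.5` by default) and reports the discard count, the
discard percentage, and the mean confidence of the kept set — the
"weighted likelihood robustness" of what survives. Placement pipelines do
not standardize a single numeric quality criterion; the summed-LWR
best-cluster confidence is this package's definition, and the threshold
is fully configurable.

`build_groups()` joins kept queries with the abundance table
(`query_id`, `context`, `tpm`) and aggregates per (taxon at the
configured rank, implementation, context): `abundance_tpm` is the TPM
sum, `d_obs` the number of distinct queries. Duplicated
(query, context) rows are an error; abundance rows for never-placed
queries warn and drop; placed queries without abundance error by default
(`missing_abundance = "zero"` keeps them at zero TPM).

# The synthetic-data generator

The generator produces every input with planted truth, at the
placement/abundance level (no sequence simulation):

* **Trees** are pure-birth (Yule) topologies with i.i.d. exponential
  branch lengths (mean 0.1) and stable labels — a neutral default for
  method testing, not a model of any particular gene family.
* **Traits** are Gaussian (`noise_sd = 1`) around a baseline, with
  planted clades shifted by a chosen multiple of the noise SD and an
  optional missing-at-random fraction.
* **Placements/abundances**: per (cluster, context), a group abundance is
  drawn from a lognormal law (`tpm_sdlog = 0.5`, heavy-tailed like real
  TPM spreads spanning orders of magnitude) and its richness set to
  $d = \max(1, \mathrm{round}(c A^\gamma))$ — the same power law the
  model fits, so planted impact tables are self-consistent with the
  model's own assumption. Each of the $d$ unique queries carries $A/d$
  TPM and places its LWR mass inside the home cluster (Dirichlet
  concentration around a focal edge; infinite concentration gives
  single-edge placements). With `exact_richness = TRUE` abundances are
  snapped onto the law exactly, making the full pipeline recover planted
  $k$ to round-off — the end-to-end correctness scenario.
* **Marker triples**: two phylomarker trees and a target are independent
  branch-rate-jittered copies of one base tree
  (lognormal, `rate_jitter_sd`); convergence events prune a leaf and
  regraft it as the sister of a distant leaf, and the pair's MRCA in the
  final target is recorded as ground truth.

What the generator does **not** emulate: placement uncertainty spilling
across cluster boundaries (LWR mass stays inside the home cluster, so
classification accuracy is 1 by construction unless the user adds
noise); phylogenetic autocorrelation of traits (background leaves are
i.i.d., which makes the type-I check a clean null but is optimistic
relative to real trait evolution); compositionality and sequencing noise
of real TPM tables; and reference-tree errors. Passing tests on
synthetic data therefore demonstrate correctness of the computations and
calibration under the stated nulls, not robustness to every failure mode
of real data.

# Problem sizes used in the checks

The package's property checks run at deliberately desk-sized conditions:
richness-law recovery on 100 noisy groups; enrichment calibration on a
128-leaf tree with 24 i.i.d. traits at 20 000 randomizations; power on
16-of-64-leaf planted clades; exact permutation enumeration on 8 leaves;
divergence calibration on 20 000 simulated node points and 20 seeds of a
100-leaf tree with three planted events; end-to-end quantification on
48–64-leaf scenarios with 4–8 clusters in two contexts. These sizes make
the whole suite run in well under a minute per module on one CPU while
keeping Monte-Carlo errors small relative to the tested tolerances.

# Known limitations

* Implementations are flat, disjoint clades; overlapping or nested
  functional spaces (e.g. a promiscuous subfamily inside a specific one)
  cannot be represented.
* The enrichment null ignores phylogenetic autocorrelation; traits that
  evolve smoothly along the tree will produce more significant nodes than
  the i.i.d. calibration suggests. Interpreting those nodes as
  *environmental* clusters still requires the divergence null model or
  external evidence.
* The most-general rule localizes signal only up to the resolution
  argument above.
* Binary univocity discards kinetic information; two functional
  implementations with very different efficiencies weigh equally per
  TPM.
* Fold changes are ratios of sums; no uncertainty is attached to them.
  Resampling queries (the group table is cheap to rebuild) is the
  recommended route when error bars are needed.
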