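---
title: "Methods: a multi-phase in-silico screen for multi-effect medicinal plants"
author: "phytoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-phase in-silico screen for multi-effect medicinal plants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoscreen)
```

## The problem

Inflammation, oxidative stress and cellular senescence are intertwined axes
of many chronic pathologies, and ethnobotanical collections are a rich but
noisy source of candidate therapeutics against them. `phytoscreen`
implements a cascade of computational filters that starts from a curated
table of medicinal plants — taxonomy, activity evidence in four classes
(anti-oxidant `AOX`, anti-inflammatory `AINF`, anti-aging `AAG`,
anti-senescence `ASEN`), and phytochemical membership — and ends with a
short list of *evidence-free* plants whose compounds are drug-like,
non-toxic, structurally similar to reference drugs with known
activity, and connected to relevant signalling pathways through reported
targets. An in-vivo paw-edema module covers the downstream validation
statistics.

The screen runs in seven phases:

1. **Taxonomy–activity networks.** Plants are arranged in a heterogeneous
   network (family–genus–species plus shared activity nodes, optionally
   compound nodes) and hub nodes are ranked.
2. **Evidence-gap ranking.** Plants *without* any evidenced class are scored
   by the connectivity of their species node in the subnetwork restricted to
   compounds that do carry reported activities.
3. **Drug-likeness.** Every phytochemical is scored with the quantitative
   estimate of drug-likeness (QED) and gated strictly at `> 0.5`.
4. **Toxicity and targets.** Compounds flagged mutagenic, tumorigenic,
   irritant or reproductive are removed; only compounds with at least one
   bioassay-reported target gene proceed.
5. **Fingerprint clustering.** Survivors are pooled with a reference-drug
   panel, compared by Tanimoto similarity of 1024-bit fingerprints, and
   clustered (Ward tree, elbow-selected K, k-means corroboration,
   silhouette/Dunn validation). Phytochemicals co-clustered with a
   reference are retained.
6. **Structural network and enrichment.** A four-criterion cascade
   (drug-like, reference-similar, has targets, lacks known activity) feeds a
   compound–target–pathway network; evidence-free plants containing
   survivors whose targets reach the pathway layer are hub-ranked, and the
   survivors' targets are tested for pathway enrichment.
7. **In-vivo statistics.** Carrageenan paw-edema measurements are expressed
   as percent change over baseline and compared against the control with
   one-way ANOVA plus Dunnett contrasts.

## Models and statistics

### QED

Each of eight descriptors (MW, ALOGP, HBA, HBD, PSA, ROTB, AROM, ALERTS) is
mapped to a desirability in \((0, 1]\) by an asymmetric double sigmoid

\[
d(x) = \frac{1}{d_{\max}}\left[a +
\frac{b}{1 + e^{-(x - c + d/2)/e}}
\left(1 - \frac{1}{1 + e^{-(x - c - d/2)/f}}\right)\right],
\]

using the published per-descriptor constants shipped as
`inst/extdata/qed_ads_params.tsv`, and the unweighted QED is the geometric
mean \(\exp\!\big(\tfrac1n\sum\ln d_i\big)\). Values are clamped to
\([10^{-6}, 1]\) before the logarithm so the geometric mean stays defined;
note the sigmoid tails themselves flatten at \(a/d_{\max}\), which is well
above the clamp for most descriptors — the floor is a numerical guard, not
part of the model. The canonical 8-descriptor form is the default;
`use_alerts = FALSE` averages the remaining seven for compatibility with
tools that ignore structural alerts (tool-internal QED variants differ, so
pass/fail counts near the 0.5 threshold are variant-sensitive). The gate is
strict: a score of exactly 0.5 fails.

### Fingerprint similarity and clustering

The Tanimoto coefficient of two binary fingerprints is \(T = c/(a+b-c)\)
(shared over union of set bits); two all-zero fingerprints are defined as
\(T = 1\) and an all-zero against a nonzero one as 0, avoiding \(0/0\).
Clustering runs on \(1 - T\) with Ward linkage in the Ward.D2 convention —
the distance is not Euclidean, but Ward.D2 on it is the dominant,
deterministic convention in this ecosystem. The dispersion of a cut is
computed directly from distances, \(\mathrm{WSS} = \sum_{\text{clusters}}
\sum_{\text{pairs}} d^2 / (2 n_c)\), which coincides with the usual
centroid sum of squares in the Euclidean case. The elbow rule selects the
interior \(K\) maximising the discrete second difference of the WSS
profile (ties to the smaller \(K\); flat profiles give \(K = 1\)) — the
method is standard, the tie-break is this package's choice. k-means runs
on the raw 0/1 coordinates (squared Euclidean = Hamming), with k-means++
seeding over the distinct rows and the best of 10 restarts by WSS; any
2-D cluster plot is visualisation only. Validity: silhouette
\(s(i) = (b_i - a_i)/\max(a_i, b_i)\) with \(s = 0\) for singleton-cluster
members, and the Dunn index (minimum single-link separation over maximum
diameter, \(+\infty\) when all clusters are singletons).

The "reference cluster" is operationalised as *any* cluster containing at
least one reference drug: selected phytochemicals are the non-reference
members of such clusters. For descriptor-panel clustering of the reference
drugs themselves, columns are standardised, constant columns dropped, and
the "top cluster" is the one holding the most user-supplied anchor drugs —
a published heat map picks it visually; an anchor list is the reproducible
equivalent.

### Hub scores

Two Cytohubba-style node scores are implemented: degree, and MCC
(\(\sum_{C \ni v} (|C|-1)!\) over maximal cliques \(C\)), which reduces to
degree on triangle-free graphs. Degree is the default because the printed
scores in the source tables come from an unnamed metric; both are reported
side by side and ties break lexicographically by node id so rankings are
deterministic.

### Enrichment

Over-representation uses the hypergeometric upper tail
\(P(X \ge k)\) with the network's gene universe as background; BH-adjusted
q-values are always reported, but selection follows raw \(p < 0.05\) to
match the screen's convention. The topology-aware revision is an
EnrichNet-style XD-score: a random walk with restart probability
\(r = 0.7\) from the query genes, iterated as mass-conserving
\(p \leftarrow r\,e_S + (1-r)\,M p\) with column-stochastic \(M\)
(dangling nodes restart immediately) to an L1 tolerance of \(10^{-10}\),
then \(\mathrm{XD} = \overline{p}_{\text{pathway}\cap\text{net}} -
\overline{p}_{\text{net}}\). The fixed point equals the dense solve of
\((I - (1-r)M)p = r e_S\), which the tests verify to \(10^{-8}\). Ranking
ties break by \((p, -\mathrm{XD}, \text{id})\).

### Candidate plants

Cascade membership is an intersection of four pure filters, so it is
order-independent; per-stage counts are logged in the printed order for
comparability. Candidate plants are restricted to evidence-free plants
containing at least one survivor whose targets reach the pathway-gene
layer — the compound-level "lacks known activity" criterion does not by
itself imply the plant lacks evidence, and the screen's purpose is
unrecognised potential, so the plant-level restriction is explicit.
The structural network's gene layer defaults to pathway genes co-membered
with at least one target (`gene_layer = "connected"`); `"all"` includes
every loaded pathway gene, since the original network's node-type
composition is not fully specified.

### In-vivo statistics

Edema percent is \(100\,(M_f - M_i)/M_i\); the printed source formula is
typeset ambiguously and is read with this conventional grouping, consistent
with its variable definitions. Group summaries use the sample sd
(\(n-1\)) over \(\sqrt{n}\). Dunnett contrasts are two-sided (sidedness is
not stated in the source) and adjusted by Monte-Carlo sampling of the
max-\(|t|\) null — group means \(N(0, 1/n_i)\), shared
\(\chi^2_{df}/df\) variance — rather than numerical integration of the
multivariate t: it is simple, seeded, and accurate to well under 0.005 at
the default \(10^5\) draws (tests cross-check the two-group case against
the closed-form t-test and the general case against an independent
multivariate-t implementation). The adjusted p is clamped to at least the
raw p, which the finite draw count could otherwise undercut.

## The synthetic-data generator

Real inputs for this screen live in a supplementary appendix and external
databases, so the package ships a generator whose defaults emulate the
study's statistical shape at desk scale, with planted structure for ground
truth:

* **Taxonomy and evidence.** 20 families × 3 genera × 3 species = 180
  plants; per-class activity prevalences 21.3% (AOX), 19.1% (AINF), 1.4%
  (AAG), 0.6% (ASEN) — the rates of the curated collection (1025 plants,
  of which 661 had no evidence).
* **Fingerprints.** 150 phytochemicals plus an 18-drug reference panel
  drawn from `K_true = 3` prototypes of density 0.12 with 5% bit flips;
  the panel size and three-cluster structure mirror the reference
  analysis. All references come from prototype 1 by default, so truth
  labels identify the reference-similar set exactly.
* **Descriptors.** Log-normal MW (median 300 Da) and PSA (median 70 Å²),
  normal ALOGP (2.5 ± 1.2), Poisson counts — realistic marginals for small
  natural products; descriptors are independent of the fingerprint
  prototypes.
* **Toxicity and targets.** Each of four flags at 13% (≈ 42% of compounds
  carry some alert, matching the observed 718 → 417 attrition); 35% of
  compounds have ≥ 1 target (matching 417 → 148); 30% carry a known
  activity label.
* **Pathways.** 15 gene sets of 10–40 genes over a 200-gene universe
  (the source used 15 named pathway collections). Targets of prototype-1
  compounds hit the planted set's genes with probability 0.6; other
  compounds avoid them, so the planted set should top the enrichment.
* **Planted candidate plant.** The first evidence-free plant receives up
  to six compounds that pass every gate, so the end-to-end screen has a
  known right answer.
* **Edema.** Six groups × six mice; baseline 2.00 ± 0.05 mm; control
  trajectory peaking at 60% at 3 h; effective treatments around 25–30% at
  peak; mouse effect sd 5 and residual sd 6 percentage points. The design
  and formula follow the source; the numeric trajectories are this
  package's realistic choice, since the source figure prints none.

Each artifact (plants, compounds, pathways, incidence, edema) draws from
its own substream of the master seed, so regenerating one does not perturb
the others, and identical configurations are byte-identical. What the
generator does *not* emulate: real chemistry (valence-consistent
structures, correlated descriptors, fingerprint bit semantics), database
biases in target reporting, or taxonomic correlation of phytochemical
content. Passing tests therefore demonstrate that the pipeline's logic and
statistics are correct under the assumed statistical shape — not that the
screen's biological conclusions transfer to any particular real
collection.

## Numerical choices and degenerate inputs

* Desirabilities are clamped to \([10^{-6}, 1]\); missing descriptors are
  an error naming the descriptor.
* Similarity matrices are symmetrised exactly and the diagonal forced to
  1; distances have an exact zero diagonal.
* `elbow_select` needs a profile of length ≥ 3; `ward_cluster` requires
  `K_max < n`; `kmeans_binary` requires `K` ≤ the number of distinct
  points (duplicate rows cannot seed distinct centres).
* Silhouette is undefined for one cluster (error); singleton members score
  0. Dunn is \(+\infty\) when every cluster is a singleton and 0 when
  duplicates straddle clusters.
* The hypergeometric test errors on an empty query and skips (with a
  warning) pathways with no gene in the background.
* RWR errors when the seed set misses the network entirely; isolated
  nodes are handled by immediate restart.
* `edema_percent` requires a positive baseline; negative percentages are
  valid observations.
* All stochastic routines (`generate_dataset`, `kmeans_binary`,
  `anova_dunnett`, …) take explicit seeds, run under a locally scoped RNG,
  and restore the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on the
default 180-plant / 168-compound configuration, 100-replicate recovery
studies for the elbow/Ward/enrichment properties, a 1000-replicate
family-wise-error simulation for the Dunnett adjustment, and exact
brute-force comparisons on 200-fingerprint similarity matrices and ≤
12-point validity fixtures. These sizes were chosen so every property is
measured with comfortable statistical resolution while the whole suite
stays quick on a laptop.

## Known limitations

* Reproduction of the source's headline counts (1373/605/718, 417, 148,
  109, 24) requires its appendix tables and the internal settings of the
  original desktop tools (QED variant, alert catalogue); the package
  reproduces the *procedure* and validates it on planted synthetic truth.
* MCC enumerates maximal cliques; on dense non-biological graphs this can
  be exponential (the screen's networks are sparse and nearly bipartite).
* The four-criterion cascade treats activity knowledge as binary; degrees
  of evidence are out of scope.
* Pathway sets are inputs; no gene-identifier mapping is attempted.
```{r session}
sessionInfo()
```
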