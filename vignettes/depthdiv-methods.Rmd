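---
title: "Methods: depth-layer diversity and functional profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-layer diversity and functional profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthdiv)
```

## The analysis

`depthdiv` implements the downstream half of a shotgun-metagenomics survey
of ocean microbial communities sampled at three depth layers: surface
water (SRF, 3–7 m), the deep chlorophyll maximum (DCM, 7–200 m) and the
mesopelagic zone (MES, 200–1000 m).  The upstream half — read cleaning,
protein-level alignment, taxonomic classification with Kaiju, and mapping
of best hits to Gene Ontology (GO) terms — is out of scope: the package
*consumes* the per-read classification tables and annotation tables those
tools emit, and everything from there on is implemented and tested here:

1. aggregation of per-read classifications into rank-resolved taxonomic
   profiles (classified reads only);
2. per-sample abundance and normalized Shannon–Wiener diversity;
3. UPGMA clustering of samples with the Mojena stopping rule;
4. pairwise depth-layer comparisons (Wilcoxon rank-sum, Bonferroni);
5. GO-term frequency profiles and layer-exclusive term sets.

## Data model

A classification table has one row per read: a `C`/`U` flag, the read id,
a taxon id, and optionally a semicolon-delimited lineage at the seven
canonical ranks (superkingdom … species).  Reads can be attributed to
higher taxonomy nodes (for instance when an identical peptide matches
several species of one genus), so a classified read may lack a name at
the analysis rank; `aggregate_profile()` tallies such reads in
`unassigned_at_rank` rather than under any taxon, and the invariant
`sum(counts) + unassigned_at_rank = classified reads` is enforced and
tested at every rank.  Unclassified reads are excluded from all analyses.

## Diversity model

For sample $j$ with taxon proportions $p_{ij}$ over its $S_j$ observed
taxa, the Shannon–Wiener index is

$$H_j = -\sum_{i=1}^{S_j} p_{ij}\,\ln p_{ij},$$

computed with the natural logarithm (values in nats).  To compare samples
of very different sequencing depth and richness, $H_j$ is normalized by
the taxon pool observed across *all* samples under comparison,
$M = |\bigcup_j \text{taxa}_j|$:

$$H'_j = \frac{H_j}{\ln M} \in [0, 1].$$

Three conventions deserve a note:

* **Sign.** Some write-ups of the normalized index carry the minus sign of
  $H_j$ into the ratio, which would make $H'_j$ non-positive.  Since
  $H_j \ge 0$ by construction, the meaningful quantity is the non-negative
  ratio above, and that is what the package computes.
* **Log base.** The ratio is base-invariant as long as numerator and
  denominator share a base; the suite asserts this for bases $e$, 2 and 10.
* **The pool $M$.** $M$ counts taxa *observed with positive count*, not
  the size of any reference database, and by default only taxa resolved at
  the analysis rank (species).  Reads assigned above the analysis rank are
  excluded from both $p_{ij}$ and $M$; a configuration switch
  (`count_unassigned`) can include them in the abundance index, but they
  never enter the entropy, whose proportions must live on the taxon
  simplex.  The abundance index itself is the total number of reads
  attributed at the analysis rank.

## Clustering and the Mojena stopping rule

Samples are clustered by UPGMA (unweighted pair-group method with
arithmetic mean) on Euclidean distances.  The default feature is the
scalar $H'_j$ per sample — clustering samples by their diversity value —
with `cluster_features = "taxon_profile"` available to cluster on
per-taxon relative-abundance vectors instead; the scalar mode is the
documented default, the vector mode is provided because diversity-based
groups are often inspected against their full taxonomic profiles, and the
method description admits either reading.  Neither mode is asserted to
reproduce any particular published dendrogram.

UPGMA merges the closest pair of clusters at fusion height equal to their
average-linkage distance; the merged cluster's distance to any third
cluster $K$ is the size-weighted mean
$(|A|\,d(A,K) + |B|\,d(B,K))/(|A|+|B|)$.  Ties at the minimal distance
are broken deterministically in favour of the pair whose smallest
original leaf indices sort first.  The implementation is a direct
$O(n^3)$ agglomeration — transparent, and ample for sample counts in the
tens to hundreds; it is verified against both an independent
cross-pair-mean formulation and `stats::hclust(method = "average")`.

The flat partition comes from the Mojena rule: over the $n-1$ fusion
heights $\alpha_1 \le \dots \le \alpha_{n-1}$, a threshold

$$\theta_k = \bar\alpha + k\,\hat\sigma_\alpha, \qquad k = 1.25$$

is computed, and the agglomeration is cut just before the first merge
whose height *strictly* exceeds $\theta_k$: if that is merge $j^*$, the
partition has $n - j^* + 1$ groups; if no height exceeds $\theta_k$ all
samples form one group.  Numerical choices: $\hat\sigma_\alpha$ is the
sample standard deviation of the fusion heights (denominator $n-2$ for
$n-1$ heights), isolated in one place should a population-variance
convention ever be preferred; with a single fusion height the standard
deviation is defined as 0, so two samples always form one group under the
strict inequality; heights are used unstandardized.  Groups are labelled
`G1..Gg` in dendrogram leaf order.  The Newick export places each leaf at
depth height/2 below every ancestor, so leaf-to-leaf path lengths
reproduce the cophenetic distances exactly.

The stopping rule has a genuine decision boundary worth knowing about:
when planted clusters sit at *equally spaced* centers, the inter-cluster
fusion heights grow roughly linearly and $\theta_k$ with $k=1.25$ lands
just below the first of them, so very noisy within-cluster spreads can
flip the cut by one group.  The recovery simulations therefore use
separations large relative to the within-cluster spread (gap $\ge 100
\times$ sd), where the planted partition is unambiguous.

## Layer comparisons

Per-sample statistics (normalized SWI, abundance, domain proportions) are
compared between every pair of layers with the two-sided Wilcoxon
rank-sum test: exact enumeration of the rank-sum null when either group
has at most 10 observations and the data are tie-free (or when forced
with `mode = "exact"`), the normal approximation with tie-corrected
variance and continuity correction otherwise.  The degenerate case —
every pooled value identical — returns $p = 1$ with a warning rather than
an error, so a constant response never aborts a batch of comparisons.

The Bonferroni family is the set of comparisons actually performed within
one response variable (normally the three layer pairs; fewer when a layer
has under two samples).  Families are *not* pooled across responses:
each response panel is corrected on its own, a choice made explicit here
because published figure panels are conventionally annotated per panel.
Stars follow the usual legend: `ns` > 0.05, `*` ≤ 0.05, `**` ≤ 0.01,
`***` ≤ 0.001, `****` ≤ 0.0001.

Domain proportions are taken over the closed set
{Archaea, Bacteria, Viruses}; reads classified to any other superkingdom
are dropped and the remainder renormalized with a warning, since the
domain panels are defined on those three groups only.

## Functional profiles

GO-term frequencies are raw occurrence counts pooled over each layer's
samples, one occurrence per annotation row (a read with two terms
contributes twice) — occurrence counting per annotation row rather than
per read is the documented choice, and the conservation invariant (layer
totals equal annotation rows) is tested.  Counts are deliberately *not*
normalized by layer sequencing depth, matching the frequency definition
the analysis is built around; `normalize = "per-million"` exists for
depth-aware exploration but is off by default.

The display matrix takes the top `n = 50` terms either by overall summed
count (default) or as the union of each layer's own top `n`
(`scope = "per_layer"`); both selections are exposed because the two
readings differ and neither is privileged.  Cells are
$\log_{10}(\text{count}+1)$, the +1 keeping the transform total on the
zero cells that appear whenever a top term is absent from one layer; raw
counts are always attached.  A term is *layer-exclusive* when its count
is positive in exactly one layer; exclusive sets are pairwise disjoint by
construction.

## The synthetic community generator

Because the original 76-sample ocean dataset requires large downloads and
reference databases, every stage is exercised on synthetic data with
known ground truth.  The generator's defaults are fixed study conditions,
not tuning knobs:

| parameter | default | what it emulates |
|---|---|---|
| stations × layers × replicates | 8 × 3 × 3 (72 samples) | multi-station survey |
| classified reads per sample | log-uniform on $[5\times10^4, 4\times10^7]$ | observed spread of read totals over ~3 orders of magnitude |
| species abundance distribution | log-normal, $\sigma = 1.5$ | community unevenness |
| per-sample richness | 60 / 60 / 150 (SRF/DCM/MES) | more diverse mesopelagic layer |
| domain mix (A/B/V %) | 3/79/18, 5/78/17, 13/84/3 | archaea rising, viruses falling with depth |
| unclassified rows | 10% of emitted rows | classified-only filtering rule |
| GO design | 200 shared + 24/53/10 exclusive terms | layer-specific functional profiles |

Per sample, the species set is drawn per domain from global pools (100
archaeal, 300 bacterial, 150 viral species, allocated to domains by
largest-remainder on the layer's mix), relative abundances are log-normal
within domains and scaled to the domain mix, and read counts are one
multinomial draw.  Every read id, taxon id and lineage is fabricated but
structurally faithful to the classifier's output format.  GO annotations
give each classified read 0–2 terms from its layer's pool; after
sampling, any pool term still unseen in its layer is planted once, so the
exclusivity sets recovered downstream equal the design exactly.  Under
these defaults the per-sample normalized SWI lands roughly in
[0.35, 0.70] (occasional stray samples just outside, as log-normal draws
produce the odd strongly dominated community), with layer means near
0.50/0.51/0.62 — the mesopelagic clearly most diverse and the two photic
layers statistically indistinguishable, which is exactly the planted
contrast the comparison stage must detect and the null it must not
reject.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: phylogenetic correlation between
species abundances, co-occurrence structure, seasonal or geographic
gradients beyond the layer effect, sequencing error, classifier bias, or
any coupling between a sample's taxonomic and functional content.  The
read-total distribution is log-uniform because only the printed
minimum/median/maximum of the real totals are known; it is a stand-in,
not an empirical fit.  Recovering planted effects here validates the
*pipeline arithmetic*, not any biological claim.

Determinism is a contract: one seed fixes the RNG kind and produces
byte-identical datasets, and the pipeline itself is deterministic given
its inputs (its manifest deliberately records no timestamps and not even
the output location, so reruns anywhere are byte-identical).

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to keep the default suite
fast while preserving the planted effects: oracle equivalence on 100
random matrices with 3–12 leaves; Mojena recovery over 100 seeded draws
of 2–4 clusters; rank-sum exactness by full enumeration up to
$n_1+n_2=12$ and a 2000-replicate null for the empirical size; the
depth-gradient detection over 50 seeded datasets at the full 72-sample
design but a reduced read depth of $10^4$ classified reads per sample
(diversity indices are scale-invariant, so depth mainly adds multinomial
noise — the hard direction for detection, not the easy one); functional
round-trips on materialized small communities (~hundreds of reads per
sample).  Full-depth materialization (tens of millions of rows per
sample) is supported but pointless for testing, which is why
`generate_dataset()` has a counts-only fast path.

## Known limitations

* UPGMA is $O(n^3)$; fine for hundreds of samples, wrong tool for tens of
  thousands.
* The Mojena rule is applied to raw fusion heights with $k = 1.25$;
  formulations on standardized fusion levels exist and would give
  different cuts near the decision boundary.
* Exact rank-sum enumeration is used only for tie-free data; ties always
  fall back to the corrected normal approximation.
* The GO module treats term ids as opaque strings: no ontology-graph
  propagation to ancestor terms and no namespace filtering, so
  "exclusive" means exclusive among *annotated* ids, not among biological
  functions.
* `M`, and with it $H'$, depends on the sample set analysed together;
  adding samples can only grow $M$ and thus shrink every $H'_j$.
  Normalized values are comparable within one analysis, not across
  analyses.
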