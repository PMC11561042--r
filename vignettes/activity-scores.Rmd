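---
title: "From taxonomic abundances to metabolic activity scores"
author: "micrometab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From taxonomic abundances to metabolic activity scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micrometab)
```

## The model

16S rRNA sequencing yields counts of taxonomic features (ASVs or OTUs) per
sample, but not the metabolic functions of the community. Curated
collections of strain-level genome-scale metabolic reconstructions of the
human gut microbiota (AGORA, AGREDA, AGORA2) list, for hundreds of
strains, exactly which biochemical reactions each organism can carry out
and which metabolic subsystem each reaction belongs to — including
exchange (uptake/secretion) reactions, which can additionally be grouped
into compound-exchange ("CE") families of metabolites. `micrometab` scores
the *potential activity* of every reaction and subsystem in each sample by
combining the relative abundance of taxa with the strain-level presence of
reactions:

1. **Collapse and normalize.** Features with an unambiguous assignment at
   the chosen rank (species by default, genus optionally) are merged by
   taxon name and converted per sample to relative frequencies, so each
   sample's frequencies sum to 1. Taxa with no match in the reconstruction
   are then deleted, giving the matrix **X** (matched taxa × samples).
2. **Reaction presence ratios.** For taxon *i* matched to a set of
   strains, `R[k, i]` is the fraction of those strains whose model
   contains reaction *k* — 1 when all strains carry it, 0.75 when three of
   four do, 0 when none does. The alternative `weightMode = "full"`
   reproduces the mgPipe convention of granting weight 1 whenever any
   strain carries the reaction.
3. **Reaction scores.** `W = R %*% X`: `W[k, j]` is the presence ratio of
   reaction *k* in sample *j* weighted by the relative frequencies of the
   matched taxa. Because columns of X sum to at most 1 and R entries lie
   in [0, 1], every score lies in [0, 1].
4. **Subsystem weights.** `S[z, k] = 1/m_z` for each of the `m_z`
   reactions annotated to subsystem *z* (annotated subsystem or CE
   family), so rows of S sum to 1. The `subsystemMode = "contextualized"`
   contrast (again mgPipe-style) recomputes the denominator per sample
   over the member reactions with nonzero activity there.
5. **Subsystem scores.** `Y = S %*% W`, again in [0, 1].

Downstream, `differentialActivity()` compares two metadata groups per
reaction or subsystem (Wilcoxon rank-sum, Benjamini–Hochberg adjustment,
effect size `delta_psi` = difference of group means), and the exploration
helpers provide PCA with a silhouette measure of group separation and
hierarchically clustered heatmap orderings.

## Parameters that matter

* `level` — taxonomic rank for collapsing, `"species"` (default) or
  `"genus"`. Species matching uses the binomial "Genus epithet"; bare
  epithets are not unique across genera.
* `weightMode` — `"ratio"` (strain-presence fraction, default) or
  `"full"` (any-strain saturation). `full` never scores below `ratio`.
* `subsystemMode` — `"global"` (fixed denominator, default) or
  `"contextualized"` (per-sample denominator). With 6 of 10 member
  reactions present in a sample, the member weight is 1/10 globally but
  1/6 contextualized.
* `renormalizeAfterMatch` — the normalization is performed *before*
  deleting unmatched taxa, so X columns may sum to less than 1 when
  coverage is partial. The flag (default `FALSE`) rescales surviving
  columns to sum 1; both behaviours are exposed because either convention
  is defensible and the worked example cannot distinguish them.
* `alpha` (0.05) and `minEffect` (0.1) — joint significance threshold:
  `q_value <= alpha` **and** `|delta_psi| >= minEffect`.

## Name matching and ambiguity

Lineage strings from 16S classifiers differ from reconstruction strain
names only in decoration: rank prefixes (`g__`, `s__`), underscores,
case, and redundant whitespace. `normalizeTaxonName()` strips all of
these before comparison. A feature counts as *ambiguous* at a rank when
the name there is empty or contains one of the placeholder tokens
`uncultured`, `metagenome`, `sp.`, `unidentified` (configurable); such
features are dropped and logged rather than guessed at. A reaction is
flagged as an exchange reaction when the CE map names it or its
identifier uses the conventional `EX_` prefix.

## Statistical choices

* The Wilcoxon rank-sum test is exact when both groups have at most 8
  samples and no ties occur, and otherwise uses the normal approximation
  with tie and continuity corrections — exact where exactness is cheap,
  the standard approximation where it is not. Note the granularity
  consequence: with 3 samples per group the smallest attainable two-sided
  exact p-value is 0.1, so very small designs cannot clear `alpha = 0.05`
  no matter how clean the separation.
* BH adjustment is applied separately to the reaction table and the
  subsystem table, not pooled, since the two families answer different
  questions and are reported separately.
* Rows constant across all samples (e.g. reactions absent from every
  matched taxon) are retained with p = 1 rather than dropped, keeping the
  multiple-testing denominator a function of the reconstruction alone.
* `delta_psi = mean(groupA) - mean(groupB)` with `groupA` the first label
  given — an explicit sign convention, tested by a swap property.

## Exploration choices

* PCA mean-centers but does not variance-scale by default: all scores
  share the [0, 1] scale already, and scaling would inflate
  near-constant reactions. A deterministic sign convention (the
  largest-magnitude loading of each component is positive) makes outputs
  reproducible across platforms.
* The silhouette score is computed on the first two PCA coordinates by
  default, matching the 2-D ordinations it annotates; samples in
  singleton groups take width 0, the standard convention.
* Heatmap ordering uses Euclidean average-linkage agglomeration on rows
  and columns independently, via `stats::hclust`, whose agglomeration
  order is deterministic for fixed input.
* Group ellipses are 1-SD covariance ellipses (semi-axes are the square
  roots of the 2×2 covariance eigenvalues); the package emits parameters
  and leaves rendering to the caller.

## Numerical conventions

* The contextualized presence test is `W[k, j] > 0` exactly; W is built
  from exact ratios of small integers, so no tolerance is needed. An
  `epsilon` argument exists for robustness with externally supplied
  score matrices.
* A subsystem with zero annotated reactions is excluded with a warning;
  one with zero *active* members in a sample scores 0 there.
* Zero-count samples are a loud error naming the sample, never silent
  data loss; reactions present in zero strains are rejected at load.
* Strains, reactions and subsystems are sorted lexicographically at load;
  all score files are written at fixed 6-decimal formatting, making
  repeated runs byte-identical.

## What the synthetic generator emulates

`makeSynthetic()` builds a random bundle (strain reaction sets drawn
independently at a chosen density) and Dirichlet-multinomial counts —
overdispersed and compositional, the standard working model for 16S
counts — with an optional per-taxon log-fold group shift and optional CE
subsystems. It reproduces the *structure* real data present to the
pipeline (sparse presence, compositionality, group effects), but not
phylogenetic correlation between strain reaction sets, realistic
subsystem sizes, or sequencing artefacts such as chimeras and variable
read depth. Passing tests therefore demonstrate algorithmic correctness
on the defined contracts, not field performance on any real cohort. The
test suite runs the generator at deliberately small sizes (4–20 taxa,
15–220 reactions, 4–16 samples; the type-I simulation uses 200 null
reaction rows at 6 vs 6 samples), chosen to exercise every code path
while keeping the whole suite fast.

The deterministic worked example (`makeToyExample()`) pins down the rest:
3 species, 4 strains, 6 reactions in two subsystems and 6 samples in two
conditions, with the hallmark values X[, m1] = (0.7, 0.3, 0),
R[v4, a3] = 0.5 and S[p1, ] = (1/3, 1/3, 1/3, 0, 0, 0).

## Known limitations

* Scores measure *potential* (reaction presence weighted by abundance),
  not flux; no constraint-based simulation is attempted.
* Matching is purely name-based at genus/species rank; strain-level
  resolution of 16S data is not attempted, which is precisely why R
  averages over the matched strain set.
* Real AGORA/AGREDA content is user-supplied through the TSV bundle
  schema; the package ships only synthetic bundles.
* Only two-group unpaired comparisons are provided; no covariate
  adjustment or paired designs.
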