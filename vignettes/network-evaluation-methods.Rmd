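---
title: "Evaluating bio-NER tools with disease networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating bio-NER tools with disease networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bionetval)
```

## The model

`bionetval` scores a biomedical named-entity recognition (bio-NER) tool by
the structure of the disease network it induces, instead of by token-level F1
against an annotated corpus. The underlying assumption is biological:
diseases that share clinical terms (symptoms, findings) tend to share genes,
proteins and drugs, and tend to fall in the same top-level category of
disease classification systems. A tool that extracts terms accurately should
therefore produce a disease–disease similarity network that (a) overlaps
omics-derived disease networks far more than chance, and (b) organizes into
communities that coincide with classification categories far more than
chance. A tool that misses terms or hallucinates them weakens both signals.

### Network construction

Input is a bipartite association table: rows `(disease_id, entity_id)` from
one source. For diseases $i, j$ with entity profiles $T_i, T_j$, the edge
weight is the Jaccard similarity

$$ s(i,j) = \frac{|T_i \cap T_j|}{|T_i \cup T_j|}, $$

the complement of the Jaccard distance. Phenotypic (term-based) networks are
filtered: only pairs with similarity **strictly above** the 95th percentile
of all *nonzero* similarities are kept. Reference omics networks are not
filtered — omics associations are specific enough that the raw network is
already sparse. Diseases left without a retained edge are dropped.

Three conventions here were genuinely open and are fixed as package policy,
recorded in network metadata:

* **Percentile convention** — linear interpolation between order statistics
  (`stats::quantile` type 7), the common scientific-computing default.
* **Tie handling** — "above the percentile" is read as strictly greater than
  the cutoff. When many pairs tie exactly at the cutoff (likely with small
  integer-ratio similarities), they are all excluded; this is the
  conservative reading.
* **Percentile population** — the cutoff is computed over nonzero
  similarities only. Computing it over all $\binom{n}{2}$ pairs would pin the
  cutoff to 0 for any sparse dataset and disable the filter entirely.

### Null models and significance

Every statistic is judged against an empirical null: the same statistic on
randomized networks with the *same node set and edge count* as the observed
network, the Erdős–Rényi $G(n, m)$ model (default `n_reps = 1000`
randomizations; tests use fewer). "Randomly connected nodes" could also be
read as degree-preserving rewiring; that stricter null is available
(`null_model = "degree_preserving"`), but $G(n,m)$ is the default as the
simplest reading, and because degree-preserving nulls systematically shrink
overlap z-scores. Null samples get a Shapiro–Wilk normality check (p > 0.05
read as consistent with normality; failures are flagged, not fatal), and the
observed value becomes

$$ z = \frac{x_{obs} - \hat\mu_{null}}{\hat\sigma_{null}}, $$

with sign-preserving infinities when a degenerate null has zero variance.
Per-replicate seeds derive from the master seed by a counter scheme, so runs
are reproducible and replicate $i$ is independent of evaluation order. In the
overlap null the random pair sample is drawn directly in pair-index space —
provably the same draw `random_gnm()` would make for that seed — which avoids
materializing a thousand graphs.

### The two criteria

**Edge overlap.** Shared nodes/edges between the tool network and a reference
network are plain set intersections (weights ignored). Percentages are
reported relative to the *reference* (the question is how much known biology
the tool recovers); tool-relative percentages are also attached. Only the
phenotypic network is randomized in the null — the omics reference is not on
trial. The simultaneous-overlap variant intersects all references first and
uses that intersection as the denominator.

**Community–category coincidence.** Louvain partitions the tool network
(weighted modularity; the node order is shuffled by the seed before each run
so "best partition" is reproducible). Each community is labelled with the
majority category among its members that appear in the classification map;
ties break lexicographically and are flagged. The aggregate ratio is the
mapped-size-weighted mean of the per-community majority proportions — the
weighting keeps two-member communities from dominating the aggregate; an
unweighted mean is available (`weighted = FALSE`). Diseases missing from a
classification map are excluded from numerator and denominator, and a
disease listed with conflicting top-level categories in one system is an
input error: the reader refuses to guess a priority.

The coincidence z-score matters more than the raw ratio: random networks
already attain a baseline ratio (at least the largest category's frequency,
higher when communities are small), and the z-score is exactly the correction
for that baseline.

### Composite ranking

For each reference column and each classification-system column, z-scores are
min–max normalized across tools to $[0,1]$; each tool receives the mean of
its normalized overlap columns and the mean of its normalized coincidence
columns, and the composite is their equal-weight mean (weights are
configurable). Ranks descend by composite with ties sharing the minimum rank.
Two open choices fixed here: normalization is per column (not over pooled
z-scores), so every reference and every classification system contributes on
an equal footing; and an all-equal column normalizes to 0.5 everywhere with a
warning, so a degenerate column neither rewards nor penalizes anyone.

## The synthetic world

The generator stands in for the data the method was designed around — a
disease-linked text corpus mined by several tools, plus curated omics
association databases. It plants the one structure the method relies on:
block-structured similarity aligned across data layers.

* `n_diseases = 600` diseases are split evenly into `n_categories = 10`
  categories (one synthetic classification system).
* Each disease draws `terms_per_disease = 25` terms: with probability
  `p_within = 0.8` from its category's private pool
  (`category_pool_size = 150`, pools disjoint across categories), otherwise
  from a global pool (`global_pool_size = 3000`).
* Gene/protein/drug profiles are drawn the same way with their own knobs
  (10 entities per disease, pools 60/1200, `omics_p_within = 0.9`): omics
  associations are fewer and more category-specific than textual terms.
* Reference tables are subsampled to `reference_fraction = 0.4` of diseases,
  independently per omics layer, emulating the concentration of curated omics
  data on a limited disease subset while text covers nearly everything.

The scale is chosen so a full pipeline run takes seconds while Louvain
structure is stable; the acceptance checks state the sizes they use.

A simulated tool keeps each true term independently with probability
`recall` and adds Poisson(`noise_rate` × 25) spurious terms per disease,
drawn uniformly from the global term pool. Diseases with empty extractions
are dropped, as a real tool would return nothing for them.

### What the generator does not emulate

* **Systematic false positives.** Real NER errors repeat: the same ambiguous
  string is mis-extracted for many diseases, creating *correlated* false
  term-sharing. Uniform draws from a 3000-term pool make spurious
  co-occurrence of even two terms between two diseases vanishingly rare, so
  simulated false positives essentially never forge a high-similarity edge
  and the percentile filter screens them out of the retained network. A
  consequence worth knowing: in this world the *overlap* z-score
  differentiates tools mainly through network size, a weak signal relative
  to the count noise of a few hundred shared edges, while the *coincidence*
  z-score carries most of the fidelity signal — the acceptance run reports
  the resulting three-tool ranking-recovery rate honestly rather than
  presenting the composite as uniformly discriminative at this scale.
  Passing the synthetic suites shows the machinery is correct and
  calibrated, not that the composite separates arbitrarily similar real
  tools.
* **Graded within-category similarity.** Term sharing and omics sharing are
  conditionally independent given the category; in reality similarity is
  graded inside categories too.
* **Text itself.** Simulation operates at the association-table level; no
  tokenization or span detection is modelled.

## Numerical choices and degenerate inputs

* Edge weights are validated into $(0, 1]$; self-loops and duplicate pairs
  are rejected. Edge-list files serialize weights with 17 significant digits,
  so write/read round trips are bit-stable.
* Topology statistics (density, transitivity, assortativity, degree CCDF,
  overlap counts) use the unweighted skeleton; modularity uses weights,
  matching common Louvain practice. Null networks carry unit weights.
* Zero-variance assortativity (regular graphs) is reported as `NA`, not 0.
* Transitivity of a triangle-free, triad-free graph is 0.
* An edgeless network cannot be partitioned or summarized — that is a domain
  error, not a silent zero.
* Identifier ordering uses C-locale radix sorting throughout, so canonical
  edge order does not depend on the session locale.
* Identifier cross-maps are plain input files; the package performs no
  terminology-service lookups, keeping runs offline-reproducible.

## Known limitations

* The method compares tools; single-tool absolute scores are less
  interpretable because min–max normalization needs at least two tools to
  anchor its range (a constant column returns 0.5 with a warning).
* Overlap significance inherits the $G(n,m)$ null's leniency: networks with
  heavy hubs overlap more than $G(n,m)$ predicts even at random, which the
  degree-preserving alternative addresses at extra cost.
* Only flat top-level category maps are supported — no ontology traversal;
  multi-category diseases must be resolved upstream.
* Louvain is the only community algorithm in this version; its resolution
  parameter defaults to 1 and is exposed but untuned.
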