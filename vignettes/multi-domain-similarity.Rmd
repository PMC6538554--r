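---
title: "Multi-domain semantic similarity: models, liftings and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain semantic similarity: models, liftings and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdsemsim)
```

## The problem

Resources in biomedical data repositories are annotated with concepts from
several *orthogonal* ontologies: a dataset about an epidemic may carry
disease, symptom, transmission-mode, environment and vaccine concepts at
once. Classical semantic-similarity measures compare entities within a
single ontology; they have no way to use the fact that two resources are
annotated with related concepts *across* domains. `mdsemsim` implements two
ways of lifting well-validated single-ontology groupwise measures into
multi-domain measures, plus the machinery needed to evaluate whether the
lifted measures are actually better than single-domain baselines.

## Single-ontology building blocks

All measures operate on a subsumption DAG (is-a edges; optionally part-of)
with information content (IC) per term, in natural-log units.

**Corpus IC.** With `freq(t)` the number of (resource, annotation) pairs
whose term is `t` or a descendant of `t`, and `N` the total number of
pairs,

$$IC(t) = -\ln\!\big(freq(t)/N\big).$$

Roots have IC 0. Terms never observed receive the maximum observed IC:
this keeps every value finite while preserving the rarity ordering, and it
cannot break parent-to-child monotonicity because an unobserved term's
ancestors are at most as frequent as the whole corpus. With multiple roots
the normaliser stays `N` (each pair is counted once) and root IC is pinned
at 0; for the single-root graphs produced by merging this changes nothing.

**Intrinsic IC.** For a domain without annotation data,
$IC(t) = 1 - \ln(1 + |desc(t)|)/\ln n$ over the $n$ non-obsolete terms,
clipped to $[0, 1]$: leaves score 1, the root 0.

**Term measures.** Resnik is the IC of the most informative common
ancestor (MICA); Lin is $2\,IC(\mathrm{MICA})/(IC(t_1) + IC(t_2))$, defined
as 0 when the denominator vanishes. MICA ties are broken by the
lexicographically smallest term id so every run is deterministic.

**Groupwise measures** compare two annotation *sets* A and B:

* `resnik_bma`, `lin_bma` — best-match average:
  $\tfrac12\big(\mathrm{mean}_{a \in A} \max_b s(a,b) +
  \mathrm{mean}_{b \in B} \max_a s(a,b)\big)$. Annotation sets are used as
  given; no ancestor pre-extension (the closure belongs to the set
  measures, not to BMA).
* `simui` — Jaccard index of the reflexive ancestor closures.
* `simgic` — IC-weighted closure Jaccard. When every closure term has IC 0
  the score is 1 if the closures coincide and 0 otherwise.

Resnik scores are normalized by the ontology's maximum IC by default
(`normalize_resnik = TRUE`). Unnormalized Resnik values from ontologies of
different depth are not commensurable, and the aggregative settings average
scores across ontologies; normalization makes that average meaningful. The
flag exists because the unnormalized variant is also legitimate within a
single domain.

## The liftings

Four settings turn a groupwise measure into a resource similarity:

* **baseline** — the measure restricted to one domain's annotation
  subsets. A per-domain control, not a multi-domain measure.
* **aggregative (raw)** — per-domain scores averaged with equal weights
  over the domains where *both* resources have at least one annotation.
  Domains missing from either resource are *excluded* from the average
  rather than scored 0: most domains cover well under 70% of resources in
  realistically sparse corpora, and zero-filling would penalize sparseness
  itself rather than dissimilarity.
* **aggregative (weighted)** — same domain set, each domain weighted by
  the two resources' combined annotation count there. With equal counts it
  collapses to the raw average.
* **integrative** — all ontologies are merged into one multi-domain
  ontology and the measure is applied once to the full annotation sets.

**The merge.** Terms with identical ids across source ontologies are
unified into one concept, so their subclasses gain a common non-root
ancestor even when they come from different domains. A fresh root (id
`MULTI:0000000`) is created and every former root attached under it —
unless all inputs already share one single common root id, in which case
that root is reused. Identical ids are the only automatic unification
criterion; aligning near-duplicate concepts with different ids is out of
scope. Under corpus IC the merged root (and any unifying ancestor shared by
everything) has IC 0, so cross-domain pairs score 0 under Resnik but
strictly above 0 under simUI, which counts the shared root in the closure
intersection.

## ML-KNN evaluation

Whether multi-domain similarity is *useful* is assessed by predicting one
domain's annotations (the target, e.g. diseases) from the others. For each
resource the `k` most similar other resources are found (ties broken by
ascending resource id); a Bayesian estimator then scores each candidate
label:

* prior $P(H_\ell) = (s + n_\ell)/(2s + m)$ for a label held by $n_\ell$
  of $m$ resources, smoothing $s = 1$ by default;
* likelihood $P(E_j \mid H_\ell) = (s + c_\ell[j]) / (s(k+1) + \sum_j
  c_\ell[j])$, where $c_\ell[j]$ counts resources carrying $\ell$ whose
  neighbourhood contains exactly $j$ positives (and the analogous counts
  for $\lnot H_\ell$);
* posterior via Bayes' rule for the observed neighbourhood count.

The protocol is leave-one-out in the sense that each resource's
neighbourhood excludes itself; the prior and count statistics are estimated
once over the whole corpus, which is what the closed-form formulas above
state. Crucially, the similarity matrices used for prediction are built
with the target domain's annotations *excluded* — otherwise the task would
be circular. A baseline setting on the target domain itself is rejected for
the same reason.

Five multi-label metrics summarize each run: hamming loss, one-error,
coverage, ranking loss (all lower-better) and average precision
(higher-better). Rankings are the deterministic total order "descending
posterior, ties by ascending label id", and ranking loss is computed from
that order. The label space defaults to the labels observed in the corpus;
a `full_ontology` mode scores every non-root term of the target ontology
instead, which inflates the coverage and ranking-loss denominators and is
off by default.

**The H_p summary.** Over all (metric, k) runs of a sweep, $H_p$ counts
the runs whose $p$ best-performing settings are all multi-domain settings.
With three multi-domain settings $p \in \{1,2,3\}$ is meaningful and
$H_3 \le H_2 \le H_1 \le$ the number of runs. A baseline *tied* with the
$p$-th best value blocks the count — the conservative resolution, since a
tie means the multi-domain settings did not strictly dominate.

## The synthetic generator

No suitable public corpus pairs multiple orthogonal domain ontologies with
per-resource annotations, so the package generates its own study data. The
generator emulates the statistical shape of a sparse multi-domain
repository: per-domain coverage well below 1, per-domain annotation volumes
near 1 with one denser domain, and resources annotated in 1–5 domains. A
`synthetic_spec_epimarket()` preset mirrors that shape with seven domains
and 204 resources as a smoke fixture.

The cross-domain signal is planted through latent resource classes:

* each generated ontology has one top-level branch per class, and each
  class's *signature pool* is drawn from its own branch. This is
  deliberate: real annotations about the same subject cluster in a region
  of the ontology, and it is exactly this shared-ancestor structure that
  IC-based similarity can detect. With scattered random pools the labels
  would still be a function of the annotations, but the function would be
  invisible to any subsumption-based measure — the generator would not be
  testing the mechanism the package implements.
* a resource of class $c$ draws its annotations in source domain $d$ from
  $c$'s pool with probability `dependency[d]`, otherwise uniformly; its
  target label is $c$'s designated target term with probability
  `max(dependency)`, otherwise uniform.
* coverage indicators for the informative domains (strength > 0) are
  coupled so that every resource has at least one informative annotation
  while each domain's marginal coverage stays exactly as requested (the
  coupling exists whenever the informative coverages sum to at least 1).
  Without it, a fraction $\prod_d (1 - c_d)$ of resources would carry no
  visible signal at all and the noiseless limit — target labels a pure
  function of the visible source annotations — would be unattainable by
  construction.

At `dependency = 1` the target label is therefore a deterministic function
of the visible source-domain terms; at 0 it is independent of them. The
defaults (200 resources, two informative source domains at strength 1, one
pure-noise domain, 8 classes, 40 terms per domain, depth 5, coverage 0.7,
volume mean 2) are the study conditions used by the tests and the
acceptance script.

What the generator does **not** emulate: real DOID/SYMP term frequency
distributions, obsolescence churn, cross-references between ontologies,
annotator bias, or resources whose only annotations sit in the target
domain. Passing the recovery test therefore shows that the pipeline detects
a planted subsumption-structured dependency at realistic sparseness — not
that any particular real corpus has such a dependency.

## Numerical and design choices

* Natural log throughout; no measure ever returns NaN — every 0/0
  convention is fixed above.
* Empty annotation sets make a groupwise score *undefined*; the lifting
  layer maps undefined to 0 (baseline, integrative) or excludes the domain
  (aggregative).
* Obsolete terms stay in the graph for id resolution (`alt_id` maps to
  primary ids) but carry no edges and cannot be queried for closures.
* All tie-breaks (MICA, neighbourhoods, label rankings) are lexicographic,
  making every pipeline stage byte-reproducible under a fixed seed.
* Zero-frequency IC capping, root-IC pinning and the Resnik normalization
  are the only places a value is clipped.

Test problem sizes: the property suites use graphs of up to 20 terms and
sets of up to 8 terms against brute-force oracles (closures by boolean
matrix powers, similarities by naive double loops, ML-KNN by direct
enumeration); the recovery experiment uses the full default conditions
(m = 200). These sizes keep the whole suite under a minute while covering
every code path; all scale-dependent behaviour (IC, coverage statistics)
is checked at m = 500.

## Limitations

* Only identical-id unification: the merge will not align "the same"
  concept published under two ids, a problem explicitly left open.
* Cross-references and relationship types other than is-a/part-of are not
  used; measures that exploit inter-domain relations are future work.
* The evaluation is leave-one-out only; no train/test splits or
  significance tests over metric differences are provided.
* `full_ontology` label spaces grow the metric denominators linearly in
  ontology size and are off by default for tractability.
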