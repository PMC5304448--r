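---
title: "From phenotype profiles to gene function: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From phenotype profiles to gene function: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofun)
```

## The scientific question

Large RNAi screens annotate gene knock-downs with cellular phenotype
ontology terms (CMPO), while gene function is standardized in the Gene
Ontology (GO) cellular-process branch. If similar phenotypes indicated
similar functions, phenotypic similarity could drive automatic
functional annotation. `phenofun` implements the three analyses needed
to test that premise on a binary gene-by-phenotype matrix plus two
annotation corpora:

1. **Measure benchmark** — fifteen phenotypic similarity measures are
   ranked by how well they separate interacting from non-interacting
   gene pairs (protein interaction as a proxy for shared function):
   ROC AUC with Mann–Whitney tie handling, plus nearest-neighbour
   interaction recovery with a hypergeometric tail probability.
2. **Per-phenotype coherence** — for each phenotype, the mean GO
   semantic similarity among genes showing it is compared with a
   permutation null that redraws each phenotype's gene set at the same
   size (column sums preserved), with Benjamini–Hochberg correction at
   an FDR operating point of 0.01.
3. **Annotation-driven functions** — gene–term annotations are
   projected onto a weighted term graph (edge weight = Jaccard index of
   the two terms' gene sets), the graph is partitioned by
   normalized-cut spectral clustering, and each cluster's cross-ontology
   coherence is tested against size-preserving label randomizations.

## Model components and conventions

**Information content.** For a term $t$,
$p(t) = \mathrm{annotations}(t)/\mathrm{totalAnnotations}$ counts
distinct genes after propagating annotations to ancestors, and
$IC(t) = -\log p(t)$ in nats. Distinct-gene counting makes
$p(\mathrm{root}) = 1$ and IC monotone along is-a edges. Only is-a
edges are traversed; `part_of` is ignored (the ontology "terms
hierarchy" reading). The log base only rescales ICs and cancels in all
ratio- and rank-based uses.

**Term similarity.** Resnik ($IC$ of the most informative common
ancestor, MICA), Lin, Schlicker (Lin times $1 - p(t_{MICA})$), bounded
Jiang–Conrath $1 - \min(1, IC_1 + IC_2 - 2\,IC_{MICA})$, and
Pesquita/simGIC (IC-weighted Jaccard of ancestor-or-self sets). The
printed source formula for Jiang is typographically garbled; the
bounded Jiang–Conrath form is the convention of the toolkit family the
measure list comes from. MICA ties break to the lexicographically
smallest term id — deterministic and seed-free.

**Gene-pair aggregation.** Term-set scores are aggregated by
best-match average (default), max, or average. BMA is the common
default of ontology-similarity toolkits and is symmetric by
construction; the benchmark reports are labelled with the aggregation
so the choice is auditable. Similarity is computed on *direct*
annotation sets; propagation enters only through ancestor search and
IC, otherwise every pair would trivially share the root in simGIC's
denominator.

**Profile measures.** Euclidean similarity is $1/(1+d^2)$ (the printed
table writes $s^2$ on the left-hand side; the two are
monotone-equivalent for every rank-based use here). Cohen's kappa uses
the two-category chance term $p_c = q_1 q_2 + (1-q_1)(1-q_2)$. TF-IDF
follows the literal printed formula
$\max_p x_1^p x_2^p\,IDF(p)$: unshared phenotypes contribute 0 to the
maximum, so a pair sharing only very common (negative-IDF) phenotypes
scores 0 rather than negative. Degenerate inputs (all-zero profile for
cosine/Jaccard, zero variance for correlation, $p_c = 1$ for kappa) map
to 0 with a warning instead of NaN so downstream AUCs stay computable;
degenerate-pair counts are kept in attributes.

**Logistic PCA.** The binary matrix is embedded in $k = 10$ dimensions
by a Bernoulli-likelihood PCA fitted with iterative majorization: the
natural-parameter matrix is repeatedly replaced by the rank-$k$
truncated SVD of the working response $Z = \Theta + 4(X - \sigma(\Theta))$
(the $1/4$ curvature bound on the Bernoulli log-likelihood gives the
majorizer), with a column-mean offset. Initialization at zero scores
makes the fit deterministic; a sign convention on the loadings makes it
platform-stable. The projection-constant hyper-parameter of other
logistic-PCA formulations does not arise in this one.

**0 means "not tested" too.** The screens record absence and
not-tested identically as 0, and the pipeline treats them identically —
that is a property of the data being modelled, not a bug. The sparsity
perturbation (`perturb_sparsity()`, removing 5/10/20/30% of the 1s)
exists to measure the consequence, and the per-phenotype and cluster
analyses are re-run under it.

## Statistics: granularity of empirical p-values

Empirical p-values use the $+1/(n+1)$ correction and never return 0: a
hundred permutations cannot support $p < 1/101 = 0.0099$. Two
consequences shape the defaults:

* With $n_\mathrm{perm} = 100$, a phenotype can clear the $q \le 0.01$
  FDR threshold only when essentially all tested phenotypes sit at the
  minimum attainable p (BH multiplies by $m/\mathrm{rank}$). This
  matches the source analysis's operating point without claiming more
  resolution.
* For the cluster-coherence test, where typically only a fraction of
  clusters carries signal, the power analyses use
  $n_\mathrm{rand} = 1000$ (the default stays at the conventional 100,
  configurable): with a tested-cluster count $m$ and minimum
  $p = 1/1001$, BH clears $q \le 0.01$ whenever roughly
  $\mathrm{rank}/m > 1/10$.

The permutation scheme preserves column sums exactly (each phenotype's
link count is fixed) but not row sums; a literal reading of the stated
randomization. Genes without functional annotation are excluded from
the observed and null means alike.

## The cluster-coherence statistic

For a cluster of ontology-A terms, genes are collected through
*propagated* A-annotations (default), the genes' *direct* B-terms are
gathered with their gene counts, and the statistic is the
gene-frequency-weighted mean of B-term-pair similarity: pair
$(b_1, b_2)$ gets weight $n(b_1)\,n(b_2)$, the product of linked-gene
counts. Two design choices depart from the plainest reading and are
worth recording:

* **Weighting.** With realistic annotation noise, the *union* of a
  cluster's genes' B-terms covers nearly the whole B vocabulary, so an
  unweighted mean over distinct B-term pairs is dominated by terms
  carried by single noisy genes and cannot distinguish any cluster from
  any other — observed and null coincide. Frequency weighting restores
  the contrast; the unweighted mean remains selectable.
* **Uninformative-term exclusion.** A term whose propagated gene set
  covers more than half the universe (the root in the extreme) links
  every gene and washes out whichever cluster contains it, observed and
  null alike. Such terms contribute no gene linkage
  (`max_coverage = 0.5`, configurable). Foreign high-level terms below
  that threshold still penalize incoherent random term sets — which is
  exactly what gives the null its discriminating power.

The randomization permutes which term carries which cluster label, so
the cluster-size multiset is preserved exactly. Clusters linked to
fewer than two B-terms are excluded, mirroring the exclusion of
functional clusters not linked to phenotypes. Both directions (GO-side
clusters scored in the phenotype ontology and vice versa) run through
the same code path.

**Clustering.** Normalized cut is realized as the standard relaxation:
symmetric normalized Laplacian, embedding in the $k$ leading
eigenvectors with row renormalization, seeded k-means with multiple
restarts, reporting the achieved objective. On graphs of at most ten
nodes the returned partition attains the exhaustive minimum (verified
in the test suite). Disconnected graphs are handled before
eigen-decomposition: partitions that never split a component have zero
cut. The recursive plan (cluster into `base_k`, then re-cluster chosen
clusters by size rank) reproduces the 100 → 33 + 9 = 140 arithmetic of
the source analysis; which of the two largest clusters receives which
sub-count is configurable since the total is invariant.

## What the synthetic generator emulates — and what it does not

`make_planted_corpus()` states one world and keeps it fixed: 500 genes
in 8 modules, symmetric annotation noise 0.1, 15% of genes partially
untested, within-module interaction rate 0.15 over a 0.005 cross-module
background, and for each ontology a tree with one top-level subtree per
module (then ternary to depth 3). Module signatures are the three leaf
children of one deep internal term, so planted similarity is driven by
high-IC terms and cross-module similarity bottoms out at $IC(\mathrm{root}) = 0$.
Phenotype noise flips 1s off and 0s on inside the observed phenotype
columns; GO noise flips inside the leaves of the annotated function
space. The latter mirrors the former deliberately: letting functional
noise scatter over arbitrary unannotated leaves creates a diffuse cloud
of near-empty terms whose tiny gene sets produce spuriously strong
Jaccard edges — a regime curated annotation corpora do not exhibit, and
one that merges planted modules in the projection graph.

A green test on this world therefore establishes that the pipeline
recovers planted structure under bounded symmetric noise and partial
testing; it does *not* establish performance on real screen data, where
ontologies are far deeper and unbalanced, annotation noise is
structured rather than symmetric, and the interaction benchmark is
itself incomplete and biased. The headline numbers of the source
analysis (absolute AUCs, the 8/36 significant phenotypes, the 45/58
coherent clusters) depend on 2015-vintage database releases and are
deliberately not regression targets.

## Known limitations

* OBO parsing covers the `[Term]` stanza fields actually needed (id,
  name, is_a, is_obsolete); typedefs, intersections and cross-products
  are ignored.
* `spectral_ncut()` recovers exact optima on small planted graphs but,
  like every spectral relaxation, offers no global guarantee on large
  irregular graphs; the achieved objective is reported so runs can be
  compared.
* The nearest-neighbour benchmark breaks ties uniformly at random
  (seeded); on binary profiles ties are massive, so the hit count `x`
  has real variance across seeds — the hypergeometric p-value treats
  the chosen partner set as one draw.
* IC is computed on whichever corpus is supplied; whether to use the
  screened-gene subset or a full reference corpus is left to the
  caller (both are valid readings of the source method).
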