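---
title: "Predicting cancer driver genes from ontology embeddings: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cancer driver genes from ontology embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ontodriver)
```

## The model

`ontodriver` treats driver-gene prediction as a knowledge-based
classification problem. The premise is that a gene's *potential* to drive a
cancer type is reflected in what the gene does — its molecular functions,
cellular locations, cellular phenotypes, and whole-organism knockout
phenotypes — and that this knowledge, recorded as ontology annotations, can
substitute for (and complement) mutation-frequency evidence.

The pipeline has four stages.

**1. Corpus.** Each ontology is first closed under subclass entailment:
every transitively entailed `A SubClassOf C` axiom is added, marked
`inferred`. Reasoning is deliberately structural — transitive closure over
plain subclass axioms only, with no propagation through existential
restrictions. The dominant axiom type in biomedical ontologies is the plain
subclass axiom, closure over it has an exact brute-force oracle (which the
test suite exercises on random DAGs), and heavier OWL reasoning would add
entailments this corpus representation cannot express anyway. The closed
ontology, its class labels, and the gene–class annotations are rendered
into sentences:

* `C_1 SubClassOf C_2` (3 tokens) or
  `C_1 SubClassOf R some C_2` (5 tokens) per axiom,
* `C_1 label <label words>` per labelled class (lower-cased,
  whitespace-tokenised),
* `GENE hasAnnotation C_1` per annotation record.

Class identifiers are rendered in underscore form so each is a single
token. The association relation is one shared token, `hasAnnotation`, for
all sources: no standard name exists for it, and a shared token lets genes
annotated in different ontologies share context structure. Sentences are
emitted in deterministic sorted order (axioms, metadata, associations) so
that embedding training is reproducible. Inferred axioms and metadata
sentences are both included by default and can be switched off
(`build_corpus(..., include_inferred =, include_metadata =)`); whether the
original experiments included them is not recoverable, so both are explicit
flags rather than silent assumptions.

**2. Embedding.** A skip-gram model with negative sampling is trained on
the corpus. The published configuration is kept as the default: embedding
size 100, window 5 (axiom sentences have 3–10 tokens, so a window of 5
spans them), minimum count 5, skip-gram objective. Two deviations from the
word2vec defaults deserve explanation:

* *Epochs (default 50, not 5).* The word2vec default of 5 passes assumes
  corpora of 10⁸–10⁹ tokens. The corpora this package builds at study
  scale have ~10⁴–10⁵ tokens; at 5 passes the gene vectors barely move
  from their random initialisation and carry no usable signal. Fifty
  passes give each gene token a few thousand gradient updates, which is
  where the planted-signal recovery experiments (below) stabilise.
* *Frequent-token subsampling (default `sample = 1e-3`, the word2vec
  default).* The relation tokens `hasAnnotation` and `SubClassOf` appear
  in every association/axiom sentence — roughly a third of all tokens.
  Without subsampling, these hubs dominate every context and all vectors
  collapse onto a single shared direction; with the standard subsampling
  they are mostly skipped and the informative co-occurrences (gene ↔
  class, class ↔ class) drive the geometry.

Gene tokens are exempt from the minimum-count threshold: with
`min_count = 5`, a gene with fewer than five annotations would otherwise
receive no vector at all, contradicting the union representation's purpose
of covering every gene with at least one annotation. Gene vectors are read
directly from the trained vocabulary (genes are corpus tokens), not
averaged over class vectors. Training is single-threaded with a private
deterministic RNG, so embeddings are bit-for-bit reproducible for a given
seed — a property the test suite asserts rather than assumes.

**3. Classification.** One binary feedforward network per cancer type:
ReLU hidden layers (default widths 128 and 64), a single sigmoid output,
binary cross-entropy loss, RMSprop updates (learning rate 10⁻³, batch
size 8, 100 epochs), inputs standardised on the training folds. Positives
are the known drivers of the type; negatives are an equal-sized uniform
sample of genes that are drivers of *no* type. Evaluation is stratified
10-fold cross-validation; per-type metrics are computed on the pooled
held-out scores, and an `"overall"` result micro-averages the pooled
predictions across types (a macro average is also reported by `glance()`,
but micro is the headline, since a single-number summary over per-type
binary tasks is most naturally the pooled one). One model per type — rather
than a 20-output multi-label network — matches the per-type negative
sampling scheme and keeps the balanced-set semantics exact. F-scores are
computed at threshold 0.5; no operating point is prescribed by the problem,
so the conventional one is used and exposed as a parameter.

Candidate drivers for type *t* are the genes scoring ≥ 0.5 for *t* that are
not already labelled as drivers of *t*, sorted by score.

**4. Validation statistics.** Three orthogonal checks, each returning a
`test_result` with statistic, one-tailed p-value, direction and group
sizes:

* *Mutation frequency.* Per-gene somatic mutation count divided by gene
  length; candidates vs genes that are neither known drivers nor
  candidates, one-tailed Welch t-test (unequal variances,
  Welch–Satterthwaite df). Whether "length" is CDS or genomic span is an
  input-level choice the package does not resolve: the frequency is
  relative to whatever length column is supplied.
* *Network modules.* The observed statistic is the number of candidate
  genes with at least one network edge to a known driver (adjacency, not
  membership). The null resamples equally sized node sets uniformly —
  10,000 times by default. Two p-values are reported side by side: the
  empirical permutation p `(1 + #{null ≥ obs})/(1 + N)`, which is the
  statistically proper one, and a one-sample t-test of the null draws
  against the observed value, which is the style of summary this
  comparison is often quoted with. They agree in every regime we generate,
  but the empirical p is the one to trust at extreme significance. The
  sampling frame excludes the known drivers by default
  (`permutation_config(exclude_drivers = TRUE)`): candidates are
  non-drivers by construction, so the null should resample from the same
  population; with a STRING-sized network the distinction is negligible,
  and the flag restores the include-everything frame if wanted.
* *Pathogenicity enrichment.* After keeping coding variants (a missing
  coding flag counts as non-coding, logged) and rare variants
  (AF < 0.01; a missing AF is kept — novel variants are rare), a
  one-tailed Mann–Whitney U test per scoring tool asks whether candidate
  -gene variants look more deleterious. Direction follows each tool's
  convention — SIFT and FATHMM score *lower* = worse, the others
  higher = worse — so "more pathogenic" is tested as `a_less` for the
  former and `a_greater` for the latter. The U statistic uses midranks;
  p-values are exact (full enumeration) for tie-free samples with
  n ≤ 12 and use the tie-corrected, continuity-corrected normal
  approximation otherwise. The enumeration and approximation paths agree
  to < 0.01 at the crossover size.

## The synthetic study

`synthetic_config()` defines a complete self-contained study; its defaults
*are* the study conditions for every empirical claim in the test suite.

| parameter | default | why |
|---|---|---|
| `n_genes` | 500 | large enough for stable pooled CV metrics, small enough for minutes-scale runs |
| `n_classes_per_ontology` ×3 | 20 | smallest DAG with enough depth-2 subtrees to host the cancer types |
| `n_cancer_types` | 6 | two signal subtrees per ontology; full-size ontologies would be needed for 20 types |
| `driver_fraction` | 0.16 | ≈ 13 drivers/type, comfortably ≥ 10 positives needed for 10-fold CV |
| `holdout_fraction` | 0.2 | one fifth of drivers are unlabelled "novel" drivers the classifier should rediscover |
| `signal_strength` | 0.9 | probability a driver's annotation (in its type's designated source) lands in the type's subtree; 0 gives an exact null |
| `annotations_per_gene` | 30 | comparable to a well-annotated human gene |
| `p_within` / `p_background` | 0.2 / 0.001 | driver–driver edge enrichment on a sparse background; denser backgrounds saturate the adjacency statistic |
| `variant_shift` | 2 | per-tool mean score shift for driver-gene variants (sign flipped for lower-worse tools) |

The signal is planted through annotation bias only — never injected into
the features directly — so that recovering it requires the whole
corpus → embedding → classifier chain to work. Each cancer type's subtree
lives in exactly one ontology, assigned round-robin, so the three sources
carry complementary information: a single-source representation can learn
only the types hosted in that source (micro-AUC ≈ 0.65–0.7 at defaults),
while the union representation sees all of them (micro-AUC ≈ 0.97–0.99).
This reproduces, qualitatively, the ordering in which merging ontologies
beats every individual source.

What the generator does *not* emulate: realistic ontology content and
annotation sparsity patterns, evidence codes, mutational signatures,
tumor heterogeneity, or tool-realistic pathogenicity score ranges (scores
are Gaussian; the Mann–Whitney tests are rank-based, so only shift and
orientation matter). Passing tests therefore demonstrate that the
machinery is correct and can recover a signal that flows through
annotations — not that real GO/MP/CMPO annotations carry that signal at
any particular strength.

## Numerical and degenerate-input choices

* AUC uses the Mann–Whitney pairwise definition with half-credit for tied
  scores; it is checked against exhaustive pair counting to 10⁻¹².
* `f_score` is 0 by convention when there are no true positives (including
  the all-zero case).
* Welch's test on two constant equal groups returns p = 0.5 with a
  warning; constant unequal groups are an error.
* Subclass cycles abort closure with the cycle listed; reflexive axioms
  are never added.
* Merging ontologies keeps the first label seen for a duplicated class id
  and warns on conflicts.
* Stratified folds are dealt round-robin after a within-class shuffle, so
  per-fold class counts differ by at most one.
* Every stochastic stage (negative sampling, fold assignment, weight
  initialisation, batch order, permutation draws, all generators) derives
  an independent stream from one master seed; two runs with the same seed
  produce byte-identical artifacts, and the test suite compares the
  files, not just the numbers.

## Problem sizes used by the checks

The cross-validation experiments run at the generator defaults above
(500 genes, five representations, 10 folds). Null calibration of the
classifier uses the mean pooled AUC over three replicate studies with
`signal_strength = 0`: a single pooled run at this size has a standard
deviation of ≈ 0.07, so a lone draw is too noisy to sit reliably in a
narrow chance band, while the 3-replicate mean is. Calibration of the
network permutation test uses 1,000 replicate random graphs (200 nodes,
edge probability 0.025, 12 drivers, 40 candidates, 300 permutations each):
the connection count is integer-valued, so its empirical p-value is
slightly conservative by construction, and smaller graphs make the
discreteness visible as a sub-nominal rejection rate. Pathogenicity
calibration uses 1,000 replicate null variant sets. The oracle-equivalence
checks run 100 random instances (AUC, Welch) and full enumerations
(Mann–Whitney n ≤ 6, closure on DAGs ≤ 12 classes).

## Known limitations

* Only OBO 1.2 term stanzas and a functional-syntax OWL subset (named
  `SubClassOf`, single `ObjectSomeValuesFrom`) are parsed; other axiom
  types are skipped with a counted warning, and no use is made of
  equivalence axioms or cross-ontology bridges beyond what input files
  assert.
* The classifier is intentionally small and CPU-bound; there is no
  hyperparameter search. Architecture and optimiser settings are exposed
  in `model_config()` and logged, not tuned per dataset.
* Probability outputs are not calibrated; the 0.5 candidate threshold is
  an operating point, not a posterior statement.
* The per-type models are independent; a gene highly ranked for several
  types is reported for each, with no joint modelling of type
  correlations.
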