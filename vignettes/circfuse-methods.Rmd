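---
title: "Multi-source circRNA functional similarity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source circRNA functional similarity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circfuse)
```

circRNAs carry almost no direct functional annotation, so their functional
similarity has to be inferred indirectly. `circfuse` builds three
similarity networks from three independent evidence channels — disease
associations, gene/ontology annotations, and the nucleotide sequence itself
— and fuses them with convex weights calibrated against a fourth, held-out
signal (shared miRNA sponging). This vignette documents the models, the
parameters that matter, the numerical conventions, and what the synthetic
data used throughout the tests can and cannot demonstrate.

## Disease channel (CDFS)

Diseases live in a MeSH-style DAG (child → parent = "is narrower than").
For a disease $D$ with ancestor closure $T_D$, the decayed-ancestor
contribution is

$$D_D(D) = 1,\qquad
  D_D(d) = \max\{\Delta \cdot D_D(d')\,:\,d' \text{ child of } d \text{ in } T_D\},$$

so with a single decay factor the contribution of an ancestor equals
$\Delta^k$ for its shortest upward hop count $k$; multiple parents take the
best path. The semantic value is $DV(D)=\sum_{d\in T_D} D_D(d)$ and two
diseases score

$$S(M,N) = \frac{\sum_{d \in T_M \cap T_N}\big(D_M(d)+D_N(d)\big)}{DV(M)+DV(N)}.$$

Two circRNAs then aggregate their disease sets $D(i)$, $D(j)$ by the
symmetric best-match average: each disease is matched to its most similar
disease on the other side and the matched scores are averaged over
$|D(i)|+|D(j)|$.

**$\Delta$ (semantic contribution factor).** Unit-less, strictly inside
$(0,1)$; default **0.5**, the standard choice for this family of measures.
Smaller values localize similarity (only near-identical disease sets
score); the tests verify $S(M,N)\to 0$ as $\Delta\to 0$ for distinct
diseases.

**Degenerate inputs.** A circRNA with no disease associations yields the
missing sentinel (`NA`) off-diagonal rather than 0: absence of evidence is
not evidence of dissimilarity, and the fusion step can renormalize around
it. Diagonals are forced to 1 by the identity convention even for
unannotated circRNAs. A disease annotated in several tree positions is
treated as one node whose ancestor closure merges all positions.

## Ontology channel (GOFS)

Every ontology axiom, gene annotation and circRNA–gene link becomes one
three-token sentence — `(GO:a, is_a, GO:b)`, `(gene, has-function, GO:a)`,
`(circRNA, has-function, gene)` — and a skip-gram model with negative
sampling is trained on the corpus. One triple per sentence is the simplest
segmentation; with window 10 every token of a triple sees every other, so
nothing is lost. Default training parameters: `sg = 1`, `min_count = 1`
(rare biological entities must keep vectors), `size = 200`, `window = 10`,
`iter = 5`, `negative = 4`, initial learning rate 0.025 with linear decay.

The trainer is implemented in C++ single-threaded and draws **all**
randomness (initialisation, noise words) from R's RNG: a fixed seed plus
the deterministic sentence order (axioms in file order, annotations sorted)
makes embeddings bit-reproducible run-to-run. This is the supported
deterministic mode; there is no multi-worker mode. CBOW is accepted as a
configuration key but deliberately not implemented.

Gene–gene similarity is the cosine of the two vectors clamped to $[0,1]$
(anti-correlated vectors score 0, preserving the similarity contract — the
metric choice follows the ontology-embedding convention). circRNA pairs
aggregate gene sets with the same best-match average as the disease
channel; a mean-over-set variant is available (`agg = "mean"`) since the
aggregation is a genuinely open choice, but best-match is the default by
analogy with the disease-group formula. circRNA token vectors are trained
and exposed for inspection, but circRNA similarity is always computed from
gene sets — the set formula is explicit, the token route is not.

## Sequence channel (SQFS)

The chaos game maps a sequence into the unit square:
$P_0=(0.5,0.5)$, $P_i = 0.5\,(P_{i-1}+S_i)$ with vertices A=(0,0), C=(1,0),
G=(1,1), U=(0,1). Conventions fixed here (the method is insensitive to
them, but bit-exact tests need one choice):

* `T` maps to `U`; `N` and IUPAC ambiguity codes are **skipped** without
  moving the point — a random vertex assignment would break determinism;
* $P_0$ is excluded from the features: the arbitrary start point carries no
  sequence information;
* the grid at subdivision exponent $s$ (default 3, i.e. 8×8 = 64 cells)
  uses half-open cells $[k/2^s,(k+1)/2^s)$ with the top/right boundary
  clamped inward, ordered row-major by (y-cell, x-cell).

Each cell contributes $(X_i, Y_i, Z_i)$: the coordinate sums of its points
and the population z-score of its point count (all zero when the counts
have zero variance). The feature vector concatenates the triples — length
$3\cdot 4^s = 192$ at $s=3$. Binning conserves mass exactly: cell counts
sum to the usable length and coordinate sums to the trajectory totals,
which the tests assert against a per-point brute-force oracle.

Pair similarity defaults to the **absolute Pearson correlation** of the two
feature vectors; a cosine form is available behind `metric = "cosine"`
(clamped at 0). Both appear in the literature for FCGR features; absolute
Pearson is the default because it is scale- and location-free on features
whose magnitudes grow with sequence length. A zero-variance feature vector
cannot be Pearson-correlated; its pairs become the missing sentinel with a
warning.

## Fusion, tuning and evaluation

$$FS = \alpha\,CDFS + \beta\,GOFS + \gamma\,SQFS,\qquad \alpha+\beta+\gamma=1 .$$

Where a modality is missing for a pair, the remaining weights are
renormalized over the present modalities, keeping $FS$ on $[0,1]$; a strict
mode (`renormalize = FALSE`) propagates the sentinel instead. The
renormalizing default exists because disease evidence is sparse for most
circRNAs in practice.

Weights are tuned by exhaustive grid search: $\alpha \in \{0, 0.1, 0.2\}$
(disease evidence is the thinnest channel, so its weight is capped),
$\beta \in \{0,\dots,1\}$, $\gamma = 1-\alpha-\beta \ge 0$, step 0.1 — 30
combinations. Each candidate is scored by the Pearson correlation between
the fused network and the miRNA Jaccard network (CMS) over
strictly-upper-triangle pairs where both are defined; self-pairs are
excluded because they are identically 1 and would inflate every
correlation equally. Ties (unstated in any convention) break
deterministically: larger $r$, then smaller $p$, then lexicographic
$(\alpha,\beta)$.

The expression evaluation computes the absolute Pearson correlation of two
circRNAs' expression profiles as expression similarity, buckets pairs by
fused similarity into bins of width 0.1, and correlates per-bin means; the
unbinned pairwise correlation is also available. Both are reported because
they answer different questions (per-pair association vs. trend across the
similarity range). With fewer than three occupied bins the p-value is
undefined and reported as `NA`; fewer than two bins is an error. The
functional network export keeps all pairs at or above the cutoff
(default 0.7, the conventional sparsification threshold for similarity
networks), sorted by descending score.

## Synthetic data: what it emulates, and what it does not

`make_dataset()` plants `n_clusters` functional clusters: members share
nearby diseases (2–4 draws from a cluster-specific subtree), genes
annotated into a cluster-specific GO subtree (3–5 terms per gene, 2–3
genes per circRNA), sequences mutated from a common cluster ancestor
(substitution probability $0.3\cdot\text{noise}$ per site), miRNA sets
drawn from disjoint cluster pools (the full pool at noise 0, so clean
within-cluster Jaccard is exactly 1), and expression profiles equal to a
cluster mean plus Gaussian noise (sd $0.1+\text{noise}$, 10 samples).
Defaults — 24 circRNAs, 3 clusters, 30 diseases, 30 genes, 40 GO terms,
40 miRNAs, 300–500 nt, noise 0.1 — are desk-scale sizes chosen to make
every channel informative while keeping a full pipeline run in seconds;
the indel-free substitution model is intentional, as FCGR features need
only substitution-level divergence to show signal.

These data demonstrate that each channel recovers planted structure and
that the fusion machinery recovers planted weights
(`make_planted_fusion()`, $\sigma=0.01$ around grid points). They do
**not** emulate the statistics of real resources — MeSH's topology, GO's
term-size distribution, real circRNA alias ambiguity, starBase's coverage
bias — so passing tests certify the algorithms, not performance on any
real corpus. Real-data headline correlations depend on those resources and
are out of scope here. One visible artifact: at noise 0, within-cluster
sequences are identical, which makes the pure-sequence corner of the grid
degenerate-optimal; the acceptance computations therefore run the pipeline
at the default noise 0.1.

## Numerical conventions

* Similarity matrices are validated symmetric within $10^{-9}$, values in
  $[0,1]$ or `NA`, diagonal 1 or `NA`; tiny numerical excursions are
  clamped and symmetrized at construction.
* Matrix TSVs serialize at 12 significant digits; write/read round-trips
  agree within $10^{-9}$. The missing sentinel serializes as `NA`.
* Identifiers are trimmed and internal whitespace collapsed, case
  preserved (MeSH headings and gene symbols are case-significant).
* The disease recursion is memoized over the ancestor closure; cycles are
  rejected at DAG construction with a witness cycle.
* All stochastic components (generator, trainer, harness) consume a single
  user-supplied seed through R's RNG.

## Known limitations

* The ontology reader covers the OBO subset (`is_a`, `relationship`
  lines); full OWL semantics and inferred axioms are out of scope.
* circRNA identifiers must be pre-reconciled across sources; no alias
  resolution is attempted.
* Embedding quality on very small corpora is noisy; the package treats
  embedding-dependent comparisons as stochastic properties (majority over
  seeds), and so should its users.
* Information-content disease measures (Resnik/Lin), k-mer/PSSM sequence
  features and alignment-based similarity are deliberately not provided.
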