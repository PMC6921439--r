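---
title: "Integrating multi-source disease association data into disease similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating multi-source disease association data into disease similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsim)
```

## The problem

How similar are two diseases? A single data source gives a partial answer:
gene–disease associations say nothing about diseases with no known genetic
component, symptom catalogs cover a different subset, and pathway
annotations yet another. `dsim` integrates several such corpora: it builds
one semantic similarity network per source over a shared disease
vocabulary, summarizes each network by random-walk diffusion, learns one
low-dimensional feature vector per disease that jointly explains all
networks, and scores disease pairs by the cosine of those vectors.

This vignette explains the model, the parameters that matter, the
numerical choices, what the synthetic test bed does and does not emulate,
and the places where the design was genuinely open.

## Semantic similarity over the disease DAG

The vocabulary (a MEDIC-style table of `DiseaseID`, `DiseaseName`,
`AltDiseaseIDs`, `ParentIDs`) defines a directed acyclic graph from child
terms to more general parents. An association corpus induces occurrence
counts on this DAG. The frequency of a term is

$$f(t) = \mathrm{self}(t) + \sum_{u \in \mathrm{desc}(t)} \mathrm{self}(u),$$

where the sum runs over the *distinct* strict descendants of $t$. On a
tree this equals the usual recursive children-sum; on a DAG the recursive
form would count a multi-parent descendant once per path, which can push
$\mathrm{prob}(t) = f(t)/N$ above 1. Summing each descendant once keeps
probabilities in $[0,1]$ and preserves the monotonicity
$\mathrm{prob}(\mathrm{parent}) \ge \mathrm{prob}(\mathrm{child})$. $N$ is
the total (resolvable) record count — the frequency of the root, or of a
virtual super-root when the vocabulary has several roots, as the disease
branch of MeSH does.

Lin's measure compares two terms by the information they share:

$$\mathrm{Score}(t_1,t_2) = \max_{t \in \mathrm{LCA}(t_1,t_2)}
\frac{2\log \mathrm{prob}(t)}{\log \mathrm{prob}(t_1) + \log \mathrm{prob}(t_2)}.$$

"Least" common ancestors are the common ancestors minimal in the ancestor
partial order — no other common ancestor descends from them; the
definition matters only for multi-parent DAGs, where the LCA can be a set.
Degenerate cases are fixed by convention: an empty LCA (terms under
disjoint roots) scores 0, a term with probability 0 scores 0 against
everything, and when both probabilities are 1 (no information) the score
is 1 for identical terms and 0 otherwise. The log base cancels in the
ratio. Because probability is monotone along edges, the maximizing
ancestor is always a minimal one, so the all-pairs network builder may
search all common ancestors — the test suite checks the equivalence pair
by pair.

The per-source **edge threshold defaults to 0** (any positive similarity
is an edge): the published network densities do not pin down a rule, and
thresholding is better left to the consumer of the network.

## Diffusion states

Each similarity network is row-normalized into a transition matrix;
zero-degree nodes get a self-loop so the walk is defined on any node
universe. The random walk with restart

$$s_i^{(t+1)} = (1 - a)\, s_i^{(t)} T + a\, e_i$$

converges to the node's diffusion state. The **restart probability
defaults to $a = 0.5$**, the standard choice for this kind of diffusion
summary; larger $a$ keeps the state more local, smaller $a$ more global.
The stopping rule is ours (the fixed point is only characterized as "a
stable distribution"): iterate until every row changes by less than
`tol = 1e-8` in L1, with a hard cap of 1000 iterations and an error —
never a silent partial result — if the cap is hit. At $a = 0.5$ the
contraction factor is $1 - a$, so convergence takes about 27 iterations
regardless of size. A direct linear solve
$s_i = a e_i (I - (1-a)T)^{-1}$ serves as the independent oracle in the
tests.

Sources cover different disease subsets. All networks are expanded to the
union node set; a disease absent from a source is isolated there, its
diffusion state the indicator vector at itself — the source simply
contributes no relational information about it.

## The embedding model

The softmax model approximates diffusion states with $d \ll n$ features:

$$\hat s_{ij} = \frac{\exp(x_i^\top w_j)}{\sum_{j'} \exp(x_i^\top w_{j'})},$$

fitted by minimizing
$C = \frac{1}{n}\sum_m \sum_i D_{KL}(s_i^m \,\|\, \hat s_i^m)$ over the
node features $X$ (shared across networks — they are the output) and one
context matrix $W^m$ per network. Sharing $X$ while letting $W^m$ vary is
what couples the networks: a disease's feature vector must simultaneously
explain its diffusion neighborhood in every source that covers it. The
$1/n$ prefactor is kept for the multi-network sum (it does not change the
minimizer) and the per-network decomposition is reported.

**The quasi-Newton fit is the default.** `fit_embeddings_lbfgs()` uses
analytic gradients ($\partial C/\partial x_i = \frac1n \sum_m
(\hat s_i^m - s_i^m) W^m$, symmetrically for $w_j$) with L-BFGS-B
(history 10, projected-gradient tolerance $10^{-5}$, at most 500
iterations, initialization from a seeded Gaussian scaled by $10^{-3}$).
The objective is evaluated through the log-softmax (logits minus
log-sum-exp), never through $\log$ of the softmax probabilities, so an
underflowing modeled probability cannot make the objective infinite. The
optimizer runs in short segments, recording the objective after each, so
fits carry an honest non-increasing trace.

`fit_embeddings_svd()` is the fast deterministic alternative. The softmax
assigns $\log \hat s_{ij} = x_i^\top w_j - c_i$ with the per-row constant
absorbed by the normalizer, so the least-squares surrogate fits the
**row-centered** $\log(S^m + \varepsilon)$ matrices, stacked side by side,
by truncated SVD ($X = U_d \Sigma_d^{1/2}$, $W^m = V_d^{(m)}
\Sigma_d^{1/2}$; signs fixed by the largest-magnitude entry of each
component; $\varepsilon = 1/n$ smooths the zero diffusion entries before
the log). Without the centering the factorization is dominated by a
rank-1 $\log \varepsilon$ background common to all nodes, which carries
no relational information yet inflates every cosine; centering removes it
and makes the surrogate markedly more stable across $d$. At full rank
$X W^{m\top} + c^m$ reconstructs $\log(S^m + \varepsilon)$ exactly
(centering costs one rank).

Why is the slower fit the default? On partially overlapping sources the
two objectives differ materially. The Frobenius objective weights every
row of the log-diffusion matrix by its squared magnitude, and the
near-indicator rows of diseases a source does not cover are among the
largest — so the weakest view's non-information distorts the shared
features. The KL objective treats each row as a probability distribution
and is far less distorted. On the synthetic test bed (below) the KL fit
integrates three 40–70%-coverage sources to a median benchmark AUC of
about 0.97 while each single source reaches only 0.64–0.86, reproducing
the qualitative integration benefit the method is built around; the SVD
surrogate shows a much smaller gap. Both fitters expose the same
interface and the suite cross-checks them on structure-recovery fixtures.

The **embedding dimension defaults to $d = 600$** for corpus-scale
vocabularies (thousands of diseases), where performance is stable over a
wide range of $d$; the desk-scale test bed uses $d = 32$ for its 200
diseases, roughly the same fraction of $n$.

## Scoring

The similarity of two diseases is the cosine of their feature vectors,
$\cos(d_x, d_y) = \sum_i d_{x,i} d_{y,i} / (\lVert d_x\rVert_2
\lVert d_y\rVert_2)$, clamped to $[-1,1]$; a zero vector scores 0 with a
warning. Embeddings can have negative entries, so raw cosine may be
negative; `rescale = TRUE` maps it to $[0,1]$ via $(c+1)/2$ and the
output headers record which convention was used. The top-quantile network
export keeps the top fraction (default 0.3%) of all unordered non-self
pair scores — ties at the cutoff are all kept — and reports node/edge
counts, the maximum-degree node and connected-component sizes.

## Evaluation protocol

Benchmark positives versus random negatives are scored and summarized by
AUC (Mann–Whitney rank form, ties counted ½) plus confusion-matrix
metrics. The classification threshold is nowhere pinned down by the
ranking protocol, so the default picks the threshold maximizing Youden's
$J$ (smallest such value on ties) and reports it; any fixed threshold can
be supplied. MCC is defined as 0 when a marginal is empty. Class
imbalance (40 positives vs 500 negatives by default) is kept as given.
The same-versus-different-category contrast uses a permutation test on
the disease-to-category assignment with the $(b+1)/(n_\mathrm{perm}+1)$
correction — the least-assumption way to attach a p-value to "same-category
pairs score higher". Ablations (each source alone versus all together) and
dimension sweeps reuse one set of diffusion states; both restrict the
benchmark to pairs inside the node universe being embedded, since pairs
outside it cannot be scored.

## The synthetic test bed

`generate_study()` emulates the three inputs end to end: a rooted DAG
whose top-level subtrees define disease categories (with occasional
double parents, as in real poly-hierarchies); association corpora whose
entities have a home category and link to it with probability
`within_cluster_bias`; and benchmark lists of within-category positives
and between-category negatives. Defaults: 200 diseases in 10 categories,
DAG depth 3, 3 sources with 500 entities and 10,000 records each, bias
0.8, per-source coverage 0.40/0.70/0.50 — the coverage ratios mirror how
unevenly real gene-, process- and symptom-derived corpora cover the
diseases they jointly mention, and the unequal coverage is what gives
integration something to contribute. Benchmark sizes default to 40
positives and 500 negatives. These sizes make a full
generate→similarity→embed→score→evaluate pass take seconds at $d = 32$.

What passing tests on this bed shows: the pipeline recovers planted
cluster structure, integration of partially-redundant views beats each
view alone, the AUC is stable in $d$, and every numerical component
matches an independent oracle. What it does not show: behavior on real
MeSH-scale hierarchies (tens of thousands of terms, 16 top-level
branches), realistic annotation biases (literature popularity, hub
diseases), or the published corpus-scale metric values, which depend on
specific proprietary-versioned downloads.

## Known limitations

- All-pairs Lin scoring is $O(n^2)$ over ancestor sets and the diffusion
  matrices are dense $n \times n$; desk-scale (hundreds to a few thousand
  diseases) is comfortable, far beyond that the memory cost grows
  quadratically.
- The L-BFGS fit restarts its curvature memory between trace segments; at
  very large $n$ the SVD surrogate is the pragmatic choice, with the
  caveat about partially overlapping sources above.
- Name-based mapping of association records is exact and case-insensitive
  only; no fuzzy matching.
- The permutation test shuffles category labels at the disease level,
  which assumes exchangeability of diseases across categories under the
  null.
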