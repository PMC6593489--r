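---
title: "Edge-semantics-aware node embeddings: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-semantics-aware node embeddings: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biomedical knowledge graphs — genes, compounds, drugs, diseases, tissues,
joined by relations such as *bind*, *expression* or *has-pathway* — are
heterogeneous: nodes and edges carry types, and type frequencies are
highly skewed. Homogeneous embedding methods (random walks plus
skip-gram, in the DeepWalk/node2vec family) treat every edge identically,
so the information carried by rare but highly informative relations (an
approved drug bound to a validated target) is diluted by frequent,
less specific ones. This package learns node embeddings that respect edge
semantics: walks are biased not only by graph distance but also by a
learned *edge-type transition matrix*.

## Model

Let $G(V, E)$ be an (by default undirected) graph with $m$ edge types.
The model has two coupled parts.

**Edge-type transition matrix.** $M \in \mathbb{R}^{m \times m}$ holds
transition weights between edge types. Given a walk that reached node $v$
from node $u$ along an edge of type $T(u,v)$, the probability of
continuing along the incident edge $(v, n)$ of type $T(v,n)$ is

$$
p(n \mid v, u, M) \;=\;
\frac{w_{vn}\, M_{T(u,v),T(v,n)}\, \alpha_{pq}(n,u)}
     {\sum_{k \in N(v)} w_{vk}\, M_{T(u,v),T(v,k)}\, \alpha_{pq}(k,u)},
\qquad
\alpha_{pq}(k,u) =
\begin{cases}
1/p & d_{ku} = 0\\
1   & d_{ku} = 1\\
1/q & d_{ku} = 2,
\end{cases}
$$

where $w_{vn}$ is the edge weight, $p$ is the return parameter, $q$ the
in-out parameter, and $d_{ku}$ the distance between candidate $k$ and the
previous node $u$. Candidates are incident *edges*, so parallel edges of
different types between the same node pair are scored separately. With
$m = 1$ the matrix factor cancels and the walk is exactly the
second-order $p/q$-biased homogeneous walk; this limit is verified by
exact enumeration in the test suite.

**Estimation of $M$ (EM loop).** $M$ is initialized to all ones (all
transitions equally plausible). Each iteration (i) samples a fraction of
nodes and generates biased walks under the current $M$, and (ii)
re-estimates every entry as the sigmoid-transformed Pearson correlation
of per-walk edge-type counts:

$$
M(e_i, e_j) \;=\; \mathrm{Sigmoid}\!\big(\mathrm{cor}(v_i, v_j)\big),
\qquad \mathrm{Sigmoid}(x) = \frac{1}{1+e^{-x}},
$$

where $v_j$ counts how often type $e_j$ occurs in each walk. Types that
travel together in the same walks get high mutual weights. Since the
self-correlation of any non-constant count vector is $+1$, the diagonal
dominates its row — trained walks prefer to continue on the edge type
they arrived by — and all updated entries lie in
$[\mathrm{Sigmoid}(-1), \mathrm{Sigmoid}(1)] \approx [0.269, 0.731]$.
The update *replaces* the previous matrix; an optional `damping`
argument blends with the previous matrix but defaults to off, since full
replacement is the plain reading of the update rule.

**Embedding (skip-gram with negative sampling).** After the EM loop a
full corpus (walks from every node) is generated under the trained $M$
and node vectors $f_v$ are fitted by maximizing, per (center, context)
pair $(v, t)$ with $k$ negative draws $u_i$,

$$
O(f) = \log \mathrm{Sigmoid}(f_t^\top f_v)
     + \sum_{i=1}^{k} \log \mathrm{Sigmoid}(-f_{u_i}^\top f_v),
$$

by single-threaded SGD with a linearly decaying learning rate. The
analytic gradient of this objective is checked against central-difference
numerical differentiation in the tests.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `p`, `q` | 0.25, 0.25 | return and in-out walk bias |
| `dimensions` | 128 | embedding dimension |
| `walks_per_node` (r) | 1 | walks started per node |
| `walk_length` (w) | 50 | nodes per walk |
| `sample_ratio` | 0.01 | node fraction per EM iteration |
| `em_iterations` (N) | 10 | EM rounds |
| `window` | 10 | skip-gram context window |
| `negative` (k) | 5 | negative samples per pair |
| `epochs`, `lr` | 5, 0.025 | SGD passes and initial rate |

The `sample_ratio` default of 0.01 is sized for graphs with hundreds of
thousands of nodes, where one percent still yields thousands of walks
per iteration. On desk-scale graphs (hundreds of nodes) one percent
would give a handful of walks — far too few observations for a Pearson
correlation — so the package's own studies and tests use
`sample_ratio = 0.5` there. The number of *walks*, not the number of
nodes, is the relevant sample size for the matrix update.

Negative sampling is **uniform** over nodes by default, which is the
plain reading of the sampling distribution in the objective;
the word2vec convention (unigram frequency to the 3/4 power) is
available via `neg_dist = "unigram75"`. Negatives equal to the true
context are rejected and redrawn. Whether negatives should depend on the
positive context is ambiguous in the usual notation; we sample them
independently, the standard practice.

## Numerical and design choices

* **First walk step.** With no previous edge, the transition formula is
  undefined; the first step is sampled proportional to edge weight
  alone, degenerating correctly to the homogeneous convention.
* **Degenerate count vectors.** A constant count vector has undefined
  correlation; it is defined as 0, giving the neutral weight
  $\mathrm{Sigmoid}(0) = 0.5$. A type absent from the sampled corpus
  keeps its previous row and column, preserving information from earlier
  iterations. No `NaN` ever reaches the matrix.
* **Distances.** $d_{ku}$ is computed exactly as 0 (return), 1 (adjacent
  to $u$) or 2 (otherwise) using a sorted-neighbor binary search —
  $O(\log \deg u)$ per candidate, no BFS.
* **Determinism.** All randomness flows from one master seed; walker and
  trainer use a fully specified 64-bit Mersenne Twister stream with
  portable uniform generation, so identical seeds give bitwise-identical
  corpora and embeddings (single-threaded).
* **Two-matrix skip-gram.** Input and output vector matrices are kept
  separately (standard skip-gram); the input matrix is exposed. Input
  vectors are initialized uniformly in $[-0.5/d, 0.5/d]$, output vectors
  at zero.
* **Undirected by default.** Walks must be able to return
  ($d_{ku} = 0$ requires traversability in both directions); a
  `directed` flag exists on the readers for directed use.
* **Ties.** Cosine rankings break ties by node-id order, making every
  ranking metric reproducible.
* **Dead ends.** A walk reaching a node with no incident edges truncates
  early; isolated start nodes give length-1 walks that contribute no
  context pairs.

## Evaluation harnesses

Three protocols mirror how such embeddings are validated in drug
discovery:

1. **Node multi-class classification** — balanced downsampling per
   class, linear SVM, 10-fold cross-validation, macro
   precision/recall/F1 and Hamming loss. A balanced 10-class random
   classifier scores precision 0.1; the balanced binary random baseline
   has accuracy 0.5 (both verified by simulation at $n = 10^5$ in the
   acceptance checks).
2. **Pairwise link (bioactivity) prediction** — pairs featurized as the
   element-wise difference of the two embeddings (an `absdiff` variant
   is provided, since the sign of the difference depends on pair order
   for undirected pair sets), logistic regression, threshold 0.5,
   metrics plus AUROC.
3. **Search ranking** — cosine-similarity top-$k$ retrieval per query,
   scored with P@K, R@K, MAP, NDCG (binary gains, $\log_2$ discount) and
   MRR. The classifiers here are harness fixtures, not contributions;
   standard implementations (`e1071::svm`, `stats::glm`, `pROC`) stand
   behind them.

## Synthetic generators and what they do (and do not) show

`generate_typed_sbm()` produces a stochastic block model whose edge
*types* carry the community signal: within-class edges carry a
class-signature type, between-class edges a shared background type.
Defaults are 5 classes of 100 nodes, within/between edge probabilities
0.10/0.02 (mean within-degree about 10, typical of community-structured
biological networks; much sparser blocks leave held-out-edge prediction
without neighborhood-overlap signal for *any* embedding, making the
benchmark uninformative), and a 0.9 type-signal mass. A
`types_per_class = 2` setting co-plants two signature types per class,
whose per-walk counts rise and fall together — exactly the positive
co-occurrence the matrix update should recover; the generator returns
the planted co-occurrence table for those tests. A `skew` exponent
reproduces the skewed type frequencies of real knowledge graphs.

`generate_bioactivity()` emulates a compound–gene layer: latent factors
score all cross pairs; the strongest become *bind* edges, the next
strongest are held out as labeled positives (never placed in the graph,
as bioactivity benchmarks are disjoint from the training network), the
weakest become labeled negatives. Same-layer similarity edges and
uniformly random *spurious* cross edges give walks several edge types of
differing informativeness.

`holdout_within_edges()` turns any node-labeled graph into a
link-prediction benchmark by removing a fraction of within-class edges
(positives) and pairing them with cross-class non-edges (negatives).

The study reported by `scripts/acceptance.R` runs, at 500 nodes:
classification macro-F1 and held-out-edge AUROC for the full model
versus an ablation with `em_iterations = 0` (all-ones matrix, i.e.
homogeneous-walk embeddings), the same-type step fraction of both walk
regimes, the transition-matrix analytics, the bipartite recovery AUROC,
and the simulated random baselines. Passing these synthetic studies
shows the estimation machinery recovers planted structure at desk scale;
it does not by itself establish effect sizes on real knowledge graphs,
whose degree and type distributions are far more skewed than the
generators emulate.

## Known limitations

* The transition matrix is order-one in edge types (pairwise
  transitions); longer type motifs are not modeled.
* Pearson-plus-sigmoid is the only correlation/activation pair
  implemented; alternatives (Spearman, cosine, ReLU) are deliberately
  out of scope.
* The per-walk count statistic ignores the *order* of types within a
  walk, so very long walks blur type-transition structure — walk length
  is a real tuning concern, not a free parameter.
* Hub nodes are not downweighted; scale-free degree distributions can
  dominate corpora.
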