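# edge2vec

Node-embedding learning for **heterogeneous networks** — graphs whose
edges carry type labels, such as biomedical knowledge graphs linking
genes, compounds, drugs and tissues through relations like *bind*,
*expression* or *has-pathway*. Homogeneous embedding methods (random
walks + skip-gram) treat every edge the same, diluting rare but highly
informative relations. This package learns an **edge-type transition
matrix** alongside the embeddings and uses it to bias the walks, so the
learned vectors reflect edge semantics as well as topology. It is aimed
at computational biologists and network scientists doing link
prediction, entity classification and similarity search on typed graphs.

## Method in brief

For a graph $G(V,E)$ with $m$ edge types, an $m \times m$ matrix $M$ of
edge-type transition weights is estimated by an EM loop over biased
second-order random walks. A walk at node $v$, having arrived from $u$
by an edge of type $T(u,v)$, continues along incident edge $(v,n)$ with
probability

$$p(n\mid v,u,M) \propto w_{vn}\; M_{T(u,v),\,T(v,n)}\; \alpha_{pq}(n,u),$$

where $\alpha_{pq}$ is the node2vec-style distance factor ($1/p$, $1$,
$1/q$ for distances 0, 1, 2 between $n$ and $u$). Each EM iteration
regenerates walks from a node sample under the current $M$ and updates

$$M(e_i,e_j) = \mathrm{Sigmoid}\big(\mathrm{cor}(v_i,v_j)\big),$$

the sigmoid-transformed Pearson correlation of per-walk edge-type
counts. Walks under the trained matrix feed a skip-gram
negative-sampling SGD trainer (objective
$\log\sigma(f_t^\top f_v) + \sum_i \log\sigma(-f_{u_i}^\top f_v)$).
Setting `em_iterations = 0` keeps $M$ at its all-ones initialization and
yields exactly homogeneous node2vec-style walks — the built-in ablation.

## Worked example

```r
library(edge2vec)

# a 500-node heterogeneous graph whose edge types carry community signal
sim <- generate_typed_sbm(seed = 1)
sim$graph
#> Heterogeneous graph: 500 nodes, 3293 edges, 6 edge types (undirected)

fit <- edge2vec(sim$graph, dimensions = 32, epochs = 3,
                sample_ratio = 0.5, seed = 1)
summary(fit)
#> edge2vec fit on 500 nodes / 3293 edges, 6 edge types
#> Trained edge-type transition matrix:
#>        t1     t5     t3     t6     t4     t2
#> t1 0.7311 0.5884 0.4541 0.3022 0.6704 0.4442
#> ...
#>   mean diagonal 0.7311, mean off-diagonal 0.4671
#>   same-type consecutive-step fraction in corpus: 0.6224
```

The diagonal sits at Sigmoid(+1) = 0.7311 — a type's count vector is
perfectly correlated with itself, so trained walks prefer to continue on
the type they arrived by (62% same-type steps here versus ~48% under
uniform walks). Evaluating the embeddings against the planted classes,
with the all-ones-matrix ablation for comparison:

```r
abl <- edge2vec(sim$graph, dimensions = 32, epochs = 3,
                em_iterations = 0, seed = 1)
node_classification_task(coef(fit), sim$labels, seed = 1)$f1  # 0.475
node_classification_task(coef(abl), sim$labels, seed = 1)$f1  # 0.326
```

Macro-F1 0.475 versus 0.326: with identical topology and training
budget, using the edge types during walk generation recovers
substantially more of the planted community structure (a balanced
5-class random classifier would score 0.2).

`predict()` gives cosine similarities or top-k rankings, `simulate()`
draws fresh walk corpora from the fitted matrix, and `plot()` images the
transition matrix. A command-line interface with `convert`, `train`,
`evaluate` and `simulate` subcommands is installed at
`system.file("cli", "edge2vec.R", package = "edge2vec")`.

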