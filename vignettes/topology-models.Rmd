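---
title: "Autoregressive tree-topology models: methods and design notes"
author: "PhyloAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoregressive tree-topology models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(PhyloAR)
```

# The generative model

PhyloAR models a distribution over unrooted bifurcating leaf-labeled tree
topologies autoregressively. Fix a taxa order (lexicographic on species
names by default, `taxaOrder()`). The unique star on the first three taxa
is grown one leaf at a time: at rank $n$ the model computes a categorical
distribution $\alpha_n$ over the $2n-3$ edges of the current subtree,
draws one, and attaches leaf $n+1$ by subdividing it. The decision
sequence $(e_3,\dots,e_{N-1})$ is in bijection with topology space, so

$$Q_\phi(\tau) \;=\; \prod_{n=3}^{N-1} Q_\phi(e_n \mid e_{<n})$$

is exactly normalized and supported on all $(2N-5)!!$ topologies. The
test suite confirms both properties by exhaustive enumeration at
$N \in \{4,5,6\}$: probabilities sum to one at machine precision for
random and for trained parameters.

## Node keys and the canonical edge order

Leaves carry their taxa positions $1..N$; the interior node created at
rank $k$ carries key $N + (k-2)$. This creation-order indexing makes the
interior adjacency $A_n$ and leaf-interior cross adjacency $C_n$ grow
append-only — attaching a leaf clears one adjacency entry and appends one
row/column, an $O(1)$ update. Edges are ordered lexicographically by
their sorted endpoint keys. Nothing in the method pins down a particular
edge indexing; what matters is that sampling and evaluation share one
deterministic order, and ours is a documented choice. `decomposeTopology`
inverts the construction by always peeling the highest-indexed leaf and
matching the fused edge through its leaf bipartition, which makes the
inverse unique and representation-independent (tested by round-tripping
every decision path at $N \le 5$ and Newick rewrites of the same tree).

## Topological node embeddings by fixed-point iteration

The embedding of leaf $i$ at rank $n$ is the one-hot $\delta_i \in
\mathbb{R}^n$; interior embeddings minimize the Dirichlet energy
$\sum_{(u,v)\in E_n} \lVert f(u)-f(v)\rVert^2$. Since every interior node
has degree 3, the minimizer solves the harmonic system
$F = A_nF/3 + C_n/3$, which the package computes by the fixed-point map
$F \leftarrow A_nF/3 + C_n/3$ from the all-$1/n$ start. Two facts give
the method its uniform budget:

* **Spectral bound.** For any bifurcating topology, a similarity
  transform by $D = \mathrm{diag}(\sqrt{2}^{d_u})$ (with $d_u$ the
  interior-graph depth) turns every row of $A_n$ into one with row sum at
  most $2\sqrt2$; Perron–Frobenius then bounds the spectral radius by
  $2\sqrt2$, independent of shape and size. Verified exhaustively for
  every topology up to $N = 8$ (10,395 trees) and on 1,000 random trees
  up to $N = 100$.
* **Contraction.** The error after one step is $(A_n/3)$ times the
  previous error, so the iteration contracts at rate $c = 2\sqrt2/3
  \approx 0.943$ in Frobenius norm (which upper-bounds the spectral norm
  the theory needs and is cheap to evaluate). Observed per-step ratios
  never exceed $c$ on any tested tree.

**Stopping rule.** The natural criterion
$\lVert F^{(m)}-F^*\rVert_2 / n < \varepsilon$ references the unknown
fixed point. We precompute the smallest $m$ with $c^m E_0(n) \le
\varepsilon n$, where $E_0(n) = \sqrt{2(n-2)}$ bounds the initial error a
priori (interior rows of both the start and the fixed point are
probability vectors, so each row error is at most $\sqrt2$). This
`iterationBound()` is a constant in the topology — only $(\varepsilon,n)$
enter — which keeps the batched code branch-free. An adaptive
successive-difference rule would also imply the criterion through the
contraction inequality; we kept the precomputed bound as the single
production path and verify sufficiency against the direct linear solve
(`exactEmbedding`, kept as a test oracle only). The norm convention
(Frobenius) is our reading of the matrix criterion; with it, tolerance
$\varepsilon n$ is guaranteed and the observed errors sit orders of
magnitude below it.

**Power trick.** $m$ plain iterations equal one application of the $m$-th
power of the augmented matrix
$\bar A_n = \begin{pmatrix} I & 0 \\ C_n/3 & A_n/3\end{pmatrix}$, so
$\lceil \log_2 m\rceil$ squarings suffice; `fixpointEmbedding(mode =
"power")` (the default) does exactly that and agrees with plain
iteration to $10^{-10}$ at matched counts. The squaring overshoots $m$ to
the next power of two, which only tightens the tolerance.

## Attention-based pooling and edge scores

Padded embeddings (zero columns appended *after* solving at native width
$n$) pass through a 2-layer MLP $L:\mathbb{R}^N\to\mathbb{R}^d$ to give
node features. A *single learnable query vector* $q$ attends over all
node features (scaled dot-product, $h$ heads, layer norm immediately
before the block, one residual connection around it); a graph readout MLP
maps the pooled vector to the graph representation $r_n$. Because the
query is a single row, pooling costs $O(nd + d^2)$ rather than the
quadratic cost of full self-attention. Per edge $e=(u,v)$, the feature is
the elementwise maximum of the endpoint features (symmetric in the stored
endpoint order); the edge readout MLP scores
$\mathrm{concat}(p_n(e), r_n) + b_n$, with $b_n$ the standard sinusoidal
embedding of the step index in dimension $2d$ (forced by the addition),
and a softmax over the canonical edge order gives $\alpha_n$.

Design points that were genuinely open, and what we chose:

* one query shared across steps, with step identity carried only by
  $b_n$ — per-step queries would not transfer across tree sizes;
* attention produces only the graph vector; node features are not
  rewritten (the pooling equation defines no per-node output), and the
  same post-$L$ features feed both the attention keys/values and the edge
  maxima;
* the residual wraps the attention block only, not the graph readout;
* no recurrence across construction steps: the growing topology itself
  plus $b_n$ is the only step memory;
* MLPs are 2-layer with ELU activations and layer norm after each linear
  layer; hidden widths default to $d$ and are exposed in `edgeModel()`;
  the scalar edge-readout head skips the output layer norm (normalizing
  a single feature is degenerate);
* fan-in-scaled Gaussian initialization with a seed argument.

All layers and their reverse-mode gradients are hand-written R matrix
code, batched tree-major (every tree at rank $n$ contributes $2n-2$
rows of one stacked matrix). Gradient correctness is tested against
central finite differences parameter-by-parameter.

# Training objectives

**Parsimony.** The target $P(\tau)\propto\exp(-\beta_t S(\tau;Y))$ uses
the Fitch score $S$ computed per site by the set recursion on a copy
rooted at leaf 1 (every internal node then has two children; the score is
root-invariant, and ambiguity codes/gaps are full-uncertainty sets). The
$K$-sample bound is maximized with the VIMCO estimator: per-sample
signals are bound differences against the leave-one-out
arithmetic-mean-of-log-weights baseline, combined with the pathwise
importance-weight term. Unbiasedness is verified on an enumerable toy to
three standard errors over $10^5$ draws. The annealing schedule
$\beta_t=\min\{1, 0.001 + t/H\}$ starts near-uniform and sharpens to the
parsimony target.

**TDE.** Maximum likelihood on a weighted tree collection; minibatches
are drawn by weight with replacement. Decision sequences and fixed-point
embeddings of the (typically few) unique training trees are precomputed
once, so an update touches only the network.

**VBPI.** The variational family is $Q_\phi(\tau)\,Q_\psi(q\mid\tau)$
with a diagonal lognormal branch model whose per-edge location and
log-scale come from a small MLP over edge features of the completed tree
(elementwise maxima of endpoint embedding rows). Topology gradients use
VIMCO; branch gradients use the reparametrization trick with the *exact*
analytic derivative of the pruning log-likelihood in every branch length
(an outside pass over the tree; tested against numerical
differentiation). The annealed target is
$p(Y\mid\tau,q)^{\beta_t}p(\tau,q)$ with uniform topology prior, i.i.d.
Exp(10) branch prior and the Jukes–Cantor substitution model; the
likelihood is Felsenstein pruning with per-site rescaling. The
marginal-likelihood estimator is log-mean-exp of importance weights at
$\beta=1$.

# Synthetic data and what passing tests show

The generators replace MCMC posterior samples with *exactly tabulated*
targets so that KL divergences are computable in closed form:

* `randomTopology` draws uniform topologies through the
  decision–topology bijection (chi-square-tested against uniform);
* `toyTarget` tabulates $p(\tau)\propto\exp(-\lambda\,\mathrm{RF}(\tau,
  \text{anchor}))$ by enumeration ($N\le7$);
* `simulateJCAlignment` runs the substitution model forward from the
  uniform stationary distribution, with Exp(10) branch lengths by
  default, matching the prior.

These emulate the *shape* of posterior tree distributions (a mode with
RF-decaying mass) and of real alignments (JC-evolved sites), not their
hard parts: no among-site rate variation, no model misspecification, no
MCMC autocorrelation, and desk-scale taxon counts. Passing the recovery
tests therefore demonstrates that the estimators, gradients and samplers
are correct and that the model family can concentrate on enumerable
targets — not that benchmark-scale accuracy is achieved.

# Scaled run configurations

The package's end-to-end checks use deliberately small, fixed
configurations, chosen once as realistic desk-scale analogues of the
full-scale settings (feature dimension 100, 4 heads, learning rate
$10^{-4}$, $2\times10^5$–$4\times10^5$ updates) that the defaults of
`edgeModel()` and `runTask()` mirror:

* **TDE recovery:** $N=6$, target $\lambda=1$, $10^4$ training samples,
  $d=16$, $h=2$, 3000 Adam steps at learning rate $10^{-3}$, batch 10.
  Exact KL over all 105 topologies ends near 0.02 nats, against a
  sampling floor of about 0.006 for the empirical distribution itself.
* **Parsimony recovery:** $N=7$, a simulated 200-site JC alignment with a
  unique exhaustive-search optimum over all 945 topologies, $K=10$,
  $H=1500$, 4000 steps at $10^{-3}$. The trained model's modal topology
  equals the optimum.
* **VBPI sanity:** $N=4$, 30 sites; the exhaustive evidence is a
  5-dimensional Gauss–Legendre quadrature over branch lengths (stable to
  well under 0.02 nats when the grid is refined from 12 to 16 nodes per
  dimension, with the Exp(10) integral truncated at $q=1.2$ where the
  remaining tail mass is $\sim 6\times10^{-6}$). After 500 joint updates
  the multi-sample bound sits slightly below the evidence and the
  1000-particle importance-sampling estimate lands within a few
  hundredths of a nat.

The larger learning rate in these runs reflects their small models and
short horizons; for paper-scale runs the conservative default $10^{-4}$
is kept. Training at these sizes takes a few minutes on one CPU.

# Numerical choices and degenerate inputs

* Layer-norm variance floor $10^{-5}$; log-scale of the branch model
  capped at 3 (with the gradient zeroed when the cap binds).
* Softmaxes subtract the column maximum; all bound computations use
  log-sum-exp.
* Edge-feature maxima break ties toward the first stored endpoint in the
  backward pass (the forward value is tie-independent).
* $N=3$ degenerates gracefully everywhere: the topology is unique, the
  decision sequence is empty and $\log Q \equiv 0$.
* Pruning rescales per site at every internal node, so long alignments
  and tiny branch lengths do not underflow; zero branch lengths are
  valid ($P(0)=I$).

# Known limitations

* Rooted or multifurcating trees are out of scope; inputs are coerced to
  (or rejected as) unrooted bifurcating topologies.
* The branch-length family is a lightweight lognormal-with-MLP head; it
  is sufficient for the four-taxon sanity analyses here, and no claim is
  made that it matches purpose-built branch models on benchmark data.
* Only the Jukes–Cantor substitution model is implemented; GTR/Gamma,
  mixtures over trees, and normalizing-flow branch models are non-goals.
* The taxa order is fixed, not learned; the decomposition depends on it,
  and the model must be retrained for a different order.
* Everything runs on CPU in plain R; the batching is the same as a GPU
  implementation would use, but wall-clock performance at hundreds of
  taxa is not a goal of this package.
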