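# PhyloAR

Autoregressive generative models over phylogenetic tree topologies, with
fixed-point topological node embeddings, attention-based graph pooling,
and three variational training tasks — in pure R.

## The problem

Bayesian phylogenetics needs probability distributions over the space of
unrooted bifurcating leaf-labeled tree topologies, a combinatorial space
of size (2N−5)!! for N taxa. Classical tree-probability estimators
(conditional clade distributions, subsplit Bayesian networks) only place
mass on splits seen in a pre-sampled tree set. An autoregressive model
avoids that restriction: under a fixed taxa order, any topology τ
decomposes uniquely into a sequence of leaf-attachment decisions
e₃, …, e_{N−1} — start from the unique 3-leaf star τ₃ and repeatedly
attach the next leaf to one edge of the current subtree — giving

    Q_φ(τ) = ∏ₙ Q_φ(eₙ | e_{<n}),

a properly normalized distribution with full support over topology space.

Each conditional is a categorical distribution over the 2n−3 edges of the
rank-n subtree, parameterized by a neural network over *topological node
embeddings*: the minimizer of the Dirichlet energy
ℓ(f, τₙ) = Σ_{(u,v)∈Eₙ} ‖f(u) − f(v)‖² with leaf embeddings pinned at
one-hot vectors. Because every internal node of a bifurcating tree has
degree 3, the minimizer solves F = AF/3 + C/3 (A the interior adjacency,
C the leaf–interior cross adjacency), and the package computes it by the
fixed-point iteration F ← AF/3 + C/3. The interior adjacency of *any*
bifurcating topology has spectral radius at most 2√2, so the iteration
contracts at rate 2√2/3 ≈ 0.943 regardless of tree shape or size, the
required iteration count M_ε depends only on (ε, n), and M_ε plain steps
can be collapsed into ⌈log₂ M_ε⌉ squarings of the augmented iteration
matrix (the "power trick"). Node features are pooled into a graph vector
with single-query multi-head attention (cost linear in the node count),
and per-edge scores combine the elementwise maximum of endpoint features,
the graph vector, and a sinusoidal embedding of the step index.

Three training objectives are provided:

* **Variational maximum parsimony** — maximize the annealed multi-sample
  bound on targets P(τ) ∝ exp(−β_t S(τ; Y)), with S the Fitch parsimony
  score and VIMCO leave-one-out gradients;
* **Tree-topology density estimation (TDE)** — maximum likelihood on a
  weighted collection of trees;
* **Variational Bayesian phylogenetic inference (VBPI)** — joint
  approximation Q_φ(τ) Q_ψ(q|τ) of the posterior over topology and branch
  lengths under the Jukes–Cantor model, uniform topology prior and
  Exp(10) branch prior, with a lognormal branch family, annealed
  multi-sample bound, and importance-sampling marginal-likelihood
  estimates.

Everything — forward passes, backpropagation, Adam — is plain R matrix
code, batched across trees; no deep-learning framework is required.

## Worked example

Fit the model to samples from an exactly tabulated target over all 105
six-taxon topologies and measure the exact KL divergence:

```r
library(PhyloAR)

taxa   <- sprintf("t%d", 1:6)
anchor <- randomTopology(taxa, seed = 2)
target <- toyTarget(anchor, lambda = 1)     # p(tau) ~ exp(-RF(tau, anchor))
trees  <- sampleTreeSet(target, 10000, seed = 3)

model <- edgeModel(taxa, d = 16L, h = 2L, seed = 4)
klToTarget(model, target)
#> [1] 2.190899                                # untrained
fit <- trainTDE(model, trees, steps = 3000, batch = 10L, lr = 1e-3, seed = 5)
klToTarget(fit$model, target)
#> [1] 0.01868144                              # after training

lp <- logProb(fit$model, enumerateTopologies(taxa))
sum(exp(lp))
#> [1] 1                                       # exactly normalized
```

The KL falls from 2.19 nats (a fresh model) to 0.019 nats, close to the
0.006-nat sampling floor of a 10,000-tree empirical estimate, and the
model's probabilities over the full enumerated tree space sum to one —
the normalization is structural, not approximate.

The same model machinery runs from the shell via `exec/phyloar` with a
YAML config (tasks `simulate`, `train-tde`, `train-parsimony`,
`train-vbpi`, `sample`, `logprob`, `eval-kl`, `eval-mll`), e.g.

```sh
./exec/phyloar config.yaml --seed 1 --out runs/tde
```

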