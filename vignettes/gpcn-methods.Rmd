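---
title: "Multiscale graph networks for coarse-grained lattice energetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale graph networks for coarse-grained lattice energetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gpcn)
```

This vignette is the package's own account of the models it implements, the
numerical choices behind them, and what its synthetic-data experiments do and
do not demonstrate. Nothing here reports a number that the test suite or
`scripts/acceptance.R` does not itself recompute.

## The problem

A 13-protofilament microtubule segment is modelled as a coarse-grained
harmonic lattice: one point mass per tubulin monomer, harmonic bond
("association") and harmonic angle interactions, no steric or dihedral
terms. Under a bending load — the first two rings clamped, the last two
pulled along $-y$ — each monomer ends up with a share of the lattice's
potential energy. The learning task is to predict this per-monomer energy
from a per-node feature vector (position, velocity, and the interaction
strengths of the run), i.e. a node-regression problem on a fixed graph of
624 nodes.

The package's contribution is the **graph prolongation convolutional
network (GPCN)**: an ensemble of graph convolutional networks (GCNs)
operating at several graph resolutions, coupled by optimized
**prolongation operators**, together with the **linear graph diffusion
distance (LGDD)** used to compute those operators and to select the coarse
graphs.

## Graphs and structure matrices

An offset tube `GTube(n, k, p)` has `n` rings of `k` monomers; lateral
bonds close each turn through a seam shifted axially by `p` monomers. The
microtubule graph is `GTube(48, 13, 3)` (624 nodes). The structure matrix
used everywhere is the raw graph Laplacian in the $L = A -
\mathrm{diag}(A\mathbf 1)$ sign convention (non-positive spectrum, zero row
sums); no symmetric normalization and no self-loop augmentation. All
spectral code uses this sign consistently, and the diffusion distance is
invariant to flipping the sign of both operands.

## The linear graph diffusion distance and prolongations

For Laplacians $L_1$ (coarse, $m \times m$) and $L_2$ (fine, $n \times n$,
$m \le n$), the LGDD at scale $\alpha > 0$ is

$$ D(G_1, G_2) \;=\; \inf_{P^\top P = I}\;
   \Big\lVert \tfrac1\alpha P L_1 - \alpha L_2 P \Big\rVert_F , $$

with $P$ an $n \times m$ column-orthogonal matrix; the minimizer is the
prolongation operator. The pipeline fixes $\alpha = 1$ throughout
(`lgdd_alpha_search()` offers a golden-section outer search for
graph-limit-style experiments, with the caveat that the objective is only
piecewise smooth in $\alpha$).

`optimize_prolongation()` computes $P$ in two stages:

1. **Spectral assignment.** With $L_i = U_i \Lambda_i U_i^\top$
   (eigenvalues ascending), restricting $P = U_2 \tilde P U_1^\top$ with
   $\tilde P$ a subpermutation matrix turns the problem into a rectangular
   linear assignment between eigenvalue lists with cost
   $c_\alpha(\lambda_j, \lambda_l) = (\lambda_j/\alpha - \alpha\lambda_l)^2$.
   A shortest-augmenting-path solver (`src/lap.cpp`, validated against
   brute-force enumeration on small instances) yields the optimal
   assignment.
2. **Stiefel refinement.** Riemannian conjugate gradient on the manifold
   $\{P : P^\top P = I\}$ (QR retraction with sign fix, tangent-projection
   transport, Polak–Ribière$^+$ directions, Armijo backtracking; gradient
   tolerance $10^{-6}$, at most 1000 iterations). Only improvements are
   accepted, so the refined objective never exceeds the initialization.

A fact worth recording: at **fixed** $\alpha$ the assignment bound is
*tight*. Writing $Q = U_2^\top P U_1$, the squared objective is $\sum_{l,j}
Q_{lj}^2\, c_\alpha(\lambda_j, \lambda_l)$ — linear in the matrix of squared
entries $[Q_{lj}^2]$, which ranges over a doubly-substochastic polytope
whose extreme points are exactly the subpermutation matrices. The RLAP
solution is therefore a global optimum of the orthogonally-constrained
problem, and the refinement typically terminates at its starting point
(it is retained as a numerical safeguard, and becomes meaningful only for
objectives where the linearity argument fails). A practical corollary is
that the distance at fixed $\alpha$ depends only on the two eigenvalue
multisets, so it is invariant under graph isomorphism — no seam-direction
or chirality convention can change it.

## Hierarchy construction and the coarsening search

The default hierarchy is `GTube(48,13,3)` → `GTube(24,13,1)` (each
$\alpha$–$\beta$ monomer pair condensed to one dimer node; 312 nodes) →
`GTube(24,3,0)` (72 nodes). `coarsening_search()` re-derives the coarsest
level by scoring every `GTube(24, k, p)` for $k \in \{3,\dots,12\}$, $p \in
\{0,\dots,3\}$, with seam weights 1 and 2 (the doubled variant reflects
pairs of seam edges condensed into one), reporting both the assignment
bound and the refined value.

On our construction the search is unambiguous about the turn size — $k = 3$
candidates occupy the four best slots by a wide margin — but the ordering
*within* $k = 3$ is tight (all four offsets fall within ~0.012 of each
other, about 15% of the distance) and the package's argmin is
`GTube(24,3,3)` rather than the conventional `GTube(24,3,0)`. Because the
fixed-$\alpha$ distance is a function of eigenvalue multisets alone (see
above), this ordering is a mathematical property of the offset-tube family
as defined here, not a tolerance issue; we keep `GTube(24,3,0)` as the
hard-coded default coarse level (it is the established choice for this
lattice and the difference among $k=3$ candidates is marginal) and report
the full ranked table so users can judge. Composed maps are literal
products $P_{1,i} = P_{1,2}\cdots P_{i-1,i}$, which stay column-orthogonal
up to accumulated tolerance.

## Model family

Every member network is a stack of ReLU GCN layers
$X_m = g(Z X_{m-1} W_m + b_m)$ whose outputs are concatenated node-wise and
passed through a node-wise dense head (sigmoid hidden layers, linear scalar
output). The ensemble kinds, all built by `gcn_model()` and fit via
`gpcn_fit()` presets:

* **GPCN** — fine member plus coarse members fed $P_{1,i}^\top X$ and
  prolonged back, summed at the fine scale; $P$ fixed.
* **A-GPCN** — identical, but the pairwise $P$ matrices are trainable
  parameters after orthogonal initialization (orthogonality is *not*
  re-enforced during training).
* **Plain ensembles** (1–3 members on the fine Laplacian), **N-GCN**
  (one member per structure-matrix power $Z^r$, radii (1,2,4) or
  (1,2,4,8,16)), and **DiffPool** (each projection replaced by the
  row-softmaxed output of an auxiliary GCN, coarse structure matrices
  $S^\top Z S$) serve as baselines.

Member widths follow the reference configuration at `scale = "paper"`
(GCN filters 64/32/16, head 256-32-8-1, coarsest member widest) and a
shrunken `"desk"` variant (16/12/8, head 32-8-1) for laptop-sized runs.
Initialization is Glorot-uniform under the run-level seed; the protocol
fixes seeds but not the initializer, so this is a package choice.

## Training

Adam with default hyperparameters ($10^{-3}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-7}$), batch size 8, MSE loss at the fine
scale on data normalized per (node, feature) by training-split statistics
only (standard deviations floored at $10^{-8}$). The train/validation split
is 90/10 over frames, drawn with the run seed so the split and batch order
are identical across models. Training and every other stochastic component
are driven by R's RNG under that single seed; re-running a configuration
reproduces histories bit-for-bit. Gradients come from a small reverse-mode
tape (`R/autodiff.R`) written for this package; the closed-form input
gradients (below) are derived independently and cross-checked against it.

**Schedules.** `schedule_spec()` supports joint training, multigrid
$\gamma$-cycles — `cycle(l) = [l] + γ·cycle(l+1) + [l]` started at the
finest level, $\gamma = 1$ giving a V-cycle, $\gamma = 0$ degenerating to
fine-only — and coarse-to-fine phases gated by 10-epoch validation
patience. A level event updates only that level's member (plus the $P$s
when adaptive) while the full-ensemble prediction defines the loss. Because
frozen members' fine-scale contributions are constant during an event, the
trainer computes them once per frame and caches them — the trained level
fits the residual, with mathematically identical loss — and invalidates a
cache whenever its member (or, for adaptive models, any projection)
changes.

**FLOP ledger.** Costs are simple operation-count products: a GCN layer is
$nF(|Z| + C)$, a node-wise dense layer $nFC$, a general matmul $nmk$, with
no hidden multiply-add factors. Backpropagation through a trained component
is priced at twice its forward cost (one transposed aggregation plus one
weight-gradient product per layer). The ledger prices the computations the
trainer actually performs, so cached contributions are charged once; this
is what makes $\gamma$-cycle events cheaper than joint epochs. Histories
record the running-minimum validation NMSE against cumulative FLOPs, which
is the package's standard comparison plot (`plot.gpcn_fit`).

NMSE is the mean squared error in normalized target space, averaged over
nodes and frames — unitless; an uninformative all-zero predictor scores
about 1.

## The simulator (synthetic-data generator)

`run_simulation()` integrates Langevin dynamics by velocity Verlet with
friction $-\gamma m v$ and seeded Gaussian kicks, at small temperature so
mechanics dominates. The load ramps linearly over the ramp phase and holds;
frames are saved on a fixed interval (12 per run at both the full-scale
step counts and the desk preset). Each frame stores $X \in
\mathbb{R}^{n \times 10}$ — position, velocity, and four interaction
coefficients constant across nodes — and the per-node potential energy
target, with per-node forces kept in frame metadata. Energies use the
harmonic styles $L(r - r_0)^2$ and $L(\varphi - \varphi_0)^2$ with angles in
radians (resting angles converted from degrees), and each interaction's
energy is split equally among its 2 or 3 participants, so per-node energies
sum exactly to the total.

Units are reduced (lengths nm, unit monomer mass, timestep 0.005, energy
arbitrary): quoted physical mass and timestep values for this kind of
coarse-grained protocol are not mutually consistent at these stiffness
scales, so no physical-unit fidelity is claimed and all parameters are
configurable. Two resting-value modes exist:
`resting = "table"` (the tabulated constants — 5.15639/5.0 nm, 153.023°,
180°, 77.0694°, 102.931° — authoritative, default) and
`resting = "geometry"` (per-interaction values measured from the built
helix, making the unloaded structure an exact equilibrium). The desk
generator uses `"geometry"` so that all recorded energy comes from the
applied load rather than from a mismatch between the analytic helix and the
tabulated constants, whose generating geometry is not stated.

The feature vector carries exactly four coefficients (LatAssoc, LongAssoc,
LatAngle, LongAngle); the desk grid ties QuadAngles to LatAngle so the
features remain a faithful function of the run. The full protocol grid — 7
values for each of 5 strength classes, $7^5 = 16807$ runs — is enumerated,
not simulated (it is cluster-scale); the desk preset sweeps $\{3, 57\}$ per
class over a 12-ring tube (16 runs × 12 frames = 192 frames, about a minute
on a laptop).

**What the generator does and does not emulate.** It reproduces the
protocol's load geometry, energy model, per-node attribution, frame layout
and parameter sweep at reduced size. It does not reproduce the authors'
LAMMPS trajectories, physical time/mass scales, thermal ensembles at
realistic temperature, or dynamic instability chemistry. Tests passing on
this generator therefore establish the *relative* behaviour of the model
family on data of this structure — not absolute errors on the original
dataset, which would require the full $7^5$ grid at full tube length.

## Energy gradients and relaxation

For a member whose first pre-activation is $A_1 = Z X W_1 + b_1$ and total
predicted energy $E = \sum_i Y_i$,

$$ \frac{\partial E}{\partial X} = Z^\top \frac{\partial E}{\partial A_1} W_1^\top, $$

with the upstream factor obtained by reverse traversal of the remaining
layers. For a prolonged member the output-layer seed is $P_{1,i}^\top
\mathbf 1$ — its energy is summed at the fine scale — and its gradient maps
back as $P_{1,i}\, \partial E^{(i)}/\partial X^{(i)}$; the ensemble gradient
is exactly the sum of member contributions. These closed forms are
validated against both the training tape and central finite differences
($10^{-5}$ relative). `relax_configuration()` descends the predicted total
energy over the position columns only — velocities and coefficients are
physically not relaxable — recording predicted energy per iterate and
flagging divergence.

## Problem sizes and numerical choices

Chosen once for the package's own experiments and used by tests and the
acceptance script alike: desk hierarchy 156/78/18 nodes; 30 epochs of 20
batches of 8; three seeds for cross-model comparisons; coarsening-search
refinement capped at 50 iterations (sufficient because the initialization
is already optimal at fixed $\alpha$); eigendecompositions are dense, which
is ample at these scales (≤ 624 nodes). Degenerate inputs are handled
explicitly: zero-length bonds and zero-length angle arms are errors; the
colinear-angle force uses a $\sin\varphi$ floor of $10^{-8}$ (torque
vanishes with $\varphi - \varphi_0$, so the floor does not bias resting
states); RLAP ties resolve by the solver's deterministic scan order;
constant features are floored, with a warning, at $10^{-8}$ standard
deviation.

## Known limitations

* The coarse-graph search's $p$-ordering within $k = 3$ differs from the
  conventional choice (see the hierarchy section); the default hierarchy
  pins the conventional coarse graph.
* Orthogonality of adaptive $P$ matrices is not maintained during training
  (by design); long adaptive runs can drift far from the Stiefel manifold.
* DiffPool is implemented as a trainable baseline without auxiliary losses
  (none are part of this comparison).
* The trainer is plain R on BLAS; it is sized for the desk preset, not for
  the full 624-node, $7^5$-run protocol.
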