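# gpcn: graph prolongation convolutional networks for coarse-grained lattice energetics

`gpcn` implements multiscale ensembles of graph convolutional networks
(GPCN, and the adaptive A-GPCN) for predicting per-monomer potential energy
in a coarse-grained mechanical model of a 13-protofilament microtubule under
bending load. It is aimed at researchers in structural bioinformatics and
scientific machine learning who want multigrid-style GCN surrogates for
lattice mechanics, and at anyone needing the spectral machinery behind them.

The package contains the full pipeline:

* **Graphs** — offset-tube graphs `GTube(n, k, p)` (the microtubule is
  `GTube(48, 13, 3)`, 624 nodes), grids, Laplacians in the `A - D` sign
  convention, and the 3D lattice geometry with typed harmonic bond/angle
  interactions.
* **Linear graph diffusion distance (LGDD)** — for Laplacians `L1 <= L2`,

  `D(G1, G2) = inf over column-orthogonal P of || (1/a) P L1 - a L2 P ||_F`

  computed by a rectangular-linear-assignment bound over eigenvalue pairs
  (cost `((1/a)λ_j - aλ_l)^2`) followed by Riemannian conjugate-gradient
  refinement on the Stiefel manifold. The minimizing `P` is the
  prolongation operator coupling two graph scales.
* **Hierarchy** — the 624/312/72-node microtubule hierarchy, plus a
  coarsening search over the candidate tube family.
* **Models** — GPCN/A-GPCN (a sum of member networks at each scale,
  prolonged to the fine scale), plain GCN ensembles, N-GCN (structure-matrix
  powers), and DiffPool baselines, trained with Adam under joint, multigrid
  γ-cycle, or coarse-to-fine schedules, with a FLOP ledger.
* **Simulator** — a Langevin/velocity-Verlet harmonic spring-lattice
  simulator that generates the training data (per-node features and
  per-node potential-energy targets) entirely in code.
* **Energy gradients** — closed-form gradients of predicted total energy
  with respect to the input (`dE/dX = Z' (dE/dA1) W1'`, summed over members
  through their prolongations), and gradient-based configuration relaxation.

## Worked example

Generate the desk-scale dataset (a 12-ring tube, 16 parameter combinations
x 12 saved frames each), fit a 3-level adaptive GPCN, and inspect it:

```r
library(gpcn)

ds  <- generate_dataset_desk(seed = 1)      # 192 frames x 156 nodes x 10 features
fit <- gpcn_fit(ds, "3-level A-GPCN", config = train_config(epochs = 30, seed = 1))
fit
#> 3-level A-GPCN fit (joint schedule): 30 epochs
#>   final val NMSE 0.1307 | min val NMSE 0.1307 | 6.63e+10 ledger FLOPs
summary(fit)
#> 3-level A-GPCN (agpcn), levels 156/78/18, 19339 parameters
#>   30 epochs, min val NMSE 0.1307, final val NMSE 0.1307
#>   final train MSE 0.1209, cumulative ledger FLOPs 6.627e+10
```

The validation NMSE (mean squared error after standardizing both signals by
training-set statistics; an uninformative predictor scores about 1) reaches
0.13 in 30 epochs; the same protocol gives about 0.49 for the non-adaptive
GPCN and 0.64 for a single fine-scale GCN, reproducing the qualitative
ordering that motivates the adaptive model. Predictions come back in energy
units per node:

```r
pred <- predict(fit)                        # 19 validation frames x 156 nodes
cor(as.numeric(pred), as.numeric(ds$y[fit$val_idx, ]))
#> [1] 0.9501638
plot(fit)                                   # min validation NMSE vs ledger FLOPs
```

The spectral machinery is exposed directly:

```r
h <- microtubule_hierarchy("desk")
#> graph hierarchy: 156 -> 78 -> 18 nodes
#>   P[1,2]: objective 0.3454
#>   P[2,3]: objective 0.15911

gmt    <- build_tube_graph(tube_spec(48, 13, 3))   # 624 nodes
search <- coarsening_search(gmt, length = 24)      # rank GTube(24, k, p) candidates
attr(search, "best")                               # nearest coarse tube (k = 3)
```

A thin command-line front end (`inst/cli/gpcn-cli.R`) wraps the same
functions: `gen-data`, `search-coarse`, `build-hierarchy`, `train`,
`evaluate`, `grad-check`, `relax`.

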