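# NNPkit

Modular neural network potentials (NNPs) in R, with physics-based priors.

An NNP is a learned function mapping atomic numbers *Z* and Cartesian
coordinates ***R*** (Å) to a per-sample scalar *y* — the potential energy —
and, by exact differentiation, its negative position gradient
*neg_dy = −∂y/∂**R*** — the atomic forces. Because the forces are the exact
gradient of the energy, the resulting force field is energy-conserving by
construction. NNPkit is for people who want to prototype, train and dissect
such potentials at desk scale with full numerical transparency: every
quantity is double precision, every gradient is auditable against finite
differences, and every padded/batched computation is contractually
bit-identical to its unpadded equivalent.

## What is in the box

* **Three representation models**, all message-passing networks over a
  cutoff-radius neighbor graph:
  * `tensornet` — per-channel Cartesian rank-2 tensors (3×3 matrices)
    decomposed into isotropic + antisymmetric + symmetric-traceless parts
    (X = I + A + S); interactions use node-level symmetrized matrix
    products instead of Clebsch–Gordan tensor products, and scalar
    readouts are Frobenius norms of the parts, which makes the energy an
    exact O(3) invariant (rotations *and* reflections).
  * `equivariant_transformer` — scalar + Cartesian-vector features with
    distance-gated dot-product attention. The `vectorCutoff` flag applies
    the cosine cutoff envelope φ(d) to the value pathway
    (split(V⊙D<sup>V</sup>) → split(φ(d)·V⊙D<sup>V</sup>)), removing a
    discontinuity in the energy surface at the cutoff radius; off
    reproduces the legacy behaviour.
  * `graph_network` — invariant continuous-filter convolutions over
    radial features (SchNet-style).
* **Physical priors**, added to the energy *before* differentiation so the
  forces include them: per-element reference energies (`atomrefPrior`,
  optionally learnable), switched Coulomb electrostatics (`coulombPrior`),
  DFT-D2 dispersion (`d2Prior`, element tables bundled as data) and
  Ziegler–Biersack–Littmark screened nuclear repulsion (`zblPrior`).
  Custom priors extend the virtual `Prior` class and compose identically.
* **A neighbor-search engine** with brute-force O(N²) and cell-list
  strategies (auto-selected at 10 000 atoms), open/rectangular/triclinic
  periodic boundary conditions via minimum-image displacements, joint
  batching with cross-batch exclusion, and a static-shape mode: pair lists
  padded with the sentinel −1 up to a fixed capacity, padded slots attached
  to a ghost atom whose contributions are exactly zeroed.
* **A reverse-mode autodiff core** whose backward rules are built from its
  own primitives, so forces are differentiable again — force-matching
  training (second derivatives) works out of the box.
* **Training and data tooling**: NumPy (`.npy`/`.npz`) "custom" layout and
  HDF5 conformer loaders and writers, seed-deterministic splits, weighted
  energy/force MSE loss, L1/MSE validation metrics, EMA-smoothed logging,
  Adam with plateau learning-rate decay, bit-exact checkpoint resume, and
  a YAML-configured command line surface (`cliTrain`/`cliPredict`, with
  Rscript wrappers in `inst/cli/`).
* **Synthetic fixtures**: seeded particle clouds with controlled neighbor
  density, analytic-potential dimer datasets, and composition datasets for
  reference-energy recovery — all test inputs are generated, nothing is
  downloaded.

## Worked example

```r
library(NNPkit)

config <- representationConfig("tensornet", embeddingDimension = 16,
                               numLayers = 2, radial = radialConfig(4.5, 16),
                               maxZ = 20)
model <- assembleModel(config, priors = list(zblPrior(), d2Prior()), seed = 1)
model
#> AssembledModel: tensornet (2 layer(s), 16 channels, cutoff 4.5 A)
#>   priors: ZBLPrior, D2Prior
#>   derivative: TRUE, parameters: 8625

sys <- particleSystem(rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
                      atomicNumbers = c(8L, 1L, 1L))
pred <- predict(model, sys)
pred
#> Prediction: 1 sample(s), forces for 3 atom(s)
#>   y: 10.1079
colSums(predictionForces(pred))
#> [1] 1.776357e-15 2.220446e-15 0.000000e+00
```

The scalar `y` is the (untrained) model energy for the water-like
structure, in whatever energy unit the priors' constants are expressed in
(eV here, via the default Coulomb constant 14.3996 eV·Å/e²). The force
rows sum to ~1e-15: translation invariance forces the net force to zero up
to floating-point roundoff.

Training on a toy dimer dataset whose energies and forces come from an
analytic Morse potential, with a combined energy + force loss (the force
term exercises second-order differentiation):

```r
ds <- makeDimerDataset(200, noiseSd = 0, seed = 3)
splits <- makeSplits(200, 160, 20, 20, seed = 1)
dimerModel <- assembleModel(representationConfig("tensornet",
                            embeddingDimension = 16, numLayers = 2,
                            radial = radialConfig(4.5, 8), maxZ = 10), seed = 11)
res <- trainLoop(dimerModel, ds, splits,
                 trainConfig(epochs = 10, batchSize = 100, learningRate = 0.01,
                             lambdaEnergy = 1, lambdaForce = 0.5, seed = 2))
round(res$history[c(1, 5, 10), c("epoch", "trainLoss", "valLoss", "l1Energy", "l1Force")], 4)
#>    epoch trainLoss valLoss l1Energy l1Force
#> 1      1    0.8261  0.7318   0.3000  0.3743
#> 5      5    0.7659  0.6615   0.3042  0.3569
#> 10    10    0.0988  0.0387   0.1396  0.1226
```

Ten epochs cut the validation loss about twenty-fold; the L1 columns are
the validation mean absolute errors of energies (energy units) and force
components (energy/Å).

The same run can be driven without code from a YAML configuration
(`cliTrain("config.yaml")`, or `Rscript inst/cli/nnpkit-train.R --conf
config.yaml`); key names mirror the usual NNP hyperparameter vocabulary
(`embedding_dimension`, `num_layers`, `num_rbf`, `cutoff`,
`max_num_neighbors`, `vector_cutoff`, ...).

## Further reading

The methods vignette (`vignettes/nnpkit-methods.Rmd`) describes the models
and their symmetry arguments, the priors' functional forms and parameter
tables, the numerical contracts (padding, determinism, differentiation),
the synthetic-data generators and what passing tests do and do not imply
about real chemical datasets, and the design decisions taken where the
architecture left room.
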