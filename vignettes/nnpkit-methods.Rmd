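---
title: "NNPkit: models, priors and numerical contracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NNPkit: models, priors and numerical contracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A neural network potential in NNPkit is a composition of four exchangeable
parts, assembled by `assembleModel()`:

1. a **neighbor graph**: all atom pairs within a cutoff radius $r_c$,
   under open, rectangular or triclinic periodic boundary conditions;
2. a **representation model** mapping atomic numbers and edge geometry to
   per-atom feature vectors;
3. an **output head** (a two-layer perceptron $C \to C/2 \to 1$) reducing
   features to per-atom scalars, aggregated per sample (sum by default,
   mean for intensive targets);
4. an ordered list of **physical priors** added at atom level (before
   reduction) or molecule level (after).

The per-sample scalar $y$ is interpreted as the potential energy; with the
`derivative` flag the model also returns $\mathrm{neg\_dy} = -\partial
y/\partial \mathbf{R}$. The gradient is taken through the *entire*
composition — network and priors alike — so the force field is
energy-conserving by construction, and prior terms contribute to forces
exactly.

Everything differentiable runs on a small reverse-mode automatic
differentiation engine (`adGrad()` and the `ad*` primitives) whose
backward rules are themselves built from the same primitives. Gradients
are therefore ordinary graph nodes and can be differentiated again; this
is what a force-matching loss needs, since the force is already a
gradient and its parameter gradient is a mixed second derivative.

### Distance featurization

Every edge is featurized by exponential-Gaussian radial bases
$\exp(-\beta_k(e^{-d}-\mu_k)^2)$ with $\mu_k$ spaced evenly from $1$
(peak at $d = 0$) down to $e^{-r_c}$ and a shared width $\beta$, each
multiplied by the cosine cutoff envelope
$\phi(d)=\tfrac12(\cos(\pi d/r_c)+1)$. The envelope has zero value *and*
zero slope at $r_c$, so every feature is once-differentiable there and
identically zero beyond. The basis family is a standard choice in this
model lineage; the bases can be made trainable (`trainableRbf`), off by
default.

### TensorNet-style representation

Each atom carries $C$ channels of Cartesian rank-2 tensors (3×3
matrices), decomposed as $X = I + A + S$ into isotropic, antisymmetric
and symmetric-traceless parts. Embedding builds per-edge tensors from the
unit edge vector $\hat u$ — identity, skew$(\hat u)$, and
$\hat u\hat u^{\top} - \mathrm{Id}/3$ — gated per channel by radial
features; aggregated tensors are rescaled per channel by a function of
the species embedding and the part norms. Interaction layers exchange
part-gated neighbor tensors and update nodes with *symmetrized* matrix
products $XY + YX$.

The symmetrization is what buys full O(3) invariance. Under a proper
rotation every tensor conjugates, $X \to RXR^{\top}$. Under an improper
operation the vector-derived $A$ part flips sign, which is equivalent to
$X \to (RXR^{\top})^{\top}$. Transposition reverses products,
$(XY)^{\top} = Y^{\top}X^{\top}$, so an unsymmetrized product would leave
this family; the symmetrized product maps transposes to transposes. Part
norms are invariant under both conjugation and transposition, so the
scalar readout — a learned function of the species embedding and the
Frobenius norms of $I$, $A$, $S$ — is exactly invariant under rotations,
reflections and translations. The package's symmetry tests exercise
improper operations explicitly.

A normalization by (Frobenius norm + 1) precedes each interaction to keep
repeated matrix products bounded. `numLayers = 0` is a valid model:
embedding and local featurization without message exchange.

### Equivariant transformer

Atoms carry invariant scalar features and equivariant Cartesian vector
features. Per edge, a distance-gated dot-product attention weight
$a_{ij} = \mathrm{SiLU}(\textstyle\sum_c q_i k_j D^K)\,\phi(d_{ij})$
scales a scalar value pathway, while the vector features receive
$s_2 \odot \vec v_j + s_3 \odot \hat u_{ij}$ with $(s_1,s_2,s_3) =
\mathrm{split}(V_j \odot D^V_{ij})$. Scalars are updated from the
aggregated messages and from invariant dot products of linearly mixed
vector features; vectors only ever combine linearly or scale by
invariants, so they transform as vectors.

With `vectorCutoff = TRUE` the value-pathway product additionally carries
$\phi(d_{ij})$: $\mathrm{split}(V_j\odot D^V_{ij}) \to
\mathrm{split}(\phi(d_{ij})\,V_j\odot D^V_{ij})$. Without it, the radial
features entering $D^V$ vanish at $r_c$ but the layer's bias does not, so
an edge crossing the cutoff causes a finite jump in the energy — the
legacy behaviour, kept reachable for backward compatibility and
demonstrated in the tests. In this implementation the scalar update uses
the *post-update* vector features, so the vector pathway (and hence the
discontinuity contrast) is visible in the energy at any depth; this is a
composition choice made here, documented rather than inherited.

With the fix on, the energy jump across $r_c$ decays *quadratically* in
the crossing distance $\varepsilon$ (the cosine envelope has zero slope
at $r_c$), which is stronger than the linear decay one would minimally
demand of a continuous-energy claim; tests assert the $O(\varepsilon)$
bound and convergence to zero.

### Graph network

Continuous-filter convolutions: per edge, a radial filter (SiLU of a
linear map of the basis features, times the envelope) multiplies linearly
transformed neighbor features; aggregated messages pass through a
residual MLP update. Only distances enter, so invariance is structural.

## Physical priors

All priors derive from the virtual S4 class `Prior` with two generics,
`priorLevel()` (atom vs molecule) and `priorEnergyNode()` (the term as a
differentiable node). Pairwise sums use the half-list convention (each
unordered pair once), asserted by two-atom oracles in the tests.

* **Atomref** — adds $\mu_{Z_i}$ per atom; optionally a learnable
  parameter initialized from the provided table. Subtracting reference
  energies leaves the network a formation-energy-like residual.
* **Coulomb** — $\mathrm{sw}(r)\,k\,q_iq_j/r$ with the cosine switch
  $\mathrm{sw}(r)=\tfrac12(1-\cos(\pi r/r_{sw}))$ below the switching
  distance and 1 beyond. $\mathrm{sw}(0)=0$ removes the short-range
  singularity; the switch meets 1 with zero slope. The switch acts on the
  inner range only; at the outer (neighbor) cutoff the term is truncated
  (below). The functional form realizes a "cosine switching function";
  the exact formula is this package's documented choice.
* **ZBL** — screened nuclear repulsion
  $\phi(r)\,k Z_iZ_j/r\,f(r/a_{ij})$ with the universal screening
  function $f(x)=\sum_{m=1}^4 c_m e^{-e_m x}$ and screening length
  $a_{ij} = a_0/(Z_i^{0.23}+Z_j^{0.23})$, $a_0 = 0.46850$ Å. The
  published coefficients sum to 1, so $f(0)=1$ — a closed-form anchor the
  tests check. The cosine envelope takes every contribution smoothly to
  zero at $r_c$.
* **D2 dispersion** — $-s_6\,C_6^{ij}/r^6\,f_{dmp}(r)$ with
  $C_6^{ij}=\sqrt{C_6^iC_6^j}$, Fermi damping
  $f_{dmp}(r) = (1+e^{-d(r/R_{ij}-1)})^{-1}$ around the summed van der
  Waals radii, steepness $d = 20$. Element tables ($C_6$ in
  J·nm⁶·mol⁻¹, radii in Å, H–Xe) ship as a versioned TSV in
  `inst/extdata/`, treated as data, not code; `c6Conversion`
  (default 10.36436) rescales to eV·Å⁶.

**Units.** Learned terms are unit-agnostic; priors require explicit
constants in the dataset's energy unit (defaults are eV-flavoured:
Coulomb constant 14.3996 eV·Å/e²). Mixing units is the caller's
responsibility and the config surface makes the constants explicit.

**Truncation.** D2 and Coulomb terms stop at the neighbor cutoff without
long-range corrections — the neighbor engine is strictly local. The
resulting energy discontinuity at $r_c$ is the magnitude of the dropped
term: for D2 at the default 6 Å evaluation cutoff that is
$(3/6)^6 \approx 1.6\%$ of the term at a 3 Å contact distance, bounded
explicitly in the tests. Ewald/PME-style electrostatics are out of scope.

## The neighbor engine and the static-shape contract

Two strategies produce identical pair sets: a brute-force $O(N^2)$ scan
(best below ten thousand atoms) and a hash-and-sort cell list (near-linear
above; the threshold boundary itself is assigned, arbitrarily but fixed,
to the cell list). One cell decomposition is built jointly over all
batches; cross-batch candidates are rejected at distance-check time.
Equality of the two pair sets over randomized clouds of every box kind is
a standing test and part of the acceptance script.

Periodic boundaries use minimum-image displacements. Triclinic boxes must
be in reduced lower-triangular form with skew at most half the box edge;
the sequential reduction against lattice rows $c, b, a$ is then exact for
any displacement shorter than half the smallest diagonal entry — and box
construction enforces $r_c \le \tfrac12\min(a_x, b_y, c_z)$, so the
neighbor search never leaves the guaranteed regime. Outside it (irrelevant
to the engine) the sequential reduction may return a longer image than an
exhaustive scan; the tests compare against a 27-image oracle inside the
regime only.

Neighbor lists are fixed-capacity and padded with the sentinel −1.
Every model forward appends one ghost atom; padded slots point at it with
a fixed, safely nonzero placeholder displacement and a zero mask. Because
each padded contribution is multiplied by an exact zero and scattered to
the ghost row only, and because edge reductions use a fixed summation
order (edges sorted by source then target, padding last), predictions are
**bit-identical** for every admissible capacity. Too small a capacity
raises a typed `neighborOverflowError` carrying the required size — never
a silent truncation. The default capacity policy is
`nAtoms * maxNumNeighbors` with `maxNumNeighbors = 32`.

Degenerate inputs: empty systems predict an empty result; a zero-length
edge would make the unit vector undefined, and the exported analytic
backward (`edgeGeometryBackward`) documents the defined-zero direction
convention for that case. Self-pairs are excluded.

## Training

The loss is $\lambda_E\,\mathrm{MSE}(y) + \lambda_F\,\mathrm{MSE}
(\mathrm{neg\_dy})$, each MSE averaged over all elements of its tensor
(per-element force averaging is this package's documented resolution of
an underdetermined convention). Validation logs L1 and MSE for energies
and forces separately; test reporting conventionally uses the L1 pair.
An exponential moving average `new = alpha*value + (1-alpha)*old`
(default $\alpha = 0.3$) smooths *logged* losses only — weights are never
averaged.

The optimizer is Adam (lr $5\times10^{-3}$ default) with plateau decay
(factor 0.8, patience 10); no optimizer is architecture-mandated, so this
is a pragmatic package choice, fully exposed in the config. Training is
deterministic under a fixed seed: single-threaded dense arithmetic,
seeded shuffles, and the RNG state carried inside checkpoints so that a
resumed run reproduces the uninterrupted run exactly — a property the
tests assert to the last bit. Heterogeneous molecules batch through the
batch index vector; samples are never ghost-padded (training-time static
shapes are deliberately not implemented).

Checkpoints carry config, weights, prior objects, optimizer state, epoch
and history; `loadModel()` can override the derivative flag at load time.
`trainableParams` (a regex over parameter names) freezes everything else
— e.g. `"^prior1\\."` fits a learnable atomref alone on a frozen zero
model, which is how the reference-energy recovery experiment is run.

## Synthetic data: what it does and does not show

All test inputs come from three seeded, pure generators:

* `makeCloud()` — uniform random particle clouds in a box sized from the
  density relation $\rho = \bar n/(\tfrac43\pi r_c^3)$ for a target mean
  neighbor count, with rectangular/triclinic/open variants and a 20%
  realized-density check for periodic kinds (open boxes lose neighbors to
  edge effects and skip the check). Used for neighbor-engine and symmetry
  properties.
* `makeDimerDataset()` — two-atom conformers from an analytic Morse
  potential ($D_e = 1$, $a = 1.7$ Å⁻¹, $r_0 = 1.5$ Å, separations
  1.0–3.5 Å), exact analytic forces, optional energy noise. Ground truth
  in closed form makes convergence and force-matching claims checkable.
* `makeAtomrefDataset()` — random compositions over {H, C, N, O, S} with
  $y = \sum_i \mu_{Z_i} + \varepsilon$ and zero forces; a learnable
  atomref must recover $\mu$ to the noise floor (the acceptance run uses
  500 samples, noise sd 0.01, recovery within 0.05 energy units; observed
  errors are ~10⁻³).

These fixtures probe *contracts* — symmetries, gradients, padding,
convergence on smooth low-dimensional targets. They do not emulate real
quantum-chemistry data: no conformational correlation, no many-body
electronic structure, no element diversity beyond small organic sets, no
label noise structure. Passing them demonstrates that the machinery is
correct and trainable, not that any particular architecture/hyperparameter
combination reaches literature accuracy on real datasets; that requires
external data and compute far beyond these tests, and is out of scope.

Problem sizes in the test-suite and acceptance runs (clouds up to 1000
atoms, clusters of 5–8 atoms, embedding widths 8–16, 25–200 epochs) are
the package's chosen desk-scale defaults; the same code paths run
unchanged at larger sizes.

## Numerical choices and limitations

* **Precision**: all computation is R double precision (float64). A
  32-bit mode is not provided — R has no native single-precision array
  type — and the config rejects `precision: 32` explicitly.
* **Determinism**: identical inputs and seeds give bit-identical outputs;
  summation orders are fixed everywhere results are accumulated.
* **Full neighbor lists** (both edge directions) are the model-facing
  default, matching message passing in both directions; priors consume
  the same list through a half-list mask so each unordered pair counts
  once.
* **Initialization**: uniform fan-in scaling from a seeded RNG; no
  normalization layers beyond the tensor-norm rescaling described above.
* **Performance**: the autodiff engine favours auditability over speed;
  R-level graph construction is the bottleneck. Desk-scale training (10²
  conformers, 10⁴ parameters) takes seconds to minutes per run; this
  package is not an MD production engine, and GPU execution, kernel
  strategies, JIT/compilation and mixed precision are explicitly out of
  scope.
* **HDF5 IO** loads files eagerly into R records (memory-mapped lazy
  reads are not provided); the NumPy custom layout reads one file group
  per molecule, conformers of a molecule sharing one embedding file.
* **No long-range electrostatics/dispersion corrections**; the D3/D4
  dispersion families and learnable charges are not implemented.
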