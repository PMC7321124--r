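---
title: "Predicting docking-protocol performance from pocket voxels and ligand fingerprints"
author: "DockSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting docking-protocol performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Docking protocols — pairings of a conformational search algorithm with a
scoring function — differ widely in how well they reproduce the
crystallographic pose of a ligand, and no single protocol dominates across
protein–ligand pairs. Self-docking benchmarks quantify this per complex with
three statistics computed from the generated poses: the minimum pose RMSD
(`rmsd_min`, Å), the mean pose RMSD (`rmsd_ave`, Å), and the number of poses
whose RMSD falls strictly below the crystal's X-ray resolution (`n_rmsd`, a
count in `[0, n_poses]`, 20 poses by default). DockSelect learns to predict
these three statistics, for each protocol in a 14-protocol registry
(AutoDock, Glide, GOLD, PLANTS, rDock, Vina variants), from the structure of
the binding pocket and the chemistry of the ligand — and then recommends,
per complex, the protocol with the lowest predicted RMSD (or the highest
predicted `n_rmsd`).

## Featurization

**Pocket.** The binding site is the set of protein heavy atoms within a
15 Å sphere around the ligand's heavy-atom center of mass (a mass-weighted
center; hydrogens are excluded so the definition is robust to missing
protonation). The pocket is rendered on a cubic grid of 24 Å edge at 1 Å
resolution, centered on the same point. Each atom contributes to a voxel at
distance $r$ an occupancy

$$ n(r) = 1 - \exp\!\left[ -\left( \frac{r_{\mathrm{vdw}}}{r} \right)^{12} \right], $$

where $r_{\mathrm{vdw}}$ is the atom's van der Waals radius from a bundled
Bondi-style element table. The kernel equals $1 - e^{-1}$ at $r =
r_{\mathrm{vdw}}$, tends to 1 at the nucleus (the value at $r = 0$ is
defined as that limit) and decays as $r^{-12}$. Atoms are typed into eight
pharmacophore channels — hydrophobic, aromatic, hydrogen-bond acceptor,
hydrogen-bond donor, positive ionizable, negative ionizable, metallic, and
total excluded volume — by a bundled, editable rule table keyed on residue
and PDB atom name (an approximation of AutoDock-style typing; the excluded
volume flag is carried by every heavy atom, and atoms matching no rule keep
only that flag). Per voxel and channel, contributions aggregate by the
**maximum** over atoms carrying the flag: this keeps every voxel in
$[0, 1]$ and makes adding an atom monotone. Voxel $(i, j, k)$ (0-based) has
its center at $\mathrm{origin} + (i + \tfrac12, j + \tfrac12, k +
\tfrac12) \cdot \mathrm{resolution}$; no distance cutoff is applied beyond
a guaranteed-negligible $10^{-13}$ occupancy floor, so grids match a naive
double loop to better than $10^{-12}$.

**Ligand.** The ligand contributes a 1024-bit hashed circular fingerprint
(bond radius 2, computed on the heavy-atom graph from iterated neighborhood
invariants; deterministic, but not bit-compatible with any external
toolkit — only within-dataset similarity structure matters here) and a
fixed panel of 183 physicochemical descriptors: element counts, global
size/charge/hydrogen-bonding descriptors, degree and ring-size counts,
element-pair bond counts, Moreau–Broto/Moran/Geary topological
autocorrelations of atomic mass, electronegativity, van der Waals radius,
polarizability and degree, and classical connectivity indices. Descriptors
are z-scored with statistics fitted on the training fold only (population
standard deviation; constant descriptors map to zero). Standardization is a
package choice: the descriptor scales span orders of magnitude and
destabilize training if left raw. Fingerprint and standardized descriptors
concatenate to the 1207-long ligand input.

## Architecture and losses

The network has two legs. The pocket leg applies five $3^3$ convolutions
with ReLU activations; the package default uses channels (8, 8, 16, 16, 32)
with strides (2, 2, 1, 2, 1) and unit padding, taking the grid from
$24^3$ to $3^3$, then flattens and projects to a 512-wide protein latent.
The ligand leg applies three ReLU linear layers (768, 640, 512). The two
latents concatenate into a single 1024 vector, pass through batch
normalization, and feed three per-protocol linear output heads with ReLU —
one head each for `rmsd_min`, `rmsd_ave` and `n_rmsd`, each emitting 14
values. The conv widths are the package's own sizing, chosen so that the
full training schedule runs comfortably on a single CPU core; only the
depth (five layers), the 1024 latent width and the three-head structure
are fixed contracts, and every width and stride is configurable
(`modelConfig()`). Output-head biases initialize at 1 so the ReLU heads
start in their active region for the non-negative targets.

The RMSD heads train with mean-squared error; the count head with the
Poisson negative log-likelihood

$$ \ell(y, \hat y) = \hat y - y \log(\hat y + \varepsilon) + \log(y!), $$

with $\varepsilon = 10^{-8}$ guarding the ReLU's exact zeros and
$\log(y!)$ via the log-gamma function. The training objective is the
unweighted sum of the three losses, each averaged over the non-masked
(complex, protocol) entries; missing labels contribute nothing. `n_rmsd`
is modeled as an unbounded Poisson rate even though observed counts are
capped at the pose count; predictions are clamped to `[0, n_poses]` only
at selection time. The forward/backward passes and the Adam optimizer are
implemented in the package (convolutions via im2col + GEMM in compiled
code) and verified against finite differences to $10^{-9}$ relative error
in the test suite.

## Training schedule

The default schedule is 200 epochs of Adam with $\beta_1 = 0.99$,
$\beta_2 = 0.999$ (an unusual first-moment decay — 0.9 is the
conventional value — kept as the default and exposed as a config field),
initial learning rate $10^{-3}$ with exponential decay $\gamma = 0.95$ per
epoch, batch size 32. Augmentation applies one fresh uniformly random
rotation (quaternion-sampled from the seeded stream) per training pocket
per epoch about the ligand center, followed by re-voxelization; validation
always uses unrotated grids, and evaluation-mode batch normalization uses
running statistics, so inference is deterministic. The descriptor
standardizer, the optimizer state and the batch-norm running statistics
see training-fold data only — a property asserted by a dedicated test that
corrupts held-out labels and features and checks the fitted parameters are
bit-identical.

## Evaluation splits

Four 5-fold cross-validation plans probe different generalization regimes:
a uniform **random** split; a **ligand-scaffold** split that k-means
clusters the fingerprint bit vectors (Euclidean metric, clusters = folds,
seeded initialization from distinct fingerprints; clusters-equal-folds is
the package convention, and unequal fold sizes are inherent to scaffold
splits); a **protein-family** split that
assigns whole families to folds by first-fit-decreasing bin packing with
capacity $\lceil n/k \rceil$ (no family ever spans folds); and a
**balanced protein-family** split that shuffles each family (seeded) and
deals members round-robin from a seeded random offset, putting exactly
$1/k$ of every size-divisible family in each fold. All four are exact
partitions, property-tested over random instances.

## Selection and significance

For `rmsd_min` and `rmsd_ave` the protocol with the minimum predicted value
is selected; for `n_rmsd` the maximum; ties break to the lowest registry
index. The experimental values of the chosen protocols are compared against
every fixed protocol with a one-sided two-sample Mann–Whitney test ("less"
for the RMSD targets, "greater" for the counts) at $\alpha = 0.01$ — exact
when the combined sample is at most 12 without ties, normal approximation
with tie correction otherwise, with no multiple-testing correction by
default (a Bonferroni flag exists). Ligand-centric metrics pool all
(complex, protocol) pairs within a fold's validation set; a
per-complex-averaged alternative is available (`method = "per_complex"`)
since both readings of a ligand-centric correlation are defensible. All
fold aggregates are reported as mean ± 1 standard deviation.

## The synthetic benchmark

Real self-docking labels require licensed docking engines and a large
curated complex set, so the package ships a generator
(`makeBenchmark()`) that emulates the statistical structure the pipeline
assumes, at desk scale. Pockets are atom clouds sampled uniformly in the
15 Å sphere from a catalog of realistic (residue, atom name, element)
protein atom types, with coordinates rounded to PDB precision so fixtures
round-trip exactly; channel flags follow from the bundled rules.
Fingerprints are Bernoulli bits (density 0.05) and descriptors are a
unit-variance AR(1) Gaussian vector. Labels come from a planted factor
model: a low-dimensional latent $z$ (default 8 dimensions) is a fixed
random projection of the pocket summary, fingerprint and descriptors plus
a per-family offset; per protocol, `rmsd_ave` is
$\mathrm{softplus}(w_p^\top z + b_p)$ plus Gaussian noise (0.3 Å by
default), `rmsd_min` is a per-complex fraction $c \sim U(0.25, 1)$ of it,
and `n_rmsd` is Binomial$(20, \sigma(-1.5\,(\mathrm{rmsd_{ave}} -
\mathrm{resolution})))$ with resolutions uniform in 1.5–3 Å — so lower
RMSD means more poses under resolution, and protocols differ through
weight perturbations of protocol-specific scale ("easy" and "hard"
protocols). The link functions are the generator's own choices; they
reproduce the qualitative structure of real benchmarks (protocol-dependent
spread, RMSD–count anticorrelation), not any specific dataset.

The `signal-dominant` preset (noise 0.1 Å, stronger descriptor weighting)
is used wherever a test must distinguish "the optimizer works" from "the
data are too noisy": the learnability acceptance check trains the default
network for 50 epochs on one fold of 500 such complexes, over three seeds,
and requires held-out pooled Pearson $R \ge 0.5$ on `rmsd_ave`. That check
runs with augmentation off: rotation augmentation is a regularizer against
pocket-orientation overfitting in real data, and with planted labels it
only adds compute without changing what the check measures. Problem sizes
throughout the suite (500 complexes for learnability, tens of complexes
for contract tests, 50 epochs rather than the production 200) are the
package's chosen desk-scale conditions.

What passing these tests shows — and what it does not: the synthetic
benchmark demonstrates that the pipeline's machinery (featurization,
optimization, splits, selection statistics) is correct and that the
network can recover a planted pocket+ligand signal out of sample. It does
not demonstrate chemical accuracy on real complexes: synthetic pockets
have no secondary structure or cavity geometry, ligand bits are
independent rather than substructure-correlated, and the planted link is
far smoother than real docking-score landscapes. Benchmark-scale results
on real data additionally require a curated complex database and the 14
licensed or open docking engines, which are outside this package's scope.

## Numerical choices and degenerate inputs

Pearson correlations on zero-variance vectors are returned as `NA` and
excluded from fold aggregates; per-protocol cells with fewer than two
observed validation complexes in a fold are likewise `NA`. Empty pockets
voxelize to all-zero grids (with a warning at extraction). The Mann–Whitney
implementation switches from exact to corrected-normal inference exactly at
a combined sample size of 12 or any tie. Family-fold repair: if first-fit-
decreasing leaves a fold empty (only possible with few, large families),
the smallest families from the most loaded folds are moved in. Label
tables are written with 17 significant digits so they round-trip
bit-exactly. All randomness flows from user-visible integer seeds; a
training run fans its master seed into fixed initialization, shuffling and
rotation substreams, so runs reproduce exactly with augmentation on or
off.

## Known limitations

The conv stack is not rotation-equivariant; augmentation only mitigates
orientation sensitivity. The channel rule table is a residue/atom-name
approximation and ignores protonation states; the fingerprint is not
bit-compatible with ECFP4 implementations elsewhere; the 183-descriptor
panel is a graph-topological stand-in for toolkit descriptor sets (the
panel is configurable). Training is single-threaded CPU; production-scale
(thousands of complexes, 200 epochs, all four splits) is hours, not
minutes, at the default widths.
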