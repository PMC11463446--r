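---
title: "Atomistic ensembles by equivariant graph denoising: models and methods"
author: "AtomEnsembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atomistic ensembles by equivariant graph denoising: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Given the chemical structure of a molecular system -- a protein, a small
molecule, or a complex of the two -- but unreliable or absent coordinates for
some of its atoms, we want to (i) rebuild physically sensible all-atom 3D
models, (ii) estimate, per atom, how far each rebuilt position is likely to be
from the truth, and (iii) turn repeated stochastic rebuilds into ensembles
that can be ranked (which sampled ligand pose is best?) and summarized (how
conformationally ordered is an active site?).

AtomEnsembles implements this programme at desk scale: every component -- the
atom-graph representation, the corruption schemes that define the denoising
task, the structural losses, the miniature SE(3)-equivariant network, and the
ensemble metrics -- is fully specified, trainable on a laptop CPU, and
testable against exact synthetic ground truth.

## Representation: one chemical graph for everything

A molecular system is converted to a `ChemGraph`: nodes are individual heavy
atoms (hydrogens are stripped at construction and never modeled), edges are
chemical bonds. Polymers are expanded through an embedded residue-template
dictionary for the 20 standard amino acids (with peptide C->N links between
consecutive residues); small molecules must arrive with explicit bonds, from
an SDF file or a template -- the package deliberately refuses to perceive
bonds from interatomic distances, because silent chemistry errors are worse
than a loud error message.

Two annotations carry most of the chemistry:

* **Bond separation** -- the number of covalent bonds on the shortest path
  between two atoms (`Inf` across components). This is the only feature that
  lets the network distinguish a 1-2 neighbor from a 1-4 neighbor in a
  collapsed input where all spatial distances are noise. In the pair features
  the separations 1-8 are one-hot encoded and larger values are carried by a
  scalar clamped at 32; the matrix itself stores exact values.
* **Chiral centers** -- (O, A, B, C) tuples at stereogenic C/N/P/S atoms with
  at least three heavy neighbours whose substituent branches are pairwise
  distinct (canonical branch labels compared to depth 4; deeper
  distinctions are rare in desk-scale molecules and cost exponentially more).
  The handedness of a center is the sign of the pseudoscalar
  $V = \hat e_A \cdot (\hat e_B \times \hat e_C)$, the triple product of unit
  vectors from the center to the ordered neighbours. For ideal tetrahedral
  geometry $|V| = 4/(3\sqrt 3) \approx 0.770$; the two enantiomers differ
  only in the sign. The stored tuple order is: neighbours sorted by atom
  index, with the lowest-index substituent of a 4-coordinate center omitted
  (the "viewing direction"). Any fixed convention works -- what matters is
  that perception (training labels) and inference use the same one, which
  they do by sharing the code path. Near-planar candidates ($|V| < 0.1$) are
  excluded rather than assigned an arbitrary sign.

## Corruption: the denoising task

Training-mode corruption collapses each residue's side-chain atoms onto the
backbone atom they are covalently anchored to, collapses every ligand
component onto one uniformly chosen atom, and then adds i.i.d. Gaussian noise
($\sigma = 1.5$ Å per coordinate) to all atoms, backbone included. Noising
the backbone too resolves an ambiguity in the task definition in the
conservative direction: denoising a noised backbone is strictly harder, so
tests trained this way remain valid for the easier fixed-backbone setting.

Docking-mode initialization is the same recipe the network sees in training,
applied at inference: choose one ligand atom at random, add $\sigma = 1.5$ Å
noise to its anchor position, collapse all ligand atoms onto it, add
independent $\sigma = 1.5$ Å noise to every ligand atom. Neither the ligand's
internal structure nor its orientation is inferable from such an input.
Protein side chains are scattered around their C$\alpha$ positions; the
backbone is kept exactly at the input coordinates. When no reference ligand
pose exists the caller must supply an anchor point for the site -- the
package will not guess a binding site.

Every corruption is a pure function of (input, seed): the random stream is
consumed in a documented order (per-component draws in ascending component
id, then one n-by-3 noise matrix filled column-major), so ensembles reproduce
bitwise across runs.

## Structural losses

**All-atom FAPE.** For every bonded triple a-b-c (each geometric triple once,
collinear reference triples excluded) a local frame is built -- origin at b,
x-axis along b->c, y by Gram-Schmidt of b->a, z completing the right-handed
set. Model and reference are each expressed in the frame built from their own
three atoms; the per-atom deviation is the distance between the two local
positions, clamped at 10 Å; the loss is the mean over all atoms and all
frames. This makes the loss exactly invariant under rigid motion of either
structure while penalizing every internal rearrangement. Because frames are
right-handed by construction, a mirror-image model does *not* score zero --
but the gradient signal toward the correct hand is weak, which is why
chirality gets its own term.

**Chirality.** The loss $(V - V_{ideal})^2$ per center, with
$V_{ideal} = \pm 4/(3\sqrt3)$ by the perceived sign. Its analytic gradient
with respect to the four atoms doubles as the *biasing vectors* fed to the
network (below): they point in the directions the atoms must move to reach
the requested hand, and gradient descent on this term alone flips a mirrored
center within a few dozen steps.

**Bonded geometry.** Mean absolute errors in bond lengths, bonded angles
(all a-b-c paths), planar angles (improper dihedrals at 3-coordinate sp$^2$
centers, flagged from bond orders) and chiral angles (improper dihedrals
O-A-B-C at chiral centers). The same quantities serve as the
`GeometryErrorReport` diagnostic and as differentiable training terms.

**Per-atom lDDT** (radius 15 Å, thresholds 0.5/1/2/4 Å) excludes pairs of
the same covalent component fewer than 4 bonds apart, so it measures packing
rather than bonded geometry. Radius and thresholds follow the convention
established by structure-prediction confidence heads and are config-exposed.

## Confidence

The network predicts a per-atom deviation $\sigma_i$ (Å), trained by
maximizing the Gaussian likelihood of the actual deviations $d_i$, i.e.
minimizing $\log\sigma_i + d_i^2/(2\sigma_i^2)$; the minimizer for fixed $d$
is $\sigma = d$, so across samples $\sigma_i$ learns the RMS deviation of
atom i. The deviations $d_i$ are measured after optimal rigid superposition
of the model onto the reference over all resolved atoms (the way RMSD-style
deviations are normally defined); a frame-median alternative is available
behind a policy switch. $\sigma$ is produced through a bounded smooth
transform with floor 0.05 Å and cap 20 Å, keeping the likelihood finite on
badly corrupted inputs.

Aggregated over an atom selection,
$\mathrm{pRMSD} = \sqrt{\tfrac1N \sum_i \sigma_i^2}$
ranks sampled models (lower = more confident). Per-pair confidence uses
signed distance-error bins with symmetric edges (-4, -2, -1, -0.5, 0.5, 1,
2, 4) Å plus open tails.

## The network

A three-track iterative denoiser. Tracks: 1D per-atom embeddings (element
one-hot, formal charge, role flag -- never reference coordinates), 2D
per-pair embeddings on the dense pair grid (bonded flag, bond order, bond
separation, unconnected token, same-component flag), and the 3D coordinate
state. Each iteration block:

1. rebuilds the neighbor graph from current coordinates -- per atom, K
   neighbors picked half by spatial distance, half by bond separation,
   deduplicated and backfilled spatially (K = 32 at reference scale, 16 for
   micro fixtures);
2. projects pair embeddings to edge embeddings through an adapter layer;
3. runs `nInner` equivariant message-passing sub-layers. Messages are an MLP
   of (h_i, h_j, a radial-basis encoding of the current distance, the edge
   embedding). The coordinate update is a sum of three bounded radial
   channels along the difference vectors -- a relative-displacement channel,
   a near-unit-direction channel, and a distance-geometry channel
   proportional to $(d_{ij} - \hat d_{ij})$, where $\hat d_{ij}$ is a
   per-edge target distance read off the pair track (a distogram-style
   head) -- plus the chirality biasing vectors scaled by a learned per-atom
   gate. All gates are rotation- and translation-invariant scalars, so the
   update is exactly SE(3)-equivariant; the chirality vectors flip under
   reflection, which is what lets the network produce a requested hand.
4. applies a pair-to-pair update biased by a radial-basis encoding of the
   current distances ("bias from structure");
5. branches off the confidence heads ($\sigma_i$, plDDT, pair bins).

Blocks share one parameter set (depth adds compute, not parameters; the
sub-layers inside a block have their own weights, mirroring the multi-layer
equivariant network a full-scale block contains). The reference
configuration is 8 blocks / K = 32; the micro configuration used in the test
suite is 2 blocks / K = 16 / widths 32 and 16. The dense pair track is
quadratic in the crop size; systems above the 600-atom crop cap are rejected
rather than chunked. Coordinate-update output weights are zero-initialized,
so an untrained block is the identity on coordinates.

The chirality biasing vectors are treated as detached inputs (no gradient
flows through their dependence on coordinates); the learned gate still
receives the full loss gradient. This is the usual detached-guidance
simplification -- it removes third-derivative terms from backpropagation at
no observed cost in training quality.

## Training

Gradient training runs on a small reverse-mode autodiff tape written for
this package (no deep-learning framework is among its dependencies); its
gradients are verified against finite differences in the test suite. The
optimizer is Adam with global-norm gradient clipping at 1.0 and cosine decay
to 15% of the stage learning rate; learning rates of ~0.005 (stage 1) and
~0.003 (stage 2) were found necessary -- an order of magnitude higher and
optimization bounces without converging.

The two-stage schedule mirrors the staged protocol of the original training:
stage 1 uses half the blocks with the structure losses only; stage 2 the
full depth plus bonded-geometry, chirality and confidence terms, with every
loss applied after every block. Two deliberate additions in stage 1, in
place of a pure single-loss stage: a within-component pair-distance MAE
("dist") and the distogram regression ("dpred") that supervises the pair
track's target distances. Without them, FAPE-only optimization from fully
collapsed inputs stalls at desk scale -- the loss surface through
model-built frames on a noise blob is too rugged for a few hundred Adam
steps. Both weights are config-exposed and documented here as this package's
own design choice; the distance terms are chirality-blind, so FAPE and the
chirality loss remain the terms that decide handedness.

Desk-scale problem sizes used throughout the test suite, chosen as the
smallest systems that exercise every code path: training sets of 5 fixtures
(6-12 atoms; chain, branched, an enantiomer pair, aromatic ring), ~250 +
~400 optimizer steps, 2 corruption replicates per fixture per step; the toy
pocket is 20 pseudo-residues (~120 atoms) with a 6-atom ligand.

## Ensembles and scores

`sampleEnsemble` draws n corruption seeds (base + i), denoises each, and
ranks samples by per-sample pRMSD over the ligand (or any selection). When a
reference pose exists, each model is first superposed on the reference over
backbone atoms -- this reconstructs the pocket frame, since the denoiser is
free to drift globally -- and the ligand RMSD is computed *without* further
superposition, minimized over chemical-graph automorphisms of the ligand
(element-, charge- and bond-order-preserving; enumeration capped at 10^4
with an identity fallback). The identity-only metric is also exposed.

The preorganization score of a selection (e.g. a catalytic lysine and its
covalent adduct) is the ensemble mean of per-sample pRMSD over the
selection's atoms excluding the backbone N, CA, C, O; the standard protocol
runs 50 samples. Lower scores mean the network keeps reproducing the same
side-chain conformation -- a preorganized site.

## The synthetic-fixture generator

All tests run against generated systems with *exact* ground truth: zigzag
chains (bond length 1.5 Å, tetrahedral angles), closed planar rings and
macrocycle-like loops (exact polygon closure), branched tetrahedral centers,
enantiomer pairs with requested handedness, Ala-Ala dipeptides built from
ideal internal coordinates, long poly-glycine backbones, and toy pockets --
a rigid cage of pseudo-residues with real backbone atom names and inward
side chains enclosing a small ligand with guaranteed contacts (>= 3 pocket
atoms within 4 Å) and no clashes (< 2 Å regenerates the layout). Geometry is
idealized rather than force-field minimized: oracle tests need exact
self-consistency (`bondedGeometryErrors(ref, ref) == 0` to machine
precision), and the network only needs a learnable, self-consistent target.

What the generator does *not* emulate -- and therefore what passing tests do
not show about real data: conformational strain and torsional preferences,
solvent, crystal contacts, the chemical diversity of real ligands, and
experimental coordinate error. Success on fixtures demonstrates that the
machinery (representation, losses, equivariance, corruption, ranking) is
correct and that the architecture can learn the denoising task; it says
nothing about accuracy on PDB-scale structures, which would require training
at full scale with the reference configuration.

## Numerical choices and degenerate inputs

* Frame construction rejects collinear triples (angle within 2 degrees of
  180) -- their Gram-Schmidt step is ill-conditioned.
* `tripleProductV` errors on substituents closer than 1e-6 Å to the center.
* Square roots in differentiable losses carry small floors (1e-12) so
  gradients stay finite at exact zero deviation.
* lDDT is NA (masked) for atoms with no qualifying partner.
* Ties: spatial neighbor ties break by atom index; chemical ties by
  (separation, index); altloc ties by file order; crop inclusion is greedy
  by increasing distance with whole residues/components kept or dropped
  atomically.
* Double-bond (E/Z) stereochemistry is not constrained -- only point
  chirality is. Planar-angle errors report it diagnostically.

## Known limitations

* No hydrogens, protonation states, tautomers or aromaticity perception
  (bond orders are taken from the input).
* The micro network is a memorization-scale model: it demonstrates the
  mechanisms on fixtures, not transferable structure prediction.
* Dense pair tracks cap systems at 600 atoms (the crop cap); larger systems
  must be cropped around a center of interest first.
* mmCIF, MOL V3000 and nucleic-acid templates are out of scope; the type
  system allows nucleic acids but no templates ship.
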