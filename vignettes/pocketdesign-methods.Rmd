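---
title: "pocketdesign: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pocketdesign: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fixed-backbone sequence design (inverse folding) asks: given a protein
backbone, which amino-acid sequences fold into it? For binders, sensors and
enzymes the answer depends critically on the *nonprotein* atoms in the
system — small molecules, nucleotides and metal ions near the designable
positions. `pocketdesign` implements a graph neural network that conditions
sequence design and sidechain packing on this full atomic context, together
with a desk-scale training loop, evaluation metrics, and synthetic-structure
generators that make the whole pipeline testable without any external data.

## The model

The network operates on three graphs built from invariant geometry:

1. **Protein graph.** Residues are nodes; each residue connects to its
   `K = 32` nearest neighbors by Cα–Cα distance. Edge features are the 25
   ordered atom-pair distances between {N, Cα, C, O, virtual Cβ} of the two
   residues, each encoded with `r = 16` Gaussian radial basis functions,
   concatenated with a relative-position encoding (sequence offset clipped
   at ±32, with a dedicated category for cross-chain pairs).
2. **Ligand (atom) graph.** For each residue, the `M = 25` context atoms
   nearest to its virtual Cβ form a fully connected graph. Node features are
   a 147-wide element one-hot (atomic number 120 + group 19 + period 8)
   embedded to width 64, plus RBF-encoded backbone-atom-to-atom distances
   and four sin/cos angle features of the atom direction in the residue's
   N–Cα–C frame. Edges are RBF-encoded atom–atom distances.
3. **Protein–ligand graph.** Each residue receives messages from its M
   context atoms, whose node states were first refined on the ligand graph.

The virtual Cβ is constructed from backbone geometry
(`Cb = -0.5827 (b × c) + 0.5680 b - 0.5407 c + Ca`, `b = Ca − N`,
`c = C − Ca`) so glycine has a sidechain-direction reference. All features
are functions of distances, sequence offsets and local-frame angles, hence
invariant to global rotations and translations — the test suite asserts this
to 1e-4 on logits under random rigid transforms.

Message passing uses one layer pattern throughout: a 3-layer GELU MLP on
`(node_i, [node_j,] edge_ij)` summed over neighbors and scaled by
`1/s, s = 30`, a residual + LayerNorm node update, and a position-wise
feed-forward sublayer (width `4m`); encoder layers additionally update edge
states with the same message pattern. The default stack is 3 protein encoder
layers, 2 alternating ligand/protein–ligand blocks whose output enters the
node states through a residual LayerNorm branch, and 3 sequence decoder
layers, all at hidden width `m = 128`. At these defaults the full model has
2,618,693 trainable parameters (2.62 M) and the protein-only ablation —
ligand featurization and protein–ligand blocks removed — has 1,660,485
(1.66 M). A note on provenance of two structural choices: the printed layer
pseudocode we reconstructed from omits the feed-forward sublayer, and the
atom-graph layer's declared edge width is inconsistent with the stated
totals; we resolved both in favor of the parameter counts, which our
instantiated stores reproduce exactly.

## Sequence decoding

Decoding is autoregressive under a uniformly random decoding order: position
`i` attends to the sequence embeddings of neighbors already decoded, while
not-yet-decoded neighbor slots fall back to encoder-only features. Sampling
draws each token from `softmax((logits + bias)/T)`. Supported constraints:

- **Fixed positions** emit their token with probability 1 and are excluded
  from the confidence average.
- **Tied groups** (symmetric design) decode at the earliest member's slot
  from the *average* of the members' probability vectors; one draw is
  assigned to all members.
- The unknown token is excluded from sampling by default via a large
  negative bias (convention; it remains in the alphabet for scoring).

**Confidence** is reported as `100 ×` the mean untempered model probability
of the emitted token over designable positions. The number this imitates is
published only as a 0–100 color scale without a formula, so our definition
is a stated convention; the suite validates it only through the
teacher-forced consistency property (per-step probabilities replay exactly
as the teacher-forced joint) and the rank-correlation calibration metric.

## Sidechain packing

A twin-encoder variant predicts, per residue, a mixture of three von Mises
(circular normal) distributions for each of chi1–chi4: 36 raw outputs
reshape to (mean, raw concentration, mixing logit) × 3 components × 4 chis.
Concentrations are floored at `0.1 + softplus(raw)`; mixture densities are
verified to quadrature-normalize on the circle. Decoding proceeds in four
stages — all chi1 first, then chi2, chi3, chi4 — and after each stage the
newly placed atoms re-enter the context set (category `protein_sidechain`),
so later chis are conditioned on earlier rotamer decisions of *all*
residues. Whether the original re-runs its full encoder per stage is not
documented; we re-run context selection plus the forward pass each stage,
which is the simplest scheme consistent with "placed atoms are used for
further decoding".

Atom placement uses sequential ideal internal coordinates (NeRF): bond
lengths/angles from standard tables, ring atoms at fixed dihedrals
(ideal-planar rings), branch atoms at fixed offsets from their chi. The
sign convention is fixed so that measuring the placed dihedral returns the
input chi exactly (round-trip asserted to 1e-6 rad) and Cβ lands on the
L-amino-acid side (validated against the virtual Cβ construction). The
proline ring is built from chi1/chi2 without re-closing the CD–N bond.
ASP/GLU/PHE/TYR terminal chis are physically 180°-symmetric; recovery
metrics treat them modulo 180°.

The packer's predictive accuracy is *not* asserted anywhere: trained packer
weights would require paper-scale training, which is out of scope. The
packer is exercised with seeded random initialization — distribution
validity, staged feedback, sampling and geometry are what the green tests
establish.

## Training

Adam (`beta1 0.9, beta2 0.98, eps 1e-9`) on masked categorical
cross-entropy of teacher-forced log-probabilities under a fresh random
decoding order per structure. Batches are assembled under a token budget
(6,000 by default), coordinates receive i.i.d. Gaussian noise (0.1 Å
default) each step, and an optional augmentation donates the sidechain
atoms of a uniformly drawn 2–4% of residues as context while keeping their
identities as prediction targets. Dataset hooks: resolution ≤ 3.5 Å and
length < 6,000 filters applied from parsed metadata (entries without
metadata are kept with a warning), and cluster-aware sampling from a
precomputed two-column id→cluster table (the clustering itself is consumed,
never computed). The learning rate is not specified by the source
architecture; the default is 1e-3 with an optional linear warmup, and the
desk-scale discrimination test uses 2e-3, chosen once for small-model
convergence speed.

## Synthetic data: what it emulates and what it does not

`make_backbone()` builds idealized backbones by NeRF from textbook dihedral
presets (helix −57/−47, strand −119/+113, omega 180) with Engh–Huber-like
bond geometry; consecutive Cα–Cα distances come out at 3.80 Å.
`make_context()` places metals as single atoms at a stated radius from a
residue's virtual Cβ and "molecules" as connected random clouds with 1.5 Å
steps. `make_planted_dataset()` assigns sequences by a deterministic rule:
residues whose virtual Cβ lies within 6 Å of a zinc trigger get histidine;
all others draw from a fixed background distribution over {A, L, S, E} with
probabilities (0.4, 0.3, 0.2, 0.1). The background mode (40%) deliberately
exceeds any marginal the forced token could reach, so a context-blind model
cannot pick up the rule from token frequencies alone.

What a green planted-rule test establishes: information flows from context
atoms through the ligand branch into the decoder strongly enough that a
small model (m = 32) learns a proximity-conditioned identity rule to >90%
held-out recovery, while the architecture-matched protein-only ablation
cannot (its recovery at trigger positions stays at the background level,
operationalized as ≤ 0.5 with the forced token absent from the background).
What it does not establish: anything about real rotamer statistics,
chemistry-aware ligand geometry, crystallographic noise, or the published
recovery percentages, which require paper-scale training on the PDB.

One subtlety worth recording: *ideal* helices have exactly symmetric
neighbor distances, so K-nearest-neighbor selection is tie-degenerate and
the graph itself is unstable to float-level perturbations. Invariance tests
therefore jitter fixture coordinates (0.2 Å, seeded) before comparing
transformed structures; real structures are never tie-degenerate.

## Numerical choices

- LayerNorm uses `eps = 1e-5` inside the square root.
- GELU uses the standard tanh approximation with `sqrt(2/pi)`.
- RBF: 16 Gaussians, centers evenly spaced on [2 Å, 22 Å], width
  `(22−2)/16 = 1.25` Å.
- Nearest-neighbor ties break toward the lower residue index; `K` and `M`
  are capped by availability and padded with masks, never errors.
- Masked residues (missing backbone atoms) keep their neighbor slots but
  are zeroed via attention masks; message sums over masked slots are
  exactly zero (asserted).
- Dropout is inverted (`1/(1−p)`) and active only in training mode.
- Weight initialization is Xavier-uniform for matrices, zeros for biases,
  ones/zeros for norm affine parameters, fully seed-controlled.
- Altlocs keep the highest-occupancy conformer (ties: first label);
  insertion codes flatten into a strictly increasing per-chain index;
  nonstandard amino acids become the unknown token and may donate
  sidechain atoms as context.

## Known limitations

- Pure-R training is desk-scale only (~1 s per 60-residue structure step at
  m = 32); paper-scale runs are a non-goal.
- The mmCIF reader handles the `_atom_site` loop of standard files, not
  multi-model or quoted-multiline edge cases; crystallographic symmetry
  expansion is out of scope.
- Proline ring closure and idealized ring geometries are approximate;
  no clash resolution or rotamer-library support.
- Original released checkpoints cannot be loaded (their layout is not part
  of the written record this package was built from).
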