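---
title: "Unified nucleic acid inverse folding: model, training targets, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unified nucleic acid inverse folding: model, training targets, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the unified biopolymer graph representation, the encoder–decoder
message-passing network, the two training objectives (design and
specificity), the motif-alignment algorithm, the evaluation metrics, and the
design decisions taken where the method left genuine freedom.

## The problem

Fixed-backbone inverse folding asks: given the three-dimensional backbone of
a macromolecule, which sequences are compatible with it? For nucleic acids
this covers two practically distinct tasks. *Sequence design* (e.g. for RNA
scaffolds) seeks one coherent sequence per backbone. *Fixed-dock protein–DNA
specificity prediction* takes a given protein–DNA complex geometry and asks
for the marginal base preference at each DNA position — the quantity that
assays such as SELEX or PBM summarize as a position probability matrix
(PPM). Both are handled here by one architecture with task-specific
supervision.

## Representation

Every residue — amino acid, deoxyribonucleotide, or ribonucleotide — is one
graph node. Assumptions baked into the representation:

* **Side-chain agnosticism.** Only backbone atoms enter the features. For
  specificity this is a deliberate guard against information leakage: base
  atoms would reveal the answer. The model therefore cannot exploit
  side-chain chemistry even where it is present in the input file.
* **Unified atom slots.** Each residue owns 18 ordered atom slots
  (`backbone_slots()`): the four protein backbone atoms plus a virtual
  C-beta, the eleven nucleic backbone atoms plus O2′ (RNA only), and a
  virtual nucleic "side-chain nitrogen". Slots outside the residue's class
  are absent, and every pairwise-distance feature involving an absent slot
  is exactly zero, so no non-physical signal crosses polymer classes.
* **Existence rule.** A residue participates only if *all* required
  backbone atoms of its class are present with occupancy strictly above 0.8
  (`new_complex()`). The inequality is strict; an occupancy of exactly 0.8
  does not count. 5′-terminal nucleotides genuinely lack a phosphate in many
  real structures; by default they are excluded (the literal reading of the
  rule), and a `permissive_termini` flag exempts P/OP1/OP2 at chain starts
  for users who need those residues.
* **Per-residue classification.** Chains are not forced into one class:
  each residue is typed by its residue name, falling back to atom content
  (presence of C1′ marks a nucleotide, O2′ distinguishes RNA from DNA), so
  DNA–RNA hybrid chains work naturally. Non-canonical nucleotides map to the
  unknown nucleic token.

### Virtual atoms

The virtual C-beta uses the published ideal-geometry construction: with
`b = CA − N`, `c = C − CA`, `a = b × c`,
`CBv = −0.58273431 a + 0.56802827 b − 0.54067466 c + CA`. Collinear
N/CA/C input makes the cross product vanish; the function then warns and
falls back to CA plus a unit offset rather than producing NaNs.

No published construction exists for the nucleic virtual nitrogen, so its
geometry is this package's choice: 1.48 Å (a typical glycosidic C1′–N
distance) from C1′ along the bisector of the O4′–C1′–C2′ angle, pointing
away from the sugar. This places it on the base side of the sugar for any
reasonable pucker, is rigid-motion equivariant by construction, and needs
only atoms that the existence rule already guarantees. A degenerate
(zero-length) bisector raises an error rather than guessing.

## Graph features

* **Neighbors.** Each node connects to its k = 32 nearest existing
  residues by representative-atom distance (Cα / C1′). Distance ties are
  broken by lower residue index; the selected neighbor list is then stored
  in residue-index order, which keeps the edge layout bit-stable under
  rigid motions that perturb exactly tied distances at floating-point
  level (messages are mean-aggregated, so neighbor order carries no
  information).
* **Edge features.** Every 18 × 18 slot-pair distance is embedded with 16
  Gaussian radial basis functions, centers uniformly spaced on [2, 22] Å,
  width equal to the spacing — the convention of the protein
  inverse-folding stack this architecture mirrors. Two scalar features are
  appended: a same-chain indicator and the signed within-chain sequence
  offset clipped to ±32 and scaled — the chain-relative information the
  parent architecture carries, retained here as a design decision.
* **Noise.** Training adds i.i.d. Gaussian noise, σ = 0.1 Å per
  coordinate, to every real atom *before* virtual-atom construction and
  neighbor search, so the augmentation perturbs topology as well as
  distances. Inference uses σ = 0.

## Network and decoding

Node features start as a polymer-type one-hot passed through a bias-free
linear map, LayerNorm, and a second linear map — giving the network the
polymer class directly instead of making it infer the class from which
slots exist. The encoder (default 3 layers, hidden 128) alternates
message passing (3-layer ReLU MLP on `[h_i, h_j, e_ij]`, mean-aggregated,
residual + LayerNorm), a position-wise feed-forward block, and an edge
update of the same shape.

The decoder is random-order autoregressive. A decoding order over the free
positions is drawn uniformly; fixed residues (all protein positions, plus
any nucleic positions the user pins) sit before every free position in the
causal order and always expose their true token. For an edge `j → i`, the
neighbor representation is the decoder state plus token embedding of `j` if
`j` precedes `i` in the order (or is fixed), and the sequence-free encoder
state of `j` otherwise. This is the standard fixation mechanism of the
parent architecture, and it makes a useful exactness property hold: a full
teacher-forced pass and stepwise decoding produce bitwise-identical
conditionals, which the test suite asserts.

Sampling restricts the 26-way softmax to the four canonical bases and
renormalizes; the unknown tokens and out-of-class tokens are masked at
sampling time only, so the training loss still sees the full output head.
Design inference samples at temperature 0.1; specificity inference runs 30
decodes at temperature 0.6 and averages the probabilities recorded at each
position's own decode step (not a teacher-forced re-scoring — the literal
reading of "save the per-position categorical probabilities from each
run").

## Training targets

* **Design:** the crystallographic base as a one-hot, label-smoothed with
  ε = 0.1 *within* the polymer class: the true base keeps 0.925 and each
  other canonical base gets 0.025. Mass never crosses classes, and the
  smoothing spreads only over canonical tokens — the unknowns are not
  design targets. Unknown bases become the uniform distribution over the
  four canonicals. Only nucleic positions are supervised; the output head
  still spans all 26 tokens.
* **Specificity:** positions with an aligned experimental PPM column take
  that column; without protein context (nucleic-only complexes, or after
  the 50%-probability protein drop) every position is uniform (0.25 each);
  with protein retained, interface positions lacking a motif keep the
  smoothed crystal base and non-interface positions become uniform. The
  interface is the side-chain contact mask: a residue is interface if any
  of its side-chain heavy atoms lies within 5 Å of an opposite-polymer
  side-chain atom among its 48 nearest residues.

The loss is exactly `(1/6000) Σ mask · Σ_c −y ln p` with the fixed 1/6000
normalizer (the token budget of a batch), not a per-token mean. Batches are
assembled by weighted sampling with replacement — example weight
`(1/N_chains) Σ 1/(1+d_i)` over chain cluster degrees — closing a batch
when the next example would exceed 6,000 tokens. An "epoch" is pool-size
draws.

## PPM loading and alignment

Motif probabilities get 10⁻¹⁰ added to every entry and are renormalized, so
logarithms are always finite. Information content uses the printed
log-ratio form `IC = Σ_c ln(p_c)/ln(0.25)`; note this is *not* the
conventional Shannon information content — it equals 4 for a uniform column
and grows without bound as columns sharpen (≈ 49.8 for an
epsilon-normalized one-hot). It is implemented exactly as stated rather
than second-guessed, as is the ½ factor in the alignment score
`½ · IC · PCC(column, onehot)`. A uniform column has zero variance, making
the correlation undefined; that case is defined to score 0.

Alignment enumerates both orientations and every offset with at least 5
non-unknown overlapping positions (unknown bases are excluded from both the
score and the length check). All best-scoring alignments are retained on
exact score ties — ties arise from genuinely symmetric inputs (e.g. a motif
present on both strands), and tie detection uses exact float equality under
a fixed summation order so that it cannot depend on enumeration order.
Overlap conflicts between groups are resolved per position by the higher
local (per-column) score; at unknown sequence positions, where no local
score exists, the higher information content wins; exact ties keep the
earlier write, groups being processed in input order.

## Metrics

Sequence recovery is the matched fraction over designed positions only.
PPM MAE is the mean over positions of the *L1 distance over the four
bases* — the printed form, with range [0, 2], not a per-entry mean.
Cross-entropy floors predicted probabilities at 10⁻¹⁰ before the log,
mirroring the loading epsilon. C1′-RMSD superposes by least-squares rigid
fit (SVD with the reflection branch excluded); when traces differ in
length, all contiguous placements of the shorter along the longer are
tried and the minimum RMSD wins. A dot-bracket cropping utility breaks
base pairs severed by the crop (the surviving partner becomes a loop),
covering all four bracket layers.

## Synthetic fixtures: what they do and do not show

The generators produce: idealized B-DNA/A-RNA helices (rise 3.38 Å / twist
36°, and 2.81 Å / 32.7°) from an internal-coordinate nucleotide template
whose bonded distances are exact by construction but which is only
self-consistent, not fiber-diffraction-exact; ideal α-helical protein
backbones with a real C-beta as side-chain proxy; interface fixtures with
an exactly controlled protein-to-DNA side-chain distance; Dirichlet-style
motifs of controllable peakedness; and planted datasets in which base
identity is encoded as a radial C1′ displacement of 0.55 Å per code unit
(A = 0 … T = 3) plus 0.02 Å jitter — a displacement at least five times the
training noise, so the signal survives augmentation. A duplex's second
strand is generated by a proper two-fold rotation of the first, so the
*backbone* has an exact dyad symmetry.

Because the nucleotide template is base-independent, fixture backbones
carry **no** real sequence signal (except the planted displacement), and no
symmetry of a fixture can exchange probability channels. Tests therefore
assert invariances (rigid motion, chain relabeling, the backbone dyad,
causality, determinism), oracle equivalences, and the learning mechanism on
planted data — they do not, and cannot, certify recovery rates on real
structures. Passing them shows the machinery is correct, not that the
desk-scale model is a trained design tool.

## Numerical and scale choices

* Parameters initialize Glorot-uniform under a recorded seed; all
  randomness (initialization, batching, noise, decode orders, sampling)
  flows from user seeds through a splitting function, so every entry point
  is reproducible end to end and training runs are deterministic on one
  thread.
* Toy training (the scale exercised by the tests) uses 8 planted strands
  of 8 nt, a 24-token batch budget, learning rate 2·10⁻³, hidden width 64
  with 2+2 layers, and disables dropout; these sizes keep a full training
  run under a minute on one CPU while leaving the learning-mechanism check
  far from its 2,000-step ceiling. Dropout (default 0.1) and the full
  128/3+3 configuration remain available through `model_config()`.
* Gradients are hand-derived; the suite validates them against central
  finite differences at 10⁻⁵ step on a tiny model.
* The interface contact rule uses `distance ≤ cutoff`, so the flag/no-flag
  boundary found by bisection sits at exactly 5 Å.
* LayerNorm uses eps 10⁻⁵; the uniform-column variance guard in the
  alignment score triggers below a standard deviation of 10⁻¹²; logits are
  max-shifted before softmax.

## Known limitations

* No released-weights loader: the checkpoint format is this package's own,
  and the full-scale trained models are out of scope.
* Protein positions are never supervised or designed; the model is context
  -conditioned on protein, not a protein design tool.
* Assemblies/symmetry expansion, alternate locations beyond the
  highest-occupancy one, ligands and waters are ignored at parse time.
* Gapped motif alignment is not supported (ungapped offsets only), and
  secondary-structure scoring beyond the dot-bracket crop utility is out
  of scope.
* The hand-rolled network is CPU-only and desk-scale; it is not an
  efficient reimplementation for production training.
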