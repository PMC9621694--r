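---
title: "Constrained hallucination at desk scale: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained hallucination at desk scale: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifscaffold)
```

## The design model

A functional site is specified as a *contig string*: motif segments named
by source chain and inclusive 1-based residue ranges, interleaved with
scaffold gaps whose lengths may be fixed or sampled from closed integer
intervals (`"5,A163-181,10-25"`). Sampling a placement realizes each gap
uniformly, yielding a design of length
$L = \sum \text{gaps} + \sum \text{motif residues}$ with a boolean motif
mask. Segment order always follows token order; searching over segment
permutations is out of scope, as is any insertion-code or negative
residue numbering.

A design is optimized by choosing a sequence (or a sequence distribution
$P \in \mathbb{R}^{L\times 20}$) so that a structure predictor's output
minimizes a weighted composite loss. All terms are *minimized*, so
optimizer code is uniform:

* **Motif distogram cross-entropy.** The native motif's 6D pairwise
  features (binned Cβ–Cβ distance; ω and θ dihedrals; φ planar angle,
  with Cβ always the idealized virtual position built from N/CA/C) are
  the reference; the loss is the mean over ordered motif–motif pairs and
  the four channels of $-\log(q_{\text{true bin}} + \varepsilon)$ with
  $\varepsilon = 10^{-8}$. The ε floor bounds the loss under an
  adversarial one-hot mismatch (at most $-\log\varepsilon \approx 18.4$
  nats rather than infinity). Only pairs with *both* endpoints in the
  motif count by default: the site's internal geometry is the
  specification, and scaffold context is free to vary.
* **Certainty.** Mean Shannon entropy of the selected pair
  distributions, or, in `kl_background` mode, the negative mean KL
  divergence from a background. The shipped background is uniform — a
  learned background network is a predictor-side concern — so the two
  modes differ by the constant $\ln B$ per channel and share a gradient.
  Restricted to the inter-chain pair mask this is the inter-chain entropy
  loss for binder design.
* **Motif coordinate RMSD.** Kabsch-superposed backbone RMSD (N, CA, C
  by default; CA-only available, since the atom set used by published
  motif-RMSD numbers is not stated).
* **Repulsion.** For two-chain predictions, the mean distance-channel
  mass within 8 Å (the conventional Cβ contact cutoff, configurable)
  over cross-chain ordered pairs *not* in an allowed set.
* **Radius of gyration** ($\max(0, R_g - R_g^{\max})^2$) and **mean
  PAE** over a pair mask.

Term weights, parameters and order live in a `loss_config`
(YAML-serializable). Exact published term weights are not available in
the text this package follows, so the defaults here are labeled
reconstructions; every weight is explicit in the configuration and in
each trajectory's provenance.

## Binning scheme

Distance: 36 equal bins over 2–20 Å plus a no-contact state (37 states).
ω, θ: 24 bins of 15° plus no-contact (25). φ: 12 bins of 15° plus
no-contact (13). Pairs whose Cβ distance exceeds the last edge take the
no-contact state in *all four* channels, as do diagonal entries. These
follow the conventions established for distogram-based design networks;
because the original supplementary definitions were not available, the
whole scheme is a `geometry_bins()` object and can be replaced
end-to-end.

## The planted landscape

Trained predictors are out of scope, so verification uses a synthetic
world with a hidden target structure $X^\*$ and sequence $s^\*$. For a
query distribution $P$:

$$m_i = P_i(s^\*_i), \qquad
  a_i = \operatorname{mean}_{j \in [i-w,\, i+w]} m_j, \qquad
  c_{ij} = a_i a_j$$

with windows clipped to chain bounds ($w = 2$ by default — small enough
that signal stays local, large enough that neighboring correct letters
reinforce each other). The emitted distogram for a pair is the mixture
$c_{ij}\,\delta_{\text{bin}(X^\*)} + (1 - c_{ij})\,\mathrm{Uniform}(B)$,
coordinates are $X^\*$ itself, $\text{pLDDT}_i = 100\,a_i$ (matching the
0–100 scale of published thresholds) and
$\text{PAE}_{ij} = \text{max\_pae}\,(1 - c_{ij})$ with a 30 Å cap, the
order of magnitude of real predictors' error caps.

Two properties make this a meaningful test oracle. First, mixture
entropy is strictly decreasing in $c$, so certainty-style losses are
uniquely minimized (over hard sequences) at $s^\*$ — recovery of the
planted sequence by the optimizers tests the whole loss/optimizer stack,
not arithmetic. Second, every output is closed-form in $P$, so the exact
gradient is available by the chain rule loss → $c$ → $a$ → $m$ → $P$
(`toy_gradient()`), and finite differences provide an independent check.
Terms that depend only on coordinates (motif RMSD, radius of gyration)
are constant in $P$ on this world and contribute zero gradient — the toy
world verifies sequence-space differentiation, not coordinate-space
terms.

The mixture distograms are kept in a compact representation (confidence
matrix + reference bins) with closed-form entropy/cross-entropy/contact
statistics; `as_dense_geometry()` materializes full probability arrays,
and tests assert both representations agree to 1e-9 on every statistic a
loss consumes.

`scaffold_world()` builds a full design-length world around a motif:
segments are grafted rigidly (their native coordinates exactly), gaps
grow as ideal helix. With multiple segments the *relative orientation*
between segments comes from the helical linkers, not the native
arrangement — a deliberate simplification; single-segment worlds embed
the site exactly.

## Optimizers

**Simulated annealing.** One non-motif position mutated per step,
uniformly over the allowed alphabet excluding the current letter (a
proposal that re-draws the same letter is a wasted predictor call).
Cysteine is excluded from the default mutation alphabet, the common de
novo practice that avoids spurious disulfides; pass
`mutation_alphabet(exclude = character())` to allow it. Cooling is
geometric, $T_k = T_0 (T_f/T_0)^{k/K}$. The default $T_0$ is calibrated
at run time as $0.1\times$ the mean absolute loss change over a short
probe of random single mutations from the initial sequence, with
$T_f = T_0/100$: single-mutation deltas are orders of magnitude smaller
than the absolute loss value, and an annealer whose temperature is
matched to the absolute loss would spend most of its budget in an
undirected random walk. Scaling the same 0.1 rule to the scale the
Metropolis criterion actually sees keeps early exploration and a genuinely
greedy tail. The probe and the whole trajectory consume a private RNG
stream seeded by the `seed` argument; no global RNG state is read or
written anywhere in the package, and identical seeds give bit-identical
trajectories. The current state's prediction is cached, so each step
costs exactly one predictor call.

**Gradient descent.** The optimization variable is a logit matrix;
$P = \operatorname{softmax}(\text{logits})$ row-wise at temperature 1.
Motif rows are clamped to one-hot native letters and receive no
updates. A straight-through option (evaluate loss and gradient at the
hard argmax) is available but off by default: the soft path is the
better-behaved default on the smooth toy landscape, and which variant
published gradient protocols used is not stated in the available text,
so both are supported. The default init is a seeded
$\mathcal{N}(0, 0.5^2)$ logit draw.

**Staged protocols.** Stage $k+1$ starts from stage $k$'s best design;
a hard sequence entering a gradient stage is lifted to one-hot logits at
scale 8 (softmax effectively one-hot, gradients still finite), a
distribution entering MCMC hands over its argmax. This supports
protocols that first optimize a smoothed objective and then add sharper,
more specific terms, and each stage's configuration is recorded in the
result's provenance.

## The masked-region benchmark

For each input record, `n_masks` contiguous windows of `mask_length`
residues are drawn with starts uniform over the valid range, *with*
replacement — the protocol says "random masks" without an exclusion
rule, so the simplest interpretation is used. Masking replaces letters
with `"X"` and coordinates with `NA` sentinels, so a completer can only
leak native information through a bug, and the harness tests exactly
that fixed point: the oracle completer (returns the native record) must
score recovery 1.0 and fixed-region RMSD 0 on every (record, mask) pair.
A poly-alanine/ideal-helix baseline gives the floor any trained
completer must beat; its expected recovery is the native alanine content
of the masked windows, which the tests verify by direct counting. The
default protocol shape is 20 masks of length 30 per protein. Scoring
masks both channels by default; sequence-only and structure-only modes
cover the wider task taxonomy.

## Evaluation and filtering

`design_metrics()` reports mean pLDDT (whole design and motif region),
motif RMSD, and for complexes inter-PAE (mean over both off-diagonal
chain blocks — mean rather than median because the published text does
not say which; median is a config switch) and target-aligned binder RMSD
(superpose on the target chain only, then measure the binder without
re-superposition). `filter_designs()` applies strict inequalities
exactly as printed thresholds are written ("pLDDT > 80" fails at 80.0),
and is monotone: tightening a threshold never converts a fail to a pass.
An atom-level surface-hydrophobicity (SAP) criterion used in one
published campaign requires SASA machinery that is out of scope, so
criteria sets are applied without it.

## Numerical choices and degenerate inputs

* Kabsch superposition corrects reflections by sign-flipping the
  smallest singular direction; improper transforms only on request.
  Collinear/coincident point sets are *flagged* (`degenerate = TRUE`)
  rather than rejected, because sampled gap geometries can come
  arbitrarily close to collinear; the closed-form solution is still
  returned.
* Virtual Cβ placement uses the fixed ideal-geometry coefficients; the
  CA–Cβ distance is the constant 1.5268 Å, asserted as a regression.
  Cβ is always recomputed, never read from the file, so glycine and
  mutated positions behave identically.
* Bin assignment sends values exactly on an inner edge to the upper bin;
  clamping guards the end points.
* Entropy/KL computations clamp probabilities away from 0 before taking
  logs; the mixture-entropy derivative clamps $c \le 1 - 10^{-12}$
  (the derivative diverges at $c = 1$, which softmax distributions never
  reach).
* Residues missing any of N/CA/C are dropped at PDB ingest with a
  warning; duplicate (chain, residue, atom) records are an error.
  1-based inclusive numbering is the file-facing convention; everything
  internal is row-indexed.

## Problem sizes used in the shipped checks

The verification suite runs entirely on synthetic fixtures generated in
code: planted worlds of length 30 (motif of 5), superposition checks on
10-point clouds (100 instances), gradient checks on 16–30-residue
worlds against central finite differences (step $10^{-5}$), annealing
runs of 3000 steps over 10 seeds and gradient runs of 500 steps over 5
seeds for planted recovery, and benchmark tables of 20 masks × length 30
over 100-residue fixtures. These sizes were chosen so the full suite
exercises every code path at interactive turnaround.

## What passing the toy checks does and does not show

The planted landscape shares the *interfaces* of a real predictor
(distograms, pLDDT, PAE, chain boundaries) and the qualitative property
that confidence grows as the sequence approaches one the predictor
"likes", with local (windowed) sequence-structure coupling. It does not
model epistasis beyond the window, rugged or deceptive loss landscapes,
multiple competing basins, prediction noise, or any real
sequence-structure physics. Passing recovery tests therefore validates
the optimization and scoring machinery — determinism, gradient
correctness, loss bookkeeping, motif pinning — not the biological
quality of designs driven by a particular real predictor.

## Known limitations

Single-model PDB files only; no insertion codes, alternate locations or
mmCIF. No segment-order search over contigs. No learned background
distributions, no atom-level SASA, no novelty search against structure
or sequence databases. Real-network adapters must implement the
predictor contract themselves; only the toy predictor ships with the
package.
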