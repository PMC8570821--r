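---
title: "Methods: iterative elastic-network conformer sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative elastic-network conformer sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmpipe)
```

## The model and its assumptions

`enmpipe` samples conformational space by alternating three operations:
harmonic mode-space deformation, similarity clustering, and relaxation.
The underlying physical assumption is the elastic-network one: near a
reference conformation, the collective, low-frequency motions of a
biomolecule are well described by the softest normal modes of a uniform
spring network on its Cα atoms, irrespective of chemical detail.  Those
modes are good *directions* for large-scale deformation, but a harmonic
model says nothing about how far one can follow them; the pipeline
therefore takes deliberately modest steps (an exact Cα RMSD per
generation), repairs the resulting geometry by relaxation, and re-derives
the modes at each new conformer so the harmonic approximation is always
local.

The anisotropic network model used here is the standard one: springs of
uniform constant γ between Cα nodes within a cutoff R_c, Hessian
superelements −(γ/r²)·ddᵀ, and a spectrum whose six zero modes are exact
rigid-body motions of any non-degenerate 3-D network.  Nonrigid modes are
orthogonal to translations and rotations, which has a convenient
consequence exploited throughout: mode-space deformations change no
rigid-body coordinates, so the deformation RMSD can be computed and
rescaled *without* superposition.

For nucleic-acid chains the per-residue node is the P atom (C4′ when P is
absent, as in a 5′-terminal nucleotide); for protein residues it is Cα.
This one-node-per-residue choice keeps the network uniform across mixed
protein/nucleic complexes.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 15 | Å | ANM interaction range; common practice for Cα networks |
| `gamma` | 1 | arbitrary | uniform spring constant; rescales eigenvalues only |
| `n_modes` | 3 | — | softest nonrigid modes combined per deformation |
| `target_rmsd` | 1.0 | Å | exact Cα RMSD of each deformation step |
| `n_confs` | 50 | — | conformers generated per parent per generation |
| `maxclust` | 60 | — | representatives kept per generation |
| `linkage` | average | — | agglomeration rule for RMSD clustering |
| `n_gens` | 5 | — | generations; excursion grows with it |
| `k_bond`, `k_rep` | 100, 10 | energy/Å² | relaxation restraint/repulsion stiffness |
| `rep_cutoff` | 2.5 | Å | heavy-atom clash onset d₀ |
| `bond_detect_max` | 1.9 | Å | bond detection distance in the reference |
| `step_size` | 0.01 | Å | displacement of the highest-force atom per step |
| `max_steps`, `force_tol` | 500, 1e-3 | — | minimizer stopping rules |

Since γ is uniform, its value only scales the spectrum (a tested
invariant), and because every deformation is rescaled to `target_rmsd`
exactly, the *magnitude* of the mode coefficients is irrelevant — only
their direction matters.  The coefficients are therefore drawn uniformly
on [−1, 1], the simplest symmetric choice; eigenvalue-dependent (thermal)
weighting of modes is deliberately not applied, keeping the sampling
unbiased across the retained modes.  `n_modes = 3` is a pragmatic default:
the softest two or three modes carry most functional transitions in hinge
systems, and a small count keeps the random search low-dimensional.  All
of these are user-settable; none is fitted to data.

With `maxclust = 60` representatives per generation and five generations a
default run emits 300 conformers — the pipeline arithmetic (tested as
such) is `n_gens × min(maxclust, parents × n_confs)`.

## Relaxation backends

Deformed conformers have distorted bonds and occasional steric clashes.
The shipped backend is a *geometric* minimizer: bond-length restraints to
the reference topology (detected once, on the input structure: heavy-atom
pairs under 1.9 Å, plus consecutive Cα pairs for coarse-grained traces)
and a quadratic repulsion between nonbonded heavy-atom pairs closer than
d₀ = 2.5 Å.  Steepest descent with backtracking (halve the step whenever
the energy would rise; never accept an increase) makes the accepted energy
trace non-increasing *by construction* — an invariant the test suite
asserts on every run.  Hydrogens, when present in the input, are carried
through untouched but excluded from the repulsion list: d₀ is a heavy-atom
scale.

Full physical relaxation (force-field MD, implicit/explicit solvent,
temperature protocols) is out of the package's scope by design; it plugs
in through `register_relax_adapter()`, a contract requiring only "same
atoms in, same atoms out, finite energy".  The pipeline treats adapter
results exactly like built-in ones, and a mock adapter ships so the
orchestration is testable without any MD dependency.

## Determinism and seeding

All randomness flows from one `master_seed`.  Each (generation, parent)
pair gets its own derived stream seed via a fixed counter-based mixing
function, so results do not depend on the order in which parents are
processed, and an interrupted run resumed from its checkpoint reproduces
the uninterrupted result exactly.  Derived seeds stay below 2³¹ (R's
integer range); equal seeds give bit-identical ensembles, records and
output files — asserted in the tests by comparing PDB output byte for
byte.

## Numerical choices

* **Eigensolver.**  Full dense symmetric decomposition
  (`eigen(symmetric = TRUE)`); at the Cα-node sizes this package targets,
  a sparse/iterative solver is an optimization, not a contract.  Modes
  with eigenvalue below 1e-8 × (largest eigenvalue) are classified
  rigid-body; exactly six must appear, otherwise the network is degenerate
  (collinear or disconnected) and the input is *rejected*, not patched —
  a silent seventh zero mode would let rigid artifacts leak into the
  sampling.
* **Pairwise RMSD.**  Kabsch superposition with the proper-rotation sign
  fix, implemented in compiled code (RcppArmadillo) because pooled
  generations reach thousands of conformers (M² pairs).  The residual is
  computed by applying the rotation explicitly rather than via the
  singular-value trace identity, which loses ~√ε‖X‖ to cancellation and
  would spoil near-zero distances.
* **Medoids and ties.**  The representative is the member minimizing the
  summed within-cluster distance; ties resolve to the lowest conformer
  index, making clustering output deterministic and
  permutation-equivariant up to the tie rule.
* **Ensemble PCA.**  Conformers are iteratively superposed onto the
  running mean until the mean shifts by under `tol` (default 1e-6 Å); the
  reported mean is the flat-row mean of the aligned coordinates, so
  projecting the mean gives exactly zero and full-rank reconstruction is
  an identity.  Component signs follow the largest-entry-positive
  convention.
* **KDE bandwidth.**  Scott's rule per axis, h_j = σ̂_j·M^(−1/6) (the 2-D
  case of M^(−1/(d+4))); the kernel is a separable Gaussian product and
  the grid extends 4 bandwidths beyond the data so the map integrates to 1
  within truncation error (asserted at 1e-3).  A zero-variance dimension
  is an error with advice, not a silent fallback.
* **Degenerate inputs.**  Collinear selections (superposition), isolated
  nodes (ANM), empty selections, atom-count mismatches and non-finite
  coordinates all fail fast with messages naming the offending entity.

## The synthetic fixtures

`make_toy()` builds two geometries: an ideal α-helical Cα trace (1.5 Å
rise, 2.3 Å radius, 100° twist, ~3.8 Å consecutive Cα spacing) with one
pseudo side-chain atom (CB) per residue, and a two-domain system — two
such helices joined by an extended linker.  A 0.005 Å seeded jitter breaks
exact helical symmetry so mode spectra are non-degenerate.  The linker
zigzags widely in y and z: a straight (collinear-node) linker would give
the Cα network a near-zero torsion mode about the linker axis — rotation
of one domain about a line through its only attachment points costs almost
no spring energy — and that spurious seventh "zero mode" is precisely the
degeneracy the ANM stage is designed to reject.  The zigzag keeps the
twist a regular soft mode.

What the fixtures emulate: realistic Cα spacing, compact domains, a
hinge whose softest mode is the inter-domain motion (a tested property),
and the coarse-grained extension path (CB follows its residue's Cα).  What
they do not emulate: side-chain chemistry, sequence effects, realistic
energetics, solvent.  Green tests on fixtures therefore validate the
*algorithmic* contracts — spectra, exact step sizes, clustering, monotone
relaxation, determinism, lineage — not the biophysical realism of any
particular ensemble; on real proteins the quality of the ensemble also
depends on the relaxation backend used.

## Problem sizes used in the tests and the acceptance script

The suite runs on 8–40-residue toys: ANM oracle checks on ≤ 30 nodes,
a thousand seed-swept deformation draws, clustering oracles on ensembles
of ≤ 12 conformers, pipeline runs of 2–5 generations with 6–60 conformers
per parent, and a five-generation, 60-representative run for the
300-conformer arithmetic.  These sizes were chosen so the full suite
exercises every contract at desk scale in a couple of minutes; every
quantity the acceptance script reports is recomputed from scratch at run
time from these same generators.

## Known limitations

* The built-in relaxer restores local geometry (bonds, clashes); it is not
  a force field and does not produce thermodynamically weighted ensembles.
  Population maps over its output describe *where sampling went*, not free
  energy.
* Rigid-residue mode extension copies each residue's node displacement to
  all its atoms; side-chain internal motion is never generated by the
  deformation step and must come from the relaxation backend.
* The exact-RMSD step is computed in the parent frame (no superposition);
  this is exact for mode-space displacements but means `target_rmsd` is a
  step length, not a guaranteed superposed distance after relaxation.
* Selections implement a small grammar (`calpha`, `chain`, `resid`,
  `name`, `and`); inter-domain angle definitions (e.g. adenylate kinase's
  LID/NMP/CORE residue ranges) are inputs, not built-ins — published
  definitions vary and hard-coding one would be arbitrary.
* PDB parsing accepts the fixed-column dialect (first model, altloc
  ' '/'A', waters dropped); mmCIF is not supported.
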