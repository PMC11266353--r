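---
title: "Methods: comparative contact, interaction and fluctuation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative contact, interaction and fluctuation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajcontact)
```

## Scope and model

`trajcontact` compares two protein conformational ensembles — typically a
native protein and an analog differing in one chemically modified residue —
through five trajectory observables: residue contact-population maps and
their difference, geometric hydrogen-bond and aromatic π–π detection,
distance probability distributions, per-residue RMSF, and total pairwise
nonbonded energies. Input is the multi-model PDB format (topology from the
first model, one frame per model); binary trajectory formats, bond-order
perception and protonation assignment are out of scope.

Residues are indexed by *serial index*: position 1..R in chain-concatenated
file order. For an insulin-like two-chain system (21-residue A chain, then
30-residue B chain) this yields A1→1 … A21→21, B1→22 … B30→51. Gaps in
author numbering do not create gaps in serial indices; occurrence order in
the file is authoritative. A chemically modified residue (e.g. a
phenylalanine-conjugated B29 lysine, which this package names `FLK` and
accepts as HETATM records) occupies the same serial index as its native
counterpart, which is what makes the two systems comparable positionally.

## Contacts

Two residues are in contact in a frame when *any* pair of their
non-hydrogen atoms is within the cutoff (default 4.5 Å). This "any heavy
atom" reading is deliberately not a residue-COM criterion: it captures
side-chain-mediated proximity at the cost of being more permissive for
large residues. Distances use the minimum-image convention exactly when
the trajectory carries an orthorhombic box (CRYST1 with 90° angles);
structures stripped of box information are treated as non-periodic.
Sequence-adjacent pairs are included in the matrix (the full residue ×
residue grid is reported); display-level masking is left to the consumer.
The population map is the per-pair mean of the 0/1 per-frame contact
indicators, so a one-frame map is binary and populations are linear in the
frame schedule. "Stable contact" reporting defaults to population ≥ 0.5 —
present for most of the trajectory. Frame stride is a config option
(default 1, every frame).

## Hydrogen bonds and π–π interactions

PDB input carries no bond table, so donor hydrogens are attached
geometrically: an H within 1.2 Å of an N/O heavy atom. A hydrogen bond is
recorded when H···A ≤ 2.5 Å, D–H···A ≥ 120° and D···A ≤ 3.5 Å, over all
N/O donors and acceptors, excluding intra-residue pairs. These thresholds
are common geometric conventions, not fitted values; they are the
assumption-laden part of the analysis, all three are configurable
(`hbond_criteria()`), and the pipeline logs the criteria actually used.
Explicit hydrogens are required; the reader refuses H-bond analysis
otherwise rather than guessing protonation.

Aromatic rings come from name templates (PHE/TYR 6-ring, TRP 5+6, HIS
variants 5-ring, plus user templates for nonstandard residues; `FLK` is
built in). Ring planes are fitted by SVD (smallest principal axis of the
centered ring coordinates) rather than a bond cross product, which is
robust to thermal ring puckering; rings with missing atoms are skipped with
a warning. A ring pair within 7 Å COM–COM distance is classified by the
unsigned interplanar angle, folded to [0°, 90°] because plane normals have
arbitrary sign: parallel ≤ 30°, T-shaped ≥ 60° (the CH/π geometry),
oblique between. The bounds are chosen so that a ~5 Å, near-perpendicular
pair — the geometry of interest for a conjugated aromatic against a
tyrosine ring — is T-shaped. CH/π contacts are not detected as a separate
class. One consequence of folding worth knowing: angles designed as
N(90°, s²) realize with mean 90° − s·√(2/π) (a folded normal), not 90°.

## Distance distributions

Distances between a named atom or a ring COM (mass-weighted, per frame)
are histogrammed with bin edges aligned to absolute multiples of the bin
width (default 0.1 Å), so binning does not depend on the data minimum, and
normalized to unit mass. Peaks are local maxima ranked by topographic
prominence with the histogram tails treated as zero; the default
prominence floor of 0.05 (5 % of probability mass) is what makes "one
prominent peak" operational — a perfectly flat distribution yields no
peaks, a single occupied bin yields one with prominence 1. Kernel density
estimates and free-energy transforms are intentionally absent.

## Superposition and RMSF

`align_trajectory()` removes global rigid motion by unit-weight Kabsch
superposition of each frame onto the mean structure, recomputing the mean
and fitting once more (two passes). The Kabsch fit corrects reflections by
flipping the smallest singular vector, and degenerate (coincident) point
sets return the identity. RMSF is the root of the time-mean squared
displacement from the time-mean position — the standard definition, stable
to the choice of any single reference frame — computed on Cα by default or
mass-combined over heavy atoms.

Two numerical facts shape how RMSF should be read here. First, fitting
absorbs six rigid degrees of freedom: with K effectively independent
fitting units the recovered fluctuation shrinks by ≈ √(1 − 6/(3K)), which
is ~2 % for a 51-residue Cα fit and under 0.5 % for an all-heavy-atom fit.
The package's closed-form validation (isotropic jitter σ per coordinate ⇒
RMSF = σ√3) therefore checks the estimator on a motion-free fixture, and
checks alignment separately. Second, residues undergoing large designed
displacements (the generator's scheduled contacts) corrupt a fit that
includes them; the fixture manifest records these mobile residues so a fit
selection excluding them can be built, and `align_trajectory()` accepts
explicit atom indices for exactly this purpose. Both points apply equally
to real trajectories with mobile termini; excluding flexible regions from
the fit is available but off by default.

## Nonbonded energies

Per frame, Coulomb `k_e q_i q_j / r_ij` with `k_e = 332.0636
kcal·Å/(mol·e²)` (the AMBER-family constant) and Lennard-Jones
`4ε_ij[(σ_ij/r)¹² − (σ_ij/r)⁶]` with Lorentz–Berthelot combining are
summed over all non-excluded pairs, with no distance cutoff and no 1–4
scaling. With no bond table, the exclusion list defaults to all
intra-residue pairs plus backbone (C, O, N, H, CA) pairs bridging
consecutive residues of a chain — enough to remove the absurd bonded
Coulomb terms without full topology. A non-excluded pair closer than
0.1 Å is treated as a clash and is an error. These totals are a
*self-consistent comparative metric*: with identical exclusion schemes on
both systems, differences are meaningful, but no attempt is made to
reproduce a simulation engine's bookkeeping (no Ewald, no solvent, no
scaling conventions), and agreement with engine-reported energies is not
claimed. Parameters come from a TSV (`chain resnum atom_name q sigma
epsilon`, `*` wildcards in chain/resnum, specific rows winning over
wildcards).

## The synthetic generator

`generate_fixture()` emulates the *statistical structure* of a real
comparison at toy scale, not its physics. Residues are minimal rigid
templates (N, H, CA, C, O, plus an ideal 1.39 Å-radius hexagon for
aromatics) on a 22 Å lattice, so undirected pairs can never interact.
Directives realize designed truths:

- **Contacts**: the mobile residue's backbone N is placed a designed
  distance (default 4.2 Å) from the anchor's Cα, radially oriented, in an
  exactly `round(p·F)`-frame subset chosen by seeded shuffle — populations
  are exact by construction, while geometric jitters stay stochastic.
- **Hydrogen bond**: explicit D–H···A geometry with the H···A distance
  drawn from N(mean, sd²) (default 2.0 ± 0.15 Å) and the angle jittered
  off 180° by a folded normal (default sd 5°).
- **Ring pair**: two hexagons with COM separation N(5.0, 0.3²) Å and
  interplanar angle N(90°, 5°²) by default.
- **Fluctuation**: per-residue rigid isotropic Gaussian displacement
  (default σ = 0; opt-in per residue), under whole-frame rigid motion
  (default 0.5 Å translation, 3° rotation sd).

Directive-mobile residues are exempt from the fluctuation jitter; this is
what keeps designed contact populations exact rather than approximately
realized, and it is why the RMSF story of `insulin_like_pair()` lives on
terminal residues (A1, A2, B26, B28, B30; σ 0.6 Å reference vs 0.3 Å
variant) that carry no directives. Directions for directive placement come
from a fixed well-separated set (cube diagonals), with radii chosen so
that simultaneously placed partners of one hub residue stay above the
contact cutoff from each other — the designed contact set is exactly the
realized one, which the tests assert. A residue moved by two directives is
a specification error.

What the generator does *not* emulate: chain connectivity, excluded
volume, realistic side chains, solvent, or correlated motions. Passing
tests on these fixtures therefore demonstrates correctness of the
*measurement machinery* (populations, geometry, distributions, RMSF
closed forms, energies) — not that the package's defaults are optimal for
any particular real system.

## Problem sizes and determinism

The validation suite uses 51-residue (~270-atom) systems at 10–1500
frames for contact/interaction/pipeline checks, and 5000-frame fixtures
for distribution-peak and RMSF closed-form checks, where sampling error
(~1 % relative at 5000 frames for an RMSF estimate) sits comfortably
inside the stated tolerances. All stochastic generation is seeded and
restores the caller's RNG state; a fixed seed reproduces byte-identical
PDB output, and the analysis pipeline itself draws no random numbers, so
`run_compare()` is byte-deterministic in its inputs.

## Known limitations

- Only orthorhombic boxes; triclinic CRYST1 records drop the box.
- Hydrogen-bond and π–π thresholds are conventions, not fitted to any
  target system; conclusions sensitive to them should be re-run across a
  threshold range.
- The energy model is comparative only (see above).
- Atom-level contact maps and distance-weighted (soft) contacts are not
  provided; the contact indicator is binary at a hard cutoff.
- `insulin_like_pair()` is a synthetic stand-in with designed ground
  truth, not actual insulin coordinates.
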