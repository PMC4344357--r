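---
title: "Packing-density-normalized B-factors for spotting site-specific radiation damage"
author: "BDamage package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Packing-density-normalized B-factors for spotting site-specific radiation damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BDamage)
```

## The problem

X-ray data collection damages protein crystals. Beyond the global decay of
the diffraction pattern, certain chemical groups are chemically altered in
a reproducible, site-specific way: disulfide bridges elongate and break,
glutamate and aspartate side chains lose their carboxylates, methionine
Sδ—Cε bonds are cleaved. A refined coordinate model deposited without dose
information gives its users no direct way to tell whether, and where, such
damage is present.

The only per-atom quantity routinely available in a deposited model that
responds to this disorder is the isotropic B-factor (atomic displacement
parameter, Å²). Raw B-factors, however, are dominated by packing density:
atoms in densely packed regions systematically show lower B than atoms
near the surface, so an elevated B is not by itself evidence of damage.

## The metric

This package computes a per-atom, packing-normalized quantity. For an atom
$a$ with isotropic B-factor $B_a$,

$$ B_{\mathrm{Damage}}(a) \;=\; \frac{B_a}{\left\langle B_s \right\rangle_{s \in S(a)}} $$

where $S(a)$ is the set of all non-hydrogen protein atoms *of the same
structure* whose packing environment resembles that of $a$. Packing is
measured by the atomic contact number (ACN): the number of non-hydrogen
protein atoms within a fixed radius of the atom, counting symmetry-related
copies of the molecule in the crystal lattice, since damage happens in the
crystal, not to an isolated molecule. Two atoms share a packing
environment when their ACNs fall into the same fixed-width bin
(`floor(acn / binWidth)`).

Values near 1 are unremarkable; values well above 1 mark atoms more
disordered than their packing predicts — candidate damage sites. By
construction the mean over all analysed atoms is exactly 1, so the metric
is relative within one structure, and comparisons between structures go
through group medians, not means.

## Parameters and their defaults

* **Contact radius, 14 Å.** Small radii (6–8 Å) see mostly local residue
  geometry and give a narrow ACN spread, which makes the binning noisy;
  very large radii blur packing across the molecule. At 14 Å contact
  numbers typically span ~100–600, wide enough to partition into many
  populated bins. The pipeline accepts any radius; the suite checks that
  results at 8, 13 and 13.5 Å rank atoms consistently with the 14 Å
  default (Spearman ρ > 0.5 on the standard fixture).
* **Bin width, 10 contacts.** Fixed-width integer binning of ACN. Too-fine
  bins introduce noise (few atoms per bin); too-coarse bins mix genuinely
  different environments. Bins holding fewer than 10 atoms trigger a
  warning listing the bins, never silent merging: the bin structure is
  part of the metric's definition.
* **Bounding-box buffer = radius.** Symmetry copies are generated for the
  whole space group, translated into the 26 neighbouring unit cells, and
  trimmed to the model's axis-aligned bounding box expanded by the buffer.
  A buffer below the radius would silently undercount contacts and is an
  error. When the buffer exceeds the smallest cell edge (tiny cells) the
  26-cell rule may not reach every relevant copy; the package keeps the
  rule and warns.

## Preprocessing policy

Before any computation: hydrogens (and deuteriums) are removed, as are
zero-occupancy atoms; of each alternate-conformer set exactly one member
survives — the first conformation with the highest occupancy, ties broken
by file order; waters and non-protein heteroatoms are removed by default
(`keepHetero`/`keepWaters` restore them) because the normalization set is
defined over protein atoms. Partial occupancies above zero are kept and
their B-factors are used unweighted; the metric's definition does not
occupancy-weight, and refined partial occupancies are rare (a few percent
of atoms). Anisotropic records are discarded — the isotropic B on the ATOM
record is always the input. Multi-model (NMR-style) files are rejected.

Two deliberate choices the file format leaves open:

* **Normalization set = asymmetric unit.** Symmetry copies contribute to
  the contact counts but never to the B-factor averages: the set $S$ is
  restricted to the deposited model, so the metric never mixes B-factors
  across crystallographically equivalent copies (which are identical
  anyway) or across neighbouring molecules.
* **Self-inclusion.** The bin mean includes the atom itself. Excluding it
  would break the exact mean-equals-1 identity that anchors the metric's
  interpretation and the whole-structure comparisons.

## Numerical choices

* The contact-distance comparison is inclusive (`<= radius`); an atom is
  never its own contact.
* Bin means accumulate in double precision; the mean-1 identity is
  asserted to 1e-9 *relative*, with no looser fallback.
* Distance work may be accelerated (the implementation vectorizes in
  chunks) but must agree *exactly* — integer for integer — with an
  all-pairs brute-force count; the suite enforces this on 50 random
  crystals per run.
* Dihedral angles use the IUPAC sign convention and live in (−180°, 180°].
  An angle of exactly 0° or ±180° carries no sign, so a disulfide with
  such an angle is reported "unclassifiable" rather than silently
  assigned.
* Solvent accessibility uses a deterministic golden-section spiral of
  sample points (default 960 per atom), not random sampling, so areas are
  bit-reproducible; the two-sphere closed form is matched to <1% at the
  default point count.

## The disulfide taxonomy

A cystine bridge is described by five dihedral angles
χ₁ (N–Cα–Cβ–Sγ), χ₂ (Cα–Cβ–Sγ–Sγ′), χ₃ (Cβ–Sγ–Sγ′–Cβ′) and their primed
counterparts from the other side. The sign of χ₃ sets the handedness (LH
if negative). The signs of χ₂ and χ₂′ relative to χ₃ set the basic group:
both concordant — *spiral*; both discordant — *staple*; exactly one —
*hook*. The χ₁/χ₁′ signs then prefix the label ("−", "+", or a mixed
prefix).

A bond can be read from either cysteine, so labels must be canonical under
reversal. Reversal swaps (χ₁, χ₂) with (χ₁′, χ₂′). For spirals and staples
the χ₂ pattern is symmetric, so a mixed χ₁ pair is a single class, written
"+/−". For hooks the reading direction can be fixed intrinsically — this
package reads the end whose χ₂ sign agrees with χ₃ first — which makes the
two mixed χ₁ orders genuinely distinct classes, written "+/−" and "−/+".
Counting orbits of the 32 sign patterns under reversal (Burnside:
(32 + 8)/2) gives 20 types — 6 spirals, 8 hooks, 6 staples — which
`enumerateDisulfideTypes()` reproduces by direct classification. The
mixed-prefix notation for hooks is this package's construction; published
type lists name the 20 classes but not a canonicalization rule.

Classification uses only the signs of the angles, not their magnitudes;
magnitude-refined subtypes are out of scope. Bond detection trusts SSBOND
records when present and otherwise pairs Sγ atoms greedily by shortest
distance up to 2.5 Å (covalent S–S ≈ 2.05 Å plus refinement slack).

## Solvent accessibility

Per-atom accessible areas come from rolling a 1.4 Å probe over van der
Waals spheres, realized as sphere-point sampling: a point on the expanded
sphere counts as accessible if it lies outside every other atom's expanded
sphere. Relative accessibility divides a residue's summed atom areas by an
extended-state (Gly-X-Gly) reference for its residue type. The van der
Waals radii and reference areas ship with the package as fixed tables;
they are one defensible choice among several in the literature, so
regressions against accessibility from a different program will differ
slightly in slope — an externally computed per-residue table can be
imported verbatim (`readAccessibilityCSV()`) when exact compatibility
matters. Accessibility is computed on the isolated model, without
symmetry neighbours, matching the per-molecule convention.

## Statistics

Low-dose/high-dose comparisons use Welch two-sample t-tests (means under
unequal variances), the Brown–Forsythe variant of Levene's test (variance
equality, median-centred — robust for the right-skewed metric), and
ordinary least-squares regression with slope significance from the
t(n − 2) distribution. All p-values are two-sided and uncorrected for
multiple testing; the comparison report exposes raw numbers. The kernel
density overlay (`plotDamageDensity()`) is presentation-only: Gaussian
kernel, reference-rule bandwidth, no statistic derived from it.

Since the whole-structure mean of the metric is pinned at 1, a Welch test
over *all* atoms of two structures is a null comparison by construction
(p = 1 up to floating point); the informative signals are group medians,
group variances, and susceptible-group shifts.

## The synthetic fixture: what it emulates, what it does not

`makeSyntheticCrystal()` builds the stated world every validation runs in:
a pseudo-peptide chain (backbone N/Cα/C/O, Cβ on non-glycines, Sγ on every
10th residue, which is a cysteine) grown as a self-avoiding random walk
inside a sphere sized at ~115 Å³ per residue — a typical protein packing
volume — and placed in a P1 cubic cell with a 6 Å solvent gap, so lattice
neighbours create realistic surface contacts. B-factors are assigned as

```
B = max(1, baseB − acnSlope · ACN + N(0, noiseSd))
```

with `baseB = 60` Å², `acnSlope = 0.08` Å² per contact and
`noiseSd = 2` Å²: with contact numbers spanning roughly 100–600 this
yields B between about 12 and 52, inside the 0–80 Å² range typical of
deposited models, and encodes the documented negative packing trend.
Damage is injected by multiplying the B of a selected group (default
`CYS:SG`) by a factor (default 1.5, the magnitude of a clear but not
cartoonish specific-damage signal). These defaults were chosen once, on
the grounds above, and are not tuned against test outcomes.

Because B is *constructed* from packing, raw B-factors confound damage
with density: a damaged Sγ in a dense core can have a lower B than an
undamaged surface atom. The core validation exploits exactly this — on the
seed-1, 300-residue fixture, ranking atoms by the normalized metric
recovers the flagged atoms with AUC > 0.9 while raw B must do at least 0.1
worse.

What the generator does not emulate: real backbone geometry and side-chain
rotamers, residue-type composition, anisotropic disorder, solvent
structure, resolution-dependent B-factor error, or dose-response kinetics.
A green test on the fixture therefore establishes that the implementation
computes the metric correctly and that the metric separates
packing-confounded damage *in a world where its assumptions hold* — it
does not certify detection power on any particular real structure.

## Space-group support

No crystallographic symmetry library is available to this package's
dependency set, so it carries its own table of Hermann–Mauguin symbols to
operator lists for the common macromolecular (Sohncke) space groups —
52 entries covering the lattice types that dominate deposited protein
crystals. The table is validated in the test suite by group axioms:
identity present, closure under composition modulo lattice translations,
and proper rotations only. Unknown symbols raise an error naming the
symbol; there is deliberately no silent P1 fallback. Non-crystallographic
symmetry (MTRIX/BIOMT) is out of scope.

## Known limitations

* The metric needs per-atom refined isotropic B-factors; structures with
  grouped or TLS-only B, multiple models, or extensive unmodelled regions
  are outside its assumptions (unmodelled regions corrupt both the
  normalization averages and the contact counts).
* Anisotropic displacement information is ignored by design.
* A single whole-structure damage score is not provided; the metric is
  per-atom, and summaries are per selected group.
* Cells smaller than the contact radius trigger the 26-cell warning; such
  crystals (not seen for real proteins) would need a wider translation
  search.
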