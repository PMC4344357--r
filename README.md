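# BDamage

Site-specific radiation damage leaves fingerprints in refined protein
crystal structures — elongated or broken disulfides, decarboxylated Glu/Asp
side chains, cleaved Met Sδ–Cε bonds — but a deposited PDB model carries no
dose information, and the one per-atom observable that responds to the
damage, the isotropic B-factor, is dominated by packing density: buried
atoms have systematically lower B than surface atoms, so a high B is not by
itself evidence of damage.

**BDamage** computes a packing-normalized damage metric for every
non-hydrogen protein atom of a structure:

$$ B_{\mathrm{Damage}}(a) = \frac{B_a}{\langle B_s\rangle_{s\in S(a)}}, $$

where $S(a)$ is the set of atoms of the *same* structure in a similar
packing environment. Packing is measured by the atomic contact number
(ACN): the number of non-hydrogen protein atoms within 14 Å, counting
crystal symmetry mates (the molecule is damaged in its lattice, not in
isolation), and atoms are pooled into ACN bins of width 10. The metric's
mean over the structure is exactly 1; atoms well above 1 are more
disordered than their packing predicts — candidate damage sites.

The package is aimed at crystallographers inspecting single structures for
damage-mediated artefacts and at anyone doing statistical surveys of
specific damage across many deposited models. It provides:

* fixed-column PDB input/output with the standard curation rules
  (hydrogens, zero-occupancy atoms, alternate conformers, hetero atoms);
* space-group symmetry expansion into the 26 neighbouring unit cells with
  a buffered bounding-box trim;
* atomic contact numbers, packing bins, and the B_Damage metric itself;
* disulfide-bond detection, the five bridge dihedrals, and classification
  into the 20 spiral/hook/staple types;
* a rolling-probe (1.4 Å) solvent-accessibility calculator with
  extended-state relative areas;
* the validation statistics used for low-dose/high-dose comparisons:
  Welch t-tests, median-centred Levene (Brown–Forsythe) tests, simple
  linear regression with t(n−2) slope significance;
* a synthetic-crystal generator with known ground truth, so the whole
  pipeline is testable without downloading anything.

## Worked example

A 300-residue synthetic crystal with a 1.5× damage multiplier on its
cysteine Sγ atoms, run through the full pipeline:

```r
library(BDamage)
sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 300, seed = 1))
res <- suppressWarnings(bdamagePipeline(sim$model))
res
#> BDamageResult: 1480 atoms, radius 14.0 A, bin width 10
#>   B_Damage mean 1.000000, median 0.9921, max 1.6185 (CYS A 60 SG)

summarizeGroup(res, "CYS:SG")
#>    n meanBDamage medianBDamage varBDamage meanB medianB  varB
#> 1 30       1.456         1.494     0.0224 50.51   52.72 252.6
```

The structure-wide mean is 1 by construction, and the most suspicious atom
is a cysteine sulfur — one of the atoms the generator actually damaged.
The damaged group's median metric (1.49) sits close to the injected 1.5×
multiplier, while its raw B-factors (mean 50.5 Å², variance 253) are
buried inside the undamaged range and rank the damaged atoms much worse:

```r
rankAUC <- function(score, flagged) { r <- rank(score)
    (sum(r[flagged]) - sum(flagged) * (sum(flagged) + 1) / 2) /
        (sum(flagged) * sum(!flagged)) }
rankAUC(bdamage(res), sim$groundTruth$flagged)   #> 0.967
rankAUC(atoms(res)$bIso, sim$groundTruth$flagged) #> 0.818
```

Annotated outputs (`writeBDamageCSV()`, `writeBDamagePDB()` with the
metric in the temperature-factor column for colour-by-B viewing,
`writeBinTableCSV()`) and a command-line wrapper
(`inst/scripts/bdamage-cli.R` with `compute`, `disulfides`, `sasa`,
`compare`, `simulate` and `enumerate-types` subcommands) round out the
pipeline. The disulfide taxonomy is available directly:

```r
classifyDisulfide(c(-60, -60, -85, -60, -60))$label  #> "-LHSpiral"
length(enumerateDisulfideTypes())                    #> 20
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's two headline acceptance
quantities from scratch against the installed package: the mean of the
metric over all analysed atoms of a freshly generated synthetic crystal
(the normalization identity), and the number of distinct disulfide type
labels obtained by classifying all 32 dihedral sign patterns. Run it from
the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/bdamage-methods.Rmd`) describes the
metric, every tunable parameter and its default, the preprocessing and
canonicalization rules, the synthetic fixture's stated world and its
limits, and the package's numerical guarantees.
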