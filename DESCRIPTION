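Package: BDamage
Title: Packing-Density-Normalized B-Factor Analysis of Site-Specific
    Radiation Damage in Protein Crystal Structures
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the B_Damage metric, a per-atom isotropic B-factor
    normalized by the mean B-factor of atoms in a similar packing-density
    environment of the same crystal structure, which flags candidate sites
    of specific radiation damage in refined X-ray protein structure models.
    Provides fixed-column PDB input/output with the associated preprocessing
    rules (hydrogen, zero-occupancy and alternate-conformer filtering),
    crystallographic symmetry expansion into the 26 neighbouring unit cells,
    atomic contact number packing profiles, disulfide-bond dihedral
    extraction and classification into the 20 spiral/hook/staple types,
    a rolling-probe solvent-accessibility calculator, the Welch/Levene/
    regression statistics used to compare low- and high-dose structures,
    and a synthetic-crystal generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'spacegroups.R'
    'unitcell.R'
    'pdb-io.R'
    'preprocess.R'
    'crystal-context.R'
    'packing.R'
    'selectors.R'
    'bdamage.R'
    'disulfide.R'
    'sasa.R'
    'damage-stats.R'
    'synthetic.R'
    'plots.R'
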