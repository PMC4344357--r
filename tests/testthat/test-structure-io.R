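test_that("a minimal PDB with CRYST1 and ANISOU records parses correctly", {
    lines <- c(
        "CRYST1   50.000   60.000   70.000  90.00  90.00  90.00 P 21 21 21   4",
        "SSBOND   1 CYS A    6    CYS A  127",
        "ATOM      1  N   ALA A   1      11.104  13.207   9.500  1.00 15.02           N",
        "ATOM      2  CA  ALA A   1      12.560  13.300   9.400  0.50 16.10           C",
        "ANISOU    2  CA  ALA A   1     2406   1892   1614    198    519   -328       C",
        "HETATM    3  O   HOH A 201      20.000  21.000  22.000  1.00 30.00           O")
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(lines, f)
    mod <- readPDB(f)
    at <- atoms(mod)
    expect_equal(nrow(at), 3L)
    expect_equal(at$name, c("N", "CA", "O"))
    expect_equal(at$x, c(11.104, 12.560, 20.000))
    expect_equal(at$occ, c(1, 0.5, 1))
    # isotropic B comes from the ATOM record; ANISOU is discarded but noted
    expect_equal(at$bIso[2], 16.10)
    expect_true(mod@metadata$hasAnisou)
    expect_equal(at$isProtein, c(TRUE, TRUE, FALSE))

    cl <- unitCell(mod)
    expect_equal(c(cl@a, cl@b, cl@c), c(50, 60, 70))
    expect_equal(cl@spaceGroup, "P 21 21 21")

    sb <- mod@metadata$ssbonds
    expect_equal(nrow(sb), 1L)
    expect_equal(sb$resSeq1, 6L)
    expect_equal(sb$resSeq2, 127L)
})

test_that("malformed and multi-model files are rejected with useful errors", {
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(c(
        "ATOM      1  N   ALA A   1      11.104  13.207   XXXXX  1.00 15.02           N"),
        f)
    expect_error(readPDB(f), "line 1")
    writeLines(c("MODEL     1", "ENDMDL", "MODEL     2", "ENDMDL"), f)
    expect_error(readPDB(f), "multi-model")
    expect_error(readPDB(file.path(tempdir(), "does-not-exist.pdb")),
                 "cannot read")
})

test_that("write/read round trip preserves the atom table byte for byte", {
    sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 25, seed = 11))
    f <- withr::local_tempfile(fileext = ".pdb")
    writePDB(sim$model, f)
    back <- readPDB(f)
    a1 <- atoms(sim$model)
    a2 <- atoms(back)
    for (col in c("serial", "name", "resName", "chain", "resSeq",
                  "x", "y", "z", "occ", "bIso", "element"))
        expect_equal(a2[[col]], a1[[col]], info = col)
    # determinism: the same seed regenerates the same file
    f2 <- withr::local_tempfile(fileext = ".pdb")
    writePDB(makeSyntheticCrystal(syntheticSpec(nResidues = 25,
                                                seed = 11))$model, f2)
    expect_identical(readLines(f), readLines(f2))
})

test_that("preprocessing applies the hydrogen/occupancy/altloc rules", {
    mod <- makeModel(
        name = c("N", "H", "CA", "CA", "CB", "O", "S"),
        resName = c("ALA", "ALA", "ALA", "ALA", "ALA", "HOH", "SO4"),
        resSeq = c(1, 1, 1, 1, 1, 90, 91),
        x = 1:7, y = 1:7, z = 1:7,
        element = c("N", "H", "C", "C", "C", "O", "S"),
        altLoc = c("", "", "A", "B", "", "", ""),
        occ = c(1, 1, 0.4, 0.6, 0, 1, 1),
        recordType = c(rep("ATOM", 5), "HETATM", "HETATM"),
        metadata = list(preprocessed = FALSE))
    out <- preprocessStructure(mod)
    at <- atoms(out)
    expect_equal(nrow(at), 2L)                       # N + winning CA
    expect_false(any(at$isHydrogen))
    expect_false(any(at$occ == 0))                   # zero-occ CB removed
    expect_equal(at$altLoc[at$name == "CA"], "B")    # higher occupancy wins
    counts <- out@metadata$removedCounts
    expect_equal(nrow(atoms(mod)) - nrow(at), sum(unlist(counts)))

    # equal occupancies: the first altloc in file order is kept
    tie <- makeModel(name = c("CA", "CA"), resName = "ALA", resSeq = 1,
                     x = 1:2, y = 1:2, z = 1:2, element = "C",
                     altLoc = c("A", "B"), occ = 0.5,
                     metadata = list(preprocessed = FALSE))
    expect_equal(atoms(preprocessStructure(tie))$altLoc, "A")

    # idempotence
    out2 <- preprocessStructure(out)
    expect_equal(atoms(out2), atoms(out))

    # everything filtered away is an error
    allH <- makeModel(name = "H", resName = "ALA", x = 1, y = 1, z = 1,
                      element = "H", metadata = list(preprocessed = FALSE))
    expect_error(preprocessStructure(allH), "no atoms survive")
})

test_that("hetero and water retention flags are honoured", {
    mod <- makeModel(
        name = c("CA", "O", "FE"),
        resName = c("ALA", "HOH", "HEM"),
        resSeq = c(1, 90, 91),
        x = 1:3, y = 1:3, z = 1:3,
        element = c("C", "O", "FE"),
        recordType = c("ATOM", "HETATM", "HETATM"),
        metadata = list(preprocessed = FALSE))
    expect_equal(nrow(atoms(preprocessStructure(mod))), 1L)
    expect_equal(nrow(atoms(preprocessStructure(mod, keepHetero = TRUE))),
                 2L)
    expect_equal(nrow(atoms(preprocessStructure(mod, keepHetero = TRUE,
                                                keepWaters = TRUE))), 3L)
})

test_that("B_Damage PDB output uses the temperature-factor column", {
    sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 20, seed = 5))
    mod <- preprocessStructure(sim$model)
    res <- suppressWarnings(
        computeBDamage(mod, computeACN(expandToCrystal(mod))))
    f <- withr::local_tempfile(fileext = ".pdb")
    writeBDamagePDB(mod, res, f)
    lines <- grep("^ATOM", readLines(f), value = TRUE)
    written <- as.numeric(substr(lines, 61, 66))
    expect_equal(written, bdamage(res), tolerance = 0.01 / min(bdamage(res)))
    expect_true(all(abs(written - bdamage(res)) <= 0.005 + 1e-9))
    # companion CSV preserves the original B
    comp <- read.csv(paste0(f, ".b_iso.csv"))
    expect_equal(comp$b_iso, atoms(mod)$bIso)

    # field overflow and empty results are refused
    res2 <- res
    res2@atoms$bIso[1] <- res2@atoms$binMeanB[1] * 1200
    res2@atoms$bdamage[1] <- 1200
    expect_error(writeBDamagePDB(mod, res2, f), "1000")
    res0 <- new("BDamageResult", atoms = res@atoms[0, ],
                binTable = res@binTable[0, ], radius = 14, binWidth = 10L)
    expect_error(writeBDamagePDB(mod, res0, f), "empty")
})

test_that("per-atom CSV export is complete, ordered and re-parsable", {
    sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 20, seed = 5))
    mod <- preprocessStructure(sim$model)
    res <- suppressWarnings(
        computeBDamage(mod, computeACN(expandToCrystal(mod))))
    f <- withr::local_tempfile(fileext = ".csv")
    writeBDamageCSV(res, f)
    df <- read.csv(f)
    expect_equal(names(df), c("chain", "res_seq", "res_name", "atom",
                              "occupancy", "b_iso", "acn", "bin",
                              "bin_mean_b", "bdamage"))
    expect_equal(nrow(df), nrow(atoms(res)))
    expect_equal(df$bdamage, signif(bdamage(res), 9), tolerance = 1e-6)
    expect_equal(df$acn, acn(res))

    # an empty result still yields a header-only file
    res0 <- new("BDamageResult", atoms = res@atoms[0, ],
                binTable = res@binTable[0, ], radius = 14, binWidth = 10L)
    writeBDamageCSV(res0, f)
    expect_equal(nrow(read.csv(f)), 0L)
    expect_equal(length(readLines(f)), 1L)
})
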