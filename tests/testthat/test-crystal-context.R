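test_that("fractional/orthogonal conversion is exact and invertible", {
    cl <- unitCellNew(10, 20, 30, 90, 90, 90)
    expect_equal(fracToOrth(cl, c(0.5, 0.5, 0.5)), c(5, 10, 15))

    # a=b=c, right angles: the conversion matrix is a scalar times identity
    cube <- unitCellNew(42, 42, 42, 90, 90, 90)
    expect_equal(fracToOrth(cube, diag(3)), 42 * diag(3))

    # random round trips in a skewed cell
    set.seed(4)
    tric <- unitCellNew(31.1, 47.3, 25.2, 83.2, 95.7, 104.1)
    pts <- matrix(runif(300, -2, 2), ncol = 3)
    back <- orthToFrac(tric, fracToOrth(tric, pts))
    expect_equal(back, pts, tolerance = 1e-9)

    expect_error(unitCellNew(10, 10, 10, 1, 179, 1), "volume")
})

test_that("the space-group table is a closed group of proper operators", {
    modfrac <- function(v) v - floor(v + 1e-9)
    opkey <- function(op) paste(c(round(op$R), round(modfrac(op$t) * 12)),
                                collapse = ",")
    for (sg in knownSpaceGroups()) {
        ops <- spaceGroupOperators(sg)
        keys <- vapply(ops, opkey, "")
        expect_false(any(duplicated(keys)), info = sg)
        # identity present, all rotations proper (Sohncke: no mirrors)
        expect_true(any(vapply(ops, function(o)
            all(o$R == diag(3)) && all(modfrac(o$t) < 1e-9), TRUE)),
            info = sg)
        dets <- vapply(ops, function(o) det(o$R), 0)
        expect_true(all(abs(dets - 1) < 1e-9 | abs(dets + 1) < 1e-9),
                    info = sg)
        expect_true(all(dets > 0), info = sg)
        # closure under composition modulo lattice translations
        for (a in ops) for (b in ops) {
            k <- opkey(list(R = a$R %*% b$R, t = a$R %*% b$t + a$t))
            expect_true(k %in% keys, info = sg)
        }
    }
    expect_equal(length(spaceGroupOperators("P 21 21 21")), 4L)
    expect_equal(length(spaceGroupOperators("P212121")), 4L)  # spacing-blind
    expect_error(spaceGroupOperators("Q 5"), "unknown")
})

test_that("lattice expansion retains exactly the copies in the buffered box", {
    # single atom centred in a 50 A P1 cell: nearest copy is 50 A away,
    # the box only reaches 14 A out, so nothing survives
    far <- expandToCrystal(singleAtomModel(25, 25, 25, 50), buffer = 14)
    expect_equal(nrow(neighbours(far)), 0L)

    # 10 A P1 cell: every one of the 26 neighbouring-cell copies is in the
    # box (brute-force enumeration of the 27 - 1 translations)
    near <- suppressWarnings(
        expandToCrystal(singleAtomModel(5, 5, 5, 10), buffer = 14))
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * 10
    shifts <- shifts[rowSums(abs(shifts)) > 0, ]
    inBox <- rowSums(abs(shifts) <= 14) == 3
    expect_equal(nrow(neighbours(near)), sum(inBox))
    expect_equal(nrow(neighbours(near)), 26L)

    # warn when the buffer exceeds the smallest cell edge
    expect_warning(expandToCrystal(singleAtomModel(5, 5, 5, 10),
                                   buffer = 14), "smallest cell edge")
})

test_that("screw-axis symmetry generates the full general-position set", {
    mod <- singleAtomModel(3.1, 7.4, 11.8, 30, "P 21 21 21")
    ctx <- expandToCrystal(mod, buffer = 30)   # box swallows the whole cell
    nb <- neighbours(ctx)
    # general position in P212121: 4 images per cell; in the home cell the
    # identity copy is the original, leaving 3 symmetry mates
    ops <- spaceGroupOperators("P 21 21 21")
    frac <- c(3.1, 7.4, 11.8) / 30
    imgs <- t(vapply(ops, function(o) {
        v <- as.numeric(o$R %*% frac + o$t); v - floor(v) }, numeric(3)))
    expect_equal(nrow(unique(round(imgs, 9))), 4L)
    homeCell <- nb[nb$x >= 0 & nb$x < 30 & nb$y >= 0 & nb$y < 30 &
                   nb$z >= 0 & nb$z < 30, ]
    expect_equal(nrow(homeCell), 3L)
    expected <- fracToOrth(unitCell(mod), imgs)
    for (i in seq_len(nrow(homeCell))) {
        d <- sqrt(rowSums((expected - matrix(as.numeric(homeCell[i, 1:3]),
                                             4, 3, byrow = TRUE))^2))
        expect_lt(min(d), 1e-6)
    }
})

test_that("special-position images never duplicate an original atom", {
    # an atom on the twofold axes of P222 is fixed by every operator
    mod <- singleAtomModel(0, 0, 0, 20, "P 2 2 2")
    ctx <- expandToCrystal(mod, buffer = 20)
    nb <- neighbours(ctx)
    if (nrow(nb)) {
        d <- sqrt((nb$x - 0)^2 + (nb$y - 0)^2 + (nb$z - 0)^2)
        expect_true(all(d > 0.01))
    }
    expect_true(TRUE)
})

test_that("neighbour-distance multiset is invariant under lattice shifts", {
    sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 15, seed = 2))
    mod <- preprocessStructure(sim$model)
    distSorted <- function(m) {
        ctx <- expandToCrystal(m, buffer = 14)
        at <- atoms(m); nb <- neighbours(ctx)
        d <- numeric()
        for (i in seq_len(nrow(at)))
            d <- c(d, sqrt((nb$x - at$x[i])^2 + (nb$y - at$y[i])^2 +
                           (nb$z - at$z[i])^2))
        sort(round(d, 6))
    }
    shifted <- mod
    shifted@atoms$x <- shifted@atoms$x + unitCell(mod)@a
    expect_equal(distSorted(shifted), distSorted(mod))
})

test_that("expansion refuses models without crystallographic context", {
    noCell <- makeModel("CA", "ALA", 1, 1, 1, "C")
    expect_error(expandToCrystal(noCell), "no crystallographic context")
    badSG <- singleAtomModel(1, 1, 1, 20, "X 9 9 9")
    expect_error(expandToCrystal(badSG), "X 9 9 9")
})
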