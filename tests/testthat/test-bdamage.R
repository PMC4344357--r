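workedExampleResult <- function() {
    mod <- makeModel(name = c("CA", "CB", "CA", "CB"),
                     resName = "ALA", resSeq = c(1, 1, 2, 2),
                     x = 1:4, y = 1:4, z = 1:4, element = "C",
                     bIso = c(10, 20, 30, 40))
    prof <- new("PackingProfile", radius = 14, binWidth = 10L,
                acn = c(12L, 15L, 23L, 27L),
                binIndex = c(1L, 1L, 2L, 2L), atomIndex = 1:4)
    suppressWarnings(computeBDamage(mod, prof))
}

test_that("the worked normalization example evaluates exactly", {
    res <- workedExampleResult()
    expect_equal(bdamage(res), c(10, 20, 30, 40) / c(15, 15, 35, 35))
    expect_equal(bdamage(res), c(0.6667, 1.3333, 0.8571, 1.1429),
                 tolerance = 1e-4)
    expect_equal(mean(bdamage(res)), 1, tolerance = 1e-12)
    bt <- binTable(res)
    expect_equal(bt$binIndex, c(1L, 2L))
    expect_equal(bt$nAtoms, c(2L, 2L))
    expect_equal(bt$meanB, c(15, 35))
})

test_that("normalization identities hold: mean one, scale and bin behaviour", {
    sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 60, seed = 21))
    mod <- preprocessStructure(sim$model)
    prof <- computeACN(expandToCrystal(mod))
    res <- suppressWarnings(computeBDamage(mod, prof))
    expect_equal(mean(bdamage(res)), 1, tolerance = 1e-9)
    # an atom whose B equals its bin mean scores exactly 1
    hit <- which(abs(atoms(res)$bIso - atoms(res)$binMeanB) < 1e-12)
    if (length(hit)) expect_equal(bdamage(res)[hit], rep(1, length(hit)))

    # uniform scaling of every B leaves the metric unchanged
    scaled <- mod
    scaled@atoms$bIso <- scaled@atoms$bIso * 7.3
    res2 <- suppressWarnings(computeBDamage(scaled, prof))
    expect_equal(bdamage(res2), bdamage(res), tolerance = 1e-12)

    # chain relabeling leaves the metric unchanged
    relab <- mod
    relab@atoms$chain <- "Z"
    res3 <- suppressWarnings(computeBDamage(relab, prof))
    expect_equal(bdamage(res3), bdamage(res))

    # atoms sharing one bin with equal B all score 1
    flat <- makeModel(name = c("CA", "CA"), resName = "ALA",
                      resSeq = 1:2, x = 1:2, y = 1:2, z = 1:2,
                      element = "C", bIso = 12)
    pf <- new("PackingProfile", radius = 14, binWidth = 10L,
              acn = c(101L, 105L), binIndex = c(10L, 10L), atomIndex = 1:2)
    expect_equal(bdamage(suppressWarnings(computeBDamage(flat, pf))),
                 c(1, 1))
})

test_that("degenerate bins and mismatched profiles are refused", {
    mod <- makeModel(name = c("CA", "CA"), resName = "ALA", resSeq = 1:2,
                     x = 1:2, y = 1:2, z = 1:2, element = "C", bIso = 0)
    pf <- new("PackingProfile", radius = 14, binWidth = 10L,
              acn = c(101L, 105L), binIndex = c(10L, 10L), atomIndex = 1:2)
    expect_error(suppressWarnings(computeBDamage(mod, pf)), "all-zero")

    sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 20, seed = 3))
    mod2 <- preprocessStructure(sim$model)
    prof <- computeACN(expandToCrystal(mod2))
    wrong <- new("PackingProfile", radius = 14, binWidth = 10L,
                 acn = prof@acn[-1], binIndex = prof@binIndex[-1],
                 atomIndex = prof@atomIndex[-1])
    expect_error(computeBDamage(mod2, wrong), "does not cover")

    # sparse bins are reported, not silently accepted
    expect_warning(computeBDamage(mod2, prof), "sparse")
})

test_that("group summaries report order-independent robust statistics", {
    res <- workedExampleResult()
    s <- summarizeGroup(res, "*")
    expect_equal(s$n, 4L)
    expect_equal(s$medianBDamage,
                 median(c(10, 20, 30, 40) / c(15, 15, 35, 35)))

    sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 30, seed = 13))
    full <- suppressWarnings(bdamagePipeline(sim$model))
    sg <- summarizeGroup(full, "CYS:SG")
    expect_equal(sg$n, 3L)                 # residues 10, 20, 30
    # median agrees with an explicit sort-based oracle (even and odd n)
    v <- bdamage(full)
    sv <- sort(v)
    oracleMedian <- if (length(v) %% 2)
        sv[(length(v) + 1) / 2] else mean(sv[length(v) / 2 + c(0, 1)])
    expect_equal(summarizeGroup(full, "*")$medianBDamage, oracleMedian)
    expect_equal(summarizeGroup(full,
                                function(at) rep(TRUE, nrow(at)))$n,
                 length(v))
    expect_error(summarizeGroup(full, "TRP:NE1"), "TRP:NE1")
})

test_that("median deltas respond to injected group-specific damage", {
    sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 60, seed = 17,
                                              damageMultiplier = 1))
    mod <- preprocessStructure(sim$model)
    prof <- computeACN(expandToCrystal(mod))
    low <- suppressWarnings(computeBDamage(mod, prof))
    expect_equal(deltaGroupMedian(low, low, "CYS:SG"), 0)

    # doubling the selected group's B raises its median B_Damage
    damaged <- mod
    sel <- parseAtomSelector("CYS:SG")(atoms(mod))
    damaged@atoms$bIso[sel] <- damaged@atoms$bIso[sel] * 2
    high <- suppressWarnings(computeBDamage(damaged, prof))
    expect_gt(deltaGroupMedian(low, high, "CYS:SG"), 0)

    # a 1.5x multiplier shifts the group median by roughly the analytic
    # amount (0.5 x typical B_Damage, diluted by the bin means absorbing a
    # little of the inflation)
    sim15 <- makeSyntheticCrystal(syntheticSpec(nResidues = 60, seed = 17,
                                                damageMultiplier = 1.5))
    mod15 <- preprocessStructure(sim15$model)
    high15 <- suppressWarnings(computeBDamage(mod15,
                                              computeACN(expandToCrystal(mod15))))
    d <- deltaGroupMedian(low, high15, "CYS:SG")
    expect_gt(d, 0.2)
    expect_lt(d, 0.8)

    # mismatched parameters are refused
    prof8 <- computeACN(expandToCrystal(mod, buffer = 8), radius = 8)
    low8 <- suppressWarnings(computeBDamage(mod, prof8))
    expect_error(deltaGroupMedian(low8, high, "CYS:SG"), "different")
})

test_that("the metric is stable across contact radii", {
    sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 100, seed = 1))
    r14 <- suppressWarnings(bdamagePipeline(sim$model, radius = 14))
    for (r in c(8, 13, 13.5)) {
        alt <- suppressWarnings(bdamagePipeline(sim$model, radius = r))
        rho <- cor(bdamage(r14), bdamage(alt), method = "spearman")
        expect_gt(rho, 0.5)
    }
})

test_that("the full pipeline wrapper reproduces the explicit chain", {
    sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 25, seed = 19))
    mod <- preprocessStructure(sim$model)
    explicit <- suppressWarnings(
        computeBDamage(mod, computeACN(expandToCrystal(mod))))
    wrapped <- suppressWarnings(bdamagePipeline(sim$model))
    expect_equal(bdamage(wrapped), bdamage(explicit))
})
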