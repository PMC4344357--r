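#' Compute the B_Damage metric
#'
#' Divides each atom's isotropic B-factor by the mean B-factor of all
#' non-hydrogen protein atoms of the same structure that share its
#' packing-density bin (the atom itself included).  The resulting values
#' average exactly 1 over the structure; atoms with B_Damage well above 1
#' are more disordered than their packing environment predicts, a signature
#' of site-specific radiation damage.
#'
#' @param model the preprocessed [StructureModel-class].
#' @param profile the [PackingProfile-class] from [computeACN()]; it must
#'   cover exactly the model's non-hydrogen protein atoms.
#' @param minBinWarn bins holding fewer atoms than this trigger a warning
#'   (default 10; narrow bins make the normalization noisy).
#' @return a [BDamageResult-class].
#' @examples
#' sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 30, seed = 1))
#' mod <- preprocessStructure(sim$model)
#' prof <- computeACN(expandToCrystal(mod))
#' res <- suppressWarnings(computeBDamage(mod, prof))
#' mean(bdamage(res))  # 1 by construction
#' @seealso [summarizeGroup()], [writeBDamageCSV()]
#' @export
computeBDamage <- function(model, profile, minBinWarn = 10) {
    stopifnot(is(model, "StructureModel"), is(profile, "PackingProfile"))
    at <- model@atoms
    expect <- which(at$isProtein & !at$isHydrogen)
    if (!identical(as.integer(expect), profile@atomIndex))
        stop("packing profile does not cover exactly the model's ",
             "non-hydrogen protein atoms; recompute it from this model")
    if (length(expect) == 0L) stop("no protein atoms to analyse")

    sub <- at[expect, , drop = FALSE]
    bin <- profile@binIndex
    binMeans <- tapply(sub$bIso, bin, mean)
    binN <- tapply(bin, bin, length)
    if (any(binMeans == 0))
        stop("packing bin(s) ",
             paste(names(binMeans)[binMeans == 0], collapse = ", "),
             " have an all-zero mean B-factor; B_Damage is undefined")

    sparse <- names(binN)[binN < minBinWarn]
    if (length(sparse))
        warning("sparse packing bin(s) with fewer than ", minBinWarn,
                " atoms: ", paste(sparse, collapse = ", "),
                "; B_Damage is noisy for the ", sum(binN[sparse]),
                " atoms in them")

    binMeanB <- as.numeric(binMeans[as.character(bin)])
    resAtoms <- data.frame(
        chain = sub$chain, resSeq = sub$resSeq, iCode = sub$iCode,
        resName = sub$resName, name = sub$name, occ = sub$occ,
        bIso = sub$bIso, acn = profile@acn, binIndex = bin,
        binMeanB = binMeanB, bdamage = sub$bIso / binMeanB,
        stringsAsFactors = FALSE)
    rownames(resAtoms) <- NULL
    binTab <- data.frame(binIndex = as.integer(names(binN)),
                         nAtoms = as.integer(binN),
                         meanB = as.numeric(binMeans))
    binTab <- binTab[order(binTab$binIndex), , drop = FALSE]
    rownames(binTab) <- NULL
    new("BDamageResult", atoms = resAtoms, binTable = binTab,
        radius = profile@radius, binWidth = profile@binWidth)
}

#' Run the whole B_Damage pipeline on one model
#'
#' Convenience wrapper: preprocess, expand into the crystal lattice,
#' compute contact numbers and the B_Damage values.
#'
#' @param model a [StructureModel-class] (raw or preprocessed).
#' @param radius contact radius, Angstrom (default 14).
#' @param binWidth packing bin width (default 10).
#' @param buffer bounding-box buffer, Angstrom; defaults to \code{radius}.
#' @param keepHetero,keepWaters passed to [preprocessStructure()].
#' @param minBinWarn passed to [computeBDamage()].
#' @return a [BDamageResult-class].
#' @export
bdamagePipeline <- function(model, radius = 14, binWidth = 10,
                            buffer = radius, keepHetero = FALSE,
                            keepWaters = FALSE, minBinWarn = 10) {
    if (!isTRUE(model@metadata$preprocessed))
        model <- preprocessStructure(model, keepHetero = keepHetero,
                                     keepWaters = keepWaters)
    ctx <- expandToCrystal(model, buffer = buffer)
    prof <- computeACN(ctx, radius = radius, binWidth = binWidth)
    computeBDamage(model, prof, minBinWarn = minBinWarn)
}

#' Summary statistics of B_Damage over an atom group
#'
#' @param result a [BDamageResult-class].
#' @param selector a selector string (see [parseAtomSelector()]) or a
#'   predicate function on the result's atom table.
#' @return a one-row data.frame: \code{n}, mean/median/variance of
#'   \code{bdamage}, and mean/median/variance of \code{bIso}, for the
#'   selected atoms.  The median uses the midpoint of the two central
#'   values for even n.
#' @examples
#' sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 30, seed = 1))
#' res <- suppressWarnings(bdamagePipeline(sim$model))
#' summarizeGroup(res, "*")
#' @export
summarizeGroup <- function(result, selector) {
    stopifnot(is(result, "BDamageResult"))
    pred <- parseAtomSelector(selector)
    mask <- pred(result@atoms)
    if (!any(mask))
        stop("selector '", .selectorLabel(selector), "' matches no atoms")
    bd <- result@atoms$bdamage[mask]
    bi <- result@atoms$bIso[mask]
    data.frame(n = sum(mask),
               meanBDamage = mean(bd), medianBDamage = stats::median(bd),
               varBDamage = if (sum(mask) > 1) stats::var(bd) else NA_real_,
               meanB = mean(bi), medianB = stats::median(bi),
               varB = if (sum(mask) > 1) stats::var(bi) else NA_real_)
}

#' Change in group median B_Damage between two structures
#'
#' The low-dose/high-dose comparison statistic: median B_Damage of the
#' selected atoms in \code{high} minus the same median in \code{low}.
#' Both results must have been computed with identical radius and bin
#' width.
#'
#' @param low,high [BDamageResult-class] objects from same-parameter runs.
#' @param selector selector string or predicate function.
#' @return numeric: \code{median(high) - median(low)} for the group.
#' @export
deltaGroupMedian <- function(low, high, selector) {
    stopifnot(is(low, "BDamageResult"), is(high, "BDamageResult"))
    if (low@radius != high@radius || low@binWidth != high@binWidth)
        stop("results were computed with different parameters (radius ",
             low@radius, "/", high@radius, ", bin width ", low@binWidth,
             "/", high@binWidth, ")")
    pred <- parseAtomSelector(selector)
    mLow <- pred(low@atoms)
    mHigh <- pred(high@atoms)
    if (!any(mLow) || !any(mHigh))
        stop("selector '", .selectorLabel(selector),
             "' matches no atoms in one of the results")
    stats::median(high@atoms$bdamage[mHigh]) -
        stats::median(low@atoms$bdamage[mLow])
}
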