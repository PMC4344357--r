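#' Specification for a synthetic crystal fixture
#'
#' Describes the stated world of the package's validation fixture: a
#' pseudo-peptide globule in a P1 cell whose B-factors follow the
#' documented negative packing-density trend (atoms in more densely packed
#' regions have lower B), with Gaussian noise, and with a damage multiplier
#' applied to a selected atom group to emulate site-specific radiation
#' damage.
#'
#' @param nResidues chain length (default 300).
#' @param baseB B-factor at zero contacts, Angstrom^2 (default 60).
#' @param acnSlope B decrease per contact, Angstrom^2 (default 0.08: with
#'   contact numbers spanning roughly 100-500 this gives B between about
#'   20 and 52, inside the usual 0-80 range).
#' @param noiseSd Gaussian noise on B, Angstrom^2 (default 2).
#' @param damageSelector selector string for the atoms to damage
#'   (default \code{"CYS:SG"}).
#' @param damageMultiplier factor (>= 1) applied to the selected atoms'
#'   B-factors (default 1.5).
#' @param cysEvery every k-th residue is a cysteine carrying an SG atom
#'   (default 10).
#' @param cellEdge P1 cubic cell edge in Angstrom, or \code{NULL} to size
#'   the cell automatically around the globule with a 6 Angstrom solvent
#'   gap.
#' @param seed mandatory RNG seed; identical seeds give byte-identical
#'   fixtures.
#' @return a list of class \code{"syntheticSpec"}.
#' @seealso [makeSyntheticCrystal()]
#' @export
syntheticSpec <- function(nResidues = 300, baseB = 60, acnSlope = 0.08,
                          noiseSd = 2, damageSelector = "CYS:SG",
                          damageMultiplier = 1.5, cysEvery = 10,
                          cellEdge = NULL, seed) {
    if (missing(seed)) stop("a seed is mandatory for a synthetic fixture")
    stopifnot(nResidues >= 2, baseB > 0, acnSlope >= 0, noiseSd >= 0,
              damageMultiplier >= 1, cysEvery >= 1)
    spec <- list(nResidues = as.integer(nResidues), baseB = baseB,
                 acnSlope = acnSlope, noiseSd = noiseSd,
                 damageSelector = damageSelector,
                 damageMultiplier = damageMultiplier,
                 cysEvery = as.integer(cysEvery), cellEdge = cellEdge,
                 seed = as.integer(seed))
    class(spec) <- c("syntheticSpec", "list")
    spec
}

.unitRand <- function() {
    repeat {
        v <- stats::rnorm(3)
        n <- sqrt(sum(v^2))
        if (n > 1e-6) return(v / n)
    }
}

#' Generate a synthetic protein crystal with known ground truth
#'
#' Builds a compact pseudo-peptide chain (backbone N, CA, C, O plus CB, and
#' SG on every \code{cysEvery}-th residue, which is a cysteine) by a
#' self-avoiding random walk inside a sphere, places it in a P1 cubic cell,
#' computes each atom's true atomic contact number inside the crystal
#' lattice, and assigns B-factors as
#' \code{baseB - acnSlope * ACN + N(0, noiseSd)}, clipped at 1, times the
#' damage multiplier for the selected atoms.  Because B is confounded with
#' packing by construction, raw B-factors rank damaged atoms poorly while
#' B_Damage recovers them -- the package's core validation.
#'
#' @param spec a [syntheticSpec()].
#' @return list with components \code{model} (a [StructureModel-class])
#'   and \code{groundTruth}: flagged atom indices and identifiers, their
#'   true contact numbers, and the generation parameters.
#' @examples
#' sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 25, seed = 7))
#' sim$model
#' sum(sim$groundTruth$flagged)
#' @export
makeSyntheticCrystal <- function(spec) {
    stopifnot(inherits(spec, "syntheticSpec"))
    set.seed(spec$seed)
    n <- spec$nResidues
    # ~115 A^3 per residue, a typical protein packing volume
    R <- (3 * n * 115 / (4 * pi))^(1 / 3)
    edge <- if (is.null(spec$cellEdge)) 2 * R + 6 else spec$cellEdge
    centre <- rep(edge / 2, 3)

    # self-avoiding-ish walk of CA positions inside the sphere
    ca <- matrix(NA_real_, n, 3)
    ca[1, ] <- centre + stats::runif(3, -1, 1)
    for (i in 2:n) {
        best <- NULL; bestScore <- -Inf
        for (try in 1:60) {
            cand <- ca[i - 1, ] + 3.8 * .unitRand()
            if (sqrt(sum((cand - centre)^2)) > R) next
            dmin <- min(sqrt(rowSums(
                (ca[seq_len(i - 1), , drop = FALSE] -
                 matrix(cand, i - 1, 3, byrow = TRUE))^2)))
            if (dmin >= 3.4) { best <- cand; break }
            if (dmin > bestScore) { bestScore <- dmin; best <- cand }
        }
        if (is.null(best))
            stop("chain does not fit the cell: walk trapped at residue ", i)
        ca[i, ] <- best
    }

    generic <- c("ALA", "SER", "VAL", "LEU", "THR", "GLY")
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        isCys <- (i %% spec$cysEvery) == 0L
        resName <- if (isCys) "CYS" else generic[(i %% 6L) + 1L]
        pos <- list(CA = ca[i, ])
        pos$N <- pos$CA + 1.46 * .unitRand()
        pos$C <- pos$CA + 1.52 * .unitRand()
        pos$O <- pos$C + 1.23 * .unitRand()
        nm <- c("N", "CA", "C", "O")
        el <- c("N", "C", "C", "O")
        if (resName != "GLY") {
            pos$CB <- pos$CA + 1.53 * .unitRand()
            nm <- c(nm, "CB"); el <- c(el, "C")
        }
        if (isCys) {
            pos$SG <- pos$CB + 1.81 * .unitRand()
            nm <- c(nm, "SG"); el <- c(el, "S")
        }
        xyz <- do.call(rbind, pos[nm])
        rows[[i]] <- data.frame(
            name = nm, resName = resName, resSeq = i,
            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = el,
            stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    if (any(df$x < 0 | df$x > edge | df$y < 0 | df$y > edge |
            df$z < 0 | df$z > edge))
        stop("chain does not fit the cell")

    at <- data.frame(
        serial = seq_len(nrow(df)), name = df$name, altLoc = "",
        resName = df$resName, chain = "A", resSeq = df$resSeq, iCode = "",
        x = round(df$x, 3), y = round(df$y, 3), z = round(df$z, 3),
        occ = 1, bIso = 1, element = df$element,
        recordType = "ATOM", isProtein = TRUE, isHydrogen = FALSE,
        stringsAsFactors = FALSE)

    cell <- unitCellNew(edge, edge, edge, 90, 90, 90, "P 1")
    model <- new("StructureModel", atoms = at, cell = cell,
                 metadata = list(synthetic = TRUE, seed = spec$seed,
                                 preprocessed = FALSE))

    # true contact numbers in the crystal lattice drive the B model
    ctx <- expandToCrystal(model, buffer = 14)
    prof <- computeACN(ctx, radius = 14)
    acnAll <- prof@acn                   # every atom is protein non-H

    b <- pmax(1, spec$baseB - spec$acnSlope * acnAll +
                  stats::rnorm(nrow(at), 0, spec$noiseSd))
    flagged <- parseAtomSelector(spec$damageSelector)(at)
    b[flagged] <- b[flagged] * spec$damageMultiplier
    at$bIso <- round(b, 2)
    model@atoms <- at

    list(model = model,
         groundTruth = list(
             flagged = flagged,
             flaggedAtoms = at[flagged, c("chain", "resSeq", "name")],
             trueAcn = acnAll,
             spec = spec))
}

# internal-coordinate (NeRF) placement: dihedral(a, b, c, new) == torsion,
# angle(b, c, new) == angleDeg, |new - c| == bond
.placeAtom <- function(a, b, c, bond, angleDeg, torsionDeg) {
    th <- angleDeg * pi / 180
    chi <- torsionDeg * pi / 180
    bc <- c - b
    bcU <- bc / sqrt(sum(bc^2))
    ab <- b - a
    nrm <- .cross3(ab, bcU)
    nU <- nrm / sqrt(sum(nrm^2))
    mU <- .cross3(nU, bcU)
    d <- c(-bond * cos(th), bond * sin(th) * cos(chi),
           bond * sin(th) * sin(chi))
    c + d[1] * bcU + d[2] * mU + d[3] * nU
}

#' Build disulfide coordinates with prescribed dihedral angles
#'
#' Inverse of the dihedral extraction: places the eight atoms
#' N-CA-CB-SG-SG'-CB'-CA'-N' by successive internal-coordinate construction
#' with standard bond lengths (CA-CB 1.53, CB-SG 1.81, SG-SG' 2.05
#' Angstrom) and tetrahedral-like angles, so that recomputing the five
#' dihedrals on the output recovers the targets (to well under 1e-6
#' degrees).
#'
#' @param chi numeric length-5 targets (chi1, chi2, chi3, chi2', chi1') in
#'   (-180, 180], none exactly 0.
#' @return 8 x 3 numeric matrix with rownames N, CA, CB, SG, SG2, CB2,
#'   CA2, N2.
#' @examples
#' g <- makeDisulfideGeometry(c(-60, -60, -85, -60, -60))
#' @seealso [classifyDisulfide()], [disulfideModelFromChi()]
#' @export
makeDisulfideGeometry <- function(chi) {
    stopifnot(is.numeric(chi), length(chi) == 5L)
    if (any(chi == 0)) stop("target dihedral angles must be nonzero")
    if (any(chi <= -180 | chi > 180))
        stop("target dihedral angles must lie in (-180, 180]")
    bonds <- c(1.81, 2.05, 1.81, 1.53, 1.46)
    angles <- c(114, 104, 104, 114, 110.5)
    out <- matrix(NA_real_, 8, 3,
                  dimnames = list(c("N", "CA", "CB", "SG", "SG2", "CB2",
                                    "CA2", "N2"), NULL))
    out["N", ] <- c(0, 0, 0)
    out["CA", ] <- c(1.46, 0, 0)
    th <- (180 - 110.5) * pi / 180
    out["CB", ] <- out["CA", ] + 1.53 * c(cos(th), sin(th), 0)
    prev <- c("N", "CA", "CB")
    nm <- c("SG", "SG2", "CB2", "CA2", "N2")
    tors <- c(chi, 180)                  # last torsion arbitrary; fix trans
    for (i in seq_len(5)) {
        out[nm[i], ] <- .placeAtom(out[prev[1], ], out[prev[2], ],
                                   out[prev[3], ], bonds[i],
                                   angles[i], tors[i])
        prev <- c(prev[2], prev[3], nm[i])
    }
    out
}

#' A two-cysteine model carrying one engineered disulfide bond
#'
#' Wraps [makeDisulfideGeometry()] output into a minimal
#' [StructureModel-class] (two CYS residues in a generous P1 cell) so the
#' whole bond-detection and classification path can be exercised on a bond
#' of known type.
#'
#' @param chi numeric length-5 dihedral targets.
#' @return a [StructureModel-class] with 8 atoms.
#' @export
disulfideModelFromChi <- function(chi) {
    g <- makeDisulfideGeometry(chi)
    shift <- 20 - colMeans(g)
    g <- g + matrix(shift, nrow(g), 3, byrow = TRUE)
    nm <- c("N", "CA", "CB", "SG", "SG", "CB", "CA", "N")
    el <- c("N", "C", "C", "S", "S", "C", "C", "N")
    resSeq <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)
    at <- data.frame(serial = 1:8, name = nm, altLoc = "", resName = "CYS",
                     chain = "A", resSeq = resSeq, iCode = "",
                     x = g[, 1], y = g[, 2], z = g[, 3], occ = 1, bIso = 20,
                     element = el, recordType = "ATOM", isProtein = TRUE,
                     isHydrogen = FALSE, stringsAsFactors = FALSE)
    new("StructureModel", atoms = at,
        cell = unitCellNew(40, 40, 40, 90, 90, 90, "P 1"),
        metadata = list(synthetic = TRUE, preprocessed = TRUE))
}
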