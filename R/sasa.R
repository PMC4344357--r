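# van der Waals radii (Angstrom), Bondi-style values for the elements seen
# in protein models; versioned with the package so results are reproducible
.VDW <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
          P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
          FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31, MN = 2.00,
          `NA` = 2.27,
          K = 2.75, CU = 1.40, NI = 1.63, CO = 2.00, CD = 1.58, HG = 1.55)

# extended-state (Gly-X-Gly) reference areas in Angstrom^2 used to express a
# residue's accessible area as a percentage
.REF_AREA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
               GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
               LEU = 201, LYS = 236, MET = 224, MSE = 224, PHE = 240,
               PRO = 159, SER = 155, THR = 172, TRP = 285, TYR = 263,
               VAL = 174)

# deterministic golden-section spiral on the unit sphere: no RNG, so SASA is
# bit-reproducible for a fixed number of points
.spherePoints <- function(n) {
    k <- seq_len(n) - 1L
    z <- 1 - (2 * k + 1) / n
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- k * pi * (3 - sqrt(5))
    cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area per atom
#'
#' Rolling-probe accessibility by deterministic sphere-point sampling: each
#' atom's sphere of radius (van der Waals + probe) is covered with a fixed
#' golden-section spiral of \code{nPoints} points, and a point counts as
#' accessible when it lies outside every other atom's expanded sphere.
#' Computed on the isolated model (no symmetry neighbours), matching
#' per-molecule accessibility.
#'
#' @param model a preprocessed [StructureModel-class].
#' @param probe probe (water) radius in Angstrom, default 1.4.
#' @param nPoints sample points per atom (default 960); accuracy improves
#'   as nPoints grows and the point set is deterministic, never random.
#' @return numeric vector of per-atom accessible areas (Angstrom^2), one
#'   entry per atom of the model, in atom order.
#' @examples
#' sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 10, seed = 1))
#' areas <- computeSASA(preprocessStructure(sim$model), nPoints = 120)
#' @seealso [relativeAccessibility()]
#' @export
computeSASA <- function(model, probe = 1.4, nPoints = 960) {
    stopifnot(is(model, "StructureModel"))
    if (probe < 0) stop("probe radius must be non-negative")
    nPoints <- as.integer(nPoints)
    if (nPoints < 1L) stop("nPoints must be positive")
    at <- model@atoms
    n <- nrow(at)
    if (n == 0L) return(numeric(0))
    unknown <- setdiff(unique(at$element), names(.VDW))
    if (length(unknown))
        stop("no van der Waals radius for element(s): ",
             paste(unknown, collapse = ", "))
    rad <- unname(.VDW[at$element]) + probe
    xyz <- as.matrix(at[, c("x", "y", "z")])
    unit <- .spherePoints(nPoints)

    # pairwise neighbour lists: spheres that can intersect
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
    areas <- numeric(n)
    for (i in seq_len(n)) {
        nbr <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
        if (length(nbr) == 0L) {
            areas[i] <- 4 * pi * rad[i]^2
            next
        }
        pts <- unit * rad[i] +
            matrix(xyz[i, ], nPoints, 3, byrow = TRUE)
        acc <- rep(TRUE, nPoints)
        for (j in nbr) {
            if (!any(acc)) break
            dd <- (pts[acc, 1] - xyz[j, 1])^2 +
                  (pts[acc, 2] - xyz[j, 2])^2 +
                  (pts[acc, 3] - xyz[j, 3])^2
            acc[acc] <- dd > rad[j]^2
        }
        areas[i] <- 4 * pi * rad[i]^2 * sum(acc) / nPoints
    }
    areas
}

#' Relative solvent accessibility per residue
#'
#' Sums per-atom accessible areas over each residue and expresses the total
#' as a percentage of an extended-state (Gly-X-Gly) reference area for that
#' residue type.  Values can exceed 100 for residues more exposed than the
#' reference conformation.
#'
#' @param model the [StructureModel-class] the areas were computed from.
#' @param areas per-atom areas from [computeSASA()] (same length and order
#'   as the model's atom table).
#' @param referenceTable named numeric vector of reference areas per
#'   residue type; defaults to the package's extended-state table.
#' @return data.frame: \code{chain}, \code{resSeq}, \code{iCode},
#'   \code{resName}, \code{absArea} (Angstrom^2), \code{relArea} (percent).
#' @export
relativeAccessibility <- function(model, areas,
                                  referenceTable = .REF_AREA) {
    stopifnot(is(model, "StructureModel"))
    at <- model@atoms
    if (length(areas) != nrow(at))
        stop("areas must have one entry per model atom")
    key <- paste(at$chain, at$resSeq, at$iCode, at$resName, sep = "\r")
    tot <- tapply(areas, key, sum)
    ids <- do.call(rbind, strsplit(names(tot), "\r"))
    resName <- ids[, 4]
    missing <- setdiff(unique(resName), names(referenceTable))
    if (length(missing))
        stop("no reference accessibility for residue type(s): ",
             paste(missing, collapse = ", "))
    out <- data.frame(chain = ids[, 1], resSeq = as.integer(ids[, 2]),
                      iCode = ifelse(is.na(ids[, 3]), "", ids[, 3]),
                      resName = resName,
                      absArea = as.numeric(tot),
                      relArea = 100 * as.numeric(tot) /
                          unname(referenceTable[resName]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$chain, out$resSeq, out$iCode), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read an externally produced per-residue accessibility table
#'
#' Accepts a CSV with columns \code{chain}, \code{resSeq}, \code{relArea}
#' (extra columns are kept), so that accessibility values computed by an
#' external program can be substituted verbatim for the package's own
#' calculator in downstream regressions.
#'
#' @param path CSV path.
#' @return data.frame keyed by chain and residue number.
#' @export
readAccessibilityCSV <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("chain", "resSeq", "relArea")
    if (!all(need %in% names(df)))
        stop("accessibility table must have columns: ",
             paste(need, collapse = ", "))
    df
}
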