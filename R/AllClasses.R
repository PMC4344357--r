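#' @import methods
NULL

.ATOM_COLUMNS <- c("serial", "name", "altLoc", "resName", "chain", "resSeq",
                   "iCode", "x", "y", "z", "occ", "bIso", "element",
                   "recordType", "isProtein", "isHydrogen")

#' Crystallographic unit cell
#'
#' Holds the six cell parameters and the Hermann-Mauguin space-group symbol
#' parsed from a CRYST1 record.  Lengths are in Angstrom, angles in degrees.
#'
#' @slot a,b,c cell edge lengths (Angstrom), strictly positive.
#' @slot alpha,beta,gamma cell angles (degrees), each in (0, 180).
#' @slot spaceGroup Hermann-Mauguin symbol, e.g. \code{"P 21 21 21"}.
#'
#' @seealso [unitCell()], [fracToOrth()], [spaceGroupOperators()]
#' @exportClass UnitCell
setClass("UnitCell",
         representation(a = "numeric", b = "numeric", c = "numeric",
                        alpha = "numeric", beta = "numeric", gamma = "numeric",
                        spaceGroup = "character"))

setValidity("UnitCell", function(object) {
    msg <- character()
    len <- c(object@a, object@b, object@c)
    ang <- c(object@alpha, object@beta, object@gamma)
    if (any(!is.finite(len)) || any(len <= 0))
        msg <- c(msg, "cell edges a, b, c must be finite and > 0")
    if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
        msg <- c(msg, "cell angles must lie in (0, 180) degrees")
    if (length(msg) == 0L) {
        # volume must be positive (angle triple must close a parallelepiped)
        ca <- cos(ang * pi / 180)
        vfac <- 1 - sum(ca^2) + 2 * prod(ca)
        if (!is.finite(vfac) || vfac <= 0)
            msg <- c(msg, "cell angles give non-positive cell volume")
    }
    if (length(msg)) msg else TRUE
})

setClassUnion("UnitCellOrNULL", c("UnitCell", "NULL"))

#' Atomic coordinate model
#'
#' An ordered table of atoms read from a fixed-column PDB file, plus the unit
#' cell (if a CRYST1 record was present) and free-form metadata (PDB id,
#' SSBOND records, preprocessing counts).  The atom table has one row per
#' atom with columns \code{serial}, \code{name}, \code{altLoc},
#' \code{resName}, \code{chain}, \code{resSeq}, \code{iCode}, \code{x},
#' \code{y}, \code{z}, \code{occ}, \code{bIso}, \code{element},
#' \code{recordType}, \code{isProtein}, \code{isHydrogen}.
#'
#' @slot atoms data.frame of per-atom records (see above).
#' @slot cell a [UnitCell-class] or \code{NULL} when no CRYST1 was present.
#' @slot metadata named list.
#'
#' @seealso [readPDB()], [preprocessStructure()], [atoms()]
#' @exportClass StructureModel
setClass("StructureModel",
         representation(atoms = "data.frame", cell = "UnitCellOrNULL",
                        metadata = "list"))

setValidity("StructureModel", function(object) {
    at <- object@atoms
    missing <- setdiff(.ATOM_COLUMNS, names(at))
    if (length(missing))
        return(paste("atom table lacks columns:",
                     paste(missing, collapse = ", ")))
    msg <- character()
    if (nrow(at)) {
        if (any(!is.finite(at$bIso)) || any(at$bIso < 0))
            msg <- c(msg, "b_iso must be finite and >= 0")
        if (any(!is.finite(at$occ)) || any(at$occ < 0) || any(at$occ > 1))
            msg <- c(msg, "occupancy must lie in [0, 1]")
        if (any(!is.finite(c(at$x, at$y, at$z))))
            msg <- c(msg, "coordinates must be finite")
    }
    if (length(msg)) msg else TRUE
})

#' Crystal lattice context of a model
#'
#' The original model together with the positions of symmetry- and
#' lattice-translation-related atom copies that fall inside the original
#' model's axis-aligned bounding box expanded by \code{buffer} Angstrom.
#' Neighbour atoms carry only position, element and protein flag: their
#' B-factors are never used (the B_Damage normalization set is restricted to
#' the deposited asymmetric-unit model).
#'
#' @slot original the preprocessed [StructureModel-class].
#' @slot neighbours data.frame with columns \code{x}, \code{y}, \code{z},
#'   \code{element}, \code{isProtein}.
#' @slot buffer bounding-box expansion, Angstrom (default 14).
#'
#' @seealso [expandToCrystal()], [computeACN()]
#' @exportClass CrystalContext
setClass("CrystalContext",
         representation(original = "StructureModel",
                        neighbours = "data.frame", buffer = "numeric"))

setValidity("CrystalContext", function(object) {
    nb <- object@neighbours
    need <- c("x", "y", "z", "element", "isProtein")
    if (!all(need %in% names(nb)))
        return(paste("neighbour table lacks columns:",
                     paste(setdiff(need, names(nb)), collapse = ", ")))
    if (length(object@buffer) != 1L || !is.finite(object@buffer) ||
        object@buffer < 0)
        return("buffer must be a single non-negative number")
    TRUE
})

#' Per-atom packing-density profile
#'
#' Atomic contact numbers (ACN) and packing-density bin indices for the
#' protein non-hydrogen atoms of a structure, computed inside its crystal
#' context.  \code{binIndex == floor(acn / binWidth)} holds for every atom.
#'
#' @slot radius contact radius, Angstrom (default 14).
#' @slot binWidth packing-density bin width in contacts (default 10).
#' @slot acn integer vector, one ACN per profiled atom.
#' @slot binIndex integer vector, \code{floor(acn / binWidth)}.
#' @slot atomIndex integer vector: row indices of the profiled atoms in the
#'   original model's atom table.
#'
#' @seealso [computeACN()], [acnBin()], [computeBDamage()]
#' @exportClass PackingProfile
setClass("PackingProfile",
         representation(radius = "numeric", binWidth = "integer",
                        acn = "integer", binIndex = "integer",
                        atomIndex = "integer"))

setValidity("PackingProfile", function(object) {
    msg <- character()
    if (length(object@acn) != length(object@binIndex) ||
        length(object@acn) != length(object@atomIndex))
        msg <- c(msg, "acn, binIndex and atomIndex must have equal length")
    if (any(object@acn < 0L))
        msg <- c(msg, "ACN values must be non-negative")
    if (length(object@binWidth) != 1L || object@binWidth < 1L)
        msg <- c(msg, "binWidth must be a single integer >= 1")
    else if (length(object@acn) &&
             !identical(object@binIndex, object@acn %/% object@binWidth))
        msg <- c(msg, "binIndex must equal floor(acn / binWidth)")
    if (length(msg)) msg else TRUE
})

#' Per-atom B_Damage result
#'
#' One row per analysed atom with its ACN, bin index, bin mean B-factor and
#' B_Damage value (\code{bIso / binMeanB}), plus a per-bin occupancy table
#' and the parameters the computation used.  The mean of \code{bdamage} over
#' all analysed atoms is 1 by construction.
#'
#' @slot atoms data.frame: \code{chain}, \code{resSeq}, \code{iCode},
#'   \code{resName}, \code{name}, \code{occ}, \code{bIso}, \code{acn},
#'   \code{binIndex}, \code{binMeanB}, \code{bdamage}.
#' @slot binTable data.frame: \code{binIndex}, \code{nAtoms}, \code{meanB}.
#' @slot radius,binWidth parameters of the packing profile used.
#'
#' @seealso [computeBDamage()], [bdamage()], [summarizeGroup()]
#' @exportClass BDamageResult
setClass("BDamageResult",
         representation(atoms = "data.frame", binTable = "data.frame",
                        radius = "numeric", binWidth = "integer"))

setValidity("BDamageResult", function(object) {
    need <- c("chain", "resSeq", "iCode", "resName", "name", "occ", "bIso",
              "acn", "binIndex", "binMeanB", "bdamage")
    if (!all(need %in% names(object@atoms)))
        return(paste("result atom table lacks columns:",
                     paste(setdiff(need, names(object@atoms)),
                           collapse = ", ")))
    at <- object@atoms
    if (nrow(at)) {
        if (any(at$binMeanB <= 0))
            return("every bin mean B must be > 0")
        if (max(abs(at$bdamage - at$bIso / at$binMeanB)) > 1e-12)
            return("bdamage must equal bIso / binMeanB")
    }
    TRUE
})
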