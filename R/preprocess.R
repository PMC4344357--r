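#' Apply the standard preprocessing rules to a parsed structure
#'
#' Reproduces the curation applied before any packing-density or B-factor
#' analysis: hydrogen (and deuterium) atoms are removed, zero-occupancy
#' atoms are removed, and for every alternate-location set exactly one
#' conformer is kept -- the first conformation with the highest occupancy,
#' ties broken by file order.  Waters and non-protein heteroatoms are
#' removed by default since the metric is defined over non-hydrogen protein
#' atoms; set \code{keepHetero = TRUE} to retain non-water heteroatoms.
#' Partial occupancies above zero are kept and their B-factors used
#' unweighted.  The number of atoms removed at each step is recorded in
#' \code{metadata(model)$removedCounts}.
#'
#' The operation is idempotent: preprocessing an already-preprocessed model
#' removes nothing.
#'
#' @param model a [StructureModel-class] from [readPDB()].
#' @param keepHetero keep non-water, non-protein HETATM records
#'   (default \code{FALSE}).
#' @param keepWaters keep water molecules (default \code{FALSE}).
#' @return the filtered [StructureModel-class].
#' @examples
#' sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 10, seed = 1))
#' preprocessStructure(sim$model)
#' @export
preprocessStructure <- function(model, keepHetero = FALSE,
                                keepWaters = FALSE) {
    stopifnot(is(model, "StructureModel"))
    at <- model@atoms
    n0 <- nrow(at)
    counts <- c(hydrogen = 0L, zeroOccupancy = 0L, altLoc = 0L,
                water = 0L, hetero = 0L)

    drop <- at$isHydrogen
    counts["hydrogen"] <- sum(drop)
    at <- at[!drop, , drop = FALSE]

    drop <- at$occ == 0
    counts["zeroOccupancy"] <- sum(drop)
    at <- at[!drop, , drop = FALSE]

    # alternate locations: within each atom site keep the first conformer
    # with the highest occupancy (file order breaks ties)
    if (nrow(at) && any(at$altLoc != "")) {
        key <- paste(at$chain, at$resSeq, at$iCode, at$resName, at$name,
                     sep = "\r")
        keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
            idx[which.max(at$occ[idx])]
        }), use.names = FALSE)
        keep <- sort(keep)
        counts["altLoc"] <- nrow(at) - length(keep)
        at <- at[keep, , drop = FALSE]
    }

    if (!keepWaters) {
        drop <- at$resName %in% .WATER
        counts["water"] <- sum(drop)
        at <- at[!drop, , drop = FALSE]
    }
    if (!keepHetero) {
        drop <- !at$isProtein & !(at$resName %in% .WATER)
        counts["hetero"] <- sum(drop)
        at <- at[!drop, , drop = FALSE]
    }

    if (nrow(at) == 0L) stop("no atoms survive preprocessing")
    stopifnot(n0 - nrow(at) == sum(counts))

    md <- model@metadata
    md$preprocessed <- TRUE
    md$removedCounts <- as.list(counts)
    new("StructureModel", atoms = at, cell = model@cell, metadata = md)
}
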