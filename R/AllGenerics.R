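#' Accessors for BDamage S4 objects
#'
#' Small accessor generics so that user code never touches slots directly:
#' \code{atoms()} returns the per-atom table of a [StructureModel-class],
#' [CrystalContext-class] (original model) or [BDamageResult-class];
#' \code{unitCell()} the [UnitCell-class]; \code{acn()}, \code{binIndex()}
#' and \code{bdamage()} the per-atom vectors; \code{binTable()} the per-bin
#' occupancy/mean table; \code{neighbours()} the retained symmetry-copy
#' positions.
#'
#' @param x an object of the documented class.
#' @return the slot content named by the accessor.
#' @examples
#' mod <- makeSyntheticCrystal(syntheticSpec(nResidues = 20, seed = 1))$model
#' head(atoms(mod))
#' unitCell(mod)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("unitCell", function(x) standardGeneric("unitCell"))

#' @rdname accessors
#' @export
setGeneric("neighbours", function(x) standardGeneric("neighbours"))

#' @rdname accessors
#' @export
setGeneric("acn", function(x) standardGeneric("acn"))

#' @rdname accessors
#' @export
setGeneric("binIndex", function(x) standardGeneric("binIndex"))

#' @rdname accessors
#' @export
setGeneric("bdamage", function(x) standardGeneric("bdamage"))

#' @rdname accessors
#' @export
setGeneric("binTable", function(x) standardGeneric("binTable"))

#' @rdname accessors
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("atoms", "CrystalContext", function(x) x@original@atoms)

#' @rdname accessors
#' @export
setMethod("atoms", "BDamageResult", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("unitCell", "StructureModel", function(x) x@cell)

#' @rdname accessors
#' @export
setMethod("unitCell", "CrystalContext", function(x) x@original@cell)

#' @rdname accessors
#' @export
setMethod("neighbours", "CrystalContext", function(x) x@neighbours)

#' @rdname accessors
#' @export
setMethod("acn", "PackingProfile", function(x) x@acn)

#' @rdname accessors
#' @export
setMethod("acn", "BDamageResult", function(x) x@atoms$acn)

#' @rdname accessors
#' @export
setMethod("binIndex", "PackingProfile", function(x) x@binIndex)

#' @rdname accessors
#' @export
setMethod("binIndex", "BDamageResult", function(x) x@atoms$binIndex)

#' @rdname accessors
#' @export
setMethod("bdamage", "BDamageResult", function(x) x@atoms$bdamage)

#' @rdname accessors
#' @export
setMethod("binTable", "BDamageResult", function(x) x@binTable)

setMethod("show", "UnitCell", function(object) {
    cat(sprintf("UnitCell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  [%s]\n",
                object@a, object@b, object@c, object@alpha, object@beta,
                object@gamma, object@spaceGroup))
})

setMethod("show", "StructureModel", function(object) {
    at <- object@atoms
    cat(sprintf("StructureModel with %d atoms (%d protein, %d hetero)\n",
                nrow(at), sum(at$isProtein), sum(!at$isProtein)))
    if (!is.null(object@cell)) show(object@cell) else
        cat("  no crystallographic cell (CRYST1 absent)\n")
    if (isTRUE(object@metadata$preprocessed))
        cat("  preprocessed: yes\n")
})

setMethod("show", "CrystalContext", function(object) {
    cat(sprintf("CrystalContext: %d original atoms, %d retained symmetry neighbours, buffer %.1f A\n",
                nrow(object@original@atoms), nrow(object@neighbours),
                object@buffer))
})

setMethod("show", "PackingProfile", function(object) {
    cat(sprintf("PackingProfile: %d atoms, radius %.1f A, bin width %d\n",
                length(object@acn), object@radius, object@binWidth))
    if (length(object@acn))
        cat(sprintf("  ACN range [%d, %d], %d occupied bins\n",
                    min(object@acn), max(object@acn),
                    length(unique(object@binIndex))))
})

setMethod("show", "BDamageResult", function(object) {
    at <- object@atoms
    cat(sprintf("BDamageResult: %d atoms, radius %.1f A, bin width %d\n",
                nrow(at), object@radius, object@binWidth))
    if (nrow(at))
        cat(sprintf("  B_Damage mean %.6f, median %.4f, max %.4f (%s %s %d %s)\n",
                    mean(at$bdamage), stats::median(at$bdamage),
                    max(at$bdamage),
                    at$resName[which.max(at$bdamage)],
                    at$chain[which.max(at$bdamage)],
                    at$resSeq[which.max(at$bdamage)],
                    at$name[which.max(at$bdamage)]))
})
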