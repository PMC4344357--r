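#' Atomic contact numbers within the crystal context
#'
#' For each non-hydrogen protein atom of the original model, counts the
#' non-hydrogen protein atoms (other original atoms plus retained symmetry
#' neighbours) whose centre lies within \code{radius} Angstrom (inclusive),
#' the atom itself excluded.  Symmetry-copy atoms count toward the contact
#' number but never enter the B-factor normalization set.
#'
#' @param context a [CrystalContext-class] built with
#'   \code{buffer >= radius}.
#' @param radius contact radius in Angstrom (default 14).
#' @param binWidth packing-density bin width (default 10).
#' @param includeHetero also count retained hetero atoms as contacts
#'   (default \code{FALSE}: protein atoms only).
#' @return a [PackingProfile-class] whose \code{atomIndex} slot holds the
#'   row indices of the profiled atoms in the original model's atom table.
#' @examples
#' sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 20, seed = 1))
#' ctx <- expandToCrystal(preprocessStructure(sim$model))
#' computeACN(ctx)
#' @export
computeACN <- function(context, radius = 14, binWidth = 10,
                       includeHetero = FALSE) {
    stopifnot(is(context, "CrystalContext"))
    if (radius <= 0) stop("radius must be positive")
    if (context@buffer < radius)
        stop("crystal context buffer (", context@buffer,
             " A) is smaller than the contact radius (", radius,
             " A): the trimmed context would undercount contacts")
    binWidth <- as.integer(binWidth)
    if (is.na(binWidth) || binWidth < 1L)
        stop("binWidth must be a positive integer")

    at <- context@original@atoms
    target <- which(at$isProtein & !at$isHydrogen)
    txyz <- as.matrix(at[target, c("x", "y", "z"), drop = FALSE])

    keepOrig <- (!at$isHydrogen) & (at$isProtein | includeHetero)
    oxyz <- as.matrix(at[keepOrig, c("x", "y", "z"), drop = FALSE])
    nb <- context@neighbours
    nbKeep <- nb$element != "H" & (nb$isProtein | includeHetero)
    nxyz <- as.matrix(nb[nbKeep, c("x", "y", "z"), drop = FALSE])
    all_xyz <- rbind(oxyz, nxyz)

    r2 <- radius^2
    counts <- integer(length(target))
    if (length(target)) {
        chunk <- max(1L, 500000L %/% max(1L, nrow(all_xyz)))
        sq_all <- rowSums(all_xyz^2)
        for (start in seq(1L, length(target), by = chunk)) {
            idx <- start:min(start + chunk - 1L, length(target))
            ti <- txyz[idx, , drop = FALSE]
            d2 <- outer(rowSums(ti^2), sq_all, "+") - 2 * ti %*% t(all_xyz)
            # self-distance is 0; subtract the self count afterwards
            counts[idx] <- as.integer(rowSums(d2 <= r2)) - 1L
        }
    }
    new("PackingProfile", radius = as.numeric(radius), binWidth = binWidth,
        acn = counts, binIndex = counts %/% binWidth,
        atomIndex = as.integer(target))
}

#' Packing-density bin of an atomic contact number
#'
#' Atoms whose contact numbers land in the same width-\code{binWidth} bin
#' (integer division) are treated as sharing a packing-density environment.
#'
#' @param acn non-negative integer vector of atomic contact numbers.
#' @param binWidth positive integer bin width (default 10).
#' @return integer vector \code{floor(acn / binWidth)}.
#' @examples
#' acnBin(127)  # 12
#' @export
acnBin <- function(acn, binWidth = 10) {
    binWidth <- as.integer(binWidth)
    if (is.na(binWidth) || binWidth < 1L)
        stop("binWidth must be a positive integer")
    acn <- as.integer(acn)
    if (any(is.na(acn)) || any(acn < 0L))
        stop("acn must be non-negative integers")
    acn %/% binWidth
}
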