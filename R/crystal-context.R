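#' Expand a model into its crystal lattice context
#'
#' Applies every space-group symmetry operator to the model's atoms (mapping
#' images into the home unit cell), translates each image by the 27 lattice
#' vectors (i, j, k in -1..1) so that the 26 spatially neighbouring unit
#' cells are covered, and keeps only copies that fall inside the original
#' model's axis-aligned bounding box expanded by \code{buffer} Angstrom in
#' every direction.  The home-cell identity copy is excluded, as is any
#' image within 0.01 Angstrom of an original atom (special-position
#' duplicates), so no atom is ever counted against itself.
#'
#' Neighbour atoms carry only position, element and protein flag: their
#' B-factors play no role in the B_Damage normalization, which is restricted
#' to the deposited asymmetric-unit model.
#'
#' @param model a preprocessed [StructureModel-class] with a unit cell and a
#'   recognized space-group symbol.
#' @param buffer bounding-box extension in Angstrom; defaults to 14, the
#'   contact-number radius, and should track it if the radius is changed.
#' @return a [CrystalContext-class].
#' @examples
#' sim <- makeSyntheticCrystal(syntheticSpec(nResidues = 20, seed = 1))
#' ctx <- expandToCrystal(preprocessStructure(sim$model))
#' ctx
#' @export
expandToCrystal <- function(model, buffer = 14) {
    stopifnot(is(model, "StructureModel"))
    if (is.null(model@cell))
        stop("no crystallographic context: model has no CRYST1 unit cell")
    cell <- model@cell
    ops <- spaceGroupOperators(cell@spaceGroup)
    if (buffer < 0) stop("buffer must be non-negative")
    if (buffer > min(cell@a, cell@b, cell@c))
        warning("buffer (", buffer, " A) exceeds the smallest cell edge; ",
                "the fixed 26-neighbouring-cell rule may truncate the ",
                "crystal environment")

    at <- model@atoms
    xyz <- as.matrix(at[, c("x", "y", "z")])
    frac <- orthToFrac(cell, xyz)

    lo <- apply(xyz, 2, min) - buffer
    hi <- apply(xyz, 2, max) + buffer

    shifts <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
    pos <- vector("list", length(ops) * nrow(shifts))
    m <- 0L
    # cell that holds the model centroid: images are mapped into it so the
    # 26-neighbouring-cell rule is anchored at the model, wherever the
    # deposited coordinates sit in the lattice
    homeShift <- floor(colMeans(frac))
    for (oi in seq_along(ops)) {
        op <- ops[[oi]]
        img <- frac %*% t(op$R) +
            matrix(op$t, nrow(frac), 3, byrow = TRUE)
        img <- img - floor(img) +
            matrix(homeShift, nrow(img), 3, byrow = TRUE)
        identityOp <- all(op$R == diag(3)) && all(abs(op$t %% 1) < 1e-12)
        # lattice offset that the home-cell mapping applied to each atom
        baseShift <- if (identityOp) img - frac else NULL
        for (si in seq_len(nrow(shifts))) {
            sh <- shifts[si, ]
            f2 <- img + matrix(sh, nrow(img), 3, byrow = TRUE)
            keepRow <- rep(TRUE, nrow(f2))
            if (identityOp) {
                # drop the copies that coincide with the original atoms
                net <- baseShift + matrix(sh, nrow(f2), 3, byrow = TRUE)
                keepRow <- rowSums(abs(net)) > 1e-9
            }
            if (!any(keepRow)) next
            o2 <- fracToOrth(cell, f2[keepRow, , drop = FALSE])
            inBox <- o2[, 1] >= lo[1] & o2[, 1] <= hi[1] &
                     o2[, 2] >= lo[2] & o2[, 2] <= hi[2] &
                     o2[, 3] >= lo[3] & o2[, 3] <= hi[3]
            if (!any(inBox)) next
            m <- m + 1L
            pos[[m]] <- data.frame(
                x = o2[inBox, 1], y = o2[inBox, 2], z = o2[inBox, 3],
                element = at$element[keepRow][inBox],
                isProtein = at$isProtein[keepRow][inBox],
                stringsAsFactors = FALSE)
        }
    }
    nb <- if (m) do.call(rbind, pos[seq_len(m)]) else
        data.frame(x = numeric(), y = numeric(), z = numeric(),
                   element = character(), isProtein = logical(),
                   stringsAsFactors = FALSE)

    # special-position duplicates: drop neighbours within 0.01 A of any
    # original atom (covers non-identity operators fixing an atom)
    if (nrow(nb)) {
        nbm <- as.matrix(nb[, c("x", "y", "z")])
        dup <- rep(FALSE, nrow(nbm))
        chunk <- 2000L
        for (start in seq(1L, nrow(nbm), by = chunk)) {
            idx <- start:min(start + chunk - 1L, nrow(nbm))
            d2 <- outer(rowSums(nbm[idx, , drop = FALSE]^2),
                        rowSums(xyz^2), "+") -
                2 * nbm[idx, , drop = FALSE] %*% t(xyz)
            dup[idx] <- apply(d2, 1, min) < 0.01^2
        }
        if (any(dup)) nb <- nb[!dup, , drop = FALSE]
        rownames(nb) <- NULL
    }

    new("CrystalContext", original = model, neighbours = nb,
        buffer = as.numeric(buffer))
}
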