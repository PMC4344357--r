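#' Construct a unit cell
#'
#' @param a,b,c cell edges in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @param spaceGroup Hermann-Mauguin symbol string.
#' @return a [UnitCell-class] object.
#' @examples
#' unitCellNew(50, 50, 50, 90, 90, 90, "P 1")
#' @export
unitCellNew <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                        spaceGroup = "P 1") {
    new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
        alpha = as.numeric(alpha), beta = as.numeric(beta),
        gamma = as.numeric(gamma), spaceGroup = as.character(spaceGroup))
}

# standard PDB orthogonalization matrix: a along x, b in the xy plane
.orthMatrix <- function(cell) {
    al <- cell@alpha * pi / 180
    be <- cell@beta * pi / 180
    ga <- cell@gamma * pi / 180
    ca <- cos(al); cb <- cos(be); cg <- cos(ga); sg <- sin(ga)
    vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
    if (!is.finite(vfac) || vfac <= 0)
        stop("degenerate unit cell: non-positive volume")
    matrix(c(cell@a, cell@b * cg,  cell@c * cb,
             0,      cell@b * sg,  cell@c * (ca - cb * cg) / sg,
             0,      0,            cell@c * sqrt(vfac) / sg),
           nrow = 3, byrow = TRUE)
}

#' Cell volume in cubic Angstrom
#' @param cell a [UnitCell-class].
#' @return numeric volume.
#' @export
cellVolume <- function(cell) {
    stopifnot(is(cell, "UnitCell"))
    det(.orthMatrix(cell))
}

#' Convert between fractional and orthogonal coordinates
#'
#' Uses the standard PDB orthogonalization convention (cell edge a along x,
#' b in the xy plane).  \code{fracToOrth} maps fractional cell coordinates
#' to orthogonal Angstrom coordinates, \code{orthToFrac} is its inverse:
#' the round trip is the identity to 1e-9 relative.
#'
#' @param cell a [UnitCell-class].
#' @param points numeric matrix with 3 columns (or a length-3 vector).
#' @return matrix of converted coordinates, same shape as the input.
#' @examples
#' cl <- unitCellNew(10, 20, 30, 90, 90, 90)
#' fracToOrth(cl, c(0.5, 0.5, 0.5))  # (5, 10, 15)
#' @export
fracToOrth <- function(cell, points) {
    stopifnot(is(cell, "UnitCell"))
    p <- .as3mat(points)
    out <- p %*% t(.orthMatrix(cell))
    if (is.null(dim(points))) drop(out) else out
}

#' @rdname fracToOrth
#' @export
orthToFrac <- function(cell, points) {
    stopifnot(is(cell, "UnitCell"))
    p <- .as3mat(points)
    out <- p %*% t(solve(.orthMatrix(cell)))
    if (is.null(dim(points))) drop(out) else out
}

.as3mat <- function(points) {
    if (is.null(dim(points))) {
        if (length(points) != 3L) stop("point must have 3 coordinates")
        matrix(points, nrow = 1)
    } else {
        if (ncol(points) != 3L) stop("points must have 3 columns")
        as.matrix(points)
    }
}
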