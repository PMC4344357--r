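# Hermann-Mauguin -> symmetry operator lookup for the space groups that occur
# commonly in macromolecular crystals (Sohncke groups only: protein crystals
# cannot contain mirrors or inversions).  Operators are stored as xyz triplet
# strings in the fractional basis; centred lattices list the full expanded set
# (centering translations applied), so length(ops) equals the general-position
# multiplicity.  Unknown symbols are an error, never a silent P1 fallback.

.SG_BASE <- list(
    "P 1" = c("x,y,z"),
    # monoclinic, b unique
    "P 1 2 1"  = c("x,y,z", "-x,y,-z"),
    "P 1 21 1" = c("x,y,z", "-x,y+1/2,-z"),
    "C 1 2 1"  = c("x,y,z", "-x,y,-z",
                   "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
    # orthorhombic
    "P 2 2 2"  = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z"),
    "P 2 2 21" = c("x,y,z", "-x,-y,z+1/2", "-x,y,-z+1/2", "x,-y,-z"),
    "P 21 21 2" = c("x,y,z", "-x,-y,z",
                    "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z"),
    "P 21 21 21" = c("x,y,z", "-x+1/2,-y,z+1/2",
                     "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
    "C 2 2 21" = c("x,y,z", "-x,-y,z+1/2", "-x,y,-z+1/2", "x,-y,-z",
                   "x+1/2,y+1/2,z", "-x+1/2,-y+1/2,z+1/2",
                   "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
    "C 2 2 2"  = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z",
                   "x+1/2,y+1/2,z", "-x+1/2,-y+1/2,z",
                   "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z"),
    "F 2 2 2"  = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z",
                   "x,y+1/2,z+1/2", "-x,-y+1/2,z+1/2",
                   "-x,y+1/2,-z+1/2", "x,-y+1/2,-z+1/2",
                   "x+1/2,y,z+1/2", "-x+1/2,-y,z+1/2",
                   "-x+1/2,y,-z+1/2", "x+1/2,-y,-z+1/2",
                   "x+1/2,y+1/2,z", "-x+1/2,-y+1/2,z",
                   "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z"),
    "I 2 2 2"  = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z",
                   "x+1/2,y+1/2,z+1/2", "-x+1/2,-y+1/2,z+1/2",
                   "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z+1/2"),
    "I 21 21 21" = c("x,y,z", "-x+1/2,-y,z+1/2",
                     "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z",
                     "x+1/2,y+1/2,z+1/2", "-x,-y+1/2,z",
                     "-x+1/2,y,-z", "x,-y,-z+1/2"),
    # tetragonal
    "P 4"  = c("x,y,z", "-x,-y,z", "-y,x,z", "y,-x,z"),
    "P 41" = c("x,y,z", "-x,-y,z+1/2", "-y,x,z+1/4", "y,-x,z+3/4"),
    "P 42" = c("x,y,z", "-x,-y,z", "-y,x,z+1/2", "y,-x,z+1/2"),
    "P 43" = c("x,y,z", "-x,-y,z+1/2", "-y,x,z+3/4", "y,-x,z+1/4"),
    "I 4"  = c("x,y,z", "-x,-y,z", "-y,x,z", "y,-x,z",
               "x+1/2,y+1/2,z+1/2", "-x+1/2,-y+1/2,z+1/2",
               "-y+1/2,x+1/2,z+1/2", "y+1/2,-x+1/2,z+1/2"),
    "I 41" = c("x,y,z", "-x+1/2,-y+1/2,z+1/2",
               "-y,x+1/2,z+1/4", "y+1/2,-x,z+3/4",
               "x+1/2,y+1/2,z+1/2", "-x,-y,z",
               "-y+1/2,x,z+3/4", "y,-x+1/2,z+1/4"),
    "P 4 2 2" = c("x,y,z", "-x,-y,z", "-y,x,z", "y,-x,z",
                  "-x,y,-z", "x,-y,-z", "y,x,-z", "-y,-x,-z"),
    "P 4 21 2" = c("x,y,z", "-x,-y,z",
                   "-y+1/2,x+1/2,z", "y+1/2,-x+1/2,z",
                   "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z",
                   "y,x,-z", "-y,-x,-z"),
    "P 41 2 2" = c("x,y,z", "-x,-y,z+1/2", "-y,x,z+1/4", "y,-x,z+3/4",
                   "-x,y,-z", "x,-y,-z+1/2", "y,x,-z+3/4", "-y,-x,-z+1/4"),
    "P 41 21 2" = c("x,y,z", "-x,-y,z+1/2",
                    "-y+1/2,x+1/2,z+1/4", "y+1/2,-x+1/2,z+3/4",
                    "-x+1/2,y+1/2,-z+1/4", "x+1/2,-y+1/2,-z+3/4",
                    "y,x,-z", "-y,-x,-z+1/2"),
    "P 42 21 2" = c("x,y,z", "-x,-y,z",
                    "-y+1/2,x+1/2,z+1/2", "y+1/2,-x+1/2,z+1/2",
                    "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z+1/2",
                    "y,x,-z", "-y,-x,-z"),
    "P 43 2 2" = c("x,y,z", "-x,-y,z+1/2", "-y,x,z+3/4", "y,-x,z+1/4",
                   "-x,y,-z", "x,-y,-z+1/2", "y,x,-z+1/4", "-y,-x,-z+3/4"),
    "P 43 21 2" = c("x,y,z", "-x,-y,z+1/2",
                    "-y+1/2,x+1/2,z+3/4", "y+1/2,-x+1/2,z+1/4",
                    "-x+1/2,y+1/2,-z+3/4", "x+1/2,-y+1/2,-z+1/4",
                    "y,x,-z", "-y,-x,-z+1/2"),
    "I 4 2 2" = c("x,y,z", "-x,-y,z", "-y,x,z", "y,-x,z",
                  "-x,y,-z", "x,-y,-z", "y,x,-z", "-y,-x,-z",
                  "x+1/2,y+1/2,z+1/2", "-x+1/2,-y+1/2,z+1/2",
                  "-y+1/2,x+1/2,z+1/2", "y+1/2,-x+1/2,z+1/2",
                  "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z+1/2",
                  "y+1/2,x+1/2,-z+1/2", "-y+1/2,-x+1/2,-z+1/2"),
    "I 41 2 2" = c("x,y,z", "-x+1/2,-y+1/2,z+1/2",
                   "-y,x+1/2,z+1/4", "y+1/2,-x,z+3/4",
                   "-x+1/2,y,-z+3/4", "x,-y+1/2,-z+1/4",
                   "y+1/2,x+1/2,-z+1/2", "-y,-x,-z",
                   "x+1/2,y+1/2,z+1/2", "-x,-y,z",
                   "-y+1/2,x,z+3/4", "y,-x+1/2,z+1/4",
                   "-x,y+1/2,-z+1/4", "x+1/2,-y,-z+3/4",
                   "y,x,-z", "-y+1/2,-x+1/2,-z+1/2"),
    # trigonal (hexagonal axes)
    "P 3"  = c("x,y,z", "-y,x-y,z", "-x+y,-x,z"),
    "P 31" = c("x,y,z", "-y,x-y,z+1/3", "-x+y,-x,z+2/3"),
    "P 32" = c("x,y,z", "-y,x-y,z+2/3", "-x+y,-x,z+1/3"),
    "R 3"  = c("x,y,z", "-y,x-y,z", "-x+y,-x,z",
               "x+2/3,y+1/3,z+1/3", "-y+2/3,x-y+1/3,z+1/3",
               "-x+y+2/3,-x+1/3,z+1/3",
               "x+1/3,y+2/3,z+2/3", "-y+1/3,x-y+2/3,z+2/3",
               "-x+y+1/3,-x+2/3,z+2/3"),
    "P 3 1 2" = c("x,y,z", "-y,x-y,z", "-x+y,-x,z",
                  "-y,-x,-z", "-x+y,y,-z", "x,x-y,-z"),
    "P 3 2 1" = c("x,y,z", "-y,x-y,z", "-x+y,-x,z",
                  "y,x,-z", "x-y,-y,-z", "-x,-x+y,-z"),
    "P 31 1 2" = c("x,y,z", "-y,x-y,z+1/3", "-x+y,-x,z+2/3",
                   "-y,-x,-z+2/3", "-x+y,y,-z+1/3", "x,x-y,-z"),
    "P 31 2 1" = c("x,y,z", "-y,x-y,z+1/3", "-x+y,-x,z+2/3",
                   "y,x,-z", "x-y,-y,-z+2/3", "-x,-x+y,-z+1/3"),
    "P 32 1 2" = c("x,y,z", "-y,x-y,z+2/3", "-x+y,-x,z+1/3",
                   "-y,-x,-z+1/3", "-x+y,y,-z+2/3", "x,x-y,-z"),
    "P 32 2 1" = c("x,y,z", "-y,x-y,z+2/3", "-x+y,-x,z+1/3",
                   "y,x,-z", "x-y,-y,-z+1/3", "-x,-x+y,-z+2/3"),
    "R 3 2" = c("x,y,z", "-y,x-y,z", "-x+y,-x,z",
                "y,x,-z", "x-y,-y,-z", "-x,-x+y,-z",
                "x+2/3,y+1/3,z+1/3", "-y+2/3,x-y+1/3,z+1/3",
                "-x+y+2/3,-x+1/3,z+1/3", "y+2/3,x+1/3,-z+1/3",
                "x-y+2/3,-y+1/3,-z+1/3", "-x+2/3,-x+y+1/3,-z+1/3",
                "x+1/3,y+2/3,z+2/3", "-y+1/3,x-y+2/3,z+2/3",
                "-x+y+1/3,-x+2/3,z+2/3", "y+1/3,x+2/3,-z+2/3",
                "x-y+1/3,-y+2/3,-z+2/3", "-x+1/3,-x+y+2/3,-z+2/3"),
    # hexagonal
    "P 6"  = c("x,y,z", "-y,x-y,z", "-x+y,-x,z",
               "-x,-y,z", "y,-x+y,z", "x-y,x,z"),
    "P 61" = c("x,y,z", "-y,x-y,z+1/3", "-x+y,-x,z+2/3",
               "-x,-y,z+1/2", "y,-x+y,z+5/6", "x-y,x,z+1/6"),
    "P 65" = c("x,y,z", "-y,x-y,z+2/3", "-x+y,-x,z+1/3",
               "-x,-y,z+1/2", "y,-x+y,z+1/6", "x-y,x,z+5/6"),
    "P 62" = c("x,y,z", "-y,x-y,z+2/3", "-x+y,-x,z+1/3",
               "-x,-y,z", "y,-x+y,z+2/3", "x-y,x,z+1/3"),
    "P 64" = c("x,y,z", "-y,x-y,z+1/3", "-x+y,-x,z+2/3",
               "-x,-y,z", "y,-x+y,z+1/3", "x-y,x,z+2/3"),
    "P 63" = c("x,y,z", "-y,x-y,z", "-x+y,-x,z",
               "-x,-y,z+1/2", "y,-x+y,z+1/2", "x-y,x,z+1/2"),
    "P 6 2 2" = c("x,y,z", "-y,x-y,z", "-x+y,-x,z",
                  "-x,-y,z", "y,-x+y,z", "x-y,x,z",
                  "y,x,-z", "x-y,-y,-z", "-x,-x+y,-z",
                  "-y,-x,-z", "-x+y,y,-z", "x,x-y,-z"),
    "P 61 2 2" = c("x,y,z", "-y,x-y,z+1/3", "-x+y,-x,z+2/3",
                   "-x,-y,z+1/2", "y,-x+y,z+5/6", "x-y,x,z+1/6",
                   "y,x,-z+1/3", "x-y,-y,-z", "-x,-x+y,-z+2/3",
                   "-y,-x,-z+5/6", "-x+y,y,-z+1/2", "x,x-y,-z+1/6"),
    "P 65 2 2" = c("x,y,z", "-y,x-y,z+2/3", "-x+y,-x,z+1/3",
                   "-x,-y,z+1/2", "y,-x+y,z+1/6", "x-y,x,z+5/6",
                   "y,x,-z+2/3", "x-y,-y,-z", "-x,-x+y,-z+1/3",
                   "-y,-x,-z+1/6", "-x+y,y,-z+1/2", "x,x-y,-z+5/6"),
    "P 63 2 2" = c("x,y,z", "-y,x-y,z", "-x+y,-x,z",
                   "-x,-y,z+1/2", "y,-x+y,z+1/2", "x-y,x,z+1/2",
                   "y,x,-z", "x-y,-y,-z", "-x,-x+y,-z",
                   "-y,-x,-z+1/2", "-x+y,y,-z+1/2", "x,x-y,-z+1/2"),
    # cubic
    "P 2 3" = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z",
                "z,x,y", "z,-x,-y", "-z,-x,y", "-z,x,-y",
                "y,z,x", "-y,z,-x", "y,-z,-x", "-y,-z,x"),
    "P 21 3" = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2",
                 "x+1/2,-y+1/2,-z",
                 "z,x,y", "z+1/2,-x+1/2,-y", "-z+1/2,-x,y+1/2",
                 "-z,x+1/2,-y+1/2",
                 "y,z,x", "-y,z+1/2,-x+1/2", "y+1/2,-z+1/2,-x",
                 "-y+1/2,-z,x+1/2"),
    "I 2 3" = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z",
                "z,x,y", "z,-x,-y", "-z,-x,y", "-z,x,-y",
                "y,z,x", "-y,z,-x", "y,-z,-x", "-y,-z,x",
                "x+1/2,y+1/2,z+1/2", "-x+1/2,-y+1/2,z+1/2",
                "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z+1/2",
                "z+1/2,x+1/2,y+1/2", "z+1/2,-x+1/2,-y+1/2",
                "-z+1/2,-x+1/2,y+1/2", "-z+1/2,x+1/2,-y+1/2",
                "y+1/2,z+1/2,x+1/2", "-y+1/2,z+1/2,-x+1/2",
                "y+1/2,-z+1/2,-x+1/2", "-y+1/2,-z+1/2,x+1/2")
)

# accepted aliases (short monoclinic symbols, H-centred rhombohedral names)
.SG_ALIASES <- c(
    "P 2"  = "P 1 2 1",
    "P 21" = "P 1 21 1",
    "C 2"  = "C 1 2 1",
    "H 3"  = "R 3",
    "H 3 2" = "R 3 2"
)

.normalizeSG <- function(symbol) {
    s <- toupper(trimws(symbol))
    gsub("[[:space:]]+", "", s)
}

.SG_LOOKUP <- local({
    keys <- c(names(.SG_BASE), names(.SG_ALIASES))
    vals <- c(names(.SG_BASE), unname(.SG_ALIASES))
    names(vals) <- vapply(keys, .normalizeSG, "")
    vals
})

#' Parse an xyz symmetry-operator triplet
#'
#' Converts strings such as \code{"-y,x-y,z+1/3"} into a rotation matrix and
#' translation vector in the fractional basis.
#'
#' @param triplet a single triplet string (three comma-separated coordinate
#'   expressions in x, y, z with optional rational translations).
#' @return list with elements \code{R} (3x3 numeric matrix) and \code{t}
#'   (length-3 numeric translation).
#' @examples
#' parseSymOp("-x,y+1/2,-z")
#' @export
parseSymOp <- function(triplet) {
    parts <- strsplit(gsub("[[:space:]]", "", tolower(triplet)), ",",
                      fixed = TRUE)[[1]]
    if (length(parts) != 3L)
        stop("symmetry operator must have three comma-separated terms: ",
             triplet)
    R <- matrix(0, 3, 3)
    tr <- numeric(3)
    for (i in seq_len(3)) {
        expr <- parts[i]
        # split into signed terms
        toks <- regmatches(expr,
                           gregexpr("[+-]?[^+-]+", expr))[[1]]
        for (tok in toks) {
            sign <- if (startsWith(tok, "-")) -1 else 1
            body <- sub("^[+-]", "", tok)
            if (body %in% c("x", "y", "z")) {
                R[i, match(body, c("x", "y", "z"))] <-
                    R[i, match(body, c("x", "y", "z"))] + sign
            } else if (grepl("^[0-9]+/[0-9]+$", body)) {
                nd <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
                tr[i] <- tr[i] + sign * nd[1] / nd[2]
            } else if (grepl("^[0-9.]+$", body)) {
                tr[i] <- tr[i] + sign * as.numeric(body)
            } else {
                stop("cannot parse symmetry operator term '", tok, "' in ",
                     triplet)
            }
        }
    }
    list(R = R, t = tr)
}

#' Symmetry operators of a space group
#'
#' Looks up the Hermann-Mauguin symbol in the package's table of common
#' macromolecular (Sohncke) space groups and returns the full list of
#' general-position operators, centering translations already expanded.
#'
#' @param symbol Hermann-Mauguin symbol (spacing-insensitive, e.g.
#'   \code{"P 21 21 21"} or \code{"P212121"}).
#' @return list of operators, each a list with rotation matrix \code{R} and
#'   translation \code{t} (fractional basis); the first operator is always
#'   the identity.
#' @examples
#' length(spaceGroupOperators("P 21 21 21"))  # 4
#' @export
spaceGroupOperators <- function(symbol) {
    key <- .normalizeSG(symbol)
    hit <- .SG_LOOKUP[key]
    if (is.na(hit))
        stop("unknown or unsupported space-group symbol: '", symbol, "'")
    lapply(.SG_BASE[[hit]], parseSymOp)
}

#' @rdname spaceGroupOperators
#' @return \code{knownSpaceGroups()} returns the character vector of
#'   supported Hermann-Mauguin symbols.
#' @export
knownSpaceGroups <- function() names(.SG_BASE)
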