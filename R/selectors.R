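#' Atom selectors
#'
#' A tiny selector syntax over residue and atom names covering the atom
#' groups used in damage comparisons without a general query engine:
#' \itemize{
#'   \item \code{"*"} -- every atom;
#'   \item \code{"CYS:SG"} -- the SG atoms of cysteines;
#'   \item \code{"GLU:OE1,OE2"} -- several atom names of one residue type;
#'   \item \code{"ASP,GLU:*"} -- all atoms of several residue types;
#'   \item \code{"CYS:SG|ASP:OD1,OD2|GLU:OE1,OE2"} -- union of clauses.
#' }
#' A function of the atom table returning a logical vector is accepted
#' wherever a selector string is.
#'
#' @param selector selector string (or a predicate function, returned
#'   unchanged).
#' @return a function mapping an atom data.frame to a logical row mask.
#' @examples
#' sel <- parseAtomSelector("CYS:SG")
#' @export
parseAtomSelector <- function(selector) {
    if (is.function(selector)) return(selector)
    stopifnot(is.character(selector), length(selector) == 1L)
    spec <- selector
    clauses <- strsplit(spec, "|", fixed = TRUE)[[1]]
    force(clauses)
    function(at) {
        mask <- rep(FALSE, nrow(at))
        for (cl in clauses) {
            cl <- trimws(cl)
            if (cl == "*" || cl == "") {
                mask <- mask | TRUE
                next
            }
            parts <- strsplit(cl, ":", fixed = TRUE)[[1]]
            res <- toupper(trimws(strsplit(parts[1], ",")[[1]]))
            m <- if (identical(res, "*")) rep(TRUE, nrow(at)) else
                at$resName %in% res
            if (length(parts) > 1L && trimws(parts[2]) != "*") {
                nm <- toupper(trimws(strsplit(parts[2], ",")[[1]]))
                m <- m & at$name %in% nm
            }
            mask <- mask | m
        }
        mask
    }
}

.selectorLabel <- function(selector) {
    if (is.function(selector)) "<function>" else as.character(selector)
}
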