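#' Dihedral angle of four points
#'
#' Signed torsion angle about the p2-p3 axis in the IUPAC convention:
#' looking from p2 toward p3, a clockwise rotation of the far bond is
#' positive.  The result lies in (-180, 180] degrees; a planar cis
#' arrangement gives 0, trans gives 180.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @examples
#' dihedralAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))  # 0 (cis)
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1
    b2 <- p3 - p2
    b3 <- p4 - p3
    if (sqrt(sum(b1^2)) < 1e-9 || sqrt(sum(b2^2)) < 1e-9 ||
        sqrt(sum(b3^2)) < 1e-9)
        stop("degenerate dihedral: consecutive points coincide")
    n1 <- .cross3(b1, b2)
    n2 <- .cross3(b2, b3)
    if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
        stop("degenerate dihedral: collinear bond vectors")
    b2hat <- b2 / sqrt(sum(b2^2))
    deg <- atan2(sum(.cross3(n1, n2) * b2hat), sum(n1 * n2)) * 180 / pi
    if (deg <= -180) deg <- deg + 360
    deg
}

.cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}

#' Classify a disulfide bond from its five dihedral angles
#'
#' The sign of the central chi3 angle sets the handedness (negative =
#' left-handed, LH; positive = right-handed, RH).  The signs of chi2 and
#' chi2' relative to chi3 set the basic group: both concordant = spiral,
#' both discordant = staple, exactly one concordant = hook.  The signs of
#' chi1 and chi1' then refine the group into the full type label
#' ("-", "+" or a mixed prefix).  Before labelling, the bond is
#' canonicalized so the label does not depend on which cysteine is read
#' first: for hooks the end whose chi2 sign matches chi3 is read first;
#' for spirals and staples a mixed chi1 pair collapses to the single
#' prefix \code{"+/-"}.  Across all sign patterns this yields exactly 20
#' types: 6 spirals, 8 hooks and 6 staples.
#'
#' @param chi numeric length-5 vector (chi1, chi2, chi3, chi2', chi1') in
#'   degrees, each in (-180, 180].  An angle of exactly 0 or +/-180 has no
#'   sign and makes the bond unclassifiable.
#' @return list with elements \code{group} ("spiral", "hook", "staple" or
#'   "unclassifiable"), \code{handedness} ("LH", "RH" or \code{NA}) and
#'   \code{label} (e.g. \code{"-LHSpiral"}).
#' @examples
#' classifyDisulfide(c(-60, -60, -85, -60, -60))$label  # "-LHSpiral"
#' classifyDisulfide(c(60, 85, -85, 85, 60))$label      # "+LHStaple"
#' @export
classifyDisulfide <- function(chi) {
    stopifnot(is.numeric(chi), length(chi) == 5L)
    if (any(chi == 0) || any(abs(chi) == 180) || any(!is.finite(chi)))
        return(list(group = "unclassifiable", handedness = NA_character_,
                    label = "unclassifiable"))
    s <- sign(chi)                       # (chi1, chi2, chi3, chi2', chi1')
    s3 <- s[3]
    handedness <- if (s3 < 0) "LH" else "RH"
    conc <- c(s[2] == s3, s[4] == s3)    # chi2 / chi2' concordant with chi3
    group <- if (all(conc)) "spiral" else if (!any(conc)) "staple" else
        "hook"
    if (group == "hook") {
        # read the chi3-concordant end first, then the chi1 pair is ordered
        ends <- if (conc[1]) c(s[1], s[5]) else c(s[5], s[1])
        prefix <- if (all(ends > 0)) "+" else if (all(ends < 0)) "-" else
            if (ends[1] > 0) "+/-" else "-/+"
    } else {
        # reversal swaps chi1 and chi1': a mixed pair is one class
        prefix <- if (all(s[c(1, 5)] > 0)) "+" else
            if (all(s[c(1, 5)] < 0)) "-" else "+/-"
    }
    grpName <- c(spiral = "Spiral", hook = "Hook", staple = "Staple")[group]
    list(group = group, handedness = handedness,
         label = paste0(prefix, handedness, grpName))
}

#' Enumerate the disulfide bond type labels
#'
#' Classifies all 2^5 = 32 sign patterns of the five dihedral angles and
#' returns the distinct labels after canonicalization for reading
#' direction: 20 types, partitioned into 6 spirals, 8 hooks and 6 staples.
#'
#' @return sorted character vector of the 20 type labels.
#' @examples
#' length(enumerateDisulfideTypes())  # 20
#' @export
enumerateDisulfideTypes <- function() {
    mag <- c(60, 85, 95, 85, 60)        # magnitudes are irrelevant, signs rule
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
    labels <- apply(signs, 1, function(s)
        classifyDisulfide(s * mag)$label)
    sort(unique(labels))
}

#' Locate and measure disulfide bonds in a model
#'
#' Uses SSBOND header records when the file carried any; otherwise pairs
#' cysteine SG atoms greedily by shortest SG-SG distance up to
#' \code{cutoff} Angstrom (each SG in at most one bond).  For every bond
#' the five dihedral angles chi1 (N-CA-CB-SG), chi2 (CA-CB-SG-SG'), chi3
#' (CB-SG-SG'-CB'), chi2' and chi1' are computed from the atomic positions
#' and the bond is classified with [classifyDisulfide()].  A cysteine
#' missing any of its N, CA, CB or SG atoms skips the bond with a warning.
#'
#' @param model a preprocessed [StructureModel-class].
#' @param cutoff SG-SG distance cutoff in Angstrom for the distance-based
#'   search (default 2.5: covalent S-S is about 2.05 plus refinement
#'   slack).
#' @param useSSBond use SSBOND records when present (default \code{TRUE}).
#' @return data.frame with one row per bond: residue identifiers of both
#'   cysteines, the five chi angles (degrees), the SG-SG distance, group,
#'   handedness and type label.  Zero rows when the model has no
#'   disulfides.
#' @export
findDisulfides <- function(model, cutoff = 2.5, useSSBond = TRUE) {
    stopifnot(is(model, "StructureModel"))
    at <- model@atoms
    empty <- data.frame(chain1 = character(), resSeq1 = integer(),
                        iCode1 = character(), chain2 = character(),
                        resSeq2 = integer(), iCode2 = character(),
                        chi1 = numeric(), chi2 = numeric(),
                        chi3 = numeric(), chi2p = numeric(),
                        chi1p = numeric(), ssDistance = numeric(),
                        group = character(), handedness = character(),
                        label = character(), stringsAsFactors = FALSE)

    cys <- at[at$resName == "CYS", , drop = FALSE]
    if (nrow(cys) == 0L) return(empty)
    key <- paste(cys$chain, cys$resSeq, cys$iCode, sep = "\r")
    resIds <- unique(key)

    getAtom <- function(k, nm) {
        i <- which(key == k & cys$name == nm)
        if (length(i) == 0L) return(NULL)
        as.numeric(cys[i[1], c("x", "y", "z")])
    }

    pairs <- NULL
    sb <- model@metadata$ssbonds
    if (useSSBond && !is.null(sb) && nrow(sb)) {
        pairs <- data.frame(
            k1 = paste(sb$chain1, sb$resSeq1, sb$iCode1, sep = "\r"),
            k2 = paste(sb$chain2, sb$resSeq2, sb$iCode2, sep = "\r"),
            stringsAsFactors = FALSE)
    } else {
        sg <- cys[cys$name == "SG", , drop = FALSE]
        sgKey <- key[cys$name == "SG"]
        if (nrow(sg) < 2L) return(empty)
        cand <- NULL
        for (i in seq_len(nrow(sg) - 1L)) for (j in (i + 1L):nrow(sg)) {
            if (sgKey[i] == sgKey[j]) next
            d <- sqrt(sum((as.numeric(sg[i, c("x", "y", "z")]) -
                           as.numeric(sg[j, c("x", "y", "z")]))^2))
            if (d <= cutoff)
                cand <- rbind(cand, data.frame(k1 = sgKey[i], k2 = sgKey[j],
                                               d = d,
                                               stringsAsFactors = FALSE))
        }
        if (is.null(cand)) return(empty)
        cand <- cand[order(cand$d), , drop = FALSE]
        used <- character()
        keep <- logical(nrow(cand))
        for (i in seq_len(nrow(cand))) {
            if (cand$k1[i] %in% used || cand$k2[i] %in% used) next
            keep[i] <- TRUE
            used <- c(used, cand$k1[i], cand$k2[i])
        }
        pairs <- cand[keep, c("k1", "k2"), drop = FALSE]
    }

    rows <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        k1 <- pairs$k1[i]; k2 <- pairs$k2[i]
        a <- lapply(c("N", "CA", "CB", "SG"), getAtom, k = k1)
        b <- lapply(c("N", "CA", "CB", "SG"), getAtom, k = k2)
        if (any(vapply(c(a, b), is.null, TRUE))) {
            warning("disulfide ", gsub("\r", " ", k1), " -- ",
                    gsub("\r", " ", k2),
                    " skipped: cysteine missing N/CA/CB/SG")
            next
        }
        names(a) <- names(b) <- c("N", "CA", "CB", "SG")
        chi <- c(dihedralAngle(a$N, a$CA, a$CB, a$SG),
                 dihedralAngle(a$CA, a$CB, a$SG, b$SG),
                 dihedralAngle(a$CB, a$SG, b$SG, b$CB),
                 dihedralAngle(a$SG, b$SG, b$CB, b$CA),
                 dihedralAngle(b$SG, b$CB, b$CA, b$N))
        cls <- classifyDisulfide(chi)
        id1 <- strsplit(k1, "\r")[[1]]
        id2 <- strsplit(k2, "\r")[[1]]
        rows[[i]] <- data.frame(
            chain1 = id1[1], resSeq1 = as.integer(id1[2]),
            iCode1 = ifelse(is.na(id1[3]), "", id1[3]),
            chain2 = id2[1], resSeq2 = as.integer(id2[2]),
            iCode2 = ifelse(is.na(id2[3]), "", id2[3]),
            chi1 = chi[1], chi2 = chi[2], chi3 = chi[3],
            chi2p = chi[4], chi1p = chi[5],
            ssDistance = sqrt(sum((a$SG - b$SG)^2)),
            group = cls$group, handedness = cls$handedness,
            label = cls$label, stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) == 0L) return(empty)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write a disulfide bond table as CSV
#' @param bonds data.frame from [findDisulfides()].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeDisulfideCSV <- function(bonds, path) {
    utils::write.csv(bonds, path, row.names = FALSE)
    invisible(path)
}
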