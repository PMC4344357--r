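.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE")

.WATER <- c("HOH", "WAT", "DOD", "H2O")

.pdbNum <- function(lines, lineno, from, to, what) {
    field <- substr(lines, from, to)
    val <- suppressWarnings(as.numeric(field))
    bad <- which(is.na(val) & trimws(field) != "")
    empty <- which(trimws(field) == "")
    if (length(bad))
        stop("malformed ", what, " field at line ", lineno[bad[1]],
             ": '", field[bad[1]], "'")
    if (length(empty))
        stop("missing ", what, " field at line ", lineno[empty[1]])
    val
}

.elementFromName <- function(name) {
    # PDB convention: element occupies the first two name columns; a leading
    # space (or digit) marks a one-letter element
    n <- toupper(name)
    two <- trimws(substr(n, 1, 2))
    one <- trimws(gsub("[0-9' ]", "", substr(n, 1, 2)))
    ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE", "CU",
                      "NI", "CO", "CD", "HG", "SI") & substr(n, 1, 1) != " ",
           two, substr(one, 1, 1))
}

#' Read a fixed-column PDB coordinate file
#'
#' Parses ATOM/HETATM records (coordinates, occupancy, isotropic B-factor,
#' alternate-location indicator), the CRYST1 record into a
#' [UnitCell-class], and retains SSBOND records in the metadata.  ANISOU
#' records are discarded; their presence is noted in
#' \code{metadata(model)$hasAnisou} and the isotropic B is always taken from
#' the ATOM record.  Multi-MODEL (NMR-style) files are rejected.
#'
#' @param path path to a PDB file.
#' @return a [StructureModel-class].
#' @seealso [preprocessStructure()], [writePDB()]
#' @export
readPDB <- function(path) {
    if (!file.exists(path)) stop("cannot read PDB file: ", path)
    lines <- readLines(path, warn = FALSE)
    rec <- substr(lines, 1, 6)
    if (sum(trimws(rec) == "MODEL") > 1L)
        stop("multi-model PDB files are not supported")

    sel <- which(rec %in% c("ATOM  ", "HETATM"))
    al <- lines[sel]
    # pad short lines so fixed-column extraction is safe
    al <- formatC(al, width = -80)
    at <- data.frame(
        serial = as.integer(.pdbNum(al, sel, 7, 11, "atom serial")),
        name = trimws(substr(al, 13, 16)),
        altLoc = trimws(substr(al, 17, 17)),
        resName = trimws(substr(al, 18, 20)),
        chain = substr(al, 22, 22),
        resSeq = as.integer(.pdbNum(al, sel, 23, 26, "residue number")),
        iCode = trimws(substr(al, 27, 27)),
        x = .pdbNum(al, sel, 31, 38, "x coordinate"),
        y = .pdbNum(al, sel, 39, 46, "y coordinate"),
        z = .pdbNum(al, sel, 47, 54, "z coordinate"),
        occ = .pdbNum(al, sel, 55, 60, "occupancy"),
        bIso = .pdbNum(al, sel, 61, 66, "B-factor"),
        element = trimws(substr(al, 77, 78)),
        recordType = trimws(substr(al, 1, 6)),
        stringsAsFactors = FALSE)
    noel <- at$element == ""
    if (any(noel)) at$element[noel] <- .elementFromName(substr(al, 13, 16)[noel])
    at$element <- toupper(at$element)
    at$isProtein <- at$resName %in% .AA3
    at$isHydrogen <- at$element %in% c("H", "D")

    cell <- NULL
    ci <- which(rec == "CRYST1")
    if (length(ci)) {
        cl <- formatC(lines[ci[1]], width = -70)
        cell <- unitCellNew(
            a = .pdbNum(cl, ci[1], 7, 15, "cell a"),
            b = .pdbNum(cl, ci[1], 16, 24, "cell b"),
            c = .pdbNum(cl, ci[1], 25, 33, "cell c"),
            alpha = .pdbNum(cl, ci[1], 34, 40, "cell alpha"),
            beta = .pdbNum(cl, ci[1], 41, 47, "cell beta"),
            gamma = .pdbNum(cl, ci[1], 48, 54, "cell gamma"),
            spaceGroup = trimws(substr(cl, 56, 66)))
    }

    ssb <- lines[rec == "SSBOND"]
    ssbonds <- NULL
    if (length(ssb)) {
        sb <- formatC(ssb, width = -40)
        ssbonds <- data.frame(
            chain1 = substr(sb, 16, 16),
            resSeq1 = as.integer(trimws(substr(sb, 18, 21))),
            iCode1 = trimws(substr(sb, 22, 22)),
            chain2 = substr(sb, 30, 30),
            resSeq2 = as.integer(trimws(substr(sb, 32, 35))),
            iCode2 = trimws(substr(sb, 36, 36)),
            stringsAsFactors = FALSE)
    }

    new("StructureModel", atoms = at, cell = cell,
        metadata = list(path = path,
                        hasAnisou = any(rec == "ANISOU"),
                        nAnisou = sum(rec == "ANISOU"),
                        ssbonds = ssbonds,
                        preprocessed = FALSE))
}

.fmtAtomName <- function(name, element) {
    # one-letter elements start in column 14 unless the name needs 4 chars
    out <- ifelse(nchar(name) >= 4L | nchar(element) >= 2L,
                  formatC(name, width = -4),
                  paste0(" ", formatC(name, width = -3)))
    substr(out, 1, 4)
}

.atomLines <- function(at, bcol) {
    sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            at$recordType, at$serial %% 100000L,
            .fmtAtomName(at$name, at$element), at$altLoc, at$resName,
            at$chain, at$resSeq, at$iCode, at$x, at$y, at$z, at$occ,
            bcol, at$element)
}

#' Write a StructureModel as a fixed-column PDB file
#'
#' Emits CRYST1 (when a cell is present), any SSBOND records carried in the
#' metadata, and one ATOM/HETATM line per atom with its stored occupancy and
#' isotropic B-factor.
#'
#' @param model a [StructureModel-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePDB <- function(model, path) {
    stopifnot(is(model, "StructureModel"))
    at <- model@atoms
    lines <- character()
    if (!is.null(model@cell)) {
        cl <- model@cell
        lines <- c(lines, sprintf(
            "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
            cl@a, cl@b, cl@c, cl@alpha, cl@beta, cl@gamma, cl@spaceGroup, 1L))
    }
    sb <- model@metadata$ssbonds
    if (!is.null(sb) && nrow(sb)) {
        lines <- c(lines, sprintf(
            "SSBOND %3d CYS %1s %4d%1s   CYS %1s %4d%1s",
            seq_len(nrow(sb)), sb$chain1, sb$resSeq1, sb$iCode1,
            sb$chain2, sb$resSeq2, sb$iCode2))
    }
    if (nrow(at)) {
        if (any(at$bIso >= 1000))
            stop("B-factor >= 1000 does not fit the PDB temperature-factor field")
        lines <- c(lines, .atomLines(at, at$bIso))
    }
    lines <- c(lines, "END")
    writeLines(lines, path)
    invisible(path)
}

#' Write a model with B_Damage in the temperature-factor column
#'
#' Produces a PDB file in which each atom's temperature-factor field holds
#' its B_Damage value (2 decimal places), for colour-by-B inspection in a
#' molecular viewer.  The original isotropic B-factors are preserved in a
#' companion CSV written next to the PDB (\code{<path>.b_iso.csv}).
#'
#' @param model the preprocessed [StructureModel-class] the result was
#'   computed from (protein non-hydrogen atoms).
#' @param result the matching [BDamageResult-class]; must cover every atom
#'   of \code{model}, in order.
#' @param path output PDB path.
#' @return invisibly, the path.
#' @seealso [computeBDamage()], [writeBDamageCSV()]
#' @export
writeBDamagePDB <- function(model, result, path) {
    stopifnot(is(model, "StructureModel"), is(result, "BDamageResult"))
    at <- model@atoms
    ra <- result@atoms
    if (nrow(ra) == 0L) stop("empty B_Damage result: nothing to write")
    keep <- at$isProtein & !at$isHydrogen
    at <- at[keep, , drop = FALSE]
    if (nrow(at) != nrow(ra) ||
        !all(at$chain == ra$chain & at$resSeq == ra$resSeq &
             at$name == ra$name))
        stop("result does not cover the model's protein non-hydrogen atoms")
    if (any(ra$bdamage >= 1000))
        stop("B_Damage >= 1000 does not fit the PDB temperature-factor field")
    mod2 <- model
    mod2@atoms <- at
    lines <- character()
    if (!is.null(model@cell)) {
        cl <- model@cell
        lines <- c(lines, sprintf(
            "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
            cl@a, cl@b, cl@c, cl@alpha, cl@beta, cl@gamma, cl@spaceGroup, 1L))
    }
    lines <- c(lines, .atomLines(at, ra$bdamage), "END")
    writeLines(lines, path)
    utils::write.csv(data.frame(serial = at$serial, chain = at$chain,
                                res_seq = at$resSeq, atom = at$name,
                                b_iso = at$bIso),
                     paste0(path, ".b_iso.csv"), row.names = FALSE)
    invisible(path)
}

#' Write a per-atom B_Damage table as CSV
#'
#' One row per analysed atom, in the original file order, with a fixed
#' header: chain, res_seq, res_name, atom, occupancy, b_iso, acn, bin,
#' bin_mean_b, bdamage.
#'
#' @param result a [BDamageResult-class].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeBDamageCSV <- function(result, path) {
    stopifnot(is(result, "BDamageResult"))
    ra <- result@atoms
    df <- data.frame(chain = ra$chain, res_seq = ra$resSeq,
                     res_name = ra$resName, atom = ra$name,
                     occupancy = ra$occ, b_iso = ra$bIso, acn = ra$acn,
                     bin = ra$binIndex,
                     bin_mean_b = signif(ra$binMeanB, 9),
                     bdamage = signif(ra$bdamage, 9))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Write the per-bin occupancy/mean table as CSV
#' @param result a [BDamageResult-class].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeBinTableCSV <- function(result, path) {
    stopifnot(is(result, "BDamageResult"))
    utils::write.csv(result@binTable, path, row.names = FALSE)
    invisible(path)
}
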