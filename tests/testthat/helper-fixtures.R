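# fixture builders shared across the suite; everything is generated in code

# compact constructor for a StructureModel from parallel vectors
makeModel <- function(name, resName, x, y, z, element,
                      chain = "A", resSeq = seq_along(name), occ = 1,
                      bIso = 20, altLoc = "", iCode = "",
                      recordType = "ATOM", cell = NULL,
                      metadata = list(preprocessed = TRUE)) {
    n <- length(name)
    at <- data.frame(serial = seq_len(n), name = name,
                     altLoc = rep_len(altLoc, n),
                     resName = rep_len(resName, n),
                     chain = rep_len(chain, n),
                     resSeq = rep_len(resSeq, n),
                     iCode = rep_len(iCode, n),
                     x = x, y = y, z = z,
                     occ = rep_len(occ, n), bIso = rep_len(bIso, n),
                     element = rep_len(element, n),
                     recordType = rep_len(recordType, n),
                     stringsAsFactors = FALSE)
    at$isProtein <- at$resName %in% c("ALA", "ARG", "ASN", "ASP", "CYS",
                                      "GLN", "GLU", "GLY", "HIS", "ILE",
                                      "LEU", "LYS", "MET", "PHE", "PRO",
                                      "SER", "THR", "TRP", "TYR", "VAL",
                                      "MSE")
    at$isHydrogen <- at$element %in% c("H", "D")
    new("StructureModel", atoms = at, cell = cell, metadata = metadata)
}

# a single-atom model, convenient for geometry-driven expectations
singleAtomModel <- function(x, y, z, cellEdge, spaceGroup = "P 1") {
    makeModel("CA", "ALA", x, y, z, "C",
              cell = unitCellNew(cellEdge, cellEdge, cellEdge,
                                 90, 90, 90, spaceGroup))
}

# random point-cloud P1 crystal for contact-number oracle checks
randomP1Fixture <- function(nAtoms, edge, seed) {
    set.seed(seed)
    makeModel(name = rep("CA", nAtoms), resName = "ALA",
              x = round(runif(nAtoms, 0, edge), 3),
              y = round(runif(nAtoms, 0, edge), 3),
              z = round(runif(nAtoms, 0, edge), 3),
              element = "C",
              resSeq = seq_len(nAtoms),
              cell = unitCellNew(edge, edge, edge, 90, 90, 90, "P 1"))
}

# independent all-pairs contact count: per-atom sweep over every candidate
# position, no chunked matrix algebra shared with the implementation
bruteForceACN <- function(context, radius) {
    at <- atoms(context)
    target <- which(at$isProtein & !at$isHydrogen)
    nb <- neighbours(context)
    nb <- nb[nb$isProtein & nb$element != "H", , drop = FALSE]
    orig <- at[at$isProtein & !at$isHydrogen, c("x", "y", "z")]
    all_pos <- rbind(as.matrix(orig), as.matrix(nb[, c("x", "y", "z")]))
    vapply(target, function(i) {
        p <- c(at$x[i], at$y[i], at$z[i])
        d2 <- (all_pos[, 1] - p[1])^2 + (all_pos[, 2] - p[2])^2 +
              (all_pos[, 3] - p[3])^2
        as.integer(sum(d2 <= radius^2) - 1L)   # drop the self count
    }, integer(1))
}

# rank-based AUC of a score for recovering a flagged set
rankAUC <- function(score, flagged) {
    r <- rank(score)
    nPos <- sum(flagged); nNeg <- sum(!flagged)
    (sum(r[flagged]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# recompute the five disulfide dihedrals from a geometry matrix
chiFromGeometry <- function(g) {
    c(dihedralAngle(g["N", ], g["CA", ], g["CB", ], g["SG", ]),
      dihedralAngle(g["CA", ], g["CB", ], g["SG", ], g["SG2", ]),
      dihedralAngle(g["CB", ], g["SG", ], g["SG2", ], g["CB2", ]),
      dihedralAngle(g["SG", ], g["SG2", ], g["CB2", ], g["CA2", ]),
      dihedralAngle(g["SG2", ], g["CB2", ], g["CA2", ], g["N2", ]))
}

# independent dihedral oracle: projection onto the plane normal to the
# central bond, signed via the scalar triple product
dihedralOracle <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    b2u <- b2 / sqrt(sum(b2^2))
    u <- -b1 + sum(b1 * b2u) * b2u       # component of -b1 normal to b2
    v <- b3 - sum(b3 * b2u) * b2u
    cosv <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    ang <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
    trip <- sum(b2u * c(u[2] * v[3] - u[3] * v[2],
                        u[3] * v[1] - u[1] * v[3],
                        u[1] * v[2] - u[2] * v[1]))
    if (trip < 0) -ang else ang
}
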