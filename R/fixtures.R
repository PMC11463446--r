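# Synthetic fixtures with exact ground-truth coordinates: toy molecules
# (chains, rings, branched, chiral centers, macrocycle-like loops),
# dipeptides, long backbone polymers and toy binding pockets. Geometry is
# idealized (fixed bond lengths and angles, exact ring closure), not
# force-field minimized: ground truth must be exact so that oracle tests and
# the self-consistency invariant bondedGeometryErrors(ref, ref) = 0 hold to
# machine precision.

.tetAngle <- 109.47122063449069  # acos(-1/3) in degrees

# NeRF: place atom d given positions a, b, c, bond length |cd|, angle bcd
# and torsion abcd (degrees)
.place4 <- function(a, b, c, len, angDeg, torDeg) {
  ang <- angDeg * pi / 180
  tor <- torDeg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- c((b - a)[2] * bc[3] - (b - a)[3] * bc[2],
         (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
         (b - a)[1] * bc[2] - (b - a)[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-len * cos(ang), len * sin(ang) * cos(tor), len * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

.molFromParts <- function(name, elements, bonds, xyz, charges = NULL) {
  if (is.null(charges)) charges <- rep(0L, length(elements))
  MolRecord(name = name,
            atoms = data.frame(element = elements, charge = charges),
            bonds = bonds, coords = xyz)
}

.zigzagChain <- function(n, L, angDeg) {
  h <- angDeg / 2 * pi / 180
  k <- seq_len(n) - 1L
  cbind(k * L * sin(h), (k %% 2) * L * cos(h), 0)
}

#' Generate a toy molecule with exact reference geometry
#'
#' Kinds: \code{chain} (zigzag, elements cycling C/N/O), \code{ring} (regular
#' planar polygon; aromatic bonds for n = 6), \code{branched} (tetrahedral
#' center with four distinct branches), \code{chiral} (tetrahedral
#' stereocenter with four distinct substituents and a requested handedness),
#' \code{macrocycle} (large planar loop with two heteroatoms breaking the
#' symmetry), \code{dipeptide} (Ala-Ala with ideal internal geometry),
#' \code{polymer} (extended poly-glycine backbone of \code{n} residues, used
#' for large-system corruption studies).
#'
#' @param kind fixture kind
#' @param n size parameter (atoms for chain/ring/macrocycle, residues for
#'   polymer)
#' @param chiralSign requested handedness (+1 or -1) for \code{chiral}
#' @param bondLength bond length in Angstrom (default 1.5)
#' @param angleDeg bond angle in degrees (default tetrahedral, 109.47)
#' @param seed integer seed (fixtures are exactly reproducible from it)
#' @return list with \code{graph} (chirality perceived and attached),
#'   \code{conformation} and \code{spec}
#' @export
makeMolecule <- function(kind = c("chain", "ring", "branched", "chiral",
                                  "macrocycle", "dipeptide", "polymer"),
                         n = 6L, chiralSign = 1L, bondLength = 1.5,
                         angleDeg = .tetAngle, seed = 1L) {
  kind <- match.arg(kind)
  L <- bondLength
  spec <- list(kind = kind, n = n, chiralSign = chiralSign,
               bondLength = bondLength, angleDeg = angleDeg, seed = seed)
  elemCycle <- c("C", "N", "O")
  if (kind == "chain") {
    stopifnot(n >= 2L)
    xyz <- .zigzagChain(n, L, angleDeg)
    elements <- elemCycle[(seq_len(n) - 1L) %% 3L + 1L]
    bonds <- data.frame(i = seq_len(n - 1L), j = 2:n, order = 1L)
    mol <- .molFromParts("chain", elements, bonds, xyz)
  } else if (kind %in% c("ring", "macrocycle")) {
    if (n < 3L) stop("makeMolecule: a ring needs at least 3 atoms")
    if (kind == "macrocycle" && n < 10L)
      stop("makeMolecule: macrocycle-like loops start at 10 atoms")
    r <- L / (2 * sin(pi / n))
    th <- 2 * pi * (seq_len(n) - 1L) / n
    xyz <- cbind(r * cos(th), r * sin(th), 0)
    elements <- rep("C", n)
    if (kind == "macrocycle") { elements[1] <- "N"; elements[2] <- "O" }
    ord <- if (kind == "ring" && n == 6L) 4L else 1L
    bonds <- data.frame(i = seq_len(n), j = c(2:n, 1L), order = ord)
    mol <- .molFromParts(kind, elements, bonds, xyz)
  } else if (kind %in% c("branched", "chiral")) {
    t <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    xyz <- rbind(c(0, 0, 0), t * L)
    elements <- c("C", "N", "O", "F", "C")
    bonds <- data.frame(i = 1L, j = 2:5, order = 1L)
    if (kind == "branched") {
      # extend the 5th atom's branch by one bond at the ideal angle
      w <- c(1, -1, 0) / sqrt(2)  # perpendicular to t[4, ]
      u <- t[4, ] / 3 + w * sqrt(8) / 3
      xyz <- rbind(xyz, xyz[5, ] + u * L)
      elements <- c(elements, "S")
      bonds <- rbind(bonds, data.frame(i = 5L, j = 6L, order = 1L))
    } else {
      V <- tripleProductV(xyz[1, ], xyz[3, ], xyz[4, ], xyz[5, ])
      if (sign(V) != sign(chiralSign)) {
        tmp <- xyz[4, ]; xyz[4, ] <- xyz[5, ]; xyz[5, ] <- tmp
      }
    }
    mol <- .molFromParts(kind, elements, bonds, xyz)
  } else if (kind == "dipeptide") {
    return(.makeDipeptide(spec))
  } else if (kind == "polymer") {
    return(.makePolymer(n, spec))
  }
  built <- buildChemGraph(ligands = list(mol))
  g <- setChiralCenters(built$graph,
                        perceiveChirality(built$graph, built$conformation))
  list(graph = g, conformation = built$conformation, spec = spec)
}

# ideal-geometry residue coordinates: named 5 x 3 (GLY: 4 x 3) matrix built
# with NeRF from standard lengths/angles; CB placed to give the L
# configuration
.idealResidueXYZ <- function(resname) {
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- .place4(c(0, 1, 0), N, CA, 1.525, 111.0, -120)
  O <- .place4(N, CA, C, 1.231, 120.8, -34.9)
  out <- rbind(N = N, CA = CA, C = C, O = O)
  if (resname != "GLY") {
    CB <- .place4(C, N, CA, 1.521, 110.5, 122.6)
    out <- rbind(out, CB = CB)
  }
  if (resname == "SER")
    out <- rbind(out, OG = .place4(out["N", ], out["CA", ], out["CB", ],
                                   1.417, 110.8, 180))
  if (resname == "VAL") {
    out <- rbind(out, CG1 = .place4(out["N", ], out["CA", ], out["CB", ],
                                    1.521, 110.5, 175))
    out <- rbind(out, CG2 = .place4(out["N", ], out["CA", ], out["CB", ],
                                    1.521, 110.5, -65))
  }
  out
}

.residueDF <- function(resname, xyz, chain, resno) {
  tplAtoms <- residueTemplates()[[resname]]$atoms
  nm <- rownames(xyz)
  data.frame(chain = chain, resno = resno, resname = resname, atomName = nm,
             element = tplAtoms$element[match(nm, tplAtoms$atomName)],
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

.makeDipeptide <- function(spec) {
  r1 <- .idealResidueXYZ("ALA")
  # extend through the peptide bond (trans, omega = 180)
  N2 <- .place4(r1["N", ], r1["CA", ], r1["C", ], 1.329, 116.6, 145.1)
  CA2 <- .place4(r1["CA", ], r1["C", ], N2, 1.458, 121.7, 180)
  C2 <- .place4(r1["C", ], N2, CA2, 1.525, 111.0, -120)
  O2 <- .place4(N2, CA2, C2, 1.231, 120.8, -34.9)
  CB2 <- .place4(C2, N2, CA2, 1.521, 110.5, 122.6)
  r2 <- rbind(N = N2, CA = CA2, C = C2, O = O2, CB = CB2)
  res <- rbind(.residueDF("ALA", r1, "A", 1L), .residueDF("ALA", r2, "A", 2L))
  built <- buildChemGraph(residues = res)
  g <- setChiralCenters(built$graph,
                        perceiveChirality(built$graph, built$conformation))
  list(graph = g, conformation = built$conformation, spec = spec)
}

# extended poly-glycine backbone, n residues (4 heavy atoms each)
.makePolymer <- function(n, spec) {
  stopifnot(n >= 2L)
  phi <- -140; psi <- 135
  coordsList <- vector("list", n)
  r <- .idealResidueXYZ("GLY")
  prev <- r
  coordsList[[1]] <- r
  for (i in seq_len(n - 1L)) {
    Nn <- .place4(prev["N", ], prev["CA", ], prev["C", ], 1.329, 116.6, psi)
    CAn <- .place4(prev["CA", ], prev["C", ], Nn, 1.458, 121.7, 180)
    Cn <- .place4(prev["C", ], Nn, CAn, 1.525, 111.0, phi)
    On <- .place4(Nn, CAn, Cn, 1.231, 120.8, -34.9)
    prev <- rbind(N = Nn, CA = CAn, C = Cn, O = On)
    coordsList[[i + 1L]] <- prev
  }
  xyz <- do.call(rbind, coordsList)
  res <- data.frame(chain = "A", resno = rep(seq_len(n), each = 4L),
                    resname = "GLY",
                    atomName = rep(c("N", "CA", "C", "O"), n),
                    element = rep(c("N", "C", "C", "O"), n),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  built <- buildChemGraph(residues = res)
  list(graph = built$graph, conformation = built$conformation, spec = spec)
}

# deterministic points spread on a sphere (Fibonacci lattice)
.fibSphere <- function(n, r) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(r * sin(phi) * cos(theta), r * sin(phi) * sin(theta), r * cos(phi))
}

.rotationFromAxisAngle <- function(axis, ang) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(ang); sa <- sin(ang)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * ca + sa * K + (1 - ca) * outer(a, a)
}

# rotation taking unit vector u to unit vector v
.rotationBetween <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(cr^2)); cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - u * sum(p * u); ax <- ax / sqrt(sum(ax^2))
    return(.rotationFromAxisAngle(ax, pi))
  }
  .rotationFromAxisAngle(cr / s, atan2(s, cth))
}

#' Generate a toy binding pocket with a ground-truth ligand pose
#'
#' A rigid cage of pseudo-residues (real backbone atom names, 1-3 side-chain
#' atoms, side chains pointing inward) on a sphere around the origin encloses
#' a small ligand placed at the center with a seed-dependent orientation.
#' The construction guarantees at least \code{minContacts} pocket atoms
#' within 4 Angstrom of the ligand and no contact below 2 Angstrom
#' (regenerated with a jittered layout up to 10 times, then an error).
#' Residues carry non-consecutive residue numbers, so the cage is not a
#' covalent chain and each pseudo-residue is its own component.
#'
#' @param nRes number of pseudo-residues (default 20)
#' @param radius cage radius in Angstrom (default 6.5)
#' @param ligandKind \code{"ring"} (aromatic 6-ring) or \code{"chain"}
#' @param ligandSize ligand atom count (default 6, range 5-12)
#' @param seed integer seed
#' @return list with \code{graph}, \code{conformation}, \code{ligandAtoms}
#'   and \code{spec}
#' @export
makeToyPocket <- function(nRes = 20L, radius = 6.5, ligandKind = "ring",
                          ligandSize = 6L, seed = 1L) {
  stopifnot(nRes >= 4L, ligandSize >= 3L, ligandSize <= 12L)
  resKinds <- c("ALA", "SER", "VAL")
  for (attempt in 0:9) {
    out <- withSeed(seed + 1000L * attempt, {
      ca <- .fibSphere(nRes, radius)
      resnames <- sample(resKinds, nRes, replace = TRUE)
      res <- vector("list", nRes)
      for (i in seq_len(nRes)) {
        xyz <- .idealResidueXYZ(resnames[i])
        inward <- -ca[i, ] / sqrt(sum(ca[i, ]^2))
        cbdir <- xyz["CB", ] - xyz["CA", ]
        R <- .rotationBetween(cbdir, inward)
        roll <- .rotationFromAxisAngle(inward, stats::runif(1, 0, 2 * pi))
        xyz <- sweep(xyz, 2, xyz["CA", ])
        xyz <- t(roll %*% R %*% t(xyz))
        rownamesKeep <- rownames(xyz)
        xyz <- sweep(xyz, 2, ca[i, ], `+`)
        rownames(xyz) <- rownamesKeep
        res[[i]] <- .residueDF(resnames[i], xyz, "A", 2L * i - 1L)
      }
      residues <- do.call(rbind, res)
      lig <- if (ligandKind == "ring")
        makeMolecule("ring", n = ligandSize, seed = seed)
      else makeMolecule("chain", n = ligandSize, seed = seed)
      lxyz <- coords(lig$conformation)
      lxyz <- sweep(lxyz, 2, colMeans(lxyz))
      Rl <- .rotationFromAxisAngle(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
      lxyz <- t(Rl %*% t(lxyz))
      ligAtoms <- atomTable(lig$graph)
      mol <- .molFromParts("LIG", ligAtoms$element,
                           bondTable(lig$graph), lxyz, ligAtoms$charge)
      list(residues = residues, mol = mol)
    })
    built <- buildChemGraph(residues = out$residues, ligands = list(out$mol))
    at <- atomTable(built$graph)
    ligIdx <- which(at$role == "ligand")
    xyz <- coords(built$conformation)
    dmat <- sqrt(outer(rowSums(xyz[ligIdx, , drop = FALSE]^2),
                       rowSums(xyz[-ligIdx, , drop = FALSE]^2), `+`) -
                   2 * xyz[ligIdx, , drop = FALSE] %*%
                   t(xyz[-ligIdx, , drop = FALSE]))
    minD <- min(dmat)
    contacts <- sum(apply(dmat, 2, min) <= 4)
    if (minD >= 2 && contacts >= 3L) {
      g <- setChiralCenters(built$graph,
                            perceiveChirality(built$graph,
                                              built$conformation))
      return(list(graph = g, conformation = built$conformation,
                  ligandAtoms = which(atomTable(g)$role == "ligand"),
                  spec = list(kind = "toy-pocket", nRes = nRes,
                              radius = radius, ligandKind = ligandKind,
                              ligandSize = ligandSize, seed = seed)))
    }
  }
  stop("makeToyPocket: could not place the ligand without clashes in 10 attempts")
}

.specHash <- function(spec) {
  s <- paste(names(spec), vapply(spec, function(v) paste(v, collapse = ","),
                                 ""), collapse = ";")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 5L
}

#' Generate a small training set of toy molecules
#'
#' Cycles through fixture kinds (chain, ring, branched, and an enantiomer
#' pair of chiral fixtures within the first five items, then macrocycle,
#' dipeptide and size variants), with a disjoint train/validation split
#' assigned by spec hash. Exactly reproducible from (n, seed).
#'
#' @param n number of systems (desk scale, at most 50)
#' @param seed integer seed
#' @return list of items with \code{graph}, \code{conformation},
#'   \code{spec} and \code{split} ("train" or "val")
#' @export
makeTrainingSet <- function(n = 5L, seed = 1L) {
  stopifnot(n >= 1L, n <= 50L)
  protos <- list(
    list(kind = "chain", n = 6L),
    list(kind = "branched"),
    list(kind = "chiral", chiralSign = +1L),
    list(kind = "chiral", chiralSign = -1L),
    list(kind = "ring", n = 6L),
    list(kind = "macrocycle", n = 12L),
    list(kind = "dipeptide"),
    list(kind = "chain", n = 8L),
    list(kind = "ring", n = 5L),
    list(kind = "chain", n = 10L)
  )
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- protos[[(i - 1L) %% length(protos) + 1L]]
    p$seed <- seed + i
    item <- do.call(makeMolecule, p)
    item$split <- if (.specHash(item$spec) == 0L) "val" else "train"
    out[[i]] <- item
  }
  out
}
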