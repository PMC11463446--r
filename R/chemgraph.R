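# Atom-level chemical graph construction and annotations.
#
# One uniform representation across molecule types: polymers are expanded
# through the residue-template dictionary, ligands arrive as MolRecords that
# must already carry bonds. Hydrogens are stripped here; the network never
# sees them.

.adjFromBonds <- function(n, bonds) {
  if (!nrow(bonds))
    return(rep(list(integer(0)), n))
  adj <- split(c(bonds$j, bonds$i),
               factor(c(bonds$i, bonds$j), levels = seq_len(n)))
  adj <- lapply(adj, function(v) sort(unique(as.integer(v))))
  names(adj) <- NULL
  adj
}

.componentsFromAdj <- function(adj) {
  n <- length(adj)
  if (n == 0L) return(integer(0))
  el <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- adj[[i]][adj[[i]] > i]
    if (length(nb)) cbind(i, nb) else NULL
  }))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  as.integer(igraph::components(g)$membership)
}

# all-pairs covalent bond counts; Inf across components (igraph BFS under the
# hood)
computeBondSeparation <- function(adj) {
  n <- length(adj)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  el <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- adj[[i]][adj[[i]] > i]
    if (length(nb)) cbind(i, nb) else NULL
  }))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  d <- igraph::distances(g)
  dimnames(d) <- NULL
  d
}

.maxSepAtoms <- 2000L

#' Build the chemical graph of a molecular system
#'
#' Expands polymer residues through the residue-template dictionary (adding
#' peptide C->N bonds between consecutive residues of a chain), appends ligand
#' \code{\link{MolRecord}}s (which must carry bonds), strips hydrogens,
#' assigns role flags (backbone / sidechain / ligand), labels covalent
#' components and computes the bond-separation matrix. Atom order is residues
#' in order of appearance (template atom order within a residue), then ligand
#' atoms.
#'
#' @param residues data.frame as returned by \code{\link{readPDB}} (columns
#'   chain, resno, resname, atomName, element, x, y, z; optional insert), or
#'   NULL for ligand-only systems
#' @param ligands list of \code{MolRecord} with bonds (and usually coords)
#' @param computeSep compute the bond-separation matrix now (default: yes for
#'   systems up to 2000 atoms; it is computed lazily by
#'   \code{\link{bondSeparation}} otherwise)
#' @return list with \code{graph} (a \linkS4class{ChemGraph}) and
#'   \code{conformation} (a \linkS4class{Conformation}; atoms without input
#'   coordinates are masked out)
#' @export
buildChemGraph <- function(residues = NULL, ligands = list(),
                           computeSep = NULL) {
  if (inherits(ligands, "MolRecord")) ligands <- list(ligands)
  tpl <- residueTemplates()
  atoms <- list()
  bonds <- list()
  xyz <- list()
  nAt <- 0L

  if (!is.null(residues) && nrow(residues)) {
    if (is.null(residues$insert)) residues$insert <- ""
    heavy <- residues$element != "H"
    residues <- residues[heavy, , drop = FALSE]
    rkey <- paste(residues$chain, residues$resno, residues$insert, sep = "\r")
    grps <- split(seq_len(nrow(residues)), rkey)
    order1st <- vapply(grps, min, 1L)
    ukeys <- names(sort(order1st))
    nr <- length(ukeys)
    # plain-vector accumulators; a single data.frame at the end keeps large
    # polymers (10^5 atoms) fast
    aEl <- aCh <- aRN <- aNm <- aRl <- vector("list", nr)
    aNo <- vector("list", nr)
    aX <- aY <- aZ <- vector("list", nr)
    bI <- bJ <- bO <- vector("list", 2L * nr)
    nb <- 0L
    prevC <- NA_integer_; prevChain <- NA_character_; prevResno <- NA_integer_
    for (ki in seq_len(nr)) {
      rows <- grps[[ukeys[ki]]]
      rn <- residues$resname[rows[1]]
      t <- tpl[[rn]]
      if (is.null(t))
        stop("buildChemGraph: no residue template for '", rn, "'")
      present <- t$atoms$atomName[t$atoms$atomName %in%
                                    residues$atomName[rows]]
      idx <- nAt + seq_along(present)
      names(idx) <- present
      m <- rows[match(present, residues$atomName[rows])]
      aEl[[ki]] <- t$atoms$element[match(present, t$atoms$atomName)]
      aCh[[ki]] <- rep(residues$chain[rows[1]], length(present))
      aNo[[ki]] <- rep(residues$resno[rows[1]], length(present))
      aRN[[ki]] <- rep(rn, length(present))
      aNm[[ki]] <- present
      aRl[[ki]] <- ifelse(present %in% t$backbone, "backbone", "sidechain")
      aX[[ki]] <- residues$x[m]; aY[[ki]] <- residues$y[m]
      aZ[[ki]] <- residues$z[m]
      tb <- t$bonds[t$bonds$a1 %in% present & t$bonds$a2 %in% present, ,
                    drop = FALSE]
      if (nrow(tb)) {
        nb <- nb + 1L
        bI[[nb]] <- unname(idx[tb$a1]); bJ[[nb]] <- unname(idx[tb$a2])
        bO[[nb]] <- tb$order
      }
      # peptide link C -> N of the next residue (consecutive resno, same chain)
      if (!is.na(prevC) && identical(prevChain, residues$chain[rows[1]]) &&
          !is.na(prevResno) && residues$resno[rows[1]] == prevResno + 1L &&
          "N" %in% present) {
        nb <- nb + 1L
        bI[[nb]] <- prevC; bJ[[nb]] <- unname(idx[["N"]]); bO[[nb]] <- 1L
      }
      prevC <- if ("C" %in% present) unname(idx[["C"]]) else NA_integer_
      prevChain <- residues$chain[rows[1]]
      prevResno <- residues$resno[rows[1]]
      nAt <- nAt + length(present)
    }
    atoms[[1L]] <- data.frame(
      element = unlist(aEl), charge = 0L, chain = unlist(aCh),
      resno = unlist(aNo), resname = unlist(aRN), atomName = unlist(aNm),
      role = unlist(aRl), stringsAsFactors = FALSE)
    xyz[[1L]] <- cbind(unlist(aX), unlist(aY), unlist(aZ))
    if (nb > 0L)
      bonds[[1L]] <- data.frame(
        i = unlist(bI[seq_len(nb)]), j = unlist(bJ[seq_len(nb)]),
        order = unlist(bO[seq_len(nb)]))
  }

  ligChain <- "L"
  for (li in seq_along(ligands)) {
    m <- ligands[[li]]
    if (!nrow(m$bonds) && nrow(m$atoms) > 1L)
      stop("buildChemGraph: ligand '", m$name, "' carries no bonds; supply ",
           "them via a companion SDF or a template (distance-based bond ",
           "perception is not performed)")
    heavy <- which(m$atoms$element != "H")
    remap <- match(seq_len(nrow(m$atoms)), heavy)
    nm <- if (!is.null(m$atomName)) m$atomName[heavy] else
      paste0(m$atoms$element[heavy], seq_along(heavy))
    atoms[[length(atoms) + 1L]] <- data.frame(
      element = m$atoms$element[heavy], charge = m$atoms$charge[heavy],
      chain = if (!is.null(attr(m, "chain"))) attr(m, "chain") else ligChain,
      resno = if (!is.null(attr(m, "resno"))) attr(m, "resno") else li,
      resname = substr(m$name, 1, 3), atomName = nm, role = "ligand",
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <-
      if (is.null(m$coords)) matrix(NA_real_, length(heavy), 3)
      else m$coords[heavy, , drop = FALSE]
    b <- m$bonds
    keep <- b$i %in% heavy & b$j %in% heavy
    b <- b[keep, , drop = FALSE]
    if (nrow(b))
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = nAt + remap[b$i], j = nAt + remap[b$j], order = b$order)
    nAt <- nAt + length(heavy)
  }

  atoms <- if (length(atoms)) do.call(rbind, atoms) else
    data.frame(element = character(), charge = integer(), chain = character(),
               resno = integer(), resname = character(), atomName = character(),
               role = character(), stringsAsFactors = FALSE)
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(i = integer(), j = integer(), order = integer())
  if (nrow(bonds)) {
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    bonds <- bonds[!duplicated(bonds[, c("i", "j")]), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  adj <- .adjFromBonds(nAt, bonds)
  atoms$component <- .componentsFromAdj(adj)
  rownames(atoms) <- NULL
  if (is.null(computeSep)) computeSep <- nAt <= .maxSepAtoms
  sep <- if (computeSep) computeBondSeparation(adj) else
    matrix(numeric(0), 0, 0)
  xyz <- if (length(xyz)) do.call(rbind, xyz) else matrix(numeric(0), 0, 3)
  g <- new("ChemGraph", atoms = atoms, bonds = bonds, adj = adj,
           bondSep = sep)
  list(graph = g, conformation = Conformation(xyz))
}

# canonical branch label to bounded depth, used for the stereogenicity test
.branchLabel <- function(adj, elements, charges, orders, from, via, depth) {
  lab <- paste0(elements[via], charges[via])
  if (depth <= 0L) return(lab)
  nb <- setdiff(adj[[via]], from)
  if (!length(nb)) return(lab)
  sub <- vapply(nb, function(w) {
    o <- orders[[paste(min(via, w), max(via, w))]]
    paste0(o, ":", .branchLabel(adj, elements, charges, orders, via, w,
                                depth - 1L))
  }, "")
  paste0(lab, "(", paste(sort(sub), collapse = ","), ")")
}

#' Perceive chiral centers from reference geometry
#'
#' Candidate centers are C, N, P or S atoms with at least three heavy
#' neighbours whose substituent branches are pairwise distinct (compared as
#' canonical subgraph labels to depth 4). For each center the tuple
#' (O, A, B, C) stores the three lowest-available neighbour indices in
#' ascending order (for 4-coordinate centers the lowest-index substituent is
#' the one viewed along, i.e. omitted from the tuple); the target sign is the
#' sign of the triple product V in the reference structure, giving
#' V_ideal = sign * 4/(3*sqrt(3)). Near-planar centers (|V| below
#' \code{planarTol}) are excluded and reported via a message.
#'
#' @param graph a \linkS4class{ChemGraph}
#' @param reference a \linkS4class{Conformation} with resolved coordinates for
#'   the candidate centers
#' @param planarTol planarity tolerance on |V| (default 0.1)
#' @return data.frame with columns O, A, B, C, sign, Videal (also directly
#'   usable to fill the graph's chiral slot via \code{\link{setChiralCenters}})
#' @export
perceiveChirality <- function(graph, reference, planarTol = 0.1) {
  at <- atomTable(graph)
  adj <- graph@adj
  xyz <- coords(reference)
  mask <- resolvedMask(reference)
  orders <- new.env(parent = emptyenv())
  b <- bondTable(graph)
  ordmap <- list()
  if (nrow(b))
    ordmap <- stats::setNames(as.list(b$order), paste(b$i, b$j))
  out <- data.frame(O = integer(), A = integer(), B = integer(),
                    C = integer(), sign = integer(), Videal = numeric())
  nPlanar <- 0L
  for (o in seq_len(nrow(at))) {
    if (!at$element[o] %in% c("C", "N", "P", "S")) next
    nb <- adj[[o]]
    if (length(nb) < 3L || length(nb) > 4L) next
    labs <- vapply(nb, function(w)
      .branchLabel(adj, at$element, at$charge, ordmap, o, w, 4L), "")
    if (anyDuplicated(labs)) next
    if (!all(mask[c(o, nb)])) next
    tupNb <- sort(nb)
    if (length(tupNb) == 4L) tupNb <- tupNb[-1L]  # view along lowest index
    V <- tripleProductV(xyz[o, ], xyz[tupNb[1], ], xyz[tupNb[2], ],
                        xyz[tupNb[3], ])
    if (abs(V) < planarTol) { nPlanar <- nPlanar + 1L; next }
    s <- as.integer(sign(V))
    out <- rbind(out, data.frame(O = o, A = tupNb[1], B = tupNb[2],
                                 C = tupNb[3], sign = s,
                                 Videal = s * 4 / (3 * sqrt(3))))
  }
  if (nPlanar > 0L)
    message("perceiveChirality: excluded ", nPlanar,
            " near-planar center(s) (|V| < ", planarTol, ")")
  rownames(out) <- NULL
  out
}

#' Attach chiral centers to a ChemGraph
#' @param graph a ChemGraph
#' @param centers data.frame as returned by \code{\link{perceiveChirality}}
#' @return the updated ChemGraph
#' @export
setChiralCenters <- function(graph, centers) {
  graph@chiral <- centers
  validObject(graph)
  graph
}

#' Crop a system to a spatial neighbourhood of a center atom
#'
#' Atoms are selected by increasing distance to \code{centerAtom}; residues
#' and ligand components are kept whole -- a unit is included if it still fits
#' under the atom cap, otherwise dropped entirely. The bond-separation matrix
#' is recomputed on the subgraph and chiral centers fully inside the crop are
#' remapped. Cropping with the same center and cap is idempotent.
#'
#' @param graph a \linkS4class{ChemGraph}
#' @param conformation reference \linkS4class{Conformation}
#' @param centerAtom atom index the crop is centered on (must be resolved)
#' @param maxAtoms atom cap (default 600)
#' @return list with \code{graph}, \code{conformation} and \code{map} (crop
#'   index -> original atom index)
#' @export
cropGraph <- function(graph, conformation, centerAtom, maxAtoms = 600L) {
  n <- natoms(graph)
  stopifnot(centerAtom >= 1L, centerAtom <= n, maxAtoms >= 1L)
  if (!resolvedMask(conformation)[centerAtom])
    stop("cropGraph: center atom is unresolved in the conformation")
  at <- atomTable(graph)
  xyz <- coords(conformation)
  unit <- ifelse(at$role == "ligand",
                 paste0("L", at$component),
                 paste(at$chain, at$resno, sep = "\r"))
  d <- sqrt(rowSums((xyz - matrix(xyz[centerAtom, ], n, 3, byrow = TRUE))^2))
  d[!resolvedMask(conformation)] <- Inf
  ord <- order(d, seq_len(n))
  unitSize <- table(unit)
  status <- new.env(parent = emptyenv())  # unit -> "in" | "out"
  size <- 0L
  for (i in ord) {
    u <- unit[i]
    if (!is.null(status[[u]])) next
    us <- unitSize[[u]]
    if (size + us <= maxAtoms) { status[[u]] <- "in"; size <- size + us }
    else status[[u]] <- "out"
  }
  keep <- which(vapply(unit, function(u) identical(status[[u]], "in"),
                       TRUE, USE.NAMES = FALSE))
  map <- keep
  inv <- match(seq_len(n), keep)
  b <- bondTable(graph)
  b <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
  b$i <- inv[b$i]; b$j <- inv[b$j]
  rownames(b) <- NULL
  newAtoms <- at[keep, , drop = FALSE]
  rownames(newAtoms) <- NULL
  adj <- .adjFromBonds(length(keep), b)
  newAtoms$component <- .componentsFromAdj(adj)
  ch <- chiralCenters(graph)
  if (nrow(ch)) {
    inside <- ch$O %in% keep & ch$A %in% keep & ch$B %in% keep & ch$C %in% keep
    ch <- ch[inside, , drop = FALSE]
    for (cc in c("O", "A", "B", "C")) ch[[cc]] <- inv[ch[[cc]]]
    rownames(ch) <- NULL
  }
  g <- new("ChemGraph", atoms = newAtoms, bonds = b, adj = adj,
           bondSep = computeBondSeparation(adj), chiral = ch)
  list(graph = g,
       conformation = Conformation(xyz[keep, , drop = FALSE],
                                   resolvedMask(conformation)[keep]),
       map = map)
}
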