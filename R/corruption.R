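# Stochastic input corruption: defines the denoising task for training and
# the initialization for docking-style inference.
#
# Determinism contract: the corruption is a pure function of (input, seed).
# The random stream is consumed in a documented order -- per ligand component
# in ascending component id (one atom-index draw, plus 3 anchor-noise draws in
# docking mode), then a single n x 3 Gaussian noise matrix drawn column-major
# over atoms; rows of that matrix are discarded for atoms the mode leaves
# untouched, so the draws for the remaining atoms do not shift.

# nearest backbone atom of the same residue, by covalent path within the
# residue's atoms (side chains hang off CA, so this is the CB anchor for
# standard residues)
.backboneAnchors <- function(graph) {
  at <- atomTable(graph)
  n <- nrow(at)
  anchor <- rep(NA_integer_, n)
  poly <- which(at$role != "ligand")
  if (!length(poly)) return(anchor)
  rkey <- paste(at$chain, at$resno, sep = "\r")
  for (grp in split(poly, rkey[poly])) {
    bb <- grp[at$role[grp] == "backbone"]
    sc <- grp[at$role[grp] == "sidechain"]
    anchor[bb] <- bb
    if (!length(sc)) next
    inRes <- rep(FALSE, n); inRes[grp] <- TRUE
    # BFS from backbone atoms through residue-internal bonds
    dist <- rep(NA_integer_, n)
    src <- rep(NA_integer_, n)
    dist[bb] <- 0L; src[bb] <- bb
    queue <- bb
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in graph@adj[[v]]) {
        if (!inRes[w] || !is.na(dist[w])) next
        dist[w] <- dist[v] + 1L
        src[w] <- src[v]
        queue <- c(queue, w)
      }
    }
    anchor[sc] <- src[sc]
    # disconnected side-chain atoms (no covalent path): fall back to CA
    orphan <- sc[is.na(anchor[sc])]
    if (length(orphan)) {
      ca <- grp[at$atomName[grp] == "CA"]
      anchor[orphan] <- if (length(ca)) ca[1] else bb[1]
    }
  }
  anchor
}

.residueCA <- function(graph) {
  at <- atomTable(graph)
  n <- nrow(at)
  ca <- rep(NA_integer_, n)
  rkey <- paste(at$chain, at$resno, sep = "\r")
  poly <- which(at$role != "ligand")
  for (grp in split(poly, rkey[poly])) {
    caIdx <- grp[at$atomName[grp] == "CA"]
    tgt <- if (length(caIdx)) caIdx[1] else
      grp[at$role[grp] == "backbone"][1]
    ca[grp] <- tgt
  }
  ca
}

#' Corrupt a conformation for training or docking-style inference
#'
#' \strong{training}: per residue, each side-chain atom is collapsed onto the
#' backbone atom it is covalently connected to within the residue; per ligand
#' component, all atoms are collapsed onto one uniformly selected atom; then
#' i.i.d. Gaussian noise of scale \code{noiseSigma} is added per coordinate
#' to every atom (backbone included).
#'
#' \strong{docking}: one ligand atom is chosen at random and Gaussian noise
#' (\code{noiseSigma}) is added to its anchor position (the atom's reference
#' position when the reference pose is resolved, otherwise a user-supplied
#' anchor point); all other ligand atoms are collapsed onto it and
#' uncorrelated Gaussian noise (\code{noiseSigma}) is added to all ligand
#' atoms -- so neither the ligand's internal structure nor its orientation is
#' inferable from the input. Protein side chains are randomly initialized
#' around their residue's C-alpha (Gaussian, \code{noiseSigma}); backbone
#' atoms keep the input coordinates exactly.
#'
#' \strong{sidechain}: side chains around C-alpha as in docking, backbone
#' exact; ligand atoms keep their reference positions plus noise (repacking
#' with the ligand present).
#'
#' @param graph a \linkS4class{ChemGraph} with roles assigned
#' @param reference a \linkS4class{Conformation}; must be resolved on all
#'   atoms the mode corrupts
#' @param config a \linkS4class{CorruptionConfig}
#' @param anchor optional length-3 anchor point for docking mode when no
#'   reference ligand pose exists
#' @return a corrupted \linkS4class{Conformation}
#' @export
corruptConformation <- function(graph, reference, config = corruptionConfig(),
                                anchor = NULL) {
  at <- atomTable(graph)
  n <- nrow(at)
  xyz <- coords(reference)
  mask <- resolvedMask(reference)
  mode <- config@mode
  sigma <- config@noiseSigma
  ligComps <- sort(unique(at$component[at$role == "ligand"]))
  needResolved <- if (mode == "training") seq_len(n) else
    which(at$role != "ligand")
  if (mode != "docking" || is.null(anchor)) {
    if (mode == "training" && !all(mask))
      stop("corruptConformation: unresolved reference atoms in training mode")
  }
  if (!all(mask[at$role != "ligand"]))
    stop("corruptConformation: unresolved polymer atoms")

  withSeed(config@seed, {
    out <- xyz
    # stage 1: per-component draws, ascending component id
    for (comp in ligComps) {
      idx <- which(at$component == comp & at$role == "ligand")
      pick <- idx[sample.int(length(idx), 1L)]
      if (mode == "training") {
        if (!all(mask[idx]))
          stop("corruptConformation: unresolved ligand atoms in training mode")
        out[idx, 1] <- xyz[pick, 1]
        out[idx, 2] <- xyz[pick, 2]
        out[idx, 3] <- xyz[pick, 3]
      } else if (mode == "docking") {
        base <- if (mask[pick]) xyz[pick, ] else
          if (!is.null(anchor)) anchor else
            stop("corruptConformation: no reference ligand pose; supply an ",
                 "anchor point for the binding site")
        start <- base + stats::rnorm(3L, 0, sigma)
        out[idx, 1] <- start[1]
        out[idx, 2] <- start[2]
        out[idx, 3] <- start[3]
      }
      # sidechain mode: ligand stays at reference here, noised below
    }
    # stage 2: residue collapse (deterministic)
    if (mode == "training") {
      anch <- .backboneAnchors(graph)
      sc <- which(at$role == "sidechain")
      if (length(sc)) out[sc, ] <- xyz[anch[sc], , drop = FALSE]
    } else {
      ca <- .residueCA(graph)
      sc <- which(at$role == "sidechain")
      if (length(sc)) out[sc, ] <- xyz[ca[sc], , drop = FALSE]
    }
    # stage 3: one noise matrix over all atoms, column-major
    noise <- matrix(stats::rnorm(3L * n, 0, sigma), n, 3)
    noised <- if (mode == "training") seq_len(n) else
      which(at$role != "backbone")
    out[noised, ] <- out[noised, , drop = FALSE] +
      noise[noised, , drop = FALSE]
    Conformation(out, rep(TRUE, n))
  })
}

#' @rdname corruptConformation
#' @param ... passed to \code{\link{corruptionConfig}}
#' @export
corruptTraining <- function(graph, reference, ...) {
  corruptConformation(graph, reference, corruptionConfig(mode = "training", ...))
}

#' @rdname corruptConformation
#' @param seed integer seed
#' @export
corruptDocking <- function(graph, reference, seed = 1L, anchor = NULL, ...) {
  corruptConformation(graph, reference,
                      corruptionConfig(mode = "docking", seed = seed, ...),
                      anchor = anchor)
}
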