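# Stochastic ensemble generation, pRMSD-based model selection,
# symmetry-aware ligand RMSD, docking success metrics and the active-site
# preorganization score.

#' Parse an atom-selection expression
#'
#' Mini-language: clauses joined by \code{and}, each optionally negated with
#' \code{not}. Clauses: \code{chain X}, \code{resi N} (or \code{N-M}),
#' \code{name A+B+C}, \code{ligand}, \code{backbone}, \code{sidechain}.
#' Example: \code{"resi 83 and not name N+CA+C+O"}.
#'
#' @param graph a \linkS4class{ChemGraph}
#' @param expr selection string
#' @return integer vector of atom indices
#' @export
selectAtoms <- function(graph, expr) {
  at <- atomTable(graph)
  keep <- rep(TRUE, nrow(at))
  clauses <- strsplit(trimws(expr), "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    cl <- trimws(cl)
    neg <- grepl("^not\\s+", cl)
    if (neg) cl <- sub("^not\\s+", "", cl)
    toks <- strsplit(cl, "\\s+")[[1]]
    m <- switch(toks[1],
      chain = at$chain %in% toks[2],
      resi = {
        if (grepl("-", toks[2])) {
          rng <- as.integer(strsplit(toks[2], "-")[[1]])
          at$resno >= rng[1] & at$resno <= rng[2]
        } else at$resno == as.integer(toks[2])
      },
      name = at$atomName %in% strsplit(toks[2], "\\+")[[1]],
      ligand = at$role == "ligand",
      backbone = at$role == "backbone",
      sidechain = at$role == "sidechain",
      stop("selectAtoms: unknown clause '", cl, "'"))
    if (neg) m <- !m
    keep <- keep & m
  }
  which(keep)
}

# ligand-subgraph automorphisms (element- and charge-colored VF2, bond
# orders verified per mapping)
.ligandAutomorphisms <- function(graph, ligandAtoms, maxAut = 10000L) {
  at <- atomTable(graph)
  b <- bondTable(graph)
  sub <- b[b$i %in% ligandAtoms & b$j %in% ligandAtoms, , drop = FALSE]
  inv <- match(seq_len(natoms(graph)), ligandAtoms)
  nl <- length(ligandAtoms)
  g <- igraph::make_empty_graph(nl, directed = FALSE)
  if (nrow(sub))
    g <- igraph::add_edges(g, rbind(inv[sub$i], inv[sub$j]))
  colr <- as.integer(factor(paste(at$element[ligandAtoms],
                                  at$charge[ligandAtoms])))
  maps <- igraph::graph.get.isomorphisms.vf2(
    g, g, vertex.color1 = colr, vertex.color2 = colr)
  if (length(maps) > maxAut) {
    warning("ligandRMSD: > ", maxAut,
            " automorphisms; falling back to the identity mapping")
    return(list(seq_len(nl)))
  }
  # keep mappings that preserve bond orders
  ordKey <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(sub)))
    assign(paste(sort(c(inv[sub$i[k]], inv[sub$j[k]])), collapse = "-"),
           sub$order[k], envir = ordKey)
  ok <- vapply(maps, function(p) {
    p <- as.integer(p)
    all(vapply(seq_len(nrow(sub)), function(k) {
      a <- p[inv[sub$i[k]]]; bb <- p[inv[sub$j[k]]]
      identical(get(paste(sort(c(a, bb)), collapse = "-"), envir = ordKey),
                sub$order[k])
    }, TRUE))
  }, TRUE)
  lapply(maps[ok], as.integer)
}

#' Symmetry-aware ligand RMSD
#'
#' Pose RMSD in the pocket frame: no re-superposition is performed. The
#' minimum is taken over chemical-graph automorphisms of the ligand (element,
#' charge and bond-order preserving), so chemically equivalent atoms (e.g. a
#' flipped aromatic ring) do not inflate the error. Set
#' \code{symmetry = FALSE} for the plain identity-mapping metric.
#'
#' @param model,reference \linkS4class{Conformation} objects on the full
#'   system atom set
#' @param graph a \linkS4class{ChemGraph}
#' @param ligandAtoms atom indices of the ligand (default: all
#'   \code{role == "ligand"} atoms)
#' @param symmetry minimize over graph automorphisms (default TRUE)
#' @return RMSD in Angstrom
#' @export
ligandRMSD <- function(model, reference, graph, ligandAtoms = NULL,
                       symmetry = TRUE) {
  if (is.null(ligandAtoms))
    ligandAtoms <- which(atomTable(graph)$role == "ligand")
  if (!length(ligandAtoms)) stop("ligandRMSD: no ligand atoms")
  xm <- coords(model)[ligandAtoms, , drop = FALSE]
  xr <- coords(reference)[ligandAtoms, , drop = FALSE]
  perms <- if (symmetry) .ligandAutomorphisms(graph, ligandAtoms)
           else list(seq_along(ligandAtoms))
  best <- Inf
  for (p in perms) {
    r <- sqrt(mean(rowSums((xm[p, , drop = FALSE] - xr)^2)))
    if (r < best) best <- r
  }
  best
}

#' Docking success rates
#'
#' Fraction of targets whose best-ranked model has ligand RMSD strictly below
#' each threshold.
#'
#' @param rmsds numeric vector, one best-ranked RMSD per target
#' @param thresholds RMSD thresholds in Angstrom (default 1 and 2)
#' @return named numeric vector of fractions
#' @export
successRate <- function(rmsds, thresholds = c(1, 2)) {
  if (!length(rmsds)) stop("successRate: empty input")
  out <- vapply(thresholds, function(t) mean(rmsds < t), 0)
  names(out) <- paste0("<", thresholds, "A")
  out
}

#' Sample a conformational ensemble by repeated denoising runs
#'
#' Sample i corrupts the input with seed \code{baseSeed + i} and runs the
#' denoiser; samples are ranked by ascending per-sample pRMSD over
#' \code{selection}. When the reference holds a resolved ligand pose, each
#' model is first superposed on the reference over backbone atoms (restoring
#' the pocket frame) and the symmetry-aware ligand RMSD is recorded. Failed
#' forward passes are excluded from the ranking but counted.
#'
#' @param graph a \linkS4class{ChemGraph}
#' @param reference the input \linkS4class{Conformation} (backbone + any
#'   known poses)
#' @param model a trained \linkS4class{DenoiserModel}
#' @param nSamples ensemble size (the preorganization protocol uses 50)
#' @param baseSeed base corruption seed
#' @param mode corruption mode (default "docking")
#' @param noiseSigma corruption noise scale (default 1.5 Angstrom)
#' @param selection atom indices scored by pRMSD (default: ligand atoms;
#'   a selection string is also accepted)
#' @param anchor optional docking anchor point (see
#'   \code{\link{corruptConformation}})
#' @param referenceLigand compute ligand RMSD against the reference pose
#'   (default: TRUE when the reference resolves all ligand atoms)
#' @return an \linkS4class{EnsembleSummary}
#' @export
sampleEnsemble <- function(graph, reference, model, nSamples = 50L,
                           baseSeed = 0L, mode = "docking", noiseSigma = 1.5,
                           selection = NULL, anchor = NULL,
                           referenceLigand = NULL) {
  stopifnot(nSamples >= 1L)
  at <- atomTable(graph)
  ligandAtoms <- which(at$role == "ligand")
  if (is.null(selection)) selection <- ligandAtoms
  if (is.character(selection)) selection <- selectAtoms(graph, selection)
  if (!length(selection)) stop("sampleEnsemble: empty scoring selection")
  if (is.null(referenceLigand))
    referenceLigand <- length(ligandAtoms) > 0 &&
      all(resolvedMask(reference)[ligandAtoms])
  bb <- which(at$role == "backbone")
  models <- vector("list", nSamples)
  confs <- vector("list", nSamples)
  prmsds <- rep(NA_real_, nSamples)
  lrmsd <- rep(NA_real_, nSamples)
  failed <- rep(FALSE, nSamples)
  for (i in seq_len(nSamples)) {
    res <- tryCatch({
      corr <- corruptConformation(graph, reference,
        corruptionConfig(noiseSigma = noiseSigma, mode = mode,
                         seed = baseSeed + i), anchor = anchor)
      denoise(graph, corr, model)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
      next
    }
    models[[i]] <- res$conformation
    confs[[i]] <- res$confidence
    prmsds[i] <- prmsd(res$confidence, selection)
    if (referenceLigand) {
      fit <- if (length(bb) >= 3L)
        superpose(res$conformation, reference, subset = bb)
      else res$conformation
      lrmsd[i] <- ligandRMSD(fit, reference, graph, ligandAtoms)
    }
  }
  rank <- rep(NA_integer_, nSamples)
  ok <- which(!failed)
  rank[ok[order(prmsds[ok])]] <- seq_along(ok)
  summary <- data.frame(sample = seq_len(nSamples),
                        seed = baseSeed + seq_len(nSamples),
                        prmsd = prmsds, ligandRMSD = lrmsd, rank = rank,
                        failed = failed)
  new("EnsembleSummary", summary = summary, models = models,
      confidences = confs, selection = as.integer(selection))
}

#' Active-site preorganization score
#'
#' Mean over ensemble samples of the per-sample pRMSD over the selection's
#' side-chain atoms, excluding the backbone N, CA, C and O atoms. Lower
#' values indicate a more preorganized (conformationally ordered) site.
#'
#' @param ensemble an \linkS4class{EnsembleSummary}
#' @param graph the system's \linkS4class{ChemGraph}
#' @param selection atom indices or a selection string (e.g.
#'   \code{"resi 83"}); backbone N/CA/C/O atoms are removed from it here
#' @return score in Angstrom
#' @export
preorganizationScore <- function(ensemble, graph, selection) {
  if (is.character(selection)) selection <- selectAtoms(graph, selection)
  at <- atomTable(graph)
  selection <- selection[!(at$role[selection] == "backbone" &
                             at$atomName[selection] %in% c("N", "CA", "C", "O"))]
  if (!length(selection))
    stop("preorganizationScore: selection resolves to zero atoms after ",
         "excluding backbone N, CA, C, O")
  s <- ensemble@summary
  ok <- which(!s$failed)
  if (!length(ok)) stop("preorganizationScore: all samples failed")
  vals <- vapply(ok, function(i)
    prmsd(ensemble@confidences[[i]], selection), 0)
  mean(vals)
}
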