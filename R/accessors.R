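#' @describeIn ChemGraph number of atoms
#' @param x,object a ChemGraph
#' @export
natoms <- function(x) {
  if (is(x, "ChemGraph")) nrow(x@atoms)
  else if (is(x, "Conformation")) nrow(x@coords)
  else stop("natoms: unsupported type")
}

#' Atom table of a ChemGraph
#' @param x a ChemGraph
#' @return data.frame of per-atom annotations
#' @export
atomTable <- function(x) x@atoms

#' Bond table of a ChemGraph
#' @param x a ChemGraph
#' @return data.frame with columns i, j, order
#' @export
bondTable <- function(x) x@bonds

#' Bond-separation matrix
#'
#' Integer-valued matrix counting covalent bonds on the shortest path between
#' every pair of atoms; \code{Inf} between different covalent components.
#' Computed at graph construction for systems up to a size cap and on demand
#' otherwise.
#'
#' @param x a ChemGraph
#' @return numeric n x n matrix
#' @export
bondSeparation <- function(x) {
  if (nrow(x@bondSep) == natoms(x)) return(x@bondSep)
  computeBondSeparation(x@adj)
}

#' Chiral centers of a ChemGraph
#' @param x a ChemGraph
#' @return data.frame with columns O, A, B, C, sign, Videal
#' @export
chiralCenters <- function(x) x@chiral

#' Coordinates of a Conformation
#' @param x a Conformation
#' @return numeric n x 3 matrix (Angstrom)
#' @export
coords <- function(x) x@coords

#' Resolved-atom mask of a Conformation
#' @param x a Conformation
#' @export
resolvedMask <- function(x) x@mask

#' Per-atom predicted deviations (sigma, Angstrom)
#' @param x a ConfidenceOutput
#' @export
sigmaValues <- function(x) x@sigma

#' Per-atom predicted lDDT
#' @param x a ConfidenceOutput
#' @export
plddtValues <- function(x) x@plddt

#' Per-sample summary table of an ensemble
#' @param x an EnsembleSummary
#' @export
ensembleTable <- function(x) x@summary

#' Sampled models of an ensemble
#' @param x an EnsembleSummary
#' @return list of Conformation
#' @export
ensembleModels <- function(x) x@models

#' Construct a Conformation
#' @param coords numeric n x 3 matrix (Angstrom)
#' @param mask logical vector; defaults to all finite rows
#' @export
Conformation <- function(coords, mask = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(mask)) mask <- apply(is.finite(coords), 1L, all)
  new("Conformation", coords = coords, mask = mask)
}

#' Construct a CorruptionConfig
#' @param noiseSigma Gaussian noise scale in Angstrom (default 1.5)
#' @param mode "training", "docking" or "sidechain"
#' @param seed integer seed; fully determines the corruption
#' @param cropMaxAtoms crop cap in heavy atoms (default 600)
#' @export
corruptionConfig <- function(noiseSigma = 1.5, mode = "training", seed = 1L,
                             cropMaxAtoms = 600L) {
  new("CorruptionConfig", noiseSigma = noiseSigma, mode = mode,
      seed = as.integer(seed), cropMaxAtoms = as.integer(cropMaxAtoms))
}

#' Reference-scale model configuration
#'
#' Eight shared-weight iteration blocks and 32-neighbor lists, the
#' configuration of the fully trained network.
#' @param ... overrides passed to \code{new("ModelConfig", ...)}
#' @export
paperConfig <- function(...) new("ModelConfig", ...)

#' Micro model configuration for desk-scale training
#'
#' Two shared-weight blocks, K = 16, narrow tracks; intended for fixtures
#' under ~40 atoms.
#' @param ... overrides
#' @export
microConfig <- function(...) {
  args <- list(...)
  defaults <- list(nBlocks = 2L, nInner = 3L, d1 = 32L, d2 = 16L, K = 16L,
                   nRBF = 8L, seed = 1L, updateCoords = TRUE)
  defaults[names(args)] <- args
  do.call(new, c(list("ModelConfig"), lapply(defaults, function(v)
    if (is.numeric(v) && !is.logical(v)) as.integer(v) else v)))
}

setMethod("show", "ChemGraph", function(object) {
  a <- object@atoms
  cat("ChemGraph:", nrow(a), "atoms,", nrow(object@bonds), "bonds,",
      length(unique(a$component)), "component(s),",
      nrow(object@chiral), "chiral center(s)\n")
  if (nrow(a)) {
    tab <- table(a$role)
    cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "Conformation", function(object) {
  cat("Conformation:", nrow(object@coords), "atoms,",
      sum(object@mask), "resolved\n")
})

setMethod("show", "CorruptionConfig", function(object) {
  cat(sprintf("CorruptionConfig: mode=%s sigma=%.2f A seed=%d crop<=%d atoms\n",
              object@mode, object@noiseSigma, object@seed, object@cropMaxAtoms))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: %d shared-weight block(s) x %d inner layer(s), d1=%d d2=%d K=%d\n",
    object@nBlocks, object@nInner, object@d1, object@d2, object@K))
})

setMethod("show", "DenoiserModel", function(object) {
  np <- sum(vapply(object@weights, length, 1L))
  cat("DenoiserModel:", np, "parameters;")
  show(object@config)
})

setMethod("show", "EnsembleSummary", function(object) {
  s <- object@summary
  cat("EnsembleSummary:", nrow(s), "samples,", sum(s$failed), "failed\n")
  if (nrow(s)) {
    best <- s[which(s$rank == 1L), , drop = FALSE]
    if (nrow(best))
      cat(sprintf("  best pRMSD = %.3f A (sample %d)\n",
                  best$prmsd[1], best$sample[1]))
  }
})

# run code under a seed without disturbing the caller's RNG stream
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
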