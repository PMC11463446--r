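#' @import methods
NULL

#' ChemGraph: atom-level chemical graph of a molecular system
#'
#' The uniform molecular representation used throughout the package: nodes are
#' individual heavy atoms, edges are chemical bonds. Hydrogens are stripped at
#' construction. The graph carries a bond-separation matrix (number of covalent
#' bonds on the shortest path between two atoms, \code{Inf} between different
#' covalent components), connected-component labels, per-atom role flags
#' (\code{"backbone"}, \code{"sidechain"}, \code{"ligand"}) and, once perceived,
#' chiral centers as ordered (O, A, B, C) tuples with a target handedness sign.
#'
#' @slot atoms data.frame with columns \code{element}, \code{charge},
#'   \code{chain}, \code{resno}, \code{resname}, \code{atomName}, \code{role},
#'   \code{component}.
#' @slot bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices, \code{i < j}) and \code{order} (1, 2, 3, or 4 = aromatic).
#' @slot adj list of integer vectors; \code{adj[[i]]} are the atoms bonded to i.
#' @slot bondSep numeric matrix of covalent bond counts along shortest paths
#'   (\code{Inf} = different components); may be 0 x 0 when deferred for very
#'   large systems.
#' @slot chiral data.frame of chiral centers: columns \code{O}, \code{A},
#'   \code{B}, \code{C}, \code{sign}, \code{Videal}.
#' @export
setClass("ChemGraph",
  representation(
    atoms = "data.frame",
    bonds = "data.frame",
    adj = "list",
    bondSep = "matrix",
    chiral = "data.frame"
  ),
  prototype(
    atoms = data.frame(),
    bonds = data.frame(i = integer(), j = integer(), order = integer()),
    adj = list(),
    bondSep = matrix(numeric(0), 0, 0),
    chiral = data.frame(O = integer(), A = integer(), B = integer(),
                        C = integer(), sign = integer(), Videal = numeric())
  )
)

setValidity("ChemGraph", function(object) {
  n <- nrow(object@atoms)
  msgs <- character()
  req <- c("element", "charge", "chain", "resno", "resname", "atomName",
           "role", "component")
  if (!all(req %in% names(object@atoms)))
    msgs <- c(msgs, "atoms must have columns element/charge/chain/resno/resname/atomName/role/component")
  b <- object@bonds
  if (nrow(b)) {
    if (any(b$i < 1L | b$i > n | b$j < 1L | b$j > n))
      msgs <- c(msgs, "bond indices out of range")
    if (any(b$i == b$j)) msgs <- c(msgs, "self-bonds are not allowed")
  }
  if (length(object@adj) != n) msgs <- c(msgs, "adj length must equal atom count")
  if (nrow(object@bondSep) > 0) {
    if (!all(dim(object@bondSep) == c(n, n)))
      msgs <- c(msgs, "bondSep must be n x n")
    else if (any(diag(object@bondSep) != 0))
      msgs <- c(msgs, "bondSep diagonal must be zero")
  }
  if (n > 0 && "element" %in% names(object@atoms) &&
      any(object@atoms$element == "H"))
    msgs <- c(msgs, "hydrogens must be stripped from a ChemGraph")
  if (length(msgs)) msgs else TRUE
})

#' Conformation: per-atom 3D coordinates with a validity mask
#'
#' Holds one coordinate state (reference, corrupted, or model) for the atoms of
#' a \linkS4class{ChemGraph}, in Angstrom.
#'
#' @slot coords numeric matrix, n x 3 (Angstrom).
#' @slot mask logical vector of length n; TRUE where the atom is resolved.
#' @export
setClass("Conformation",
  representation(coords = "matrix", mask = "logical"),
  prototype(coords = matrix(numeric(0), 0, 3), mask = logical(0))
)

setValidity("Conformation", function(object) {
  msgs <- character()
  if (ncol(object@coords) != 3) msgs <- c(msgs, "coords must have 3 columns")
  if (length(object@mask) != nrow(object@coords))
    msgs <- c(msgs, "mask length must equal coordinate row count")
  if (any(object@mask) && !all(is.finite(object@coords[object@mask, , drop = FALSE])))
    msgs <- c(msgs, "coords must be finite where mask is TRUE")
  if (length(msgs)) msgs else TRUE
})

#' CorruptionConfig: parameters of the stochastic input corruption
#'
#' @slot noiseSigma Gaussian noise scale in Angstrom added per coordinate
#'   (default 1.5).
#' @slot mode one of \code{"training"}, \code{"docking"}, \code{"sidechain"}.
#' @slot seed integer; fully determines the corruption output for a given input.
#' @slot cropMaxAtoms crop cap in heavy atoms (default 600).
#' @export
setClass("CorruptionConfig",
  representation(noiseSigma = "numeric", mode = "character",
                 seed = "integer", cropMaxAtoms = "integer"),
  prototype(noiseSigma = 1.5, mode = "training", seed = 1L,
            cropMaxAtoms = 600L)
)

setValidity("CorruptionConfig", function(object) {
  msgs <- character()
  if (object@noiseSigma <= 0) msgs <- c(msgs, "noiseSigma must be > 0")
  if (!object@mode %in% c("training", "docking", "sidechain"))
    msgs <- c(msgs, "mode must be training, docking or sidechain")
  if (object@cropMaxAtoms < 1L) msgs <- c(msgs, "cropMaxAtoms must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' ModelConfig: architecture hyperparameters of the denoising network
#'
#' The reference-scale configuration uses 8 shared-weight iteration blocks and
#' 32 neighbors per atom; the micro configuration used for desk-scale training
#' shrinks everything (2 blocks, K = 16, narrow tracks).
#'
#' @slot nBlocks number of shared-weight iteration blocks.
#' @slot nInner equivariant update sub-layers inside one block.
#' @slot d1 width of the 1D (per-atom) track.
#' @slot d2 width of the 2D (per-pair) track.
#' @slot K neighbor-list size (even; half spatial, half chemical).
#' @slot nRBF number of radial basis functions encoding distances.
#' @slot seed integer seed for weight initialization.
#' @slot updateCoords logical; FALSE freezes the coordinate track (used for
#'   confidence-only calibration).
#' @export
setClass("ModelConfig",
  representation(nBlocks = "integer", nInner = "integer", d1 = "integer",
                 d2 = "integer", K = "integer", nRBF = "integer",
                 seed = "integer", updateCoords = "logical"),
  prototype(nBlocks = 8L, nInner = 3L, d1 = 64L, d2 = 32L, K = 32L,
            nRBF = 8L, seed = 1L, updateCoords = TRUE)
)

setValidity("ModelConfig", function(object) {
  msgs <- character()
  if (object@K %% 2L != 0L || object@K < 2L) msgs <- c(msgs, "K must be even and >= 2")
  if (any(c(object@d1, object@d2, object@nRBF) < 1L))
    msgs <- c(msgs, "track widths must be >= 1")
  if (object@nBlocks < 0L) msgs <- c(msgs, "nBlocks must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' ConfidenceOutput: per-atom and per-pair confidence predictions
#'
#' @slot sigma per-atom predicted positional deviation in Angstrom (> 0).
#' @slot plddt per-atom predicted lDDT in [0, 1].
#' @slot pairIdx integer matrix (nPairs x 2) of atom index pairs scored.
#' @slot pairLogits numeric matrix (nPairs x nBins) of signed distance-error
#'   bin logits.
#' @slot binEdges numeric vector of signed-error bin edges in Angstrom.
#' @export
setClass("ConfidenceOutput",
  representation(sigma = "numeric", plddt = "numeric",
                 pairIdx = "matrix", pairLogits = "matrix",
                 binEdges = "numeric"),
  prototype(sigma = numeric(0), plddt = numeric(0),
            pairIdx = matrix(integer(0), 0, 2),
            pairLogits = matrix(numeric(0), 0, 0),
            binEdges = c(-4, -2, -1, -0.5, 0.5, 1, 2, 4))
)

setValidity("ConfidenceOutput", function(object) {
  msgs <- character()
  if (length(object@sigma) && any(object@sigma <= 0, na.rm = TRUE))
    msgs <- c(msgs, "sigma must be strictly positive")
  if (length(object@plddt) && any(object@plddt < 0 | object@plddt > 1,
                                  na.rm = TRUE))
    msgs <- c(msgs, "plddt must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' DenoiserModel: network weights plus configuration
#'
#' @slot config a \linkS4class{ModelConfig}.
#' @slot weights named list of numeric parameter matrices shared across
#'   iteration blocks.
#' @export
setClass("DenoiserModel",
  representation(config = "ModelConfig", weights = "list"),
  prototype(weights = list())
)

#' EnsembleSummary: per-sample scores and ranking of a sampled ensemble
#'
#' @slot summary data.frame with one row per sample: \code{sample},
#'   \code{seed}, \code{prmsd} (Angstrom, over the scored selection),
#'   \code{ligandRMSD} (Angstrom, NA when no reference pose), \code{rank}
#'   (ascending pRMSD; NA for failed samples), \code{failed}.
#' @slot models list of \linkS4class{Conformation} objects, one per sample.
#' @slot confidences list of \linkS4class{ConfidenceOutput}, one per sample.
#' @slot selection integer vector of atom indices the pRMSD was taken over.
#' @export
setClass("EnsembleSummary",
  representation(summary = "data.frame", models = "list",
                 confidences = "list", selection = "integer"),
  prototype(summary = data.frame(), models = list(), confidences = list(),
            selection = integer(0))
)

setValidity("EnsembleSummary", function(object) {
  s <- object@summary
  if (!nrow(s)) return(TRUE)
  ok <- s$rank[!s$failed]
  if (length(ok) && !setequal(ok, seq_along(ok)))
    return("rank must be a permutation over non-failed samples")
  TRUE
})
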