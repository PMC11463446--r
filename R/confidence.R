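# Confidence targets and losses: per-atom deviation likelihood (sigma),
# pRMSD aggregation, pairwise signed distance-error bins.

.sigmaFloor <- 0.05  # Angstrom; training floor keeping the NLL bounded
.sigmaCap <- 20

# Kabsch: rotation + translation mapping x onto y (least squares)
.kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, cx = cx, cy = cy)
}

#' Superpose a conformation onto a reference
#'
#' Optimal proper rigid superposition (Kabsch) over the given atom subset.
#'
#' @param model,reference \linkS4class{Conformation} objects
#' @param subset atom indices used to fit the superposition (default: atoms
#'   resolved in both)
#' @return a \linkS4class{Conformation} with the transformed model coordinates
#' @export
superpose <- function(model, reference, subset = NULL) {
  xm <- coords(model); xr <- coords(reference)
  if (is.null(subset))
    subset <- which(resolvedMask(model) & resolvedMask(reference))
  if (length(subset) < 3L)
    stop("superpose: need at least 3 resolved atoms")
  k <- .kabsch(xm[subset, , drop = FALSE], xr[subset, , drop = FALSE])
  out <- sweep(xm, 2, k$cx) %*% k$R
  out <- sweep(out, 2, k$cy, `+`)
  Conformation(out, resolvedMask(model))
}

#' Per-atom deviation targets d_i
#'
#' Actual positional deviations of a model from the reference, the targets
#' the sigma head is trained to recapitulate. Under the default
#' \code{"global-superposition"} policy the model is first optimally
#' superposed on the reference over all resolved atoms and d_i is the
#' per-atom residual distance; \code{"frame-median"} instead takes the
#' median frame-local deviation over FAPE frames.
#'
#' @param model,reference \linkS4class{Conformation} objects
#' @param graph a \linkS4class{ChemGraph} (needed for frame-median)
#' @param policy "global-superposition" (default) or "frame-median"
#' @return numeric vector of per-atom deviations in Angstrom
#' @export
deviationTargets <- function(model, reference, graph = NULL,
                             policy = c("global-superposition",
                                        "frame-median")) {
  policy <- match.arg(policy)
  if (policy == "global-superposition") {
    fitted <- superpose(model, reference)
    sqrt(rowSums((coords(fitted) - coords(reference))^2))
  } else {
    if (is.null(graph)) stop("deviationTargets: frame-median needs the graph")
    dv <- fapeAllAtom(model, reference, graph, clamp = Inf,
                      returnDeviations = TRUE)$deviations
    apply(dv, 2L, stats::median)
  }
}

#' Gaussian deviation negative log-likelihood
#'
#' Per-atom confidence loss: the negative log of the isotropic Gaussian
#' density N(d; 0, sigma^2) reduced to its sufficient statistic,
#' \code{log(sigma) + d^2 / (2 sigma^2)} (up to an additive constant).
#' Maximizing the likelihood teaches the sigma head to recapitulate the
#' actual deviations: for fixed d the minimizer is sigma = d.
#'
#' @param d deviation(s) in Angstrom
#' @param sigma predicted deviation(s) in Angstrom, > 0
#' @return per-atom loss values
#' @export
gaussianNLL <- function(d, sigma) {
  if (any(sigma <= 0)) stop("gaussianNLL: sigma must be > 0")
  log(sigma) + d^2 / (2 * sigma^2)
}

#' Predicted RMSD over an atom selection
#'
#' pRMSD = sqrt(mean(sigma_i^2)) over the selection; used to rank sampled
#' models and, averaged over an ensemble of side-chain selections, to score
#' active-site preorganization.
#'
#' @param sigma per-atom predicted deviations (Angstrom), or a
#'   \linkS4class{ConfidenceOutput}
#' @param selection optional atom indices (default: all)
#' @return scalar pRMSD in Angstrom
#' @export
prmsd <- function(sigma, selection = NULL) {
  if (is(sigma, "ConfidenceOutput")) sigma <- sigmaValues(sigma)
  if (!is.null(selection)) sigma <- sigma[selection]
  if (!length(sigma)) stop("prmsd: empty selection")
  sqrt(mean(sigma^2))
}

.defaultBinEdges <- c(-4, -2, -1, -0.5, 0.5, 1, 2, 4)

#' Signed distance-error bin targets for atom pairs
#'
#' For each scored pair, the signed error d_model - d_reference is assigned
#' to a bin of the symmetric edge set (open tails below the first and above
#' the last edge). These are the classification targets of the pairwise
#' confidence head.
#'
#' @param model,reference \linkS4class{Conformation} objects
#' @param pairs integer matrix (nPairs x 2) of atom index pairs
#' @param binEdges signed-error bin edges in Angstrom
#' @return integer vector of bin indices in 1..(length(binEdges) + 1)
#' @export
pairErrorTargets <- function(model, reference, pairs,
                             binEdges = .defaultBinEdges) {
  xm <- coords(model); xr <- coords(reference)
  dm <- sqrt(rowSums((xm[pairs[, 1], , drop = FALSE] -
                        xm[pairs[, 2], , drop = FALSE])^2))
  dr <- sqrt(rowSums((xr[pairs[, 1], , drop = FALSE] -
                        xr[pairs[, 2], , drop = FALSE])^2))
  findInterval(dm - dr, binEdges, left.open = TRUE) + 1L
}
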