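# Structural loss / metric core: all-atom FAPE, chirality pseudoscalar and
# bias vectors, bonded-geometry errors, all-atom lDDT.
#
# Frame convention (shared by model and reference through this single code
# path): origin at atom b; x-axis along b->c; y-axis = Gram-Schmidt of b->a
# against x; z = x cross y.

#' Enumerate local frames from bonded atom triples
#'
#' One frame per path a-b-c of bonded atoms with a < c (each geometric triple
#' once). When a reference conformation is given, triples that are collinear
#' in it (angle within \code{collinearTolDeg} of 180 degrees) are excluded.
#'
#' @param graph a \linkS4class{ChemGraph}
#' @param reference optional \linkS4class{Conformation} used for the
#'   collinearity screen
#' @param collinearTolDeg collinearity tolerance (default 2 degrees)
#' @return integer matrix with columns a, b, c
#' @export
enumerateFrames <- function(graph, reference = NULL, collinearTolDeg = 2) {
  adj <- graph@adj
  out <- list()
  for (b in seq_along(adj)) {
    nb <- adj[[b]]
    if (length(nb) < 2L) next
    cmb <- utils::combn(nb, 2L)
    out[[length(out) + 1L]] <- cbind(a = cmb[1, ], b = b, c = cmb[2, ])
  }
  fr <- if (length(out)) do.call(rbind, out) else
    matrix(integer(0), 0, 3, dimnames = list(NULL, c("a", "b", "c")))
  if (!is.null(reference) && nrow(fr)) {
    xyz <- coords(reference)
    v1 <- xyz[fr[, "a"], , drop = FALSE] - xyz[fr[, "b"], , drop = FALSE]
    v2 <- xyz[fr[, "c"], , drop = FALSE] - xyz[fr[, "b"], , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    drop <- ang > (180 - collinearTolDeg)
    if (any(drop))
      message("enumerateFrames: excluded ", sum(drop),
              " collinear triple(s)")
    fr <- fr[!drop, , drop = FALSE]
  }
  fr
}

# rotation rows (e1, e2, e3) for every frame; each an F x 3 matrix.
# Local coordinates of point p are (e1.(p-b), e2.(p-b), e3.(p-b)).
.frameBasis <- function(xyz, frames) {
  A <- xyz[frames[, 1], , drop = FALSE]
  B <- xyz[frames[, 2], , drop = FALSE]
  C <- xyz[frames[, 3], , drop = FALSE]
  x <- C - B
  x <- x / sqrt(rowSums(x^2))
  u <- A - B
  u <- u - x * rowSums(u * x)
  y <- u / sqrt(rowSums(u^2))
  z <- cbind(x[, 2] * y[, 3] - x[, 3] * y[, 2],
             x[, 3] * y[, 1] - x[, 1] * y[, 3],
             x[, 1] * y[, 2] - x[, 2] * y[, 1])
  list(e1 = x, e2 = y, e3 = z, origin = B)
}

# F x N matrices of local coordinates along each basis vector
.localCoords <- function(xyz, basis) {
  n <- nrow(xyz)
  f <- nrow(basis$origin)
  lapply(list(basis$e1, basis$e2, basis$e3), function(e) {
    out <- matrix(0, f, n)
    for (c in 1:3)
      out <- out + outer(e[, c], xyz[, c]) -
        matrix(e[, c] * basis$origin[, c], f, n)
    out
  })
}

#' All-atom frame-aligned point error
#'
#' For every frame (bonded triple a-b-c) the model and the reference are each
#' expressed in the local frame built from their own three atoms; the per-atom
#' deviation is the distance between the two local positions, clamped at
#' \code{clamp} Angstrom. The returned value is the mean over all atoms and
#' all frames, which makes the loss invariant under global rigid motion of
#' either structure but sensitive to any internal rearrangement, including
#' (via frames) reflection-asymmetric ones.
#'
#' @param model,reference \linkS4class{Conformation} objects on the same atom
#'   set
#' @param graph the system's \linkS4class{ChemGraph}
#' @param clamp deviation clamp in Angstrom (default 10)
#' @param frames optional precomputed frame matrix (from
#'   \code{\link{enumerateFrames}})
#' @param returnDeviations also return the F x N matrix of clamped deviations
#' @return mean clamped deviation in Angstrom (scalar), or a list with
#'   \code{fape} and \code{deviations} when \code{returnDeviations = TRUE}
#' @export
fapeAllAtom <- function(model, reference, graph, clamp = 10, frames = NULL,
                        returnDeviations = FALSE) {
  if (is.null(frames)) frames <- enumerateFrames(graph, reference)
  if (nrow(frames) < 1L)
    stop("fapeAllAtom: no frames (need at least one bonded a-b-c triple)")
  xm <- coords(model); xr <- coords(reference)
  stopifnot(nrow(xm) == nrow(xr))
  lm <- .localCoords(xm, .frameBasis(xm, frames))
  lr <- .localCoords(xr, .frameBasis(xr, frames))
  dev2 <- (lm[[1]] - lr[[1]])^2 + (lm[[2]] - lr[[2]])^2 +
    (lm[[3]] - lr[[3]])^2
  dev <- pmin(sqrt(dev2), clamp)
  if (returnDeviations) list(fape = mean(dev), deviations = dev)
  else mean(dev)
}

#' Chirality pseudoscalar V
#'
#' Triple product of the unit vectors from a central atom O to three ordered
#' neighbours A, B, C. Its sign encodes handedness; for ideal tetrahedral
#' geometry |V| = 4/(3*sqrt(3)).
#'
#' @param o,a,b,c numeric length-3 coordinate vectors (Angstrom)
#' @return scalar pseudoscalar value
#' @export
tripleProductV <- function(o, a, b, c) {
  ea <- a - o; eb <- b - o; ec <- c - o
  na <- sqrt(sum(ea^2)); nb <- sqrt(sum(eb^2)); nc <- sqrt(sum(ec^2))
  if (min(na, nb, nc) < 1e-6)
    stop("tripleProductV: degenerate center (substituent at < 1e-6 A)")
  ea <- ea / na; eb <- eb / nb; ec <- ec / nc
  cr <- c(eb[2] * ec[3] - eb[3] * ec[2],
          eb[3] * ec[1] - eb[1] * ec[3],
          eb[1] * ec[2] - eb[2] * ec[1])
  sum(ea * cr)
}

# gradient of V w.r.t. the raw coordinates of o, a, b, c.
# d(unit u)/dx for u = v/|v| is (I - u u^T)/|v|; V is trilinear in the unit
# vectors with dV/dea = eb x ec (cyclic).
.gradTripleProductV <- function(o, a, b, c) {
  vs <- list(a - o, b - o, c - o)
  ns <- vapply(vs, function(v) sqrt(sum(v^2)), 0)
  if (min(ns) < 1e-6)
    stop("gradTripleProductV: degenerate center (substituent at < 1e-6 A)")
  us <- Map(function(v, n) v / n, vs, ns)
  cross <- function(p, q) c(p[2] * q[3] - p[3] * q[2],
                            p[3] * q[1] - p[1] * q[3],
                            p[1] * q[2] - p[2] * q[1])
  dVdu <- list(cross(us[[2]], us[[3]]),   # dV/d ea
               cross(us[[3]], us[[1]]),   # dV/d eb
               cross(us[[1]], us[[2]]))   # dV/d ec
  gA <- vector("list", 3)
  for (k in 1:3) {
    u <- us[[k]]
    gA[[k]] <- (dVdu[[k]] - u * sum(u * dVdu[[k]])) / ns[k]
  }
  list(o = -(gA[[1]] + gA[[2]] + gA[[3]]), a = gA[[1]], b = gA[[2]],
       c = gA[[3]])
}

#' Chirality biasing vectors
#'
#' Analytic gradient of (V - V_ideal)^2 with respect to the coordinates of
#' the four atoms of a chiral center; the negative gradient points in the
#' directions the atoms should move to recreate the requested handedness.
#'
#' @param center one row of a chiral-center table (columns O, A, B, C,
#'   Videal), or a list with those fields
#' @param xyz n x 3 coordinate matrix
#' @return list with 3-vectors \code{o}, \code{a}, \code{b}, \code{c} and the
#'   current \code{V}
#' @export
chiralityBiasVectors <- function(center, xyz) {
  io <- center$O; ia <- center$A; ib <- center$B; ic <- center$C
  V <- tripleProductV(xyz[io, ], xyz[ia, ], xyz[ib, ], xyz[ic, ])
  g <- .gradTripleProductV(xyz[io, ], xyz[ia, ], xyz[ib, ], xyz[ic, ])
  fac <- 2 * (V - center$Videal)
  list(o = fac * g$o, a = fac * g$a, b = fac * g$b, c = fac * g$c, V = V)
}

.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

.angleDeg <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) *
    180 / pi
}

.wrapAbsDeg <- function(d) abs(((d + 180) %% 360) - 180)

# sp2 centers: 3-coordinate C/N with an incident double or aromatic bond
.planarCenters <- function(graph) {
  at <- atomTable(graph)
  b <- bondTable(graph)
  hasMult <- rep(FALSE, nrow(at))
  mult <- b[b$order %in% c(2L, 4L), , drop = FALSE]
  hasMult[unique(c(mult$i, mult$j))] <- TRUE
  which(vapply(seq_len(nrow(at)), function(i)
    at$element[i] %in% c("C", "N") && length(graph@adj[[i]]) == 3L &&
      hasMult[i], TRUE))
}

#' Bonded-geometry error report
#'
#' Mean absolute model-vs-reference errors in bond lengths (Angstrom), bonded
#' angles (degrees, over all a-b-c paths), planar angles (degrees, improper
#' dihedrals at sp2 centers flagged planar from bond orders) and chiral
#' angles (degrees, improper dihedrals O-A-B-C at perceived chiral centers).
#' Categories with no members report 0 with \code{defined = FALSE}.
#'
#' @param model,reference \linkS4class{Conformation} objects
#' @param graph a \linkS4class{ChemGraph} (chiral centers must be attached
#'   for the chiral-angle entry)
#' @return object of class \code{GeometryErrorReport}: list with \code{bond},
#'   \code{angle}, \code{planar}, \code{chiral}, \code{defined}, \code{counts}
#' @export
bondedGeometryErrors <- function(model, reference, graph) {
  xm <- coords(model); xr <- coords(reference)
  b <- bondTable(graph)
  bondErr <- if (nrow(b)) {
    dm <- sqrt(rowSums((xm[b$i, , drop = FALSE] - xm[b$j, , drop = FALSE])^2))
    dr <- sqrt(rowSums((xr[b$i, , drop = FALSE] - xr[b$j, , drop = FALSE])^2))
    mean(abs(dm - dr))
  } else 0
  fr <- enumerateFrames(graph)  # all a-b-c paths, no collinearity screen
  angErr <- if (nrow(fr)) {
    am <- vapply(seq_len(nrow(fr)), function(k)
      .angleDeg(xm[fr[k, 1], ], xm[fr[k, 2], ], xm[fr[k, 3], ]), 0)
    ar <- vapply(seq_len(nrow(fr)), function(k)
      .angleDeg(xr[fr[k, 1], ], xr[fr[k, 2], ], xr[fr[k, 3], ]), 0)
    mean(abs(am - ar))
  } else 0
  pc <- .planarCenters(graph)
  planErr <- if (length(pc)) {
    mean(vapply(pc, function(o) {
      nb <- sort(graph@adj[[o]])
      tm <- .torsion(xm[o, ], xm[nb[1], ], xm[nb[2], ], xm[nb[3], ])
      tr <- .torsion(xr[o, ], xr[nb[1], ], xr[nb[2], ], xr[nb[3], ])
      .wrapAbsDeg(tm - tr)
    }, 0))
  } else 0
  ch <- chiralCenters(graph)
  chirErr <- if (nrow(ch)) {
    mean(vapply(seq_len(nrow(ch)), function(k) {
      idx <- c(ch$O[k], ch$A[k], ch$B[k], ch$C[k])
      tm <- .torsion(xm[idx[1], ], xm[idx[2], ], xm[idx[3], ], xm[idx[4], ])
      tr <- .torsion(xr[idx[1], ], xr[idx[2], ], xr[idx[3], ], xr[idx[4], ])
      .wrapAbsDeg(tm - tr)
    }, 0))
  } else 0
  structure(list(
    bond = bondErr, angle = angErr, planar = planErr, chiral = chirErr,
    defined = c(bond = nrow(b) > 0, angle = nrow(fr) > 0,
                planar = length(pc) > 0, chiral = nrow(ch) > 0),
    counts = c(bond = nrow(b), angle = nrow(fr), planar = length(pc),
               chiral = nrow(ch))),
    class = "GeometryErrorReport")
}

#' @export
print.GeometryErrorReport <- function(x, ...) {
  cat(sprintf(
    "GeometryErrorReport: bond %.4f A | angle %.3f deg | planar %.3f deg | chiral %.3f deg\n",
    x$bond, x$angle, x$planar, x$chiral))
  und <- names(x$defined)[!x$defined]
  if (length(und)) cat("  (no members:", paste(und, collapse = ", "), ")\n")
  invisible(x)
}

#' Per-atom all-atom lDDT
#'
#' Local distance difference test: for each atom, over reference partners
#' within \code{radius} Angstrom -- excluding partners of the same covalent
#' component fewer than \code{minSep} bonds away, so the score measures
#' packing rather than bonded geometry -- the fraction of pair distances
#' preserved within each threshold, averaged over thresholds. Atoms with no
#' qualifying partner are NA.
#'
#' @param model,reference \linkS4class{Conformation} objects
#' @param graph a \linkS4class{ChemGraph}
#' @param radius inclusion radius in the reference (default 15 Angstrom)
#' @param thresholds preservation thresholds (default 0.5, 1, 2, 4 Angstrom)
#' @param minSep minimum bond separation for same-component partners
#'   (default 4)
#' @return numeric vector of per-atom scores in [0, 1] (NA = undefined)
#' @export
lddtPerAtom <- function(model, reference, graph, radius = 15,
                        thresholds = c(0.5, 1, 2, 4), minSep = 4L) {
  xm <- coords(model); xr <- coords(reference)
  n <- nrow(xr)
  dr <- as.matrix(stats::dist(xr))
  dm <- as.matrix(stats::dist(xm))
  sep <- bondSeparation(graph)
  qual <- dr <= radius & !(is.finite(sep) & sep < minSep)
  diag(qual) <- FALSE
  err <- abs(dm - dr)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- which(qual[i, ])
    if (!length(p)) next
    out[i] <- mean(vapply(thresholds, function(t) mean(err[i, p] < t), 0))
  }
  out
}
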