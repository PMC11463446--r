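# Miniature three-track iterative denoiser.
#
# Tracks: 1D per-atom embeddings, 2D per-pair embeddings on the dense crop
# pair grid, and the 3D coordinate state. Each shared-weight iteration block
# (i) rebuilds the mixed spatial/chemical neighbor graph from the current
# coordinates, (ii) runs nInner equivariant message-passing sub-layers that
# update coordinates and 1D embeddings, (iii) applies a pair-to-pair update
# biased by a radial-basis encoding of current distances, and (iv) branches
# off per-atom (sigma, plddt) and per-pair (signed distance-error bins)
# confidence heads.
#
# The coordinate update is strictly SE(3)-equivariant: displacements are
# sums of difference vectors to neighbors and of chirality bias vectors
# (type-1 features recomputed from the current coordinates), both scaled by
# invariant gates. All scalar tracks see only distances and graph features,
# so they are rigid-motion invariant; chirality vectors flip under
# reflection, which is what lets the network distinguish enantiomers.

.featElements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Se",
                   "Na", "K", "Mg", "Ca", "Zn", "Fe", "Mn", "Cu")
.nBins <- 9L
.sepClamp <- 32L

#' Input featurization of a chemical graph
#'
#' 1D features: element one-hot (supported organic set plus common metals,
#' hydrogens excluded), formal charge, role flag. 2D features (dense pair
#' grid, column-major pair index i + (j-1)*n): bonded flag, bond order,
#' clamped bond separation, an "unconnected" token for cross-component pairs,
#' and a same-component flag. No feature depends on reference coordinates.
#'
#' @param graph a \linkS4class{ChemGraph}
#' @return list with \code{f1} (n x 23) and \code{f2} (n^2 x 5)
#' @export
embedInputs <- function(graph) {
  at <- atomTable(graph)
  n <- nrow(at)
  bad <- !at$element %in% .featElements
  if (any(bad))
    stop("embedInputs: unsupported element(s): ",
         paste(unique(at$element[bad]), collapse = ", "))
  f1 <- matrix(0, n, length(.featElements) + 4L)
  f1[cbind(seq_len(n), match(at$element, .featElements))] <- 1
  f1[, length(.featElements) + 1L] <- pmax(-3, pmin(3, at$charge)) / 3
  f1[cbind(seq_len(n), length(.featElements) + 1L +
             match(at$role, c("backbone", "sidechain", "ligand")))] <- 1
  sep <- bondSeparation(graph)
  b <- bondTable(graph)
  bonded <- matrix(0, n, n)
  order <- matrix(0, n, n)
  if (nrow(b)) {
    bonded[cbind(b$i, b$j)] <- 1; bonded[cbind(b$j, b$i)] <- 1
    ov <- ifelse(b$order == 4L, 1.5, b$order)
    order[cbind(b$i, b$j)] <- ov; order[cbind(b$j, b$i)] <- ov
  }
  unconnected <- !is.finite(sep)
  sepC <- pmin(sep, .sepClamp)
  sepC[unconnected] <- .sepClamp
  sameComp <- outer(at$component, at$component, `==`)
  # small separations one-hot encoded so that 1-, 2- and 3-bond contexts are
  # sharply distinguishable; larger ones carried by the clamped scalar
  sepOneHot <- vapply(1:8, function(s) as.vector(sep == s) * 1, numeric(n * n))
  f2 <- cbind(as.vector(bonded), as.vector(order) / 3, sepOneHot,
              as.vector(sepC) / .sepClamp, as.vector(unconnected) * 1,
              as.vector(sameComp) * 1)
  list(f1 = f1, f2 = f2)
}

#' Mixed spatial/chemical neighbor graph
#'
#' For every atom, K neighbors picked in equal proportions by spatial
#' proximity (current 3D distance, ties broken by atom index) and by
#' proximity in the chemical graph (bond separation, ties by separation then
#' index). Duplicates between the two halves are replaced by next-nearest
#' spatial candidates; lists are padded with NA when the system has fewer
#' than K other atoms.
#'
#' @param graph a \linkS4class{ChemGraph}
#' @param xyz current coordinates (n x 3)
#' @param K neighbor count (even, default 32)
#' @return integer matrix n x K (NA = sentinel padding)
#' @export
buildNeighborGraph <- function(graph, xyz, K = 32L) {
  stopifnot(K %% 2L == 0L, K >= 2L)
  n <- nrow(xyz)
  sep <- bondSeparation(graph)
  out <- matrix(NA_integer_, n, K)
  half <- K %/% 2L
  d2 <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    spatOrd <- others[order(d2[i, others], others)]
    fin <- others[is.finite(sep[i, others])]
    chemOrd <- fin[order(sep[i, fin], fin)]
    sel <- unique(c(spatOrd[seq_len(min(half, length(spatOrd)))],
                    chemOrd[seq_len(min(half, length(chemOrd)))]))
    for (cand in spatOrd) {
      if (length(sel) >= min(K, length(others))) break
      if (!cand %in% sel) sel <- c(sel, cand)
    }
    out[i, seq_along(sel)] <- sel
  }
  out
}

.rbfCenters <- function(nRBF) seq(0, 12, length.out = nRBF)

#' Initialize denoiser weights
#'
#' All blocks share this single parameter set. The coordinate-update and
#' chirality-gate output weights start at zero, so a freshly initialized
#' block leaves coordinates unchanged.
#'
#' @param config a \linkS4class{ModelConfig}
#' @return a \linkS4class{DenoiserModel}
#' @export
initNetwork <- function(config = microConfig()) {
  d1 <- config@d1; d2 <- config@d2; R <- config@nRBF
  f1 <- length(.featElements) + 4L
  f2 <- 13L
  rn <- function(r, c) matrix(stats::rnorm(r * c, 0, 1 / sqrt(r)), r, c)
  w <- withSeed(config@seed, {
    w <- list(
      Wemb1 = rn(f1, d1), bemb1 = numeric(d1),
      Wemb2 = rn(f2, d2), bemb2 = numeric(d2),
      Wadapt = rn(d2, d2), badapt = numeric(d2),
      Wp1 = rn(d2 + R, d2), bp1 = numeric(d2),
      Wp2 = rn(d2, d2), bp2 = numeric(d2),
      wSig = rn(d1, 1), bSig = -2.9,
      wPl = rn(d1, 1), bPl = 0,
      Wbin = rn(d2, .nBins), bbin = numeric(.nBins),
      # distogram-style per-edge target-distance head on the pair track
      wD = rn(d2, 1), bD = 1
    )
    # the equivariant network inside a block has nInner layers with their
    # own weights; only blocks share parameters
    for (l in seq_len(config@nInner)) {
      w[[paste0("Wmsg1_", l)]] <- rn(2L * d1 + R + d2, d1)
      w[[paste0("bmsg1_", l)]] <- numeric(d1)
      w[[paste0("Wmsg2_", l)]] <- rn(d1, d1)
      w[[paste0("bmsg2_", l)]] <- numeric(d1)
      w[[paste0("wX_", l)]] <- matrix(0, d1, 3)   # three radial channels
      w[[paste0("bX_", l)]] <- numeric(3)
      w[[paste0("wChir_", l)]] <- matrix(0, d1, 1)
      w[[paste0("bChir_", l)]] <- numeric(1)
      w[[paste0("Wh1_", l)]] <- rn(2L * d1, d1)
      w[[paste0("bh1_", l)]] <- numeric(d1)
      w[[paste0("Wh2_", l)]] <- rn(d1, d1)
      w[[paste0("bh2_", l)]] <- numeric(d1)
    }
    w
  })
  new("DenoiserModel", config = config, weights = w)
}

# summed chirality bias fields, one 3-vector per atom, computed from the
# current coordinates for the *requested* handedness of every center.
# f = -grad (V - V_ideal)^2 : the descent direction toward the target sign.
.chiralityField <- function(graph, xyz) {
  ch <- chiralCenters(graph)
  f <- matrix(0, nrow(xyz), 3)
  if (!nrow(ch)) return(f)
  for (k in seq_len(nrow(ch))) {
    bv <- chiralityBiasVectors(ch[k, ], xyz)
    f[ch$O[k], ] <- f[ch$O[k], ] - bv$o
    f[ch$A[k], ] <- f[ch$A[k], ] - bv$a
    f[ch$B[k], ] <- f[ch$B[k], ] - bv$b
    f[ch$C[k], ] <- f[ch$C[k], ] - bv$c
  }
  f
}

# One full forward pass. `weights` entries may be tape nodes (training) or
# plain matrices (inference); `X` likewise becomes a node chain when a tape
# is supplied. Returns per-block coordinate states and confidence outputs
# (as nodes when recording).
.forwardInternal <- function(graph, corrupted, weights, config,
                             nBlocks = NULL) {
  n <- natoms(graph)
  if (n > 600L)
    stop("forward: systems above the 600-atom crop cap are rejected; crop first")
  if (is.null(nBlocks)) nBlocks <- config@nBlocks
  feats <- embedInputs(graph)
  centers <- .rbfCenters(config@nRBF)
  gamma <- 1 / (2 * (centers[2] - centers[1])^2)
  W <- weights
  H <- adTanh(adAddRowVec(adMatmul(feats$f1, W$Wemb1), W$bemb1))
  P <- adTanh(adAddRowVec(adMatmul(feats$f2, W$Wemb2), W$bemb2))
  X <- coords(corrupted)
  blocks <- list()
  for (blk in seq_len(nBlocks)) {
    ng <- buildNeighborGraph(graph, adVal(X), config@K)
    ei <- rep(seq_len(n), times = ncol(ng))
    ej <- as.vector(ng)
    keep <- !is.na(ej)
    ei <- ei[keep]; ej <- ej[keep]
    cnt <- tabulate(ei, nbins = n)
    pidx <- ei + (ej - 1L) * n
    Ee <- adTanh(adAddRowVec(adMatmul(adGatherRows(P, pidx), W$Wadapt),
                             W$badapt))
    # predicted target distance per neighbor edge (softplus keeps it > 0.3)
    dpre <- adAdd(adVec(adMatmul(Ee, W$wD)), W$bD)
    dhat <- adAdd(adLog(adAdd(adExp(dpre), 1)), 0.3)
    for (l in seq_len(config@nInner)) {
      xi <- adGatherRows(X, ei)
      xj <- adGatherRows(X, ej)
      diff <- adSub(xj, xi)
      dist <- adSqrt(adAdd(adRowSums(adSquare(diff)), 1e-8))
      rbf <- adExp(adMul(adSquare(adOuterSub(dist, centers)), -gamma))
      hi <- adGatherRows(H, ei)
      hj <- adGatherRows(H, ej)
      m1 <- adTanh(adAddRowVec(adMatmul(adCbind(hi, hj, rbf, Ee),
                                        W[[paste0("Wmsg1_", l)]]),
                               W[[paste0("bmsg1_", l)]]))
      msg <- adTanh(adAddRowVec(adMatmul(m1, W[[paste0("Wmsg2_", l)]]),
                                W[[paste0("bmsg2_", l)]]))
      if (config@updateCoords) {
        gates <- adTanh(adAddRowVec(adMatmul(msg, W[[paste0("wX_", l)]]),
                                    W[[paste0("bX_", l)]]))
        # three bounded radial channels: relative displacement, near-unit
        # direction, and distance-geometry relaxation toward the pair
        # track's predicted target distance
        w1 <- adMul(adDiv(adCol(gates, 1), adAdd(dist, 1)), 4)
        w2 <- adDiv(adCol(gates, 2), adAdd(dist, 0.3))
        w3 <- adDiv(adMul(adCol(gates, 3), adSub(dist, dhat)),
                    adAdd(dist, 0.3))
        contrib <- adAdd(adAdd(adRowMul(diff, w1), adRowMul(diff, w2)),
                         adRowMul(diff, w3))
        dx <- adRowMul(adSegSum(contrib, ei, n), 1 / pmax(cnt, 1L))
        fch <- .chiralityField(graph, adVal(X))
        cg <- adTanh(adAdd(adVec(adMatmul(H, W[[paste0("wChir_", l)]])),
                           W[[paste0("bChir_", l)]]))
        X <- adAdd(X, adAdd(dx, adRowMul(fch, cg)))
      }
      S <- adRowMul(adSegSum(msg, ei, n), 1 / pmax(cnt, 1L))
      u <- adTanh(adAddRowVec(adMatmul(adCbind(H, S),
                                       W[[paste0("Wh1_", l)]]),
                              W[[paste0("bh1_", l)]]))
      H <- adAdd(H, adAddRowVec(adMatmul(u, W[[paste0("Wh2_", l)]]),
                                W[[paste0("bh2_", l)]]))
    }
    # pair-to-pair update with bias from structure
    G <- adMatmul(X, adT(X))
    r2 <- adRowSums(adSquare(X))
    D2 <- adSub(adOuterPlus(r2, r2), adMul(G, 2))
    Dv <- adSqrt(adAdd(adVec(D2), 1e-8))
    rbfP <- adExp(adMul(adSquare(adOuterSub(Dv, centers)), -gamma))
    up <- adTanh(adAddRowVec(adMatmul(adCbind(P, rbfP), W$Wp1), W$bp1))
    P <- adAdd(P, adAddRowVec(adMatmul(up, W$Wp2), W$bp2))
    # confidence heads
    sig <- adAdd(.sigmaFloor,
                 adMul(adSigmoid(adAdd(adVec(adMatmul(H, W$wSig)), W$bSig)),
                       .sigmaCap - .sigmaFloor))
    pl <- adSigmoid(adAdd(adVec(adMatmul(H, W$wPl)), W$bPl))
    logits <- adAddRowVec(adMatmul(adGatherRows(P, pidx), W$Wbin), W$bbin)
    if (any(!is.finite(adVal(X))))
      stop("forward: NaN coordinates in block ", blk)
    blocks[[blk]] <- list(X = X, sigma = sig, plddt = pl, logits = logits,
                          pairIdx = cbind(ei, ej), dhat = dhat)
  }
  list(blocks = blocks, X = X, H = H, P = P)
}

#' Run the denoiser
#'
#' Applies \code{nBlocks} shared-weight iteration blocks to a corrupted
#' conformation. The network itself is deterministic: all stochasticity lives
#' in the input corruption.
#'
#' @param graph a \linkS4class{ChemGraph}
#' @param corrupted the corrupted input \linkS4class{Conformation}
#' @param model a trained (or freshly initialized) \linkS4class{DenoiserModel}
#' @param nBlocks optional override of the block count
#' @return list with \code{conformation} (denoised), \code{confidence}
#'   (final-block \linkS4class{ConfidenceOutput}) and \code{perBlock} (list
#'   of per-iteration coordinate matrices)
#' @export
denoise <- function(graph, corrupted, model, nBlocks = NULL) {
  out <- .forwardInternal(graph, corrupted, model@weights, model@config,
                          nBlocks = nBlocks)
  n <- natoms(graph)
  if (!length(out$blocks)) {
    conf <- new("ConfidenceOutput", sigma = rep(1, n), plddt = rep(NA_real_, n),
                pairIdx = matrix(integer(0), 0, 2),
                pairLogits = matrix(numeric(0), 0, .nBins))
    return(list(conformation = Conformation(adVal(out$X)), confidence = conf,
                perBlock = list()))
  }
  last <- out$blocks[[length(out$blocks)]]
  conf <- new("ConfidenceOutput", sigma = adVal(last$sigma),
              plddt = adVal(last$plddt), pairIdx = last$pairIdx,
              pairLogits = adVal(last$logits),
              binEdges = .defaultBinEdges)
  list(conformation = Conformation(adVal(last$X)), confidence = conf,
       perBlock = lapply(out$blocks, function(b) adVal(b$X)))
}

#' Number of trainable parameters of a model
#' @param model a DenoiserModel
#' @export
parameterCount <- function(model) {
  sum(vapply(model@weights, length, 1L))
}
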