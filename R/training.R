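# Desk-scale training: two-stage schedule (stage 1 FAPE-only with fewer
# blocks; stage 2 full depth plus bonded-geometry and confidence losses),
# losses applied after every iteration block, full-batch Adam.

# ---- differentiable structural losses on the tape ------------------------

# local coordinates of all atoms in frames built from (possibly node) X
.adLocalCoords <- function(X, frames) {
  A <- adGatherRows(X, frames[, 1])
  B <- adGatherRows(X, frames[, 2])
  C <- adGatherRows(X, frames[, 3])
  ex <- adUnitRows(adSub(C, B))
  u <- adSub(A, B)
  u <- adSub(u, adRowMul(ex, adRowSums(adMul(u, ex))))
  ey <- adUnitRows(u)
  ez <- adCross3(ex, ey)
  lapply(list(ex, ey, ez), function(e) {
    acc <- NULL
    for (c in 1:3) {
      term <- adOuterProd(adCol(e, c), adCol(X, c))
      acc <- if (is.null(acc)) term else adAdd(acc, term)
    }
    q <- adRowSums(adMul(e, B))
    adRowAddVec(acc, adNeg(q))
  })
}

# sweep a (possibly node) column vector over the rows of a matrix
adRowAddVec <- function(m, v) .binop(m, v,
  function(mv, vv) sweep(mv, 1L, vv, `+`),
  function(g, mv, vv) g,
  function(g, mv, vv) rowSums(g))

adFape <- function(X, refLocal, frames, clamp = 10) {
  lm <- .adLocalCoords(X, frames)
  dev2 <- NULL
  for (k in 1:3) {
    t <- adSquare(adSub(lm[[k]], refLocal[[k]]))
    dev2 <- if (is.null(dev2)) t else adAdd(dev2, t)
  }
  adMean(adClampMax(adSqrt(adAdd(dev2, 1e-12)), clamp))
}

adBondLoss <- function(X, bonds, refLen) {
  di <- adGatherRows(X, bonds$i)
  dj <- adGatherRows(X, bonds$j)
  len <- adSqrt(adAdd(adRowSums(adSquare(adSub(di, dj))), 1e-12))
  adMean(adAbs(adSub(len, refLen)))
}

adAngleLoss <- function(X, frames, refAngDeg) {
  A <- adGatherRows(X, frames[, 1])
  B <- adGatherRows(X, frames[, 2])
  C <- adGatherRows(X, frames[, 3])
  u <- adUnitRows(adSub(A, B))
  v <- adUnitRows(adSub(C, B))
  ang <- adMul(adAcosSafe(adRowSums(adMul(u, v))), 180 / pi)
  adMean(adAbs(adSub(ang, refAngDeg)))
}

adChiralLoss <- function(X, centers) {
  O <- adGatherRows(X, centers$O)
  ua <- adUnitRows(adSub(adGatherRows(X, centers$A), O))
  ub <- adUnitRows(adSub(adGatherRows(X, centers$B), O))
  uc <- adUnitRows(adSub(adGatherRows(X, centers$C), O))
  V <- adRowSums(adMul(ua, adCross3(ub, uc)))
  adMean(adSquare(adSub(V, centers$Videal)))
}

# mean absolute error over within-component pair distances (superposition-
# free, chirality-blind; used only as a warm-up to condition the expansion
# field before FAPE takes over)
adDistLoss <- function(X, pairs, refD) {
  di <- adGatherRows(X, pairs[, 1])
  dj <- adGatherRows(X, pairs[, 2])
  d <- adSqrt(adAdd(adRowSums(adSquare(adSub(di, dj))), 1e-12))
  adMean(adAbs(adSub(d, refD)))
}

adNLLLoss <- function(sigma, dRaw) {
  adMean(adAdd(adLog(sigma),
               adDiv(dRaw^2, adMul(adSquare(sigma), 2))))
}

adPlddtLoss <- function(plddt, targetRaw) {
  ok <- which(!is.na(targetRaw))
  if (!length(ok)) return(0)
  adMean(adSquare(adSub(adGatherVec(plddt, ok), targetRaw[ok])))
}

adCrossEntropy <- function(logits, targetIdx) {
  nr <- nrow(adVal(logits))
  mx <- apply(adVal(logits), 1L, max)
  sh <- adRowAddVec(logits, -mx)
  lse <- adAdd(adLog(adRowSums(adExp(sh))), mx)
  picked <- adGatherVec(adVec(sh), seq_len(nr) + (targetIdx - 1L) * nr)
  adMean(adSub(lse, adAdd(picked, -mx)))
}

# ---- schedule ------------------------------------------------------------

#' Default two-stage training schedule
#'
#' Stage 1 runs fewer blocks with the all-atom FAPE as the only loss; stage 2
#' runs the configured depth and adds bonded-geometry, chirality and
#' confidence loss terms. Loss weights (FAPE 1.0, bond 1.0 per Angstrom,
#' angles 0.02 per degree, chirality 1.0, plus small confidence weights) are
#' exposed here.
#'
#' @param config a \linkS4class{ModelConfig}
#' @param steps1,steps2 optimizer steps per stage
#' @param lr1,lr2 learning rates
#' @export
trainingSchedule <- function(config = microConfig(), steps1 = 150L,
                             steps2 = 250L, lr1 = 0.005, lr2 = 0.003) {
  list(
    list(nBlocks = max(1L, config@nBlocks %/% 2L), steps = as.integer(steps1),
         lr = lr1,
         weights = c(fape = 1, dist = 0.3, dpred = 0.3, bond = 0, angle = 0,
                     chiral = 0, nll = 0, plddt = 0, pairbin = 0)),
    list(nBlocks = config@nBlocks, steps = as.integer(steps2), lr = lr2,
         weights = c(fape = 1, dist = 0.1, dpred = 0.3, bond = 1,
                     angle = 0.02, chiral = 1, nll = 0.1, plddt = 0.05,
                     pairbin = 0.02))
  )
}

# per-fixture constants reused at every step
.prepItem <- function(item) {
  graph <- item$graph
  ref <- item$conformation
  frames <- enumerateFrames(graph, ref)
  xr <- coords(ref)
  refLocal <- .adLocalCoords(xr, frames)
  b <- bondTable(graph)
  refLen <- sqrt(rowSums((xr[b$i, , drop = FALSE] - xr[b$j, , drop = FALSE])^2))
  allAng <- enumerateFrames(graph)
  refAng <- vapply(seq_len(nrow(allAng)), function(k)
    .angleDeg(xr[allAng[k, 1], ], xr[allAng[k, 2], ], xr[allAng[k, 3], ]), 0)
  sep <- bondSeparation(graph)
  pr <- which(upper.tri(sep) & is.finite(sep), arr.ind = TRUE)
  refD <- sqrt(rowSums((xr[pr[, 1], , drop = FALSE] -
                          xr[pr[, 2], , drop = FALSE])^2))
  list(graph = graph, ref = ref, frames = frames, refLocal = refLocal,
       bonds = b, refLen = refLen, angFrames = allAng, refAng = refAng,
       chiral = chiralCenters(graph), distPairs = pr, refD = refD)
}

#' Train the denoiser on a small fixture dataset
#'
#' Full-batch gradient training with a two-stage schedule; the corruption is
#' resampled every step from a deterministic seed stream, and the combined
#' loss is averaged over all iteration blocks (losses applied after every
#' iteration). A fixed \code{seed} reproduces the loss trace exactly on one
#' device.
#'
#' @param dataset list of items with \code{graph} and \code{conformation}
#'   (e.g. from \code{\link{makeTrainingSet}}); at most 50 systems
#' @param config a \linkS4class{ModelConfig}
#' @param schedule list of stages, see \code{\link{trainingSchedule}}
#' @param noiseSigma corruption noise scale (Angstrom)
#' @param corruptor function(graph, reference, seed) returning the corrupted
#'   \linkS4class{Conformation}; defaults to the standard training-mode
#'   corruption. Override for calibration toys with bespoke noise models.
#' @param seed master seed for weight init and the corruption stream
#' @param verbose print the loss every 25 steps
#' @return list with \code{model} (a \linkS4class{DenoiserModel}) and
#'   \code{trace} (data.frame: stage, step, loss, fape)
#' @export
trainMicro <- function(dataset, config = microConfig(),
                       schedule = trainingSchedule(config),
                       noiseSigma = 1.5, corruptor = NULL, seed = 1L,
                       replicates = 2L, verbose = FALSE) {
  if (is.null(corruptor))
    corruptor <- function(graph, reference, seed)
      corruptConformation(graph, reference,
        corruptionConfig(noiseSigma = noiseSigma, mode = "training",
                         seed = seed))
  if (length(dataset) > 50L)
    stop("trainMicro: desk-scale training accepts at most 50 systems")
  config@seed <- as.integer(seed)
  model <- initNetwork(config)
  params <- model@weights
  items <- lapply(dataset, .prepItem)
  trace <- list()
  stepGlobal <- 0L
  for (si in seq_along(schedule)) {
    st <- schedule[[si]]
    stReps <- if (!is.null(st$replicates)) st$replicates else replicates
    state <- adamInit(params)
    for (step in seq_len(st$steps)) {
      stepGlobal <- stepGlobal + 1L
      tape <- adTape()
      pnodes <- lapply(params, function(p) adParam(tape, p))
      total <- NULL
      fapeAcc <- 0
      for (ii in seq_along(items)) {
       for (rep in seq_len(stReps)) {
        it <- items[[ii]]
        cseed <- (as.integer(seed) + 7919L * stepGlobal + 104729L * ii +
                    611953L * rep) %% 2000000000L
        corr <- corruptor(it$graph, it$ref, cseed)
        fw <- .forwardInternal(it$graph, corr, pnodes, config,
                               nBlocks = st$nBlocks)
        w <- st$weights
        itemLoss <- NULL
        for (bi in seq_along(fw$blocks)) {
          bl <- fw$blocks[[bi]]
          li <- adMul(adFape(bl$X, it$refLocal, it$frames), w[["fape"]])
          if (!is.na(w["dist"]) && w[["dist"]] > 0 && nrow(it$distPairs))
            li <- adAdd(li, adMul(adDistLoss(bl$X, it$distPairs, it$refD),
                                  w[["dist"]]))
          if (!is.na(w["dpred"]) && w[["dpred"]] > 0) {
            xr <- coords(it$ref)
            dr <- sqrt(rowSums((xr[bl$pairIdx[, 1], , drop = FALSE] -
                                  xr[bl$pairIdx[, 2], , drop = FALSE])^2))
            li <- adAdd(li, adMul(adMean(adAbs(adSub(bl$dhat, pmin(dr, 12)))),
                                  w[["dpred"]]))
          }
          if (w[["bond"]] > 0 && nrow(it$bonds))
            li <- adAdd(li, adMul(adBondLoss(bl$X, it$bonds, it$refLen),
                                  w[["bond"]]))
          if (w[["angle"]] > 0 && nrow(it$angFrames))
            li <- adAdd(li, adMul(adAngleLoss(bl$X, it$angFrames, it$refAng),
                                  w[["angle"]]))
          if (w[["chiral"]] > 0 && nrow(it$chiral))
            li <- adAdd(li, adMul(adChiralLoss(bl$X, it$chiral), w[["chiral"]]))
          if (w[["nll"]] > 0) {
            dRaw <- deviationTargets(Conformation(adVal(bl$X)), it$ref)
            li <- adAdd(li, adMul(adNLLLoss(bl$sigma, dRaw), w[["nll"]]))
          }
          if (w[["plddt"]] > 0) {
            tgt <- lddtPerAtom(Conformation(adVal(bl$X)), it$ref, it$graph)
            pls <- adPlddtLoss(bl$plddt, tgt)
            if (.isNode(pls)) li <- adAdd(li, adMul(pls, w[["plddt"]]))
          }
          if (w[["pairbin"]] > 0 && nrow(bl$pairIdx)) {
            tIdx <- pairErrorTargets(Conformation(adVal(bl$X)), it$ref,
                                     bl$pairIdx)
            li <- adAdd(li, adMul(adCrossEntropy(bl$logits, tIdx),
                                  w[["pairbin"]]))
          }
          itemLoss <- if (is.null(itemLoss)) li else adAdd(itemLoss, li)
          if (bi == length(fw$blocks) && rep == 1L)
            fapeAcc <- fapeAcc + adVal(adFape(bl$X, it$refLocal, it$frames))
        }
        itemLoss <- adMul(itemLoss, 1 / length(fw$blocks))
        total <- if (is.null(total)) itemLoss else adAdd(total, itemLoss)
       }
      }
      total <- adMul(total, 1 / (length(items) * stReps))
      if (!is.finite(adVal(total))) {
        tr <- do.call(rbind, trace)
        stop("trainMicro: loss diverged (NaN) at stage ", si, " step ", step,
             "; trace has ", if (is.null(tr)) 0L else nrow(tr), " rows")
      }
      adBackward(tape, total)
      grads <- lapply(pnodes, function(p)
        if (is.null(p$grad)) p$val * 0 else p$grad)
      # cosine decay to 15% of the stage learning rate
      lrt <- st$lr * (0.15 + 0.85 * 0.5 * (1 + cos(pi * (step - 1) / st$steps)))
      upd <- adamStep(params, grads, state, lr = lrt)
      params <- upd$params
      state <- upd$state
      trace[[length(trace) + 1L]] <- data.frame(
        stage = si, step = step, loss = adVal(total),
        fape = fapeAcc / length(items))
      if (verbose && step %% 25L == 0L)
        message(sprintf("stage %d step %4d  loss %.4f  fape %.3f", si, step,
                        adVal(total), fapeAcc / length(items)))
    }
  }
  model@weights <- params
  list(model = model, trace = do.call(rbind, trace))
}
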