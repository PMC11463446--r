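# featurization, neighbor graph, iteration behavior of the denoiser

test_that("features never leak reference coordinates and permute with the atoms", {
  m <- makeMolecule("chain", 6)
  f <- embedInputs(m$graph)
  expect_equal(nrow(f$f1), 6L)
  expect_equal(nrow(f$f2), 36L)
  # permuted construction: reverse the atom order of the same molecule
  rev <- MolRecord("chain", data.frame(
    element = rev(atomTable(m$graph)$element), charge = 0L),
    data.frame(i = 6L - bondTable(m$graph)$j + 1L,
               j = 6L - bondTable(m$graph)$i + 1L,
               order = 1L),
    coords(m$conformation)[6:1, ])
  mrev <- buildChemGraph(ligands = list(rev))
  frev <- embedInputs(mrev$graph)
  perm <- 6:1
  expect_equal(frev$f1, f$f1[perm, ])
  idx <- as.vector(outer(perm, (perm - 1L) * 6L, `+`))
  expect_equal(frev$f2, f$f2[idx, ])
})

test_that("disconnected pairs carry the unconnected token", {
  two <- buildChemGraph(ligands = list(
    MolRecord("a", data.frame(element = c("C", "C"), charge = 0L),
              data.frame(i = 1L, j = 2L, order = 1L),
              rbind(c(0, 0, 0), c(1.5, 0, 0))),
    MolRecord("b", data.frame(element = "N", charge = 0L),
              data.frame(i = integer(0), j = integer(0), order = integer(0)),
              matrix(c(8, 0, 0), 1))))
  f <- embedInputs(two$graph)
  n <- 3L
  uncol <- ncol(f$f2) - 1L  # unconnected token column
  p13 <- 1L + (3L - 1L) * n
  p12 <- 1L + (2L - 1L) * n
  expect_equal(f$f2[p13, uncol], 1)
  expect_equal(f$f2[p12, uncol], 0)
  expect_error(embedInputs(setChiralCenters(local({
    g <- two$graph; g@atoms$element[1] <- "Xx"; g
  }), chiralCenters(two$graph))), "unsupported element")
})

test_that("every neighbor list has length 32 on a 120-atom system under reference defaults", {
  p <- makeToyPocket(nRes = 22, seed = 7)
  expect_gte(natoms(p$graph), 110L)
  ng <- buildNeighborGraph(p$graph, coords(p$conformation), K = 32L)
  expect_equal(ncol(ng), 32L)
  expect_true(all(rowSums(!is.na(ng)) == 32L))
  expect_true(all(ng != row(ng), na.rm = TRUE))
})

test_that("small systems pad their neighbor lists with sentinels", {
  m <- makeMolecule("chain", 10)
  ng <- buildNeighborGraph(m$graph, coords(m$conformation), K = 16L)
  expect_true(all(rowSums(!is.na(ng)) == 9L))
  for (i in 1:10) expect_setequal(ng[i, !is.na(ng[i, ])], setdiff(1:10, i))
})

test_that("the chemical half matches a sorting oracle on bond separation", {
  p <- makeToyPocket(nRes = 22, seed = 8)
  sep <- bondSeparation(p$graph)
  ng <- buildNeighborGraph(p$graph, coords(p$conformation), K = 32L)
  d <- as.matrix(dist(coords(p$conformation)))
  n <- natoms(p$graph)
  for (i in c(1L, 25L, 60L)) {
    others <- setdiff(seq_len(n), i)
    fin <- others[is.finite(sep[i, others])]
    chemOracle <- fin[order(sep[i, fin], fin)][seq_len(min(16L, length(fin)))]
    spatial <- others[order(d[i, others], others)][1:16]
    expect_true(all(union(spatial, chemOracle) %in% ng[i, ]))
  }
})

test_that("a freshly initialized block leaves coordinates unchanged", {
  m <- makeMolecule("branched")
  mdl <- initNetwork(microConfig(seed = 5))
  corr <- corruptConformation(m$graph, m$conformation, corruptionConfig(seed = 2))
  out <- denoise(m$graph, corr, mdl)
  expect_equal(coords(out$conformation), coords(corr))
})

test_that("zero blocks return the input; the forward pass itself is deterministic", {
  m <- makeMolecule("ring", 6)
  mdl <- initNetwork(microConfig(seed = 5))
  corr <- corruptConformation(m$graph, m$conformation, corruptionConfig(seed = 2))
  out0 <- denoise(m$graph, corr, mdl, nBlocks = 0L)
  expect_identical(coords(out0$conformation), coords(corr))
  a <- denoise(m$graph, corr, mdl)
  b <- denoise(m$graph, corr, mdl)
  expect_identical(coords(a$conformation), coords(b$conformation))
  corr2 <- corruptConformation(m$graph, m$conformation, corruptionConfig(seed = 3))
  c <- denoise(m$graph, corr2, mdl)
  expect_false(identical(coords(a$conformation), coords(c$conformation)))
})

test_that("the reference-scale configuration reports 8 blocks and K = 32", {
  cfg <- paperConfig()
  expect_equal(cfg@nBlocks, 8L)
  expect_equal(cfg@K, 32L)
})

test_that("parameter count is independent of the block count (shared weights)", {
  a <- initNetwork(microConfig(seed = 1, nBlocks = 2L))
  b <- initNetwork(microConfig(seed = 1, nBlocks = 8L))
  expect_equal(parameterCount(a), parameterCount(b))
})

randomizedModel <- function(seed, ...) {
  mdl <- initNetwork(microConfig(seed = seed, ...))
  set.seed(seed + 100)
  mdl@weights <- lapply(mdl@weights, function(w)
    w + rnorm(length(w), 0, 0.25))
  mdl
}

test_that("forward is end-to-end equivariant and heads invariant for arbitrary weights", {
  m <- makeMolecule("dipeptide")
  mdl <- randomizedModel(11)
  corr <- corruptConformation(m$graph, m$conformation, corruptionConfig(seed = 6))
  base <- denoise(m$graph, corr, mdl)
  for (s in 1:5) {
    rig <- randomRigid(40 + s)
    out <- denoise(m$graph, applyRigid(corr, rig), mdl)
    want <- coords(base$conformation) %*% rig$R +
      matrix(rig$t, natoms(m$graph), 3, byrow = TRUE)
    expect_lt(max(abs(coords(out$conformation) - want)), 1e-3)
    expect_lt(max(abs(sigmaValues(out$confidence) -
                        sigmaValues(base$confidence))), 1e-5)
    expect_lt(max(abs(plddtValues(out$confidence) -
                        plddtValues(base$confidence))), 1e-5)
    expect_lt(max(abs(out$confidence@pairLogits -
                        base$confidence@pairLogits)), 1e-5)
  }
})

test_that("permuting atoms permutes the outputs consistently", {
  m <- makeMolecule("chain", 6)
  rev <- MolRecord("chain", data.frame(
    element = rev(atomTable(m$graph)$element), charge = 0L),
    data.frame(i = 6L - bondTable(m$graph)$j + 1L,
               j = 6L - bondTable(m$graph)$i + 1L, order = 1L),
    coords(m$conformation)[6:1, ])
  mrev <- buildChemGraph(ligands = list(rev))
  mdl <- randomizedModel(13)
  corr <- corruptConformation(m$graph, m$conformation, corruptionConfig(seed = 4))
  corrRev <- Conformation(coords(corr)[6:1, ])
  a <- denoise(m$graph, corr, mdl)
  b <- denoise(mrev$graph, corrRev, mdl)
  expect_equal(coords(b$conformation), coords(a$conformation)[6:1, ],
               tolerance = 1e-8)
  expect_equal(sigmaValues(b$confidence), sigmaValues(a$confidence)[6:1],
               tolerance = 1e-8)
})

test_that("systems beyond the 600-atom crop cap are rejected by the forward pass", {
  pol <- makeMolecule("polymer", n = 160)  # 640 atoms
  mdl <- initNetwork(microConfig(seed = 1))
  blank <- Conformation(coords(pol$conformation))
  expect_error(denoise(pol$graph, blank, mdl), "600-atom")
})

test_that("micro-training runs, is reproducible, and records the configured stage depth", {
  ds <- makeTrainingSet(2, seed = 3)
  cfg <- microConfig(seed = 2, nInner = 2L, d1 = 16L, d2 = 8L)
  sch <- trainingSchedule(cfg, steps1 = 4L, steps2 = 3L)
  r1 <- trainMicro(ds, cfg, schedule = sch, seed = 5)
  r2 <- trainMicro(ds, cfg, schedule = sch, seed = 5)
  expect_identical(r1$trace$loss, r2$trace$loss)
  expect_equal(nrow(r1$trace), 7L)
  expect_equal(unique(r1$trace$stage), c(1L, 2L))
  expect_identical(r1$model@weights, r2$model@weights)
})
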