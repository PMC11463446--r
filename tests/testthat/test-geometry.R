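# FAPE, chirality pseudoscalar / bias vectors, bonded geometry, lDDT

test_that("frame enumeration: 3-chain has 1 frame, benzene 6, disconnected diatomics 0", {
  expect_equal(nrow(enumerateFrames(makeMolecule("chain", 3)$graph)), 1L)
  expect_equal(nrow(enumerateFrames(makeMolecule("ring", 6)$graph)), 6L)
  two <- buildChemGraph(ligands = list(
    MolRecord("a", data.frame(element = c("C", "C"), charge = 0L),
              data.frame(i = 1L, j = 2L, order = 1L), rbind(c(0, 0, 0), c(1.5, 0, 0))),
    MolRecord("b", data.frame(element = c("N", "N"), charge = 0L),
              data.frame(i = 1L, j = 2L, order = 1L), rbind(c(9, 0, 0), c(10.5, 0, 0)))))
  expect_equal(nrow(enumerateFrames(two$graph)), 0L)
  expect_error(fapeAllAtom(two$conformation, two$conformation, two$graph),
               "no frames")
})

test_that("collinear reference triples are excluded from frames", {
  lin <- MolRecord("lin", data.frame(element = c("C", "C", "C"), charge = 0L),
                   data.frame(i = 1:2, j = 2:3, order = 1L),
                   rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)))
  built <- buildChemGraph(ligands = list(lin))
  expect_message(fr <- enumerateFrames(built$graph, built$conformation),
                 "collinear")
  expect_equal(nrow(fr), 0L)
})

test_that("FAPE is zero for identical and rigidly moved structures", {
  m <- makeMolecule("macrocycle", 12)
  expect_equal(fapeAllAtom(m$conformation, m$conformation, m$graph), 0)
  for (s in 1:5) {
    rig <- randomRigid(s)
    moved <- applyRigid(m$conformation, rig)
    expect_lt(fapeAllAtom(moved, m$conformation, m$graph), 1e-9)
  }
})

test_that("FAPE equals a brute-force double loop on random molecules", {
  for (s in 1:6) {
    rnd <- randomMolecule(12, seed = 500 + s)
    set.seed(s)
    pert <- Conformation(coords(rnd$conformation) +
                           matrix(rnorm(36, 0, 0.7), 12, 3))
    expect_equal(fapeAllAtom(pert, rnd$conformation, rnd$graph),
                 bruteFape(pert, rnd$conformation, rnd$graph),
                 tolerance = 1e-9)
  }
})

test_that("a 50 A displacement contributes exactly the 10 A clamp", {
  ch <- makeMolecule("chain", 4)
  xm <- coords(ch$conformation)
  xm[4, ] <- xm[4, ] + c(50, 0, 0)
  dv <- fapeAllAtom(Conformation(xm), ch$conformation, ch$graph,
                    returnDeviations = TRUE)
  fr <- enumerateFrames(ch$graph, ch$conformation)
  f123 <- which(fr[, "a"] == 1 & fr[, "b"] == 2 & fr[, "c"] == 3)
  expect_equal(dv$deviations[f123, 4], 10)
})

test_that("FAPE saturates in an atom's coordinates once it is beyond the clamp", {
  ch <- makeMolecule("chain", 4)
  xm <- coords(ch$conformation)
  xm[4, ] <- xm[4, ] + c(60, 0, 0)
  dv0 <- fapeAllAtom(Conformation(xm), ch$conformation, ch$graph,
                     returnDeviations = TRUE)
  expect_true(all(dv0$deviations[, 4] == 10))
  xm2 <- xm; xm2[4, 1] <- xm2[4, 1] + 1e-3
  dv1 <- fapeAllAtom(Conformation(xm2), ch$conformation, ch$graph,
                     returnDeviations = TRUE)
  # the displaced atom's own terms stay pinned at the clamp ...
  expect_true(all(dv1$deviations[, 4] == 10))
  # ... so the loss is locally flat in its coordinates up to the residual
  # frame-definition coupling, which decays with the displacement distance
  expect_lt(abs(dv1$fape - dv0$fape) / 1e-3, 1e-3)
})

test_that("the chirality pseudoscalar hits the ideal tetrahedral value and parity", {
  t <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)) / sqrt(3)
  o <- c(0, 0, 0)
  V <- tripleProductV(o, t[1, ], t[2, ], t[3, ])
  expect_equal(abs(V), 4 / (3 * sqrt(3)), tolerance = 1e-12)
  # coplanar
  expect_equal(tripleProductV(o, c(1, 0, 0), c(0, 1, 0), c(-1, -1, 0)), 0,
               tolerance = 1e-12)
  # mirror flips the sign
  m <- diag(c(-1, 1, 1))
  expect_equal(tripleProductV(o, t[1, ] %*% m, t[2, ] %*% m, t[3, ] %*% m),
               -V, tolerance = 1e-12)
  expect_error(tripleProductV(o, o, t[2, ], t[3, ]), "degenerate")
})

test_that("bias vectors vanish at the ideal value and match finite differences", {
  m <- makeMolecule("chiral", chiralSign = 1)
  ctr <- chiralCenters(m$graph)[1, ]
  xyzIdeal <- coords(m$conformation)
  bv <- chiralityBiasVectors(ctr, xyzIdeal)
  expect_equal(bv$V, ctr$Videal, tolerance = 1e-12)
  expect_lt(max(abs(c(bv$o, bv$a, bv$b, bv$c))), 1e-10)
  for (s in 1:5) {
    set.seed(s)
    xyz <- xyzIdeal + matrix(rnorm(15, 0, 0.15), 5, 3)
    bv <- chiralityBiasVectors(ctr, xyz)
    fd <- function(ai, k) {
      h <- 1e-5
      f <- function(z) (tripleProductV(z[ctr$O, ], z[ctr$A, ], z[ctr$B, ],
                                       z[ctr$C, ]) - ctr$Videal)^2
      xp <- xyz; xp[ai, k] <- xp[ai, k] + h
      xm <- xyz; xm[ai, k] <- xm[ai, k] - h
      (f(xp) - f(xm)) / (2 * h)
    }
    for (nm in c("o", "a", "b", "c")) {
      ai <- ctr[[toupper(nm)]]
      num <- vapply(1:3, function(k) fd(ai, k), 0)
      scale <- max(abs(num), 1e-6)
      expect_lt(max(abs(bv[[nm]] - num)) / scale, 1e-6)
    }
  }
})

test_that("descending the chirality bias flips a mirrored center within 200 steps", {
  m <- makeMolecule("chiral", chiralSign = 1)
  ctr <- chiralCenters(m$graph)[1, ]
  xyz0 <- coords(m$conformation) %*% diag(c(-1, 1, 1))  # wrong-handed start
  for (s in 1:5) {
    set.seed(s)
    xyz <- xyz0 + matrix(rnorm(15, 0, 0.05), 5, 3)
    ok <- FALSE
    for (step in 1:200) {
      bv <- chiralityBiasVectors(ctr, xyz)
      if (sign(bv$V) == sign(ctr$Videal)) { ok <- TRUE; break }
      lr <- 0.5
      xyz[ctr$O, ] <- xyz[ctr$O, ] - lr * bv$o
      xyz[ctr$A, ] <- xyz[ctr$A, ] - lr * bv$a
      xyz[ctr$B, ] <- xyz[ctr$B, ] - lr * bv$b
      xyz[ctr$C, ] <- xyz[ctr$C, ] - lr * bv$c
    }
    expect_true(ok)
  }
})

test_that("bonded geometry errors are zero at the reference and localize a stretched bond", {
  m <- makeMolecule("macrocycle", 12)
  r0 <- bondedGeometryErrors(m$conformation, m$conformation, m$graph)
  expect_equal(r0$bond, 0); expect_equal(r0$angle, 0)
  expect_equal(r0$planar, 0); expect_equal(r0$chiral, 0)
  # diatomic-only graph: stretching the bond by 0.2 A moves only the bond MAE
  di <- buildChemGraph(ligands = list(
    MolRecord("d", data.frame(element = c("C", "O"), charge = 0L),
              data.frame(i = 1L, j = 2L, order = 1L),
              rbind(c(0, 0, 0), c(1.2, 0, 0)))))
  stretched <- Conformation(rbind(c(0, 0, 0), c(1.4, 0, 0)))
  r <- bondedGeometryErrors(stretched, di$conformation, di$graph)
  expect_equal(r$bond, 0.2, tolerance = 1e-12)
  expect_false(r$defined[["angle"]])
  expect_false(r$defined[["chiral"]])
})

test_that("bonded geometry errors match explicit trigonometry on random perturbations", {
  for (s in 1:5) {
    rnd <- randomMolecule(15, seed = 700 + s)
    set.seed(s)
    pert <- Conformation(coords(rnd$conformation) +
                           matrix(rnorm(45, 0, 0.2), 15, 3))
    got <- bondedGeometryErrors(pert, rnd$conformation, rnd$graph)
    want <- bruteGeometryErrors(pert, rnd$conformation, rnd$graph)
    expect_equal(got$bond, want$bond, tolerance = 1e-9)
    expect_equal(got$angle, want$angle, tolerance = 1e-9)
  }
})

test_that("per-atom lDDT is 1 at the reference and ~0 for scattered atoms", {
  p <- makeToyPocket(nRes = 10, seed = 5)
  l <- lddtPerAtom(p$conformation, p$conformation, p$graph)
  expect_true(all(l[!is.na(l)] == 1))
  set.seed(9)
  huge <- Conformation(matrix(runif(natoms(p$graph) * 3, -500, 500),
                              ncol = 3))
  lh <- lddtPerAtom(huge, p$conformation, p$graph)
  expect_lt(mean(lh, na.rm = TRUE), 0.05)
})

test_that("per-atom lDDT equals a brute-force implementation exactly", {
  for (s in 1:4) {
    rnd <- randomMolecule(18, seed = 900 + s)
    set.seed(s)
    pert <- Conformation(coords(rnd$conformation) +
                           matrix(rnorm(54, 0, 0.8), 18, 3))
    expect_equal(lddtPerAtom(pert, rnd$conformation, rnd$graph),
                 bruteLddt(pert, rnd$conformation, rnd$graph))
  }
})
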