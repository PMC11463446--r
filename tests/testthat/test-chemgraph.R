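# chemical graph construction, bond separation, chirality, crops

test_that("an Ala-Ala dipeptide expands to 10 atoms and 9 bonds incl. the peptide bond", {
  dp <- makeMolecule("dipeptide")
  expect_equal(natoms(dp$graph), 10L)
  expect_equal(nrow(bondTable(dp$graph)), 9L)
  at <- atomTable(dp$graph)
  cIdx <- which(at$atomName == "C" & at$resno == 1)
  nIdx <- which(at$atomName == "N" & at$resno == 2)
  b <- bondTable(dp$graph)
  expect_true(any((b$i == cIdx & b$j == nIdx) | (b$i == nIdx & b$j == cIdx)))
  expect_equal(length(unique(at$component)), 1L)
  expect_false(any(at$element == "H"))
})

test_that("bond separation: chain A-B-C gives separation(A, C) = 2; benzene para = 3", {
  ch <- makeMolecule("chain", 3)
  expect_equal(bondSeparation(ch$graph)[1, 3], 2)
  bz <- makeMolecule("ring", 6)
  sep <- bondSeparation(bz$graph)
  expect_equal(sep[1, 4], 3)
  expect_equal(sep[2, 5], 3)
  expect_equal(max(sep), 3)
})

test_that("bond separation matches an independent all-pairs shortest-path computation", {
  for (s in 1:12) {
    n <- sample(4:40, 1)
    rnd <- randomMolecule(n, seed = 1000 + s)
    expect_equal(bondSeparation(rnd$graph), bruteBondSeparation(rnd$graph))
  }
})

test_that("bond separation is symmetric with a zero diagonal and Inf across components", {
  two <- buildChemGraph(ligands = list(
    MolRecord("a", data.frame(element = c("C", "C"), charge = 0L),
              data.frame(i = 1L, j = 2L, order = 1L), rbind(c(0, 0, 0), c(1.5, 0, 0))),
    MolRecord("b", data.frame(element = c("N", "N"), charge = 0L),
              data.frame(i = 1L, j = 2L, order = 1L), rbind(c(9, 0, 0), c(10.5, 0, 0)))))
  sep <- bondSeparation(two$graph)
  expect_true(all(sep == t(sep)))
  expect_true(all(diag(sep) == 0))
  expect_true(all(is.infinite(sep[1:2, 3:4])))
})

test_that("unknown residues and bond-less ligands are rejected with clear errors", {
  res <- data.frame(chain = "A", resno = 1L, resname = "XYZ", atomName = "CA",
                    element = "C", x = 0, y = 0, z = 0)
  expect_error(buildChemGraph(residues = res), "XYZ")
  lig <- MolRecord("naked", data.frame(element = c("C", "C"), charge = 0L),
                   data.frame(i = integer(0), j = integer(0), order = integer(0)),
                   rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_error(buildChemGraph(ligands = list(lig)), "no bonds")
})

test_that("chirality perception assigns opposite signs to mirror images", {
  plus <- makeMolecule("chiral", chiralSign = +1)
  expect_equal(chiralCenters(plus$graph)$sign, 1L)
  minus <- makeMolecule("chiral", chiralSign = -1)
  expect_equal(chiralCenters(minus$graph)$sign, -1L)
  expect_equal(chiralCenters(plus$graph)$Videal, 4 / (3 * sqrt(3)),
               tolerance = 1e-12)
})

test_that("perceived sign flips under a coordinate mirror for every center", {
  for (s in 1:8) {
    m <- makeMolecule("chiral", chiralSign = if (s %% 2) 1 else -1, seed = s)
    x <- coords(m$conformation) + matrix(rnorm(15, 0, 0.08), 5, 3)
    conf <- Conformation(x)
    mir <- Conformation(x %*% diag(c(-1, 1, 1)))
    a <- perceiveChirality(m$graph, conf)
    b <- perceiveChirality(m$graph, mir)
    expect_equal(a$sign, -b$sign)
  }
})

test_that("planar sp2 centers emit no chiral center", {
  # flat 3-coordinate nitrogen
  lig <- MolRecord("flatN", data.frame(element = c("N", "C", "O", "F"),
                                       charge = 0L),
                   data.frame(i = 1L, j = 2:4, order = 1L),
                   rbind(c(0, 0, 0), c(1.4, 0, 0), c(-0.7, 1.2, 0),
                         c(-0.7, -1.2, 0)))
  built <- buildChemGraph(ligands = list(lig))
  expect_message(out <- perceiveChirality(built$graph, built$conformation),
                 "near-planar")
  expect_equal(nrow(out), 0L)
})

test_that("the alanine CA center agrees with a signed-volume oracle", {
  dp <- makeMolecule("dipeptide")
  ch <- chiralCenters(dp$graph)
  at <- atomTable(dp$graph)
  caRows <- which(at$atomName == "CA")
  expect_setequal(ch$O, caRows)
  x <- coords(dp$conformation)
  for (k in seq_len(nrow(ch))) {
    # raw signed volume of the three substituent directions (unnormalized)
    eA <- x[ch$A[k], ] - x[ch$O[k], ]
    eB <- x[ch$B[k], ] - x[ch$O[k], ]
    eC <- x[ch$C[k], ] - x[ch$O[k], ]
    vol <- det(rbind(eA, eB, eC))
    expect_equal(sign(vol), ch$sign[k])
  }
})

monatomicSystem <- function(n, seed) {
  set.seed(seed)
  res <- data.frame(chain = "A", resno = 2L * seq_len(n), resname = "GLY",
                    atomName = "CA", element = "C",
                    x = rnorm(n, 0, 12), y = rnorm(n, 0, 12), z = rnorm(n, 0, 12))
  buildChemGraph(residues = res)
}

test_that("cropping a dense 1000-atom monatomic-residue system at cap 600 keeps exactly 600", {
  sys <- monatomicSystem(1000, seed = 3)
  cr <- cropGraph(sys$graph, sys$conformation, centerAtom = 1L, maxAtoms = 600L)
  expect_equal(natoms(cr$graph), 600L)
  # selected atoms are the 600 spatially closest to the center
  d <- sqrt(rowSums(sweep(coords(sys$conformation), 2,
                          coords(sys$conformation)[1, ])^2))
  expect_setequal(cr$map, order(d)[1:600])
})

test_that("cropping is idempotent and leaves small systems unchanged", {
  dp <- makeMolecule("dipeptide")
  cr <- cropGraph(dp$graph, dp$conformation, centerAtom = 1L, maxAtoms = 600L)
  expect_equal(natoms(cr$graph), 10L)
  expect_equal(cr$map, 1:10)
  pocket <- makeToyPocket(nRes = 12, seed = 2)
  cr1 <- cropGraph(pocket$graph, pocket$conformation, centerAtom = 5L,
                   maxAtoms = 40L)
  center2 <- which(cr1$map == 5L)
  cr2 <- cropGraph(cr1$graph, cr1$conformation, centerAtom = center2,
                   maxAtoms = 40L)
  expect_equal(natoms(cr2$graph), natoms(cr1$graph))
  expect_equal(coords(cr2$conformation), coords(cr1$conformation))
})

test_that("crops keep residues whole and preserve internal bonds exactly", {
  pocket <- makeToyPocket(nRes = 16, seed = 4)
  cr <- cropGraph(pocket$graph, pocket$conformation, centerAtom = 1L,
                  maxAtoms = 45L)
  at <- atomTable(cr$graph)
  full <- atomTable(pocket$graph)
  # every kept residue appears with all of its atoms
  for (key in unique(paste(at$chain, at$resno))) {
    inCrop <- sum(paste(at$chain, at$resno) == key)
    inFull <- sum(paste(full$chain, full$resno) == key)
    expect_equal(inCrop, inFull)
  }
  # bonds among kept atoms are exactly the original bonds restricted to them
  bFull <- bondTable(pocket$graph)
  kept <- bFull[bFull$i %in% cr$map & bFull$j %in% cr$map, ]
  expect_equal(nrow(bondTable(cr$graph)), nrow(kept))
  expect_error(cropGraph(pocket$graph,
                         Conformation(coords(pocket$conformation),
                                      mask = rep(FALSE, natoms(pocket$graph))),
                         centerAtom = 1L, maxAtoms = 40L), "unresolved")
})
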