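# stochastic corruption: training collapse + noise, docking initialization

test_that("with vanishing noise all side-chain atoms collapse onto their backbone anchor", {
  dp <- makeMolecule("dipeptide")
  out <- corruptConformation(dp$graph, dp$conformation,
                             corruptionConfig(noiseSigma = 1e-12, seed = 1))
  at <- atomTable(dp$graph)
  for (r in 1:2) {
    cb <- which(at$atomName == "CB" & at$resno == r)
    ca <- which(at$atomName == "CA" & at$resno == r)
    expect_equal(coords(out)[cb, ], coords(dp$conformation)[ca, ],
                 tolerance = 1e-6)
  }
  # backbone atoms stay at their reference position in the zero-noise limit
  bb <- which(at$role == "backbone")
  expect_equal(coords(out)[bb, ], coords(dp$conformation)[bb, ],
               tolerance = 1e-6)
})

test_that("ligand components collapse onto a single atom before noising", {
  m <- makeMolecule("chain", 8)
  out <- corruptConformation(m$graph, m$conformation,
                             corruptionConfig(noiseSigma = 1e-12, seed = 2))
  spread <- max(dist(coords(out)))
  expect_lt(spread, 1e-6)
  expect_true(any(apply(coords(m$conformation), 1, function(p)
    sum((p - coords(out)[1, ])^2) < 1e-12)))
})

test_that("corruption is a pure function of (input, seed)", {
  m <- makeToyPocket(nRes = 8, seed = 1)
  a <- corruptConformation(m$graph, m$conformation, corruptionConfig(seed = 7))
  b <- corruptConformation(m$graph, m$conformation, corruptionConfig(seed = 7))
  c <- corruptConformation(m$graph, m$conformation, corruptionConfig(seed = 8))
  expect_identical(coords(a), coords(b))
  expect_false(identical(coords(a), coords(c)))
  d1 <- corruptConformation(m$graph, m$conformation,
                            corruptionConfig(mode = "docking", seed = 7))
  d2 <- corruptConformation(m$graph, m$conformation,
                            corruptionConfig(mode = "docking", seed = 7))
  expect_identical(coords(d1), coords(d2))
})

test_that("training noise has the configured per-coordinate scale", {
  pol <- makeMolecule("polymer", n = 2500)  # 10,000 backbone atoms
  out <- corruptConformation(pol$graph, pol$conformation,
                             corruptionConfig(seed = 3))
  disp <- as.vector(coords(out) - coords(pol$conformation))
  expect_equal(sd(disp), 1.5, tolerance = 0.03)
  expect_equal(mean(disp), 0, tolerance = 0.05)
})

test_that("docking mode fixes the backbone and scatters side chains around CA", {
  p <- makeToyPocket(nRes = 10, seed = 2)
  out <- corruptConformation(p$graph, p$conformation,
                             corruptionConfig(mode = "docking", seed = 4))
  at <- atomTable(p$graph)
  bb <- which(at$role == "backbone")
  expect_identical(coords(out)[bb, ], coords(p$conformation)[bb, ])
  sc <- which(at$role == "sidechain")
  ca <- AtomEnsembles:::.residueCA(p$graph)
  d <- sqrt(rowSums((coords(out)[sc, , drop = FALSE] -
                       coords(p$conformation)[ca[sc], , drop = FALSE])^2))
  expect_lt(max(d), 1.5 * 6)  # Gaussian around CA, not reference position
  expect_gt(mean(d), 0.5)
})

test_that("docking initialization leaks neither ligand structure nor orientation", {
  p <- makeToyPocket(nRes = 10, ligandSize = 8, seed = 3)
  lig <- p$ligandAtoms
  # pairwise ligand distances behave like distances between iid Gaussian
  # offsets: Monte-Carlo oracle for the mean of |N(0, s^2 I3) - N(0, s^2 I3)|
  set.seed(1)
  mcl <- replicate(4000, sqrt(sum((rnorm(3, 0, 1.5) - rnorm(3, 0, 1.5))^2)))
  got <- c()
  for (s in 1:60) {
    out <- corruptConformation(p$graph, p$conformation,
                               corruptionConfig(mode = "docking", seed = 100 + s))
    xl <- coords(out)[lig, ]
    got <- c(got, as.vector(dist(xl)))
  }
  expect_equal(mean(got), mean(mcl), tolerance = 0.05)
  # ligand centroid spread across seeds ~ anchor + N(0, sigma^2) per axis
  cents <- t(sapply(1:80, function(s) {
    out <- corruptConformation(p$graph, p$conformation,
                               corruptionConfig(mode = "docking", seed = 500 + s))
    colMeans(coords(out)[lig, ])
  }))
  spread <- apply(cents, 2, sd)
  # centroid = anchor-noise (sd 1.5) + mean of n atom noises (sd 1.5/sqrt(8))
  expect_equal(mean(spread), sqrt(1.5^2 + 1.5^2 / 8), tolerance = 0.25)
})

test_that("permuting ligand atom identities leaves the initialization distribution unchanged", {
  p <- makeToyPocket(nRes = 8, ligandSize = 6, seed = 5)
  lig <- p$ligandAtoms
  draw <- function(conf, seeds) {
    unlist(lapply(seeds, function(s) {
      out <- corruptConformation(p$graph, conf,
                                 corruptionConfig(mode = "docking", seed = s))
      as.vector(coords(out)[lig, ] -
                  matrix(colMeans(coords(out)[lig, ]), length(lig), 3,
                         byrow = TRUE))
    }))
  }
  xyz <- coords(p$conformation)
  perm <- xyz
  perm[lig, ] <- xyz[sample(lig), ]
  a <- draw(p$conformation, 1:120)
  b <- draw(Conformation(perm), 1:120)
  expect_gt(suppressWarnings(ks.test(a, b))$p.value, 0.01)
})

test_that("training mode refuses unresolved reference atoms", {
  m <- makeMolecule("chain", 5)
  mask <- rep(TRUE, 5); mask[3] <- FALSE
  broken <- Conformation(coords(m$conformation), mask)
  expect_error(corruptConformation(m$graph, broken, corruptionConfig(seed = 1)),
               "unresolved")
})

test_that("docking without any pose or anchor asks for an anchor point", {
  m <- makeMolecule("chain", 5)
  blank <- Conformation(matrix(NA_real_, 5, 3), rep(FALSE, 5))
  expect_error(
    corruptConformation(m$graph, blank,
                        corruptionConfig(mode = "docking", seed = 1)),
    "anchor")
  ok <- corruptConformation(m$graph, blank,
                            corruptionConfig(mode = "docking", seed = 1),
                            anchor = c(1, 2, 3))
  expect_true(all(is.finite(coords(ok))))
  expect_lt(max(sqrt(rowSums(sweep(coords(ok), 2, c(1, 2, 3))^2))), 1.5 * 8)
})

test_that("sidechain mode resamples side chains while ligand stays near its pose", {
  p <- makeToyPocket(nRes = 8, seed = 7)
  out <- corruptConformation(p$graph, p$conformation,
                             corruptionConfig(mode = "sidechain", seed = 5))
  at <- atomTable(p$graph)
  bb <- which(at$role == "backbone")
  expect_identical(coords(out)[bb, ], coords(p$conformation)[bb, ])
  lig <- p$ligandAtoms
  d <- sqrt(rowSums((coords(out)[lig, , drop = FALSE] -
                       coords(p$conformation)[lig, , drop = FALSE])^2))
  expect_lt(max(d), 1.5 * 6)   # reference pose + Gaussian noise, not collapsed
  expect_gt(mean(d), 0.5)
})
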