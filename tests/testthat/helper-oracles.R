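# Independent brute-force oracles used to validate the package's vectorized
# implementations. These deliberately share no code with the package: plain
# double loops and textbook formulas.

# random connected toy molecule: spanning tree plus a few extra edges,
# random 3D coordinates
randomMolecule <- function(n, seed) {
  set.seed(seed)
  elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (n >= 2) {
    parent <- vapply(2:n, function(k) sample.int(k - 1L, 1L), 1L)
    bonds <- data.frame(i = parent, j = 2:n, order = 1L)
    extra <- min(n %/% 3L, 3L)
    for (e in seq_len(extra)) {
      ij <- sort(sample.int(n, 2L))
      if (!any(bonds$i == ij[1] & bonds$j == ij[2]))
        bonds <- rbind(bonds, data.frame(i = ij[1], j = ij[2], order = 1L))
    }
  }
  xyz <- matrix(rnorm(n * 3, 0, 3), n, 3)
  mol <- MolRecord("rnd", data.frame(element = elements, charge = 0L),
                   bonds, xyz)
  built <- buildChemGraph(ligands = list(mol))
  list(graph = built$graph, conformation = built$conformation)
}

randomRigid <- function(seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 5))
}

applyRigid <- function(conf, rig) {
  x <- coords(conf)
  Conformation(x %*% rig$R + matrix(rig$t, nrow(x), 3, byrow = TRUE),
               resolvedMask(conf))
}

# Floyd-Warshall all-pairs bond counts
bruteBondSeparation <- function(graph) {
  n <- natoms(graph)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  b <- bondTable(graph)
  for (k in seq_len(nrow(b))) {
    d[b$i[k], b$j[k]] <- 1
    d[b$j[k], b$i[k]] <- 1
  }
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# explicit double loop over frames and atoms, building each rotation from
# scratch with the documented convention
bruteFape <- function(model, reference, graph, clamp = 10) {
  fr <- enumerateFrames(graph, reference)
  xm <- coords(model); xr <- coords(reference)
  basisOf <- function(xyz, a, b, c) {
    x <- xyz[c, ] - xyz[b, ]; x <- x / sqrt(sum(x^2))
    u <- xyz[a, ] - xyz[b, ]; u <- u - x * sum(u * x)
    y <- u / sqrt(sum(u^2))
    z <- c(x[2] * y[3] - x[3] * y[2], x[3] * y[1] - x[1] * y[3],
           x[1] * y[2] - x[2] * y[1])
    rbind(x, y, z)
  }
  tot <- 0; cnt <- 0
  for (f in seq_len(nrow(fr))) {
    Bm <- basisOf(xm, fr[f, 1], fr[f, 2], fr[f, 3])
    Br <- basisOf(xr, fr[f, 1], fr[f, 2], fr[f, 3])
    for (i in seq_len(nrow(xm))) {
      lm <- Bm %*% (xm[i, ] - xm[fr[f, 2], ])
      lr <- Br %*% (xr[i, ] - xr[fr[f, 2], ])
      tot <- tot + min(sqrt(sum((lm - lr)^2)), clamp)
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

bruteLddt <- function(model, reference, graph, radius = 15,
                      thresholds = c(0.5, 1, 2, 4), minSep = 4) {
  xm <- coords(model); xr <- coords(reference)
  n <- nrow(xr)
  sep <- bondSeparation(graph)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    hits <- 0; tries <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      dr <- sqrt(sum((xr[i, ] - xr[j, ])^2))
      if (dr > radius) next
      if (is.finite(sep[i, j]) && sep[i, j] < minSep) next
      dm <- sqrt(sum((xm[i, ] - xm[j, ])^2))
      for (t in thresholds) {
        tries <- tries + 1
        if (abs(dm - dr) < t) hits <- hits + 1
      }
    }
    if (tries > 0) out[i] <- hits / tries
  }
  out
}

bruteTorsionDeg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

bruteGeometryErrors <- function(model, reference, graph) {
  xm <- coords(model); xr <- coords(reference)
  b <- bondTable(graph)
  bondE <- if (nrow(b)) mean(vapply(seq_len(nrow(b)), function(k)
    abs(sqrt(sum((xm[b$i[k], ] - xm[b$j[k], ])^2)) -
          sqrt(sum((xr[b$i[k], ] - xr[b$j[k], ])^2))), 0)) else 0
  angleOf <- function(xyz, a, b2, c) {
    v1 <- xyz[a, ] - xyz[b2, ]; v2 <- xyz[c, ] - xyz[b2, ]
    acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) *
      180 / pi
  }
  fr <- enumerateFrames(graph)
  angE <- if (nrow(fr)) mean(vapply(seq_len(nrow(fr)), function(k)
    abs(angleOf(xm, fr[k, 1], fr[k, 2], fr[k, 3]) -
          angleOf(xr, fr[k, 1], fr[k, 2], fr[k, 3])), 0)) else 0
  list(bond = bondE, angle = angE)
}
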