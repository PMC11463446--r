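# Minimal reverse-mode automatic differentiation on numeric vectors/matrices.
#
# Every op accepts either plain numerics or tape nodes and returns a node
# whenever any input is a node, so the network forward pass is written once
# and runs in two modes: raw (inference) and recorded (training). Nodes are
# environments holding the value, accumulated gradient and a backward
# closure; the tape replays them in reverse order.
#
# This engine exists because the denoiser and its structural losses (FAPE
# through frame construction, bonded-geometry terms, confidence NLL) need
# exact gradients and no autodiff framework is part of the package's
# dependency set; the op inventory is deliberately small and matched to the
# network's needs.

adTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$k <- 0L
  t
}

.isNode <- function(x) is.environment(x) && !is.null(x$.ad)

adVal <- function(x) if (.isNode(x)) x$val else x

.tapeOf <- function(...) {
  for (x in list(...)) if (.isNode(x)) return(x$tape)
  NULL
}

.newNode <- function(tape, val, back = NULL) {
  n <- new.env(parent = emptyenv())
  n$.ad <- TRUE
  n$val <- val
  n$grad <- NULL
  n$back <- back
  n$tape <- tape
  tape$k <- tape$k + 1L
  if (tape$k > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$k]] <- n
  n
}

.acc <- function(node, g) {
  if (is.null(node)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

adParam <- function(tape, val) .newNode(tape, val)

# seed the output gradient and sweep the tape backwards
adBackward <- function(tape, loss) {
  stopifnot(.isNode(loss), length(loss$val) == 1L)
  loss$grad <- 1
  for (k in seq(tape$k, 1L)) {
    n <- tape$nodes[[k]]
    if (!is.null(n$back) && !is.null(n$grad)) n$back(n$grad)
  }
  invisible(NULL)
}

.binop <- function(x, y, fval, bx, by) {
  tape <- .tapeOf(x, y)
  v <- fval(adVal(x), adVal(y))
  if (is.null(tape)) return(v)
  xn <- if (.isNode(x)) x else NULL
  yn <- if (.isNode(y)) y else NULL
  xv <- adVal(x); yv <- adVal(y)
  .newNode(tape, v, function(g) {
    if (!is.null(xn)) .acc(xn, bx(g, xv, yv))
    if (!is.null(yn)) .acc(yn, by(g, xv, yv))
  })
}

.unop <- function(x, fval, bx) {
  if (!.isNode(x)) return(fval(x))
  v <- fval(x$val)
  xv <- x$val
  .newNode(x$tape, v, function(g) .acc(x, bx(g, xv, v)))
}

# reduce a gradient to a scalar if the forward input was scalar (broadcasting)
.likeShape <- function(g, x) if (length(x) == 1L) sum(g) else g

adAdd <- function(x, y) .binop(x, y, `+`,
  function(g, xv, yv) .likeShape(g, xv),
  function(g, xv, yv) .likeShape(g, yv))

adSub <- function(x, y) .binop(x, y, `-`,
  function(g, xv, yv) .likeShape(g, xv),
  function(g, xv, yv) .likeShape(-g, yv))

adMul <- function(x, y) .binop(x, y, `*`,
  function(g, xv, yv) .likeShape(g * yv, xv),
  function(g, xv, yv) .likeShape(g * xv, yv))

adDiv <- function(x, y) .binop(x, y, `/`,
  function(g, xv, yv) .likeShape(g / yv, xv),
  function(g, xv, yv) .likeShape(-g * xv / yv^2, yv))

adMatmul <- function(x, y) .binop(x, y, `%*%`,
  function(g, xv, yv) g %*% t(yv),
  function(g, xv, yv) t(xv) %*% g)

adT <- function(x) .unop(x, t, function(g, xv, v) t(g))

adTanh <- function(x) .unop(x, tanh, function(g, xv, v) g * (1 - v^2))

adSigmoid <- function(x) .unop(x, function(z) 1 / (1 + exp(-z)),
                               function(g, xv, v) g * v * (1 - v))

adExp <- function(x) .unop(x, exp, function(g, xv, v) g * v)

adLog <- function(x) .unop(x, log, function(g, xv, v) g / xv)

adSqrt <- function(x) .unop(x, sqrt, function(g, xv, v) g / (2 * v))

adSquare <- function(x) .unop(x, function(z) z^2,
                              function(g, xv, v) 2 * g * xv)

adAbs <- function(x) .unop(x, abs, function(g, xv, v) g * sign(xv))

adNeg <- function(x) .unop(x, `-`, function(g, xv, v) -g)

adClampMax <- function(x, cap) .unop(x, function(z) pmin(z, cap),
  function(g, xv, v) g * (xv < cap))

# acos with the argument softly clamped away from +-1 (keeps gradients finite)
adAcosSafe <- function(x, eps = 1e-7) {
  .unop(x, function(z) acos(pmin(1 - eps, pmax(-1 + eps, z))),
        function(g, xv, v) {
          zc <- pmin(1 - eps, pmax(-1 + eps, xv))
          -g / sqrt(1 - zc^2) * (abs(xv) < 1 - eps)
        })
}

adSum <- function(x) .unop(x, sum, function(g, xv, v) {
  out <- xv; out[] <- g; out
})

adMean <- function(x) .unop(x, mean, function(g, xv, v) {
  out <- xv; out[] <- g / length(xv); out
})

adRowSums <- function(x) .unop(x, rowSums, function(g, xv, v)
  matrix(g, nrow(xv), ncol(xv)))

adVec <- function(x) .unop(x, as.vector, function(g, xv, v)
  matrix(g, nrow(xv), ncol(xv)))

adGatherRows <- function(x, idx) {
  f <- function(z) z[idx, , drop = FALSE]
  .unop(x, f, function(g, xv, v) {
    out <- matrix(0, nrow(xv), ncol(xv))
    rs <- rowsum(g, group = idx)
    out[as.integer(rownames(rs)), ] <- rs
    out
  })
}

adGatherVec <- function(x, idx) {
  .unop(x, function(z) z[idx], function(g, xv, v) {
    out <- numeric(length(xv))
    rs <- rowsum(matrix(g, ncol = 1), group = idx)
    out[as.integer(rownames(rs))] <- rs[, 1]
    out
  })
}

# ordered segment sum with empty groups kept as zero rows
adSegSum <- function(x, groups, n) {
  f <- function(z) {
    out <- matrix(0, n, ncol(z))
    rs <- rowsum(z, group = groups)
    out[as.integer(rownames(rs)), ] <- rs
    out
  }
  .unop(x, f, function(g, xv, v) g[groups, , drop = FALSE])
}

# M (r x c) with each row scaled by v (length r)
adRowMul <- function(m, v) .binop(m, v, function(mv, vv) mv * vv,
  function(g, mv, vv) g * vv,
  function(g, mv, vv) rowSums(g * mv))

# add a row vector (bias of length ncol) to every row
adAddRowVec <- function(m, v) .binop(m, v,
  function(mv, vv) sweep(mv, 2L, vv, `+`),
  function(g, mv, vv) g,
  function(g, mv, vv) colSums(g))

# outer(u, v) differences/sums/products; v may be a plain vector
adOuterSub <- function(u, v) .binop(u, v, function(uv, vv) outer(uv, vv, `-`),
  function(g, uv, vv) rowSums(g),
  function(g, uv, vv) -colSums(g))

adOuterPlus <- function(u, v) .binop(u, v, function(uv, vv) outer(uv, vv, `+`),
  function(g, uv, vv) rowSums(g),
  function(g, uv, vv) colSums(g))

adOuterProd <- function(u, v) .binop(u, v, function(uv, vv) outer(uv, vv),
  function(g, uv, vv) g %*% vv,
  function(g, uv, vv) t(g) %*% uv)

adCol <- function(m, j) {
  .unop(m, function(z) z[, j], function(g, xv, v) {
    out <- matrix(0, nrow(xv), ncol(xv))
    out[, j] <- g
    out
  })
}

adCbind <- function(...) {
  xs <- list(...)
  tape <- do.call(.tapeOf, xs)
  vals <- lapply(xs, adVal)
  vals <- lapply(vals, function(v) if (is.matrix(v)) v else matrix(v, ncol = 1))
  v <- do.call(cbind, vals)
  if (is.null(tape)) return(v)
  widths <- vapply(vals, ncol, 1L)
  offs <- cumsum(c(0L, widths))
  .newNode(tape, v, function(g) {
    for (k in seq_along(xs)) {
      if (!.isNode(xs[[k]])) next
      gk <- g[, (offs[k] + 1L):offs[k + 1L], drop = FALSE]
      if (!is.matrix(adVal(xs[[k]]))) gk <- as.vector(gk)
      .acc(xs[[k]], gk)
    }
  })
}

# cross product of 3-column matrices, row-wise (composed from primitives)
adCross3 <- function(a, b) {
  a1 <- adCol(a, 1); a2 <- adCol(a, 2); a3 <- adCol(a, 3)
  b1 <- adCol(b, 1); b2 <- adCol(b, 2); b3 <- adCol(b, 3)
  adCbind(adSub(adMul(a2, b3), adMul(a3, b2)),
          adSub(adMul(a3, b1), adMul(a1, b3)),
          adSub(adMul(a1, b2), adMul(a2, b1)))
}

# rows normalized to unit length (with a small floor for stability)
adUnitRows <- function(m, eps = 1e-9) {
  n2 <- adRowSums(adSquare(m))
  inv <- adDiv(1, adSqrt(adAdd(n2, eps)))
  adRowMul(m, inv)
}

# Adam step over a flat list of parameter arrays
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-2, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8, clip = 1) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(gn) && gn > clip)
    grads <- lapply(grads, function(g) g * (clip / gn))
  state$t <- state$t + 1L
  for (k in seq_along(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
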