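# Minimal reverse-mode automatic differentiation over dense matrices.
#
# A tape records nodes in creation order; backward() replays it in reverse,
# accumulating gradients into each node's $grad. All values are plain
# matrices; scalars are 1 x 1. Nodes created with const = TRUE never receive
# gradients (their parents are skipped in the backward pass), which keeps
# the per-molecule scatter/gather matrices free.
#
# Internal machinery: not exported. The model and attention blocks are the
# only consumers.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(tape, val, parents = list(), backfn = NULL, const = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$const <- const
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd$id <- n
  nd
}

ag_const <- function(tape, val) ag_node(tape, val, const = TRUE)
ag_var <- function(tape, val) ag_node(tape, val)

ag_accum <- function(nd, g) {
  if (nd$const) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

ag_backward <- function(tape, loss) {
  loss$grad <- matrix(1, nrow(loss$val), ncol(loss$val))
  for (i in seq(loss$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd, nd$grad)
  }
  invisible(NULL)
}

# ---- primitive ops -------------------------------------------------------

ag_mm <- function(a, b, tape) {
  ag_node(tape, a$val %*% b$val, list(a, b), function(nd, g) {
    ag_accum(a, g %*% t(b$val))
    ag_accum(b, t(a$val) %*% g)
  })
}

# a %*% t(b)
ag_mmt <- function(a, b, tape) {
  ag_node(tape, a$val %*% t(b$val), list(a, b), function(nd, g) {
    ag_accum(a, g %*% b$val)
    ag_accum(b, t(g) %*% a$val)
  })
}

ag_add <- function(a, b, tape) {
  ag_node(tape, a$val + b$val, list(a, b), function(nd, g) {
    ag_accum(a, g); ag_accum(b, g)
  })
}

ag_sub <- function(a, b, tape) {
  ag_node(tape, a$val - b$val, list(a, b), function(nd, g) {
    ag_accum(a, g); ag_accum(b, -g)
  })
}

ag_mul <- function(a, b, tape) {
  ag_node(tape, a$val * b$val, list(a, b), function(nd, g) {
    ag_accum(a, g * b$val); ag_accum(b, g * a$val)
  })
}

# add a 1 x d row vector to every row of an n x d matrix
ag_addrow <- function(a, r, tape) {
  val <- sweep(a$val, 2L, as.numeric(r$val), "+")
  ag_node(tape, val, list(a, r), function(nd, g) {
    ag_accum(a, g)
    ag_accum(r, matrix(colSums(g), 1L))
  })
}

# multiply every row of an n x d matrix by a 1 x d row vector
ag_mulrow <- function(a, r, tape) {
  rv <- as.numeric(r$val)
  val <- sweep(a$val, 2L, rv, "*")
  ag_node(tape, val, list(a, r), function(nd, g) {
    ag_accum(a, sweep(g, 2L, rv, "*"))
    ag_accum(r, matrix(colSums(g * a$val), 1L))
  })
}

ag_scale <- function(a, s, tape) {
  ag_node(tape, a$val * s, list(a), function(nd, g) ag_accum(a, g * s))
}

ag_addconst <- function(a, cmat, tape) {
  ag_node(tape, a$val + cmat, list(a), function(nd, g) ag_accum(a, g))
}

ag_relu <- function(a, tape) {
  mask <- a$val > 0
  ag_node(tape, a$val * mask, list(a), function(nd, g) ag_accum(a, g * mask))
}

ag_sigmoid <- function(a, tape) {
  s <- 1 / (1 + exp(-a$val))
  ag_node(tape, s, list(a), function(nd, g) ag_accum(a, g * s * (1 - s)))
}

# row-wise softmax of an n x k matrix
ag_softmax_rows <- function(a, tape) {
  x <- a$val
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  s <- e / rowSums(e)
  ag_node(tape, s, list(a), function(nd, g) {
    ag_accum(a, s * (g - rowSums(g * s)))
  })
}

# softmax over the single column of an n x 1 matrix
ag_softmax_vec <- function(a, tape) {
  x <- as.numeric(a$val)
  x <- x - max(x)
  e <- exp(x)
  s <- matrix(e / sum(e), ncol = 1L)
  ag_node(tape, s, list(a), function(nd, g) {
    ag_accum(a, s * (g - sum(g * s)))
  })
}

# colSums as a 1 x d row
ag_sumrows <- function(a, tape) {
  n <- nrow(a$val)
  ag_node(tape, matrix(colSums(a$val), 1L), list(a), function(nd, g) {
    ag_accum(a, matrix(g, n, ncol(g), byrow = TRUE))
  })
}

ag_cols <- function(a, idx, tape) {
  ag_node(tape, a$val[, idx, drop = FALSE], list(a), function(nd, g) {
    full <- matrix(0, nrow(a$val), ncol(a$val))
    full[, idx] <- g
    ag_accum(a, full)
  })
}

ag_cbind <- function(nodes, tape) {
  vals <- lapply(nodes, function(x) x$val)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(tape, do.call(cbind, vals), nodes, function(nd, g) {
    for (i in seq_along(nodes))
      ag_accum(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
  })
}

# multiply by a constant matrix on the left: C %*% a
ag_lmulconst <- function(cmat, a, tape) {
  tc <- t(cmat)
  ag_node(tape, cmat %*% a$val, list(a), function(nd, g) {
    ag_accum(a, tc %*% g)
  })
}

# row-wise layer normalization with affine parameters (gamma, beta: 1 x d)
ag_layernorm_rows <- function(a, gamma, beta, tape, eps = 1e-5) {
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  s2 <- rowMeans(xc ^ 2)
  inv <- 1 / sqrt(s2 + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$val)
  val <- sweep(xhat, 2L, gv, "*")
  val <- sweep(val, 2L, as.numeric(beta$val), "+")
  ag_node(tape, val, list(a, gamma, beta), function(nd, g) {
    dxhat <- sweep(g, 2L, gv, "*")
    t1 <- rowSums(dxhat) / d
    t2 <- rowSums(dxhat * xhat) / d
    dx <- inv * (dxhat - t1 - xhat * t2)
    ag_accum(a, dx)
    ag_accum(gamma, matrix(colSums(g * xhat), 1L))
    ag_accum(beta, matrix(colSums(g), 1L))
  })
}

# inverted dropout; identity unless training and p > 0
ag_dropout <- function(a, p, training, tape) {
  if (!training || p <= 0) return(a)
  mask <- (matrix(stats::runif(length(a$val)), nrow(a$val)) >= p) / (1 - p)
  ag_node(tape, a$val * mask, list(a), function(nd, g) ag_accum(a, g * mask))
}

# ---- losses (scalar 1 x 1 nodes) -----------------------------------------

# masked mean squared error; pred and target are n x k, mask is n x k 0/1
ag_mse_masked <- function(pred, target, mask, tape) {
  nval <- sum(mask)
  if (nval == 0) return(ag_const(tape, matrix(0, 1, 1)))
  diff <- (pred$val - target) * mask
  ag_node(tape, matrix(sum(diff ^ 2) / nval, 1, 1), list(pred),
          function(nd, g) {
    ag_accum(pred, g[1] * 2 * diff / nval)
  })
}

# masked binary cross-entropy with logits
ag_bce_masked <- function(pred, target, mask, tape) {
  nval <- sum(mask)
  if (nval == 0) return(ag_const(tape, matrix(0, 1, 1)))
  z <- pred$val
  t0 <- ifelse(is.na(target), 0, target)
  # log(1 + exp(z)) - y z, computed stably
  ll <- pmax(z, 0) - z * t0 + log1p(exp(-abs(z)))
  s <- 1 / (1 + exp(-z))
  ag_node(tape, matrix(sum(ll * mask) / nval, 1, 1), list(pred),
          function(nd, g) {
    ag_accum(pred, g[1] * (s - t0) * mask / nval)
  })
}

ag_transpose <- function(a, tape) {
  ag_node(tape, t(a$val), list(a), function(nd, g) ag_accum(a, t(g)))
}
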