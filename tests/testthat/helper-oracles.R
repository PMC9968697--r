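# Independent straight-line oracles used only by the tests. Each one is a
# deliberately naive re-implementation (scalar loops, no shared code with
# the package) so that agreement is a genuine cross-check.

# Coulomb matrix by explicit double loop with scalar arithmetic
oracleCoulomb <- function(Z, R) {
  m <- length(Z)
  out <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) {
        out[i, j] <- 0.5 * Z[i] ^ 2.4
      } else {
        d <- sqrt((R[i, 1] - R[j, 1]) ^ 2 + (R[i, 2] - R[j, 2]) ^ 2 +
                  (R[i, 3] - R[j, 3]) ^ 2)
        out[i, j] <- Z[i] * Z[j] / d
      }
    }
  }
  out
}

oracleSoftmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# additive pooling by scalar loops
oracleAdditivePool <- function(tokens, sv) {
  n <- nrow(tokens); d <- ncol(tokens)
  scores <- numeric(n)
  for (i in seq_len(n)) scores[i] <- sum(tokens[i, ] * sv) / sqrt(d)
  w <- oracleSoftmax(scores)
  g <- numeric(d)
  for (i in seq_len(n)) g <- g + w[i] * tokens[i, ]
  list(global = g, weights = w)
}

# straight-line Fastformer bond attention reference from a model's params
oracleFastformer <- function(model, x) {
  p <- model@params
  cf <- model@config
  dh <- cf$d / cf$nHeads
  n <- nrow(x)
  u <- matrix(0, n, cf$d)
  for (h in seq_len(cf$nHeads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    q <- x[, cols, drop = FALSE]              # q = k = v = input slice
    pq <- oracleAdditivePool(q, as.numeric(p$baWq[[h]]))
    pmat <- sweep(q, 2, pq$global, "*")
    pk <- oracleAdditivePool(pmat, as.numeric(p$baWk[[h]]))
    u[, cols] <- sweep(q, 2, pk$global, "*")
  }
  r <- u %*% p$baWr
  r <- sweep(r, 2, as.numeric(p$baBr), "+")
  z <- r + x
  out <- matrix(0, n, cf$d)
  for (i in seq_len(n)) {
    mu <- mean(z[i, ])
    sd0 <- sqrt(mean((z[i, ] - mu) ^ 2) + 1e-5)
    out[i, ] <- ((z[i, ] - mu) / sd0) * as.numeric(p$baGamma) +
      as.numeric(p$baBeta)
  }
  out
}

# plain multi-head scaled dot-product attention (optionally biased)
oracleMultihead <- function(wq, wk, wv, wo, bo, x, biases = NULL) {
  nh <- length(wq)
  dh <- ncol(wq[[1]])
  outs <- vector("list", nh)
  for (h in seq_len(nh)) {
    q <- x %*% wq[[h]]; k <- x %*% wk[[h]]; v <- x %*% wv[[h]]
    s <- q %*% t(k) / sqrt(dh)
    if (!is.null(biases) && !is.null(biases[[h]])) s <- s + biases[[h]]
    a <- t(apply(s, 1, oracleSoftmax))
    if (nrow(s) == 1) a <- matrix(a, 1)
    outs[[h]] <- a %*% v
  }
  sweep(do.call(cbind, outs) %*% wo, 2, as.numeric(bo), "+")
}

# directed bond message step by explicit loops over bonds
oracleMessageStep <- function(h, origin, dest, revIdx) {
  out <- matrix(0, nrow(h), ncol(h))
  for (e in seq_len(nrow(h))) {
    for (e2 in seq_len(nrow(h))) {
      if (dest[e2] == origin[e]) out[e, ] <- out[e, ] + h[e2, ]
    }
    out[e, ] <- out[e, ] - h[revIdx[e], ]
  }
  out
}

# AUROC by explicit pair counting
oracleAuroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) tot <- tot + 1
    else if (scores[i] == scores[j]) tot <- tot + 0.5
  }
  tot / (length(pos) * length(neg))
}

# AUPRC by step-function integration over the sorted score sweep
oracleAuprc <- function(scores, labels) {
  o <- order(-scores)
  lab <- labels[o]
  tp <- 0; fp <- 0
  ap <- 0
  for (i in seq_along(lab)) {
    if (lab[i] == 1) {
      tp <- tp + 1
      ap <- ap + tp / (tp + fp)
    } else {
      fp <- fp + 1
    }
  }
  ap / sum(labels == 1)
}

oracleRmse <- function(p, y) sqrt(sum((p - y) ^ 2) / length(y))
oracleMae <- function(p, y) sum(abs(p - y)) / length(y)
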