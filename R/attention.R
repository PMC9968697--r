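# Attention primitives: additive (global-context) pooling, Fastformer-style
# bond attention, and biased multi-head scaled dot-product atom attention.
#
# Each block exists twice: a tape version (ag_*) used inside training, and a
# plain numeric exported wrapper that runs the tape version on constant
# parameters and returns values. Both therefore share one code path.

#' Additive attention pooling
#'
#' Scores each token by the dot product with a learned score vector, scaled
#' by 1/sqrt(d); softmax-normalizes the scores into weights; and returns the
#' weighted sum of the tokens as a single global vector. This is the
#' linear-complexity pooling at the heart of the global-context (Fastformer)
#' bond attention.
#'
#' @param tokens n x d numeric matrix (n >= 1).
#' @param scoreVector Numeric length-d score vector.
#' @return List with \code{global} (length-d vector) and \code{weights}
#'   (length-n vector summing to 1).
#' @examples
#' additivePool(matrix(1:6, 2, 3), c(1, 0, 0))
#' @export
additivePool <- function(tokens, scoreVector) {
  tokens <- as.matrix(tokens)
  if (nrow(tokens) == 0L) stop("no tokens to pool", call. = FALSE)
  stopifnot(length(scoreVector) == ncol(tokens))
  tape <- ag_tape()
  tk <- ag_const(tape, tokens)
  sv <- ag_const(tape, matrix(scoreVector, ncol = 1L))
  res <- ag_additive_pool(tk, sv, tape)
  list(global = as.numeric(res$global$val),
       weights = as.numeric(res$weights$val))
}

# tokens: n x dh node; w: dh x 1 score-vector node
ag_additive_pool <- function(tokens, w, tape) {
  dh <- ncol(tokens$val)
  scores <- ag_scale(ag_mm(tokens, w, tape), 1 / sqrt(dh), tape)
  al <- ag_softmax_vec(scores, tape)
  global <- ag_mm(ag_transpose(al, tape), tokens, tape)  # 1 x dh
  list(global = global, weights = al)
}

.headCols <- function(d, nHeads) {
  dh <- d %/% nHeads
  lapply(seq_len(nHeads), function(h) (h - 1L) * dh + seq_len(dh))
}

# Fastformer (additive-attention) bond attention block.
# x: 2N x d node. Query, key and value all equal the input; per head there
# are two additive score vectors (query pooling, key pooling); the key-value
# interaction vectors are concatenated over heads, passed through a shared
# linear transform, added to the queries via a skip connection and layer
# normalized.
ag_fastformer <- function(x, p, cf, tape, training = FALSE, capture = NULL) {
  cols <- .headCols(cf$d, cf$nHeads)
  us <- vector("list", cf$nHeads)
  for (h in seq_len(cf$nHeads)) {
    q <- ag_cols(x, cols[[h]], tape)           # q = k = v = input slice
    pq <- ag_additive_pool(q, p$baWq[[h]], tape)
    pmat <- ag_mulrow(q, pq$global, tape)      # q_b (*) k_i
    pk <- ag_additive_pool(pmat, p$baWk[[h]], tape)
    us[[h]] <- ag_mulrow(q, pk$global, tape)   # k_b (*) v_i
    if (!is.null(capture)) {
      capture$additiveWeights[[length(capture$additiveWeights) + 1L]] <-
        as.numeric(pq$weights$val)
      capture$additiveWeights[[length(capture$additiveWeights) + 1L]] <-
        as.numeric(pk$weights$val)
    }
  }
  u <- ag_cbind(us, tape)
  r <- ag_addrow(ag_mm(u, p$baWr, tape), p$baBr, tape)
  out <- ag_layernorm_rows(ag_add(r, x, tape), p$baGamma, p$baBeta, tape)
  ag_dropout(out, cf$dropout, training, tape)
}

# Multi-head scaled dot-product attention with optional per-head additive
# pre-softmax bias matrices. Used for atom attention (with inter-atomic
# biases) and for the Transformer variant of bond attention (without).
ag_multihead <- function(x, wq, wk, wv, wo, bo, biases, cf, tape,
                         training = FALSE, capture = NULL) {
  dh <- cf$d %/% cf$nHeads
  outs <- vector("list", cf$nHeads)
  for (h in seq_len(cf$nHeads)) {
    q <- ag_mm(x, wq[[h]], tape)
    k <- ag_mm(x, wk[[h]], tape)
    v <- ag_mm(x, wv[[h]], tape)
    s <- ag_scale(ag_mmt(q, k, tape), 1 / sqrt(dh), tape)
    if (!is.null(biases) && !is.null(biases[[h]]))
      s <- ag_addconst(s, biases[[h]], tape)
    a <- ag_softmax_rows(s, tape)
    if (!is.null(capture)) capture$maps[[h]] <- unname(a$val)
    a <- ag_dropout(a, cf$dropout, training, tape)
    outs[[h]] <- ag_mm(a, v, tape)
  }
  o <- ag_cbind(outs, tape)
  out <- ag_addrow(ag_mm(o, wo, tape), bo, tape)
  ag_dropout(out, cf$dropout, training, tape)
}

# resolve the per-head bias matrices from the head assignment
.headBiases <- function(matrices, assignment) {
  if (is.null(matrices)) return(NULL)
  lapply(assignment, function(a) {
    if (a == "none") NULL else matrices[[a]]
  })
}

#' Fastformer bond attention (forward computation)
#'
#' Applies the additive-attention (global-context) block to the directed
#' bond message matrix: per head, a global query is pooled from the queries,
#' multiplied elementwise into the keys, a global key is pooled from the
#' result and multiplied into the values; head outputs are concatenated,
#' linearly transformed, added to the queries through a skip connection and
#' layer normalized. Query, key and value all equal the input bond messages.
#'
#' @param model An \code{\linkS4class{ABTModel}} built with
#'   \code{bondAttention = "fastformer"}.
#' @param messages 2N x d numeric matrix of bond messages.
#' @param capture Optional environment; on return its
#'   \code{additiveWeights} field holds the per-head additive weight
#'   vectors (two per head: query pooling and key pooling).
#' @return 2N x d numeric matrix (empty input returns an empty matrix).
#' @export
bondAttention <- function(model, messages, capture = NULL) {
  messages <- as.matrix(messages)
  cf <- model@config
  if (nrow(messages) == 0L) return(matrix(0, 0L, cf$d))
  stopifnot(ncol(messages) == cf$d)
  if (cf$bondAttention == "none")
    stop("model was built without bond attention", call. = FALSE)
  if (!is.null(capture)) capture$additiveWeights <- list()
  tape <- ag_tape()
  x <- ag_const(tape, messages)
  p <- lapply_params_const(model@params, tape)
  out <- if (cf$bondAttention == "fastformer")
    ag_fastformer(x, p, cf, tape, training = FALSE, capture = capture)
  else
    ag_multihead(x, p$btWQ, p$btWK, p$btWV, p$btWO, p$btBO, NULL, cf, tape)
  out$val
}

#' Biased multi-head atom attention (forward computation)
#'
#' Standard multi-head scaled dot-product self-attention over atoms, except
#' that each head's pre-softmax query-key interaction matrix receives one
#' Z-score normalized, lambda-scaled inter-atomic matrix as an additive
#' bias. The default head assignment pairs heads 1-2 with the adjacency
#' matrix, 3-4 with the 3D distance matrix and 5-6 with the Coulomb matrix.
#'
#' @param model An \code{\linkS4class{ABTModel}} with atom attention.
#' @param messages M x d numeric matrix of aggregated atom messages.
#' @param biases Optional list with M x M matrices named \code{adjacency},
#'   \code{distance}, \code{coulomb} (normally from
#'   \code{\link{normalizedMatrices}}); NULL runs plain multi-head
#'   attention.
#' @param capture Optional environment; on return its \code{maps} field
#'   holds the per-head M x M row-stochastic attention maps.
#' @return M x d numeric matrix.
#' @export
atomAttention <- function(model, messages, biases = NULL, capture = NULL) {
  messages <- as.matrix(messages)
  cf <- model@config
  stopifnot(ncol(messages) == cf$d)
  if (!cf$atomAttention)
    stop("model was built without atom attention", call. = FALSE)
  if (!is.null(biases)) {
    m <- nrow(messages)
    for (b in biases)
      if (!is.null(b) && (nrow(b) != m || ncol(b) != m))
        stop("bias matrix dimension does not match atom count", call. = FALSE)
  }
  if (!is.null(capture)) capture$maps <- vector("list", cf$nHeads)
  tape <- ag_tape()
  x <- ag_const(tape, messages)
  p <- lapply_params_const(model@params, tape)
  hb <- .headBiases(biases, cf$headAssignment)
  out <- ag_multihead(x, p$aaWQ, p$aaWK, p$aaWV, p$aaWO, p$aaBO, hb, cf,
                      tape, training = FALSE, capture = capture)
  out$val
}

# wrap every matrix in a (possibly nested) parameter list as a const node
lapply_params_const <- function(params, tape) {
  lapply(params, function(p) {
    if (is.list(p)) lapply(p, function(q) ag_const(tape, q))
    else ag_const(tape, p)
  })
}

# wrap as variable nodes (gradients collected after backward)
lapply_params_var <- function(params, tape) {
  lapply(params, function(p) {
    if (is.list(p)) lapply(p, function(q) ag_var(tape, q))
    else ag_var(tape, p)
  })
}
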