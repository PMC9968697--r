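# ABT-MPNN model: parameter construction and the full forward computation.
#
# Phases (all shapes use the row-per-token convention, so projections
# right-multiply): initialization h0 = ReLU([x_v, e_vw] Wi); T bond-embedding
# iterations m = neighbor-sum minus reverse, b = BondAttention(m) + m,
# h = ReLU(h0 + b Wh); atom embedding m_v = ReLU([x_v, sum outgoing h] Wo),
# h_v = AtomAttention(m_v, biases) + m_v; molecule embedding h = sum h_v,
# yhat = FFN([h, h_f]).

.xavier <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Construct an ABT-MPNN model
#'
#' Builds all learnable parameters (seeded Glorot-uniform initialization)
#' for the requested architecture. The ablation family of the original
#' design is fully expressible: \code{bondAttention} selects no bond
#' attention, the additive-attention (Fastformer) block or a standard
#' multi-head Transformer block; \code{atomAttention} toggles atom-level
#' self-attention; \code{atomBias} toggles the inter-atomic bias matrices
#' inside it.
#'
#' @param nTasks Number of prediction tasks (output columns).
#' @param taskType \code{"regression"} or \code{"classification"}.
#' @param T Message-passing iterations (>= 1; tuned over 2..6).
#' @param d Hidden dimension (divisible by \code{nHeads}; tuned over
#'   300..2400 in steps of 100).
#' @param lambda Inter-atomic feature scaler in [0, 0.5]; 0 disables the
#'   attention biases numerically.
#' @param dropout Dropout probability in [0, 0.4].
#' @param nHeads Attention heads (default 6).
#' @param bondAttention \code{"fastformer"}, \code{"transformer"} or
#'   \code{"none"}.
#' @param atomAttention Use the biased multi-head atom attention block.
#' @param atomBias Add the inter-atomic matrices as pre-softmax biases.
#' @param headAssignment Character vector of length \code{nHeads} mapping
#'   each head to \code{"adjacency"}, \code{"distance"}, \code{"coulomb"}
#'   or \code{"none"}; default pairs heads 1-2/3-4/5-6 with
#'   adjacency/distance/Coulomb.
#' @param aggregate Atom aggregation over \code{"outgoing"} (algorithm
#'   statement) or \code{"incoming"} directed bond hidden states.
#' @param ffnHidden Width of the readout hidden layer (default \code{d}).
#' @param nDescriptors Length of the molecular descriptor vector.
#' @param seed Integer seed for weight initialization.
#' @return An \code{\linkS4class{ABTModel}}.
#' @examples
#' m <- abtModel(nTasks = 1, taskType = "regression", d = 12, T = 2, seed = 1)
#' nParams(m)
#' @export
abtModel <- function(nTasks, taskType = c("regression", "classification"),
                     T = 3L, d = 300L, lambda = 0.1, dropout = 0,
                     nHeads = 6L,
                     bondAttention = c("fastformer", "transformer", "none"),
                     atomAttention = TRUE, atomBias = TRUE,
                     headAssignment = NULL,
                     aggregate = c("outgoing", "incoming"),
                     ffnHidden = NULL, nDescriptors = 200L, seed = 0L) {
  taskType <- match.arg(taskType)
  bondAttention <- match.arg(bondAttention)
  aggregate <- match.arg(aggregate)
  if (d %% nHeads != 0) stop("d must be divisible by nHeads", call. = FALSE)
  if (is.null(ffnHidden)) ffnHidden <- d
  if (is.null(headAssignment)) {
    headAssignment <- if (atomBias)
      rep(c("adjacency", "distance", "coulomb"), each = ceiling(nHeads / 3))[seq_len(nHeads)]
    else rep("none", nHeads)
  }
  if (!atomBias) headAssignment <- rep("none", nHeads)
  da <- atomFeatureDim(); db <- bondFeatureDim()
  dh <- d %/% nHeads
  set.seed(seed)
  p <- list(
    Wi = .xavier(da + db, d),
    Wh = .xavier(d, d),
    Wo = .xavier(da + d, d),
    bo = matrix(0, 1, d))
  if (bondAttention == "fastformer") {
    p$baWq <- lapply(seq_len(nHeads), function(h) .xavier(dh, 1))
    p$baWk <- lapply(seq_len(nHeads), function(h) .xavier(dh, 1))
    p$baWr <- .xavier(d, d)
    p$baBr <- matrix(0, 1, d)
    p$baGamma <- matrix(1, 1, d)
    p$baBeta <- matrix(0, 1, d)
  } else if (bondAttention == "transformer") {
    p$btWQ <- lapply(seq_len(nHeads), function(h) .xavier(d, dh))
    p$btWK <- lapply(seq_len(nHeads), function(h) .xavier(d, dh))
    p$btWV <- lapply(seq_len(nHeads), function(h) .xavier(d, dh))
    p$btWO <- .xavier(d, d)
    p$btBO <- matrix(0, 1, d)
  }
  if (atomAttention) {
    p$aaWQ <- lapply(seq_len(nHeads), function(h) .xavier(d, dh))
    p$aaWK <- lapply(seq_len(nHeads), function(h) .xavier(d, dh))
    p$aaWV <- lapply(seq_len(nHeads), function(h) .xavier(d, dh))
    p$aaWO <- .xavier(d, d)
    p$aaBO <- matrix(0, 1, d)
  }
  p$W1 <- .xavier(d + nDescriptors, ffnHidden)
  p$b1 <- matrix(0, 1, ffnHidden)
  p$W2 <- .xavier(ffnHidden, nTasks)
  p$b2 <- matrix(0, 1, nTasks)

  methods::new("ABTModel",
    params = p,
    config = list(T = as.integer(T), d = as.integer(d), lambda = lambda,
                  dropout = dropout, nHeads = as.integer(nHeads),
                  bondAttention = bondAttention,
                  atomAttention = atomAttention, atomBias = atomBias,
                  headAssignment = headAssignment, aggregate = aggregate,
                  ffnHidden = as.integer(ffnHidden),
                  nTasks = as.integer(nTasks), taskType = taskType,
                  nDescriptors = as.integer(nDescriptors)),
    schema = list(da = da, db = db, nDescriptors = as.integer(nDescriptors),
                  descriptorNames = descriptorNames()),
    norm = list())
}

# ---- per-molecule constant structure -------------------------------------

# Message-passing and aggregation as constant linear maps:
#   Cmsg[e, e'] = 1 if dest(e') == origin(e), minus the reverse bond;
#   Sout[v, e] = 1 if origin(e) == v;  Sin[v, e] = 1 if dest(e) == v.
.graphMaps <- function(g) {
  nb2 <- 2L * g@nBonds
  m <- g@nAtoms
  cmsg <- matrix(0, nb2, nb2)
  sout <- matrix(0, m, nb2)
  sin <- matrix(0, m, nb2)
  if (nb2 > 0) {
    for (e in seq_len(nb2)) {
      incoming <- which(g@bondDest == g@bondOrigin[e])
      cmsg[e, incoming] <- 1
      cmsg[e, g@bondReverse[e]] <- cmsg[e, g@bondReverse[e]] - 1
      sout[g@bondOrigin[e], e] <- 1
      sin[g@bondDest[e], e] <- 1
    }
  }
  list(cmsg = cmsg, sout = sout, sin = sin)
}

# Everything the forward pass needs for one molecule, computed once.
.prepareMolecule <- function(g, model) {
  cf <- model@config
  maps <- .graphMaps(g)
  nb2 <- 2L * g@nBonds
  f0 <- if (nb2 > 0)
    cbind(g@atomFeatures[g@bondOrigin, , drop = FALSE], g@bondFeatures)
  else matrix(0, 0, model@schema$da + model@schema$db)
  biases <- NULL
  if (cf$atomAttention && cf$atomBias && cf$lambda > 0 &&
      nrow(g@distance) > 0) {
    biases <- normalizedMatrices(g, cf$lambda)
  }
  desc <- g@descriptors
  if (length(desc) == 0L) desc <- numeric(model@schema$nDescriptors)
  if (!is.null(model@norm$descriptorMean)) {
    sd <- model@norm$descriptorSd
    sd[!is.finite(sd) | sd <= 0] <- Inf
    desc <- (desc - model@norm$descriptorMean) / sd
    desc[!is.finite(desc)] <- 0
  }
  list(f0 = f0, maps = maps, x = g@atomFeatures, biases = biases,
       desc = matrix(desc, 1), m = g@nAtoms, nb2 = nb2)
}

# tape forward for one prepared molecule; returns the 1 x nTasks output node
ag_forward_molecule <- function(prep, p, cf, tape, training = FALSE,
                                capture = NULL) {
  d <- cf$d
  if (prep$nb2 > 0) {
    f0 <- ag_const(tape, prep$f0)
    h0 <- ag_relu(ag_mm(f0, p$Wi, tape), tape)
    h <- h0
    for (t in seq_len(cf$T)) {
      msg <- ag_lmulconst(prep$maps$cmsg, h, tape)
      b <- if (cf$bondAttention == "fastformer")
        ag_add(ag_fastformer(msg, p, cf, tape, training, capture), msg, tape)
      else if (cf$bondAttention == "transformer")
        ag_add(ag_multihead(msg, p$btWQ, p$btWK, p$btWV, p$btWO, p$btBO,
                            NULL, cf, tape, training), msg, tape)
      else msg
      h <- ag_relu(ag_add(h0, ag_mm(b, p$Wh, tape), tape), tape)
      h <- ag_dropout(h, cf$dropout, training, tape)
    }
    s <- if (cf$aggregate == "outgoing") prep$maps$sout else prep$maps$sin
    bondSum <- ag_lmulconst(s, h, tape)
  } else {
    bondSum <- ag_const(tape, matrix(0, prep$m, d))
  }
  xa <- ag_const(tape, prep$x)
  mV <- ag_relu(ag_addrow(ag_mm(ag_cbind(list(xa, bondSum), tape),
                                p$Wo, tape), p$bo, tape), tape)
  mV <- ag_dropout(mV, cf$dropout, training, tape)
  if (cf$atomAttention) {
    hb <- .headBiases(prep$biases, cf$headAssignment)
    att <- ag_multihead(mV, p$aaWQ, p$aaWK, p$aaWV, p$aaWO, p$aaBO, hb, cf,
                        tape, training, capture)
    hV <- ag_add(att, mV, tape)
  } else {
    hV <- mV
  }
  hMol <- ag_sumrows(hV, tape)
  z <- ag_cbind(list(hMol, ag_const(tape, prep$desc)), tape)
  hid <- ag_relu(ag_addrow(ag_mm(z, p$W1, tape), p$b1, tape), tape)
  hid <- ag_dropout(hid, cf$dropout, training, tape)
  ag_addrow(ag_mm(hid, p$W2, tape), p$b2, tape)
}

#' Forward pass over a batch of molecules
#'
#' Runs the full computation (initialization, T message-passing iterations
#' with bond attention, atom aggregation, biased atom attention, readout)
#' for each featurized molecule. Molecules are processed independently, so
#' batched and per-molecule results are identical.
#'
#' @param model An \code{\linkS4class{ABTModel}}.
#' @param graphs List of featurized \code{\linkS4class{MolGraph}} objects
#'   (see \code{\link{featurizeMolecule}}).
#' @return Numeric batch x nTasks matrix of raw scores (no sigmoid).
#' @export
modelForward <- function(model, graphs) {
  cf <- model@config
  out <- matrix(0, length(graphs), cf$nTasks)
  if (length(graphs) == 0L) return(out)
  for (i in seq_along(graphs)) {
    tape <- ag_tape()
    p <- lapply_params_const(model@params, tape)
    prep <- .prepareMolecule(graphs[[i]], model)
    out[i, ] <- ag_forward_molecule(prep, p, cf, tape)$val
  }
  out
}

#' Predict properties for molecules
#'
#' Featurizes raw SMILES if needed, runs the forward pass, applies the
#' sigmoid for classification models and un-scales regression outputs back
#' to the original target units using the training-split statistics stored
#' in the model.
#'
#' @param model A trained \code{\linkS4class{ABTModel}}.
#' @param molecules Character vector of SMILES or list of
#'   \code{\linkS4class{MolGraph}}.
#' @param conformerSeed Seed for conformer embedding of raw SMILES.
#' @return Numeric matrix, one row per molecule, one column per task.
#' @export
predictMolecules <- function(model, molecules, conformerSeed = 0L) {
  graphs <- if (is.character(molecules))
    featurizeDataset(molecules, conformerSeed = conformerSeed)
  else molecules
  out <- modelForward(model, graphs)
  if (model@config$taskType == "classification") {
    out <- 1 / (1 + exp(-out))
  } else if (!is.null(model@norm$targetMean)) {
    out <- sweep(sweep(out, 2, model@norm$targetSd, "*"), 2,
                 model@norm$targetMean, "+")
  }
  out
}

# ---- exported single-phase operations ------------------------------------

#' Initial directed-bond hidden states
#'
#' h0_vw = ReLU(concat(x_v, e_vw) Wi) for every directed bond (v, w); Wi
#' carries no additive bias.
#'
#' @param model An \code{\linkS4class{ABTModel}}.
#' @param graph A parsed \code{\linkS4class{MolGraph}}.
#' @return 2N x d numeric matrix.
#' @export
initBondHidden <- function(model, graph) {
  nb2 <- 2L * graph@nBonds
  if (nb2 == 0L) return(matrix(0, 0, model@config$d))
  f0 <- cbind(graph@atomFeatures[graph@bondOrigin, , drop = FALSE],
              graph@bondFeatures)
  if (ncol(f0) != nrow(model@params$Wi))
    stop("feature width does not match Wi", call. = FALSE)
  h <- unname(f0 %*% model@params$Wi)
  h * (h > 0)
}

#' One directed-bond message-passing step
#'
#' The message for directed bond (v, w) is the sum of the hidden states of
#' all directed bonds arriving at v, excluding the reverse bond (w, v) —
#' the directed scheme that prevents a message from flowing straight back
#' to where it came from.
#'
#' @param hPrev 2N x d matrix of directed-bond hidden states.
#' @param graph The \code{\linkS4class{MolGraph}} the states belong to.
#' @return 2N x d matrix of messages m_vw.
#' @export
bondMessageStep <- function(hPrev, graph) {
  hPrev <- as.matrix(hPrev)
  stopifnot(nrow(hPrev) == 2L * graph@nBonds, all(is.finite(hPrev)))
  .graphMaps(graph)$cmsg %*% hPrev
}

#' Bond hidden-state update
#'
#' b = BondAttention(messages) + messages (skip connection) when the model
#' has bond attention and \code{useBondAttention} is TRUE, else
#' b = messages; then h = ReLU(h0 + b Wh).
#'
#' @param model An \code{\linkS4class{ABTModel}}.
#' @param h0 2N x d initial hidden states.
#' @param messages 2N x d messages from \code{\link{bondMessageStep}}.
#' @param useBondAttention Apply the model's bond attention block.
#' @return 2N x d updated hidden states.
#' @export
bondUpdate <- function(model, h0, messages, useBondAttention = TRUE) {
  stopifnot(dim(h0) == dim(messages))
  b <- if (useBondAttention && model@config$bondAttention != "none" &&
           nrow(messages) > 0)
    bondAttention(model, messages) + messages
  else messages
  h <- h0 + b %*% model@params$Wh
  h * (h > 0)
}

#' Aggregate directed-bond hidden states into atom messages
#'
#' m_v = ReLU(concat(x_v, sum of h_vw over the directed bonds at v) Wo + bo).
#' The sum runs over bonds originating at v by default; the incoming-bond
#' variant is selected by the model's \code{aggregate} configuration.
#'
#' @param model An \code{\linkS4class{ABTModel}}.
#' @param graph A parsed \code{\linkS4class{MolGraph}}.
#' @param bondHiddens 2N x d hidden states after T iterations.
#' @return M x d matrix of atom messages.
#' @export
atomAggregate <- function(model, graph, bondHiddens) {
  maps <- .graphMaps(graph)
  s <- if (model@config$aggregate == "outgoing") maps$sout else maps$sin
  bondSum <- if (2L * graph@nBonds > 0) s %*% as.matrix(bondHiddens)
             else matrix(0, graph@nAtoms, model@config$d)
  h <- unname(cbind(graph@atomFeatures, bondSum) %*% model@params$Wo)
  h <- sweep(h, 2, as.numeric(model@params$bo), "+")
  h * (h > 0)
}

#' Attended atom hidden states
#'
#' h_v = AtomAttention(m_v, biases) + m_v (skip connection).
#'
#' @param model An \code{\linkS4class{ABTModel}} with atom attention.
#' @param aggregated M x d atom messages.
#' @param biases Normalized inter-atomic matrices
#'   (\code{\link{normalizedMatrices}}) or NULL.
#' @return M x d matrix.
#' @export
atomEmbedding <- function(model, aggregated, biases = NULL) {
  atomAttention(model, aggregated, biases) + aggregated
}

#' Molecule embedding and readout
#'
#' Sums the atom hidden states into a single molecule vector, concatenates
#' the molecular descriptors and applies the two-layer feed-forward readout.
#'
#' @param model An \code{\linkS4class{ABTModel}}.
#' @param hidden M x d attended atom states.
#' @param descriptors Length-200 descriptor vector (normalized).
#' @return List with \code{embedding} (length-d molecule vector) and
#'   \code{output} (length-nTasks raw scores).
#' @export
moleculeReadout <- function(model, hidden, descriptors) {
  h <- colSums(as.matrix(hidden))
  z <- matrix(c(h, descriptors), 1)
  hid <- z %*% model@params$W1
  hid <- hid + matrix(as.numeric(model@params$b1), 1)
  hid <- hid * (hid > 0)
  out <- hid %*% model@params$W2 + matrix(as.numeric(model@params$b2), 1)
  list(embedding = h, output = as.numeric(out))
}

# ---- parameter flattening for the optimizer ------------------------------

.flattenParams <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (is.list(p[[nm]])) {
      for (i in seq_along(p[[nm]]))
        out[[paste0(nm, ".", i)]] <- p[[nm]][[i]]
    } else out[[nm]] <- p[[nm]]
  }
  out
}

.unflattenParams <- function(flat, template) {
  for (nm in names(template)) {
    if (is.list(template[[nm]])) {
      for (i in seq_along(template[[nm]]))
        template[[nm]][[i]] <- flat[[paste0(nm, ".", i)]]
    } else template[[nm]] <- flat[[nm]]
  }
  template
}

.collectGrads <- function(pnodes) {
  out <- list()
  for (nm in names(pnodes)) {
    if (is.list(pnodes[[nm]]) && !is.environment(pnodes[[nm]])) {
      for (i in seq_along(pnodes[[nm]])) {
        nd <- pnodes[[nm]][[i]]
        out[[paste0(nm, ".", i)]] <-
          if (is.null(nd$grad)) matrix(0, nrow(nd$val), ncol(nd$val)) else nd$grad
      }
    } else {
      nd <- pnodes[[nm]]
      out[[nm]] <-
        if (is.null(nd$grad)) matrix(0, nrow(nd$val), ncol(nd$val)) else nd$grad
    }
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores parameters, configuration, feature schema and
#' normalization statistics, sufficient for bit-compatible reload.
#'
#' @param model An \code{\linkS4class{ABTModel}}.
#' @param path File path.
#' @return \code{loadCheckpoint} returns the restored model.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(params = model@params, config = model@config,
               schema = model@schema, norm = model@norm), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  methods::new("ABTModel", params = x$params, config = x$config,
               schema = x$schema, norm = x$norm)
}
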