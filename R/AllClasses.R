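#' MolGraph: a featurized molecular graph
#'
#' Container for one molecule as a directed bond graph over heavy atoms.
#' Each undirected chemical bond contributes two directed bonds (v,w) and
#' (w,v), which carry independent hidden states during message passing but
#' share one (direction-independent) bond feature row.
#'
#' @slot smiles Canonical SMILES (OpenBabel canonicalization).
#' @slot nAtoms Number of heavy atoms M.
#' @slot nBonds Number of undirected bonds N.
#' @slot elements Element symbols, length M.
#' @slot atomicNumbers Nuclear charges Z, length M.
#' @slot formalCharges Integer formal charges, length M.
#' @slot aromatic Logical, atom is in an aromatic ring.
#' @slot inRing Logical, atom is in any ring.
#' @slot nHydrogens Implicit hydrogen counts, length M.
#' @slot hybridization Character in \code{c("sp","sp2","sp3","other")}.
#' @slot bondOrigin,bondDest Integer vectors of length 2N; directed bond b
#'   runs from atom \code{bondOrigin[b]} to \code{bondDest[b]} (1-based).
#' @slot bondReverse Integer vector of length 2N; index of the opposite
#'   direction of each directed bond.
#' @slot bondOrders Numeric length 2N (kekulized orders 1/2/3).
#' @slot bondAromatic,bondConjugated,bondInRing Logical, length 2N.
#' @slot atomFeatures M x d_a feature matrix (rows are x_v).
#' @slot bondFeatures 2N x d_b feature matrix (rows are e_vw; reverse pairs
#'   identical).
#' @slot coords2d M x 2 depiction coordinates.
#' @slot coords3d M x 3 conformer coordinates in Angstrom (0 x 3 until
#'   \code{\link{embedConformer}} is run or a full featurization requests it).
#' @slot adjacency,distance,coulomb M x M inter-atomic matrices (0 x 0 until
#'   computed).
#' @slot distanceIsTopological Logical; TRUE when conformer embedding failed
#'   and the graph shortest-path bond-count matrix is standing in for the 3D
#'   distance matrix.
#' @slot descriptors Named numeric vector of molecule-level descriptors
#'   (length 0 until computed).
#' @slot sdf The underlying \code{ChemmineR::SDF} object (or NULL).
#' @export
setClass("MolGraph", representation(
  smiles = "character",
  nAtoms = "integer",
  nBonds = "integer",
  elements = "character",
  atomicNumbers = "integer",
  formalCharges = "integer",
  aromatic = "logical",
  inRing = "logical",
  nHydrogens = "integer",
  hybridization = "character",
  bondOrigin = "integer",
  bondDest = "integer",
  bondReverse = "integer",
  bondOrders = "numeric",
  bondAromatic = "logical",
  bondConjugated = "logical",
  bondInRing = "logical",
  atomFeatures = "matrix",
  bondFeatures = "matrix",
  coords2d = "matrix",
  coords3d = "matrix",
  adjacency = "matrix",
  distance = "matrix",
  coulomb = "matrix",
  distanceIsTopological = "logical",
  descriptors = "numeric",
  sdf = "ANY"
))

setValidity("MolGraph", function(object) {
  msg <- character(0)
  m <- object@nAtoms
  nb <- length(object@bondOrigin)
  if (m < 1L) msg <- c(msg, "a molecule must have at least one heavy atom")
  if (nb != 2L * object@nBonds)
    msg <- c(msg, "directed bond count must equal 2 * nBonds")
  if (length(object@bondDest) != nb || length(object@bondReverse) != nb)
    msg <- c(msg, "bondOrigin/bondDest/bondReverse lengths differ")
  if (nb > 0L) {
    if (any(object@bondOrigin < 1L | object@bondOrigin > m) ||
        any(object@bondDest < 1L | object@bondDest > m))
      msg <- c(msg, "bond endpoints out of atom range")
    rev <- object@bondReverse
    if (any(rev[rev] != seq_len(nb)))
      msg <- c(msg, "bondReverse is not an involution")
    if (any(object@bondOrigin != object@bondDest[rev]) ||
        any(object@bondDest != object@bondOrigin[rev]))
      msg <- c(msg, "reverse bonds must swap origin and destination")
  }
  if (nrow(object@atomFeatures) != m)
    msg <- c(msg, "atomFeatures must have one row per atom")
  if (nrow(object@bondFeatures) != nb)
    msg <- c(msg, "bondFeatures must have one row per directed bond")
  if (nb > 0L) {
    if (max(abs(object@bondFeatures - object@bondFeatures[object@bondReverse, , drop = FALSE])) > 0)
      msg <- c(msg, "bond features must be direction independent")
  }
  for (nm in c("adjacency", "distance", "coulomb")) {
    a <- slot(object, nm)
    if (nrow(a) > 0L) {
      if (nrow(a) != m || ncol(a) != m)
        msg <- c(msg, sprintf("%s matrix must be M x M", nm))
      else if (max(abs(a - t(a))) > 1e-8)
        msg <- c(msg, sprintf("%s matrix must be symmetric", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ABTModel: parameters and configuration of an ABT-MPNN
#'
#' Holds all learnable weights, the architecture configuration, the feature
#' schema it was built for, and the normalization statistics fitted on a
#' training split. Construct with \code{\link{abtModel}}.
#'
#' @slot params Named list of weight matrices.
#' @slot config Named list (T, d, lambda, dropout, nHeads, bondAttention,
#'   atomAttention, atomBias, headAssignment, aggregate, ffnHidden, nTasks,
#'   taskType).
#' @slot schema Named list (da, db, nDescriptors, descriptorNames).
#' @slot norm Named list of normalization statistics (targetMean, targetSd,
#'   descriptorMean, descriptorSd); empty until fitted.
#' @export
setClass("ABTModel", representation(
  params = "list",
  config = "list",
  schema = "list",
  norm = "list"
))

setValidity("ABTModel", function(object) {
  cf <- object@config
  msg <- character(0)
  if (cf$d %% cf$nHeads != 0)
    msg <- c(msg, "hidden dimension d must be divisible by nHeads")
  if (cf$T < 1) msg <- c(msg, "T must be >= 1")
  if (cf$lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (cf$dropout < 0 || cf$dropout >= 1) msg <- c(msg, "dropout must be in [0,1)")
  if (!cf$bondAttention %in% c("none", "fastformer", "transformer"))
    msg <- c(msg, "bondAttention must be none/fastformer/transformer")
  if (!is.null(object@params$Wi) &&
      nrow(object@params$Wi) != object@schema$da + object@schema$db)
    msg <- c(msg, "Wi rows must equal d_a + d_b")
  if (length(msg)) msg else TRUE
})

#' AttentionRecord: captured atom-attention maps for one molecule
#'
#' @slot smiles Canonical SMILES of the molecule.
#' @slot heads List of 6 M x M row-stochastic attention maps.
#' @slot pairAverages List with elements \code{adjacency} (mean of heads
#'   1-2), \code{distance} (3-4) and \code{coulomb} (5-6).
#' @slot overall Elementwise mean over all heads.
#' @export
setClass("AttentionRecord", representation(
  smiles = "character",
  heads = "list",
  pairAverages = "list",
  overall = "matrix"
))

setMethod("show", "MolGraph", function(object) {
  cat(sprintf("MolGraph: %s\n  %d heavy atoms, %d bonds (%d directed)\n",
              object@smiles, object@nAtoms, object@nBonds,
              2L * object@nBonds))
  cat(sprintf("  atom features: %d x %d; bond features: %d x %d\n",
              nrow(object@atomFeatures), ncol(object@atomFeatures),
              nrow(object@bondFeatures), ncol(object@bondFeatures)))
  has <- c(adjacency = nrow(object@adjacency) > 0,
           distance = nrow(object@distance) > 0,
           coulomb = nrow(object@coulomb) > 0,
           descriptors = length(object@descriptors) > 0)
  cat("  computed:", if (any(has)) paste(names(has)[has], collapse = ", ")
      else "(topology and local features only)", "\n")
})

setMethod("show", "ABTModel", function(object) {
  cf <- object@config
  cat(sprintf("ABTModel: T=%d, d=%d, lambda=%.2f, dropout=%.2f, heads=%d\n",
              cf$T, cf$d, cf$lambda, cf$dropout, cf$nHeads))
  cat(sprintf("  bond attention: %s; atom attention: %s (inter-atomic bias: %s)\n",
              cf$bondAttention,
              if (cf$atomAttention) "on" else "off",
              if (cf$atomBias) "on" else "off"))
  cat(sprintf("  task: %s, %d task(s); %d parameters\n",
              cf$taskType, cf$nTasks, nParams(object)))
})

setMethod("show", "AttentionRecord", function(object) {
  m <- nrow(object@overall)
  cat(sprintf("AttentionRecord: %s (%d atoms, %d heads)\n",
              object@smiles, m, length(object@heads)))
})
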