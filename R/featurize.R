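# SMILES -> molecular graph featurization.
#
# Parsing, canonicalization, 2D/3D coordinate generation and ring/aromaticity
# perception are delegated to ChemmineR / ChemmineOB (OpenBabel). Feature
# encodings follow the Chemprop convention: one-hot categorical blocks with a
# reserved trailing "other" slot, so unusual values never raise.

.ATOM_BLOCKS <- list(
  atomicNumber = 101L,   # Z = 1..100 + other
  degree       = 7L,     # 0..5 + other
  formalCharge = 6L,     # -2..2 + other
  chirality    = 4L,     # none / CW / CCW / other
  nHydrogens   = 6L,     # 0..4 + other
  hybridization = 4L)    # sp / sp2 / sp3 / other
.ATOM_EXTRA <- c("aromatic", "massScaled")

.BOND_BLOCKS <- list(
  bondType = 5L,         # single / double / triple / aromatic + other
  stereo   = 6L)         # none / any / Z / E / cis / trans
.BOND_EXTRA <- c("nullBond", "conjugated", "inRing")

#' Width of the atom feature vector
#' @return Integer d_a.
#' @export
atomFeatureDim <- function() sum(unlist(.ATOM_BLOCKS)) + length(.ATOM_EXTRA)

#' Width of the bond feature vector
#' @return Integer d_b.
#' @export
bondFeatureDim <- function() sum(unlist(.BOND_BLOCKS)) + length(.BOND_EXTRA)

.onehot <- function(index, size) {
  # index is 1-based position or NA -> "other" (last slot)
  v <- numeric(size)
  if (is.na(index) || index < 1L || index >= size) v[size] <- 1 else v[index] <- 1
  v
}

.obTry <- function(from, to, text, options = NULL) {
  if (is.null(options)) options <- data.frame()
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, text, options = options)),
    error = function(e) "")
  if (is.null(out) || !nzchar(trimws(out))) NA_character_ else out
}

#' Canonicalize a SMILES string
#'
#' @param smiles A SMILES string.
#' @return The OpenBabel canonical SMILES.
#' @export
canonicalSmiles <- function(smiles) {
  out <- .obTry("SMI", "CAN", smiles)
  if (is.na(out)) stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  strsplit(trimws(out), "[ \t]")[[1]][1]
}

# Parse the V2000 molfile block of a single molecule into atoms/bonds/coords.
# Used directly only for the zero-bond degenerate case and 3D readback;
# multi-atom topology parsing goes through ChemmineR::read.SDFset.
.parseMolfile <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atoms <- lines[4 + seq_len(na)]
  coords <- cbind(as.numeric(substr(atoms, 1, 10)),
                  as.numeric(substr(atoms, 11, 20)),
                  as.numeric(substr(atoms, 21, 30)))
  symbols <- trimws(substr(atoms, 31, 33))
  bonds <- if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    cbind(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6)),
          as.integer(substr(bl, 7, 9)))
  } else matrix(integer(0), 0, 3)
  chg <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    k <- f[1]
    for (i in seq_len(k)) chg[f[2 * i]] <- f[2 * i + 1]
  }
  list(nAtoms = na, nBonds = nb, symbols = symbols, coords = coords,
       bonds = bonds, charges = chg)
}

.largestFragment <- function(smiles) {
  if (!grepl(".", smiles, fixed = TRUE)) return(smiles)
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  sizes <- vapply(frags, function(f) {
    g <- tryCatch(.parseMolfile(.obTry("SMI", "SDF", f)), error = function(e) NULL)
    if (is.null(g)) -1L else g$nAtoms
  }, integer(1))
  if (all(sizes < 0)) stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  warning("multi-fragment SMILES '", smiles, "': keeping largest fragment",
          call. = FALSE)
  frags[which.max(sizes)]
}

.hybridization <- function(orders, aromaticAtom) {
  # heuristic from kekulized bond orders around the atom
  if (aromaticAtom) return("sp2")
  if (any(orders >= 3) || sum(orders >= 2) >= 2) return("sp")
  if (any(orders >= 2)) return("sp2")
  "sp3"
}

.buildAtomFeatures <- function(g) {
  m <- g@nAtoms
  out <- matrix(0, m, atomFeatureDim())
  for (v in seq_len(m)) {
    z <- g@atomicNumbers[v]
    deg <- sum(g@bondOrigin == v)
    ch <- g@formalCharges[v]
    hyb <- match(g@hybridization[v], c("sp", "sp2", "sp3"))
    row <- c(
      .onehot(if (z >= 1L && z <= 100L) z else NA, 101L),
      .onehot(deg + 1L, 7L),                        # degree 0..5
      .onehot(if (ch >= -2L && ch <= 2L) ch + 3L else NA, 6L),
      .onehot(1L, 4L),                              # chirality: none
      .onehot(g@nHydrogens[v] + 1L, 6L),            # H count 0..4
      .onehot(hyb, 4L),
      as.numeric(g@aromatic[v]),
      if (z >= 1L && z <= 100L) .ATOMIC_WEIGHTS[z] / 100 else 0)
    out[v, ] <- row
  }
  rownames(out) <- g@elements
  out
}

.buildBondFeatures <- function(g) {
  nb <- length(g@bondOrigin)
  out <- matrix(0, nb, bondFeatureDim())
  if (nb == 0L) return(out)
  for (b in seq_len(nb)) {
    type <- if (g@bondAromatic[b]) 4L else match(g@bondOrders[b], c(1, 2, 3))
    out[b, ] <- c(
      0,                                            # null-bond flag
      .onehot(type, 5L),
      as.numeric(g@bondConjugated[b]),
      as.numeric(g@bondInRing[b]),
      .onehot(1L, 6L))                              # stereo: none
  }
  out
}

#' Parse a SMILES string into a featurized molecular graph
#'
#' Heavy atoms become graph nodes (implicit hydrogens are folded into the
#' attached-H-count feature) unless \code{keepHydrogens} is set. Every
#' undirected bond contributes two directed bonds in opposite directions;
#' the two directions share one bond feature row. Aromaticity and ring
#' membership are perceived by \code{ChemmineR::rings}. Multi-fragment
#' inputs are reduced to the largest fragment with a warning.
#'
#' @param smiles SMILES string (non-empty).
#' @param keepHydrogens If TRUE, explicit hydrogens are added and become
#'   graph nodes.
#' @return A \code{\linkS4class{MolGraph}} with topology, local atom/bond
#'   feature matrices, 2D depiction coordinates and the adjacency matrix
#'   filled in.
#' @examples
#' g <- parseSmiles("CCO")
#' nAtoms(g); nBonds(g)
#' @export
parseSmiles <- function(smiles, keepHydrogens = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  smiles <- .largestFragment(smiles)
  canon <- canonicalSmiles(smiles)
  optNames <- c("gen2d", if (keepHydrogens) "h")
  opts <- data.frame(names = optNames, args = rep("", length(optNames)))
  mtext <- .obTry("SMI", "SDF", canon, options = opts)
  if (is.na(mtext)) stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  mol <- .parseMolfile(mtext)
  m <- mol$nAtoms
  if (m < 1L) stop("unparseable SMILES: '", smiles, "'", call. = FALSE)

  sdf <- NULL
  if (m >= 2L && mol$nBonds >= 1L) {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(
      strsplit(mtext, "\n", fixed = TRUE)[[1]]))
    sdf <- sdfset[[1]]
  }

  # undirected bond table -> interleaved directed bonds (fwd, rev, fwd, ...)
  ub <- mol$bonds
  nb <- nrow(ub)
  bondOrigin <- as.integer(rbind(ub[, 1], ub[, 2]))
  bondDest <- as.integer(rbind(ub[, 2], ub[, 1]))
  bondReverse <- if (nb > 0) as.integer(rbind(seq_len(nb) * 2L,
                                              seq_len(nb) * 2L - 1L))
                 else integer(0)
  bondOrders <- as.numeric(rep(ub[, 3], each = 2L))

  # ring perception and aromaticity
  aromaticAtom <- logical(m)
  ringAtom <- logical(m)
  ringBond <- logical(2L * nb)
  aromaticBond <- logical(2L * nb)
  ringSizes <- integer(0)
  nAromaticRings <- 0L
  if (!is.null(sdf) && nb > 0L) {
    rr <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = 12, type = "all", arom = TRUE)),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    bondKey <- paste(pmin(bondOrigin, bondDest), pmax(bondOrigin, bondDest))
    for (ri in seq_along(rr$RINGS)) {
      ids <- as.integer(sub("^.*_", "", rr$RINGS[[ri]]))
      ringAtom[ids] <- TRUE
      ringSizes <- c(ringSizes, length(ids))
      arom <- isTRUE(rr$AROMATIC[[ri]])
      if (arom) {
        aromaticAtom[ids] <- TRUE
        nAromaticRings <- nAromaticRings + 1L
      }
      cyc <- cbind(ids, c(ids[-1], ids[1]))
      keys <- paste(pmin(cyc[, 1], cyc[, 2]), pmax(cyc[, 1], cyc[, 2]))
      hit <- bondKey %in% keys
      ringBond[hit] <- TRUE
      if (arom) aromaticBond[hit] <- TRUE
    }
  }

  z <- atomicNumber(mol$symbols)
  # implicit hydrogens from the standard valence model (kekulized orders)
  nH <- integer(m)
  hyb <- character(m)
  for (v in seq_len(m)) {
    idx <- which(bondOrigin == v)
    bosum <- sum(bondOrders[idx])
    dv <- .DEFAULT_VALENCE[mol$symbols[v]]
    if (is.na(dv)) dv <- 0
    nH[v] <- max(0L, as.integer(round(dv + mol$charges[v] - bosum)))
    if (mol$symbols[v] == "H") nH[v] <- 0L
    hyb[v] <- .hybridization(bondOrders[idx], aromaticAtom[v])
  }

  multip <- vapply(seq_len(m), function(v) {
    idx <- which(bondOrigin == v)
    aromaticAtom[v] || any(bondOrders[idx] >= 2)
  }, logical(1))
  conj <- aromaticBond | (multip[bondOrigin] & multip[bondDest])

  adjacency <- matrix(0, m, m)
  if (nb > 0) {
    adjacency[cbind(bondOrigin, bondDest)] <- 1
  }

  g <- new("MolGraph",
    smiles = canon, nAtoms = m, nBonds = nb,
    elements = mol$symbols, atomicNumbers = z,
    formalCharges = as.integer(mol$charges),
    aromatic = aromaticAtom, inRing = ringAtom,
    nHydrogens = nH, hybridization = hyb,
    bondOrigin = bondOrigin, bondDest = bondDest, bondReverse = bondReverse,
    bondOrders = bondOrders, bondAromatic = aromaticBond,
    bondConjugated = conj, bondInRing = ringBond,
    atomFeatures = matrix(0, m, atomFeatureDim()),
    bondFeatures = matrix(0, 2L * nb, bondFeatureDim()),
    coords2d = mol$coords[, 1:2, drop = FALSE],
    coords3d = matrix(0, 0, 3),
    adjacency = adjacency,
    distance = matrix(0, 0, 0), coulomb = matrix(0, 0, 0),
    distanceIsTopological = FALSE,
    descriptors = numeric(0),
    sdf = sdf)
  g@atomFeatures <- .buildAtomFeatures(g)
  g@bondFeatures <- .buildBondFeatures(g)
  attr(g@atomFeatures, "ringSizes") <- ringSizes
  attr(g@atomFeatures, "nAromaticRings") <- nAromaticRings
  methods::validObject(g)
  g
}

#' Atom feature matrix
#'
#' Rows are the per-atom feature vectors x_v: one-hot atomic number, degree,
#' formal charge, chirality tag, attached hydrogen count and hybridization
#' blocks (each with a reserved "other" slot), an aromaticity flag, and the
#' atomic mass scaled by 1/100.
#'
#' @param graph A \code{\linkS4class{MolGraph}}.
#' @return M x d_a numeric matrix.
#' @export
atomFeatures <- function(graph) graph@atomFeatures

#' Bond feature matrix
#'
#' Rows are the per-directed-bond feature vectors e_vw: a null-bond flag,
#' one-hot bond type (single/double/triple/aromatic), conjugation and
#' ring-membership flags, and a one-hot stereo block. Reverse-direction rows
#' are identical.
#'
#' @param graph A \code{\linkS4class{MolGraph}}.
#' @return 2N x d_b numeric matrix (0 x d_b for bond-less molecules).
#' @export
bondFeatures <- function(graph) graph@bondFeatures

#' Column index blocks of the one-hot atom/bond features
#'
#' @param what \code{"atom"} or \code{"bond"}.
#' @return Named list of integer column index vectors, one per one-hot block.
#' @export
featureBlocks <- function(what = c("atom", "bond")) {
  what <- match.arg(what)
  sizes <- if (what == "atom") .ATOM_BLOCKS else
    list(nullBond = NA, bondType = .BOND_BLOCKS$bondType,
         conjugated = NA, inRing = NA, stereo = .BOND_BLOCKS$stereo)
  out <- list()
  at <- 0L
  for (nm in names(sizes)) {
    k <- sizes[[nm]]
    if (is.na(k)) { at <- at + 1L; next }
    out[[nm]] <- at + seq_len(k)
    at <- at + k
  }
  out
}

#' Adjacency matrix of a molecular graph
#'
#' @param graph A \code{\linkS4class{MolGraph}}.
#' @return Symmetric M x M binary matrix with zero diagonal; entry (i,j) is
#'   1 when a chemical bond joins atoms i and j.
#' @export
adjacencyMatrix <- function(graph) {
  m <- graph@nAtoms
  a <- matrix(0, m, m)
  if (graph@nBonds > 0)
    a[cbind(graph@bondOrigin, graph@bondDest)] <- 1
  a
}

.covRadius <- function(symbols) {
  r <- .COVALENT_RADII[symbols]
  r[is.na(r)] <- .COVALENT_RADIUS_DEFAULT
  unname(r)
}

# equilibrium length of a directed bond from covalent radii and bond order
.bondLength <- function(g, b) {
  r <- .covRadius(g@elements)
  base <- r[g@bondOrigin[b]] + r[g@bondDest[b]]
  f <- ifelse(g@bondAromatic[b], 0.92,
              ifelse(g@bondOrders[b] >= 3, 0.78,
                     ifelse(g@bondOrders[b] >= 2, 0.87, 1)))
  base * f
}

#' Embed a 3D conformer
#'
#' Deterministic, seeded distance-geometry embedding: classical
#' multidimensional scaling of the topological distance matrix (scaled by
#' covalent-radius bond lengths) provides the initial coordinates, which
#' are then relaxed by gradient descent on a harmonic pseudo-force-field
#' with bond-length terms, 1-3 angle terms (ideal angles from the central
#' atom's hybridization) and a soft repulsion floor for distant pairs. The
#' same seed always yields the same coordinates.
#'
#' @param graph A \code{\linkS4class{MolGraph}}.
#' @param seed Integer seed for the symmetry-breaking jitter applied to the
#'   initial coordinates.
#' @return M x 3 coordinate matrix in Angstrom.
#' @export
embedConformer <- function(graph, seed = 0L) {
  g <- graph
  m <- g@nAtoms
  if (m == 1L) return(matrix(0, 1, 3))
  blen <- .bondLength(g, seq_along(g@bondOrigin))
  meanBond <- if (length(blen)) mean(blen) else 1.5
  td <- topologicalDistances(g)
  x <- tryCatch({
    # planar/linear topologies legitimately have < 3 positive eigenvalues
    fit <- suppressWarnings(stats::cmdscale(td * meanBond, k = min(3L, m - 1L)))
    cbind(fit, matrix(0, m, 3L - ncol(fit)))
  }, error = function(e) matrix(0, m, 3))
  set.seed(seed)
  x <- x + matrix(stats::rnorm(3 * m, 0, 0.05), m, 3)

  # harmonic targets: bonds at covalent length; 1-3 pairs at the law-of-
  # cosines distance for the central atom's ideal angle; others repelled
  # below a floor
  fwd <- seq_len(g@nBonds) * 2L - 1L
  bi <- g@bondOrigin[fwd]; bj <- g@bondDest[fwd]; bt <- blen[fwd]
  ang <- which(td == 2, arr.ind = TRUE)
  ang <- ang[ang[, 1] < ang[, 2], , drop = FALSE]
  at <- numeric(nrow(ang))
  if (nrow(ang)) {
    for (k in seq_len(nrow(ang))) {
      i <- ang[k, 1]; j <- ang[k, 2]
      ni <- g@bondDest[g@bondOrigin == i]
      nj <- g@bondDest[g@bondOrigin == j]
      ctr <- intersect(ni, nj)[1]
      theta <- switch(g@hybridization[ctr], sp = pi,
                      sp2 = 2 * pi / 3, 109.47 * pi / 180)
      a <- bt[match(TRUE, (bi == i & bj == ctr) | (bi == ctr & bj == i))]
      b <- bt[match(TRUE, (bi == j & bj == ctr) | (bi == ctr & bj == j))]
      if (is.na(a)) a <- meanBond
      if (is.na(b)) b <- meanBond
      at[k] <- sqrt(a ^ 2 + b ^ 2 - 2 * a * b * cos(theta))
    }
  }
  far <- which(td >= 3, arr.ind = TRUE)
  far <- far[far[, 1] < far[, 2], , drop = FALSE]
  floorD <- 2.4

  lr <- 0.05
  for (it in seq_len(400L)) {
    grad <- matrix(0, m, 3)
    pull <- function(i, j, target, w) {
      dvec <- x[i, ] - x[j, ]
      d <- sqrt(sum(dvec ^ 2)) + 1e-9
      f <- w * 2 * (d - target) / d
      grad[i, ] <<- grad[i, ] + f * dvec
      grad[j, ] <<- grad[j, ] - f * dvec
    }
    for (k in seq_along(bi)) pull(bi[k], bj[k], bt[k], 1)
    if (nrow(ang)) for (k in seq_len(nrow(ang)))
      pull(ang[k, 1], ang[k, 2], at[k], 0.4)
    if (nrow(far)) for (k in seq_len(nrow(far))) {
      i <- far[k, 1]; j <- far[k, 2]
      d <- sqrt(sum((x[i, ] - x[j, ]) ^ 2))
      if (d < floorD) pull(i, j, floorD, 0.2)
    }
    x <- x - lr * grad
  }
  x
}

#' Euclidean distance matrix from coordinates
#'
#' @param coords M x 3 finite coordinate matrix.
#' @return Symmetric M x M matrix of pairwise distances, zero diagonal.
#' @export
distanceMatrix <- function(coords) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  as.matrix(stats::dist(coords))
}

#' Topological distance matrix
#'
#' Shortest-path bond counts between atom pairs; the fallback "distance"
#' matrix when 3D embedding fails.
#'
#' @param graph A \code{\linkS4class{MolGraph}}.
#' @return Symmetric M x M matrix of bond counts.
#' @export
topologicalDistances <- function(graph) {
  m <- graph@nAtoms
  if (graph@nBonds == 0L) return(matrix(0, m, m))
  ig <- igraph::graph_from_edgelist(
    cbind(graph@bondOrigin, graph@bondDest), directed = FALSE)
  d <- igraph::distances(ig, v = seq_len(m), to = seq_len(m))
  d[!is.finite(d)] <- m  # disconnected pairs (largest fragment rule makes this rare)
  unname(d)
}

#' Coulomb matrix
#'
#' Diagonal entries are the atomic self-energy fit 0.5 Z^2.4; off-diagonal
#' entries are the inter-nuclear repulsion Z_i Z_j / |R_i - R_j|.
#'
#' @param charges Integer vector of nuclear charges Z (length M).
#' @param coords M x 3 coordinate matrix.
#' @return Symmetric M x M Coulomb matrix.
#' @examples
#' coulombMatrix(1L, matrix(0, 1, 3))  # [[0.5]]
#' @export
coulombMatrix <- function(charges, coords) {
  coords <- as.matrix(coords)
  m <- length(charges)
  stopifnot(nrow(coords) == m)
  d <- as.matrix(stats::dist(coords))
  if (m > 1 && any(d[upper.tri(d)] == 0))
    stop("coincident atoms: zero inter-atomic distance", call. = FALSE)
  cm <- outer(charges, charges)
  diag(d) <- 1
  cm <- cm / d
  diag(cm) <- 0.5 * charges ^ 2.4
  unname(cm)
}

#' Z-score normalize and scale an inter-atomic matrix
#'
#' Centers and scales by the mean and population standard deviation taken
#' over all M^2 entries of this molecule's matrix, then multiplies by the
#' inter-atomic feature scaler lambda. A constant matrix (zero standard
#' deviation) maps to the all-zero matrix.
#'
#' @param mat M x M finite numeric matrix.
#' @param lambda Nonnegative scalar scale.
#' @return M x M matrix lambda * (mat - mean) / sd.
#' @export
normalizeAndScale <- function(mat, lambda) {
  stopifnot(lambda >= 0, all(is.finite(mat)))
  mu <- mean(mat)
  sd0 <- sqrt(mean((mat - mu) ^ 2))
  if (sd0 == 0 || lambda == 0) return(matrix(0, nrow(mat), ncol(mat)))
  lambda * (mat - mu) / sd0
}

#' Normalized, lambda-scaled inter-atomic matrices
#'
#' @param graph A featurized \code{\linkS4class{MolGraph}} whose adjacency,
#'   distance and Coulomb matrices have been computed.
#' @param lambda Inter-atomic feature scaler.
#' @return List with elements \code{adjacency}, \code{distance},
#'   \code{coulomb}, each Z-score normalized per molecule and scaled.
#' @export
normalizedMatrices <- function(graph, lambda) {
  stopifnot(nrow(graph@distance) > 0, nrow(graph@coulomb) > 0)
  list(adjacency = normalizeAndScale(graph@adjacency, lambda),
       distance = normalizeAndScale(graph@distance, lambda),
       coulomb = normalizeAndScale(graph@coulomb, lambda))
}

#' Fully featurize a molecule
#'
#' Parses the SMILES and fills in the 3D conformer, distance and Coulomb
#' matrices and the molecular descriptor vector. When 3D embedding fails the
#' topological bond-count matrix stands in for the distance matrix (flagged
#' in \code{distanceIsTopological}) and the Coulomb matrix uses unit
#' distances scaled by bond counts.
#'
#' @param smiles SMILES string.
#' @param conformerSeed Seed forwarded to \code{\link{embedConformer}}.
#' @param withDescriptors Compute the 200-descriptor vector (slower).
#' @param distanceKind \code{"euclidean"} (3D, default) or
#'   \code{"topological"} to force graph distances.
#' @return A complete \code{\linkS4class{MolGraph}}.
#' @export
featurizeMolecule <- function(smiles, conformerSeed = 0L,
                              withDescriptors = TRUE,
                              distanceKind = c("euclidean", "topological")) {
  distanceKind <- match.arg(distanceKind)
  g <- parseSmiles(smiles)
  coords <- if (distanceKind == "euclidean")
    tryCatch({
      cc <- embedConformer(g, conformerSeed)
      coulombMatrix(g@atomicNumbers, cc)  # validates non-coincidence
      cc
    }, error = function(e) {
      warning("3D embedding failed for ", g@smiles, "; using topological ",
              "distances", call. = FALSE)
      NULL
    })
  else NULL
  if (is.null(coords)) {
    g@distance <- topologicalDistances(g)
    g@distanceIsTopological <- TRUE
    # unit-bond-length surrogate coordinates are unavailable; approximate the
    # repulsion term with graph distances (diagonal stays exact)
    d <- g@distance
    diag(d) <- 1
    cm <- outer(g@atomicNumbers, g@atomicNumbers) / pmax(d, 1)
    diag(cm) <- 0.5 * g@atomicNumbers ^ 2.4
    g@coulomb <- unname(cm)
  } else {
    g@coords3d <- coords
    g@distance <- distanceMatrix(coords)
    g@coulomb <- coulombMatrix(g@atomicNumbers, coords)
  }
  if (withDescriptors) g@descriptors <- molecularDescriptors(g)
  methods::validObject(g)
  g
}

#' Featurize a vector of SMILES
#'
#' @param smiles Character vector.
#' @param ... Passed to \code{\link{featurizeMolecule}}.
#' @return List of \code{\linkS4class{MolGraph}} objects.
#' @export
featurizeDataset <- function(smiles, ...) {
  lapply(smiles, featurizeMolecule, ...)
}
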