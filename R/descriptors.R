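# Molecule-level descriptor vector (fixed registry of 200 descriptors).
#
# The registry combines OpenBabel physicochemical properties, composition
# and topology counts, ring statistics, functional-group counts
# (ChemmineR::groups), Moreau-Broto-style topological autocorrelations and
# typed atom-pair counts. Length and ordering are identical for every
# molecule; failed or undefined entries are imputed to 0.

.DESC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
                    "Se", "Br", "I", "other")
.DESC_GROUPS <- c("RNH2", "R2NH", "R3N", "ROPO3", "ROH", "RCHO", "RCOR",
                  "RCOOH", "RCOOR", "ROR", "RCCH", "RCN")
.DESC_AC_PROPS <- c("Z", "degree", "aromatic", "hetero", "abscharge")
.DESC_PAIRS <- c("CC", "CN", "CO", "CS", "CHal", "NN", "NO", "HetHet")

#' Names of the 200 molecular descriptors
#'
#' @return Character vector of length 200, fixed order.
#' @export
descriptorNames <- function() {
  c(paste0("ob_", c("MW", "exactMass", "logP", "TPSA", "MR", "HBA1",
                    "HBA2", "HBD", "nF")),
    c("n_atoms", "n_bonds", "n_hydrogens", "n_heteroatoms",
      "heteroatom_fraction", "n_halogens", "total_formal_charge",
      "total_abs_charge", "n_aromatic_atoms", "aromatic_fraction",
      "n_ring_atoms", "ring_atom_fraction", "n_rings", "n_aromatic_rings",
      "graph_diameter", "graph_radius", "mean_topo_distance",
      "wiener_index", "zagreb_index", "n_branch_atoms", "n_terminal_atoms",
      "graph_density", "mean_degree", "max_degree"),
    c("n_single", "n_double", "n_triple", "n_aromatic_bonds",
      "n_ring_bonds", "n_conjugated_bonds", "n_rotatable_bonds"),
    paste0("count_", .DESC_ELEMENTS),
    paste0("n_degree", 0:5),
    paste0("n_", c("sp", "sp2", "sp3", "hyb_other")),
    paste0("n_hcount", 0:4),
    paste0("n_ring_size", 3:8),
    paste0("fg_", .DESC_GROUPS),
    paste0("n_", rep(c("C", "N", "O", "S"), each = 4), "_deg",
           rep(1:4, times = 4)),
    paste0("ats_", rep(.DESC_AC_PROPS, each = 10), "_d", rep(1:10, times = 5)),
    paste0("pair_", rep(.DESC_PAIRS, each = 5), "_d", rep(1:5, times = 8)),
    c("fraction_sp3_carbon", "n_sp3_carbons", "mw_per_atom",
      "bonds_per_atom", "n_CH3", "n_quaternary_C", "n_aromatic_hetero"))
}

.sdfSet <- function(g) {
  if (is.null(g@sdf)) return(NULL)
  methods::new("SDFset", SDF = list(g@sdf), ID = g@smiles)
}

.obPropBlock <- function(g) {
  out <- stats::setNames(numeric(9), paste0("ob_", c(
    "MW", "exactMass", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")))
  ss <- .sdfSet(g)
  if (is.null(ss)) {
    ss <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(g@smiles)),
                   error = function(e) NULL)
  }
  if (is.null(ss)) return(out)
  p <- tryCatch(suppressWarnings(ChemmineOB::propOB(ss)), error = function(e) NULL)
  if (!is.null(p) && nrow(p) >= 1) {
    for (nm in c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")) {
      v <- suppressWarnings(as.numeric(p[[nm]][1]))
      if (length(v) == 1 && is.finite(v)) out[paste0("ob_", nm)] <- v
    }
  }
  em <- tryCatch(suppressWarnings(ChemmineOB::exactMass_OB(ss)),
                 error = function(e) NULL)
  if (!is.null(em) && is.finite(em[1])) out["ob_exactMass"] <- em[1]
  out
}

.groupBlock <- function(g) {
  out <- stats::setNames(numeric(12), paste0("fg_", .DESC_GROUPS))
  ss <- .sdfSet(g)
  if (is.null(ss)) return(out)
  gr <- tryCatch(suppressWarnings(ChemmineR::groups(ss, type = "countMA")),
                 error = function(e) NULL)
  if (is.null(gr)) return(out)
  gr <- as.matrix(gr)
  for (nm in .DESC_GROUPS)
    if (nm %in% colnames(gr)) out[paste0("fg_", nm)] <- as.numeric(gr[1, nm])
  out
}

#' Compute the 200-descriptor vector of a molecule
#'
#' @param graph A parsed \code{\linkS4class{MolGraph}}.
#' @param stats Optional list with numeric vectors \code{mean} and \code{sd}
#'   (from \code{\link{fitDescriptorStats}} on the training split); when
#'   supplied, each descriptor is Z-scored with these statistics.
#' @return Named numeric vector of length 200; all entries finite
#'   (non-finite raw values are imputed to 0 before normalization).
#' @export
molecularDescriptors <- function(graph, stats = NULL) {
  g <- graph
  m <- g@nAtoms
  deg <- vapply(seq_len(m), function(v) sum(g@bondOrigin == v), numeric(1))
  hetero <- !(g@elements %in% c("C", "H"))
  halogen <- g@elements %in% c("F", "Cl", "Br", "I")
  td <- topologicalDistances(g)
  ut <- upper.tri(td)
  ecc <- if (m > 1) apply(td, 1, max) else 0
  ringSizes <- attr(g@atomFeatures, "ringSizes")
  if (is.null(ringSizes)) ringSizes <- integer(0)
  nAromRings <- attr(g@atomFeatures, "nAromaticRings")
  if (is.null(nAromRings)) nAromRings <- 0L
  fwd <- seq_len(g@nBonds) * 2L - 1L  # one direction per undirected bond
  rot <- if (g@nBonds > 0)
    sum(g@bondOrders[fwd] == 1 & !g@bondInRing[fwd] &
        deg[g@bondOrigin[fwd]] > 1 & deg[g@bondDest[fwd]] > 1)
  else 0

  global <- c(
    n_atoms = m, n_bonds = g@nBonds, n_hydrogens = sum(g@nHydrogens),
    n_heteroatoms = sum(hetero), heteroatom_fraction = sum(hetero) / m,
    n_halogens = sum(halogen),
    total_formal_charge = sum(g@formalCharges),
    total_abs_charge = sum(abs(g@formalCharges)),
    n_aromatic_atoms = sum(g@aromatic), aromatic_fraction = sum(g@aromatic) / m,
    n_ring_atoms = sum(g@inRing), ring_atom_fraction = sum(g@inRing) / m,
    n_rings = length(ringSizes), n_aromatic_rings = nAromRings,
    graph_diameter = max(ecc), graph_radius = min(ecc),
    mean_topo_distance = if (m > 1) mean(td[ut]) else 0,
    wiener_index = sum(td[ut]),
    zagreb_index = sum(deg ^ 2),
    n_branch_atoms = sum(deg >= 3), n_terminal_atoms = sum(deg == 1),
    graph_density = if (m > 1) 2 * g@nBonds / (m * (m - 1)) else 0,
    mean_degree = mean(deg), max_degree = max(deg))

  bondCounts <- c(
    n_single = sum(g@bondOrders[fwd] == 1 & !g@bondAromatic[fwd]),
    n_double = sum(g@bondOrders[fwd] == 2 & !g@bondAromatic[fwd]),
    n_triple = sum(g@bondOrders[fwd] == 3),
    n_aromatic_bonds = sum(g@bondAromatic[fwd]),
    n_ring_bonds = sum(g@bondInRing[fwd]),
    n_conjugated_bonds = sum(g@bondConjugated[fwd]),
    n_rotatable_bonds = rot)

  elemCounts <- vapply(.DESC_ELEMENTS, function(el) {
    if (el == "H") sum(g@nHydrogens)
    else if (el == "other") sum(!(g@elements %in% .DESC_ELEMENTS))
    else sum(g@elements == el)
  }, numeric(1))
  names(elemCounts) <- paste0("count_", .DESC_ELEMENTS)

  degCounts <- vapply(0:5, function(k) sum(deg == k), numeric(1))
  hybCounts <- vapply(c("sp", "sp2", "sp3"), function(h)
    sum(g@hybridization == h), numeric(1))
  hybCounts <- c(hybCounts, m - sum(hybCounts))
  hCounts <- vapply(0:4, function(k) sum(g@nHydrogens == k), numeric(1))
  ringSizeCounts <- vapply(3:8, function(k) sum(ringSizes == k), numeric(1))

  elDeg <- as.numeric(t(vapply(c("C", "N", "O", "S"), function(el)
    vapply(1:4, function(k) sum(g@elements == el & deg == k), numeric(1)),
    numeric(4))))

  acProps <- list(Z = as.numeric(g@atomicNumbers), degree = deg,
                  aromatic = as.numeric(g@aromatic),
                  hetero = as.numeric(hetero),
                  abscharge = abs(as.numeric(g@formalCharges)))
  ats <- numeric(0)
  for (p in acProps) {
    for (k in 1:10) {
      pairs <- which(td == k & ut, arr.ind = TRUE)
      ats <- c(ats, if (nrow(pairs)) sum(p[pairs[, 1]] * p[pairs[, 2]]) else 0)
    }
  }

  isC <- g@elements == "C"; isN <- g@elements == "N"
  isO <- g@elements == "O"; isS <- g@elements == "S"
  pairDefs <- list(CC = list(isC, isC), CN = list(isC, isN),
                   CO = list(isC, isO), CS = list(isC, isS),
                   CHal = list(isC, halogen), NN = list(isN, isN),
                   NO = list(isN, isO), HetHet = list(hetero, hetero))
  pairCounts <- numeric(0)
  for (pd in pairDefs) {
    for (k in 1:5) {
      pairs <- which(td == k & ut, arr.ind = TRUE)
      n <- if (nrow(pairs))
        sum((pd[[1]][pairs[, 1]] & pd[[2]][pairs[, 2]]) |
            (pd[[2]][pairs[, 1]] & pd[[1]][pairs[, 2]]))
      else 0
      pairCounts <- c(pairCounts, n)
    }
  }

  sp3C <- sum(isC & g@hybridization == "sp3")
  misc <- c(
    fraction_sp3_carbon = if (sum(isC)) sp3C / sum(isC) else 0,
    n_sp3_carbons = sp3C,
    mw_per_atom = 0,  # filled below from ob_MW
    bonds_per_atom = g@nBonds / m,
    n_CH3 = sum(isC & g@nHydrogens == 3),
    n_quaternary_C = sum(isC & deg == 4),
    n_aromatic_hetero = sum(hetero & g@aromatic))

  ob <- .obPropBlock(g)
  fg <- .groupBlock(g)
  misc["mw_per_atom"] <- ob["ob_MW"] / m

  out <- c(ob, global, bondCounts, elemCounts,
           stats::setNames(degCounts, paste0("n_degree", 0:5)),
           stats::setNames(hybCounts, paste0("n_", c("sp", "sp2", "sp3", "hyb_other"))),
           stats::setNames(hCounts, paste0("n_hcount", 0:4)),
           stats::setNames(ringSizeCounts, paste0("n_ring_size", 3:8)),
           fg,
           stats::setNames(elDeg, paste0("n_", rep(c("C", "N", "O", "S"), each = 4),
                                         "_deg", rep(1:4, times = 4))),
           stats::setNames(ats, paste0("ats_", rep(.DESC_AC_PROPS, each = 10),
                                       "_d", rep(1:10, times = 5))),
           stats::setNames(pairCounts, paste0("pair_", rep(.DESC_PAIRS, each = 5),
                                              "_d", rep(1:5, times = 8))),
           misc)
  out <- out[descriptorNames()]
  out[!is.finite(out)] <- 0
  if (!is.null(stats)) {
    sd <- stats$sd
    sd[!is.finite(sd) | sd <= 0] <- Inf  # constant descriptors map to 0
    out <- (out - stats$mean) / sd
    out[!is.finite(out)] <- 0
  }
  out
}

#' Fit descriptor normalization statistics on a training split
#'
#' @param descMatrix Numeric matrix with one row per molecule and 200
#'   descriptor columns (raw, unnormalized).
#' @return List with \code{mean} and \code{sd} vectors (sample sd).
#' @export
fitDescriptorStats <- function(descMatrix) {
  descMatrix <- as.matrix(descMatrix)
  list(mean = apply(descMatrix, 2, mean),
       sd = apply(descMatrix, 2, stats::sd))
}
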