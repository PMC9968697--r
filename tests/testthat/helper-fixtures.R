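# Shared fixtures, built once per test run (featurization dominates the
# suite's runtime, so graphs are memoized in this cache environment).

.fixtureCache <- new.env(parent = emptyenv())

fixtureCorpus <- function(n = 32L, seed = 7L) {
  key <- paste0("corpus_", n, "_", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- makeCorpus(n, seed = seed)
  .fixtureCache[[key]]
}

fixtureGraphs <- function(n = 32L, seed = 7L) {
  key <- paste0("graphs_", n, "_", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- featurizeDataset(fixtureCorpus(n, seed))
  .fixtureCache[[key]]
}

fixtureModel <- function(...) {
  args <- list(...)
  key <- paste0("model_", paste(deparse(args), collapse = ""))
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- do.call(abtModel, args)
  .fixtureCache[[key]]
}

# Consistently relabel the atoms of a featurized graph by a permutation:
# perm[old] = new index. Directed bond order is preserved; only endpoint
# indices and all per-atom slots move.
permuteGraph <- function(g, perm) {
  inv <- order(perm)  # inv[new] = old
  adj <- g@adjacency[inv, inv, drop = FALSE]
  dst <- if (nrow(g@distance)) g@distance[inv, inv, drop = FALSE] else g@distance
  cou <- if (nrow(g@coulomb)) g@coulomb[inv, inv, drop = FALSE] else g@coulomb
  methods::new("MolGraph",
    smiles = g@smiles, nAtoms = g@nAtoms, nBonds = g@nBonds,
    elements = g@elements[inv], atomicNumbers = g@atomicNumbers[inv],
    formalCharges = g@formalCharges[inv], aromatic = g@aromatic[inv],
    inRing = g@inRing[inv], nHydrogens = g@nHydrogens[inv],
    hybridization = g@hybridization[inv],
    bondOrigin = as.integer(perm[g@bondOrigin]),
    bondDest = as.integer(perm[g@bondDest]),
    bondReverse = g@bondReverse, bondOrders = g@bondOrders,
    bondAromatic = g@bondAromatic, bondConjugated = g@bondConjugated,
    bondInRing = g@bondInRing,
    atomFeatures = g@atomFeatures[inv, , drop = FALSE],
    bondFeatures = g@bondFeatures,
    coords2d = g@coords2d[inv, , drop = FALSE],
    coords3d = if (nrow(g@coords3d)) g@coords3d[inv, , drop = FALSE]
               else g@coords3d,
    adjacency = adj, distance = dst, coulomb = cou,
    distanceIsTopological = g@distanceIsTopological,
    descriptors = g@descriptors, sdf = g@sdf)
}
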