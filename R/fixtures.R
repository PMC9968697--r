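# Deterministic small-molecule fixture corpora with synthetic targets of
# known structure, so the full pipeline is testable with no download.
# Molecules are enumerated from valence-safe templates (1-12 heavy atoms,
# C/N/O/S/halogens) rather than randomly grown graphs.

.fixtureTemplates <- function() {
  chains <- vapply(1:10, function(k) strrep("C", k), character(1))
  branched <- c("CC(C)C", "CC(C)CC", "CC(C)(C)C", "CCC(C)CC", "CC(C)CCC",
                "CC(C)C(C)C", "CCC(C)(C)CC", "CC(C)(C)CC", "CC(CC)CC",
                "CC(C)CC(C)C")
  tails <- c("O", "N", "Cl", "F", "Br", "S", "C#N", "C(=O)O", "C(=O)C",
             "OC", "NC", "C=C", "SC", "C(=O)N")
  funChains <- as.character(outer(chains[1:8], tails, paste0))
  aromatics <- c("c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
                 "Clc1ccccc1", "Fc1ccccc1", "Brc1ccccc1", "C=Cc1ccccc1",
                 "OC(=O)c1ccccc1", "COc1ccccc1", "N#Cc1ccccc1",
                 "CCc1ccccc1", "CC(C)c1ccccc1", "OCc1ccccc1",
                 "NCc1ccccc1", "CC(=O)c1ccccc1",
                 "c1ccncc1", "Cc1ccncc1", "c1cc[nH]c1", "c1ccoc1",
                 "c1ccsc1", "Cc1ccco1", "Cc1cccs1", "c1ccc2ccccc2c1",
                 "Sc1ccccc1", "CSc1ccccc1")
  disub <- as.character(outer(
    c("C", "O", "N", "F", "Cl", "Br", "OC", "C#N"),
    c("Cc1ccccc1%s", "Cc1cccc(%s)c1", "Cc1ccc(%s)cc1"),
    function(s, tmpl) sprintf(tmpl, s)))
  rings <- c("C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCCCCC1",
             "C1CCOC1", "C1CCNC1", "C1CCSC1", "C1CCOCC1", "C1CCNCC1",
             "C1COCCO1", "C1COCCN1", "OC1CCCCC1", "O=C1CCCCC1",
             "NC1CCCCC1", "CC1CCCCC1", "CC1CCCC1", "ClC1CCCCC1")
  carbonyl <- c("CC(=O)OC", "CC(=O)OCC", "CCC(=O)OC", "CC(=O)NC",
                "CC(=O)N(C)C", "CC(=O)C", "CCC(=O)CC", "CC(=O)CC",
                "CC(=O)CCC", "O=CC", "O=CCC", "O=CCCC", "CC(=O)CC(=O)C")
  etheramine <- c("COC", "CCOC", "CCOCC", "CCCOC", "CN", "CNC", "CN(C)C",
                  "CCN", "CCNCC", "CCCN", "CCN(C)C", "COCCOC", "OCCO",
                  "OCCCO", "NCCN", "OCCN", "CC(O)C", "CC(O)CC", "CC(N)C")
  halides <- c("ClCCCl", "FC(F)F", "ClC(Cl)Cl", "BrCCBr", "CC(Cl)C",
               "FCC(F)F", "ClCCCCl", "CC(F)(F)F", "ClCCO", "FCCO")
  sulfur <- c("CS", "CSC", "CCS", "CCSC", "CSSC", "CCSCC", "SCCS",
              "CSCC(=O)O")
  alkenes <- c("C=C", "CC=C", "CC=CC", "C=CC=C", "CC=CCC", "C#C", "CC#C",
               "CC#CC", "C=CCO", "C=CCN", "C=CC(=O)O")
  unique(c("C", chains, branched, funChains, aromatics, disub, rings,
           carbonyl, etheramine, halides, sulfur, alkenes))
}

#' Generate a deterministic fixture corpus
#'
#' Draws n unique canonical SMILES from the enumerated template pool.
#' The first four slots always cover the structural edge cases: a zero-bond
#' molecule (methane), a linear chain, a branched alkane and an aromatic
#' ring; the remainder is a seeded sample of the pool.
#'
#' @param n Corpus size (>= 1; at most the pool size, about 250).
#' @param seed Integer seed; same seed, same corpus.
#' @return Character vector of n unique canonical SMILES with
#'   attribute \code{seed}.
#' @export
makeCorpus <- function(n, seed = 0L) {
  stopifnot(n >= 1)
  pool <- vapply(.fixtureTemplates(), canonicalSmiles, character(1),
                 USE.NAMES = FALSE)
  pool <- unique(pool)
  core <- vapply(c("C", "CCCCCC", "CC(C)C", "c1ccccc1"), canonicalSmiles,
                 character(1), USE.NAMES = FALSE)
  rest <- setdiff(pool, core)
  if (n > length(core) + length(rest))
    stop("corpus pool has only ", length(pool), " molecules", call. = FALSE)
  set.seed(seed)
  rest <- rest[sample.int(length(rest))]
  out <- if (n <= length(core)) core[seq_len(n)]
         else c(core, rest[seq_len(n - length(core))])
  attr(out, "seed") <- as.integer(seed)
  out
}

.ringCount <- function(g) {
  rs <- attr(g@atomFeatures, "ringSizes")
  if (is.null(rs)) 0 else length(rs)
}

#' Synthetic regression targets with known structure
#'
#' target = rule(molecule) + Gaussian noise. Registered rules:
#' \code{heavy_atom_count}, \code{heteroatom_fraction} (non-carbon fraction
#' of heavy atoms), \code{ring_count}.
#'
#' @param corpus Character vector of SMILES (e.g. \code{\link{makeCorpus}}).
#' @param rule Rule name.
#' @param noiseSd Gaussian noise standard deviation (0 = exact rule values).
#' @param seed Integer seed for the noise.
#' @return Numeric vector of targets.
#' @export
regressionTargets <- function(corpus,
                              rule = c("heavy_atom_count",
                                       "heteroatom_fraction", "ring_count"),
                              noiseSd = 0, seed = 0L) {
  rule <- match.arg(rule)
  vals <- vapply(corpus, function(s) {
    g <- parseSmiles(s)
    switch(rule,
      heavy_atom_count = as.numeric(g@nAtoms),
      heteroatom_fraction = mean(g@elements != "C"),
      ring_count = as.numeric(.ringCount(g)))
  }, numeric(1), USE.NAMES = FALSE)
  if (noiseSd > 0) {
    set.seed(seed)
    vals <- vals + stats::rnorm(length(vals), 0, noiseSd)
  }
  vals
}

#' Substructure-defined binary targets
#'
#' Labels a molecule 1 when the SMARTS pattern matches (OpenBabel
#' substructure search), with optional seeded label flips to emulate label
#' noise.
#'
#' @param corpus Character vector of SMILES.
#' @param smarts SMARTS pattern (default hydroxyl, \code{"[OX2H]"}).
#' @param flipProb Probability of flipping each label.
#' @param seed Integer seed for the flips.
#' @return Integer 0/1 vector.
#' @export
classificationTargets <- function(corpus, smarts = "[OX2H]", flipProb = 0,
                                  seed = 0L) {
  labels <- as.integer(matchesSmarts(corpus, smarts))
  if (flipProb > 0) {
    set.seed(seed)
    flip <- stats::runif(length(labels)) < flipProb
    labels[flip] <- 1L - labels[flip]
  }
  labels
}

#' SMARTS substructure matching
#'
#' Matches each SMILES against a SMARTS pattern via the OpenBabel
#' command-line filter.
#'
#' @param smiles Character vector of SMILES.
#' @param smarts SMARTS pattern.
#' @return Logical vector.
#' @export
matchesSmarts <- function(smiles, smarts) {
  inFile <- tempfile(fileext = ".smi")
  on.exit(unlink(inFile), add = TRUE)
  ids <- paste0("mol", seq_along(smiles))
  writeLines(paste(smiles, ids), inFile)
  out <- suppressWarnings(system2("obabel",
    c("-ismi", inFile, "-osmi", "-s", shQuote(smarts)),
    stdout = TRUE, stderr = FALSE))
  hit <- vapply(strsplit(out, "[ \t]+"), function(f)
    if (length(f) >= 2) f[2] else NA_character_, character(1))
  ids %in% hit
}
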