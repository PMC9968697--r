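# Dataset splitting: Z-score binarization, random 80:10:10 split,
# Bemis-Murcko scaffold split, and k-fold cross-validation folds.

#' Binarize growth-inhibition Z-scores
#'
#' A molecule is active (1) when its Z-score is strictly below the
#' threshold (default -4), inactive (0) otherwise; missing values stay
#' missing.
#'
#' @param z Numeric vector of Z-scores.
#' @param threshold Strict cutoff (default -4).
#' @return Integer 0/1 vector with NAs preserved.
#' @examples
#' binarizeZscore(c(-5, -4, 0))  # 1 0 0
#' @export
binarizeZscore <- function(z, threshold = -4) {
  out <- as.integer(z < threshold)
  out[is.na(z)] <- NA_integer_
  out
}

.splitSizes <- function(n, ratios) {
  nTrain <- floor(ratios[1] * n)
  nVal <- floor(ratios[2] * n)
  c(nTrain, nVal, n - nTrain - nVal)
}

#' Random train/validation/test split
#'
#' @param n Number of molecules (>= 3).
#' @param ratios Split ratios, default \code{c(0.8, 0.1, 0.1)}; sizes are
#'   floor(0.8 n), floor(0.1 n) and the remainder.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with integer index vectors \code{train},
#'   \code{validation}, \code{test}, plus \code{ratios}, \code{kind},
#'   \code{seed}.
#' @export
randomSplit <- function(n, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  stopifnot(n >= 3, length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  sz <- .splitSizes(n, ratios)
  set.seed(seed)
  idx <- sample.int(n)
  list(train = sort(idx[seq_len(sz[1])]),
       validation = sort(idx[sz[1] + seq_len(sz[2])]),
       test = sort(idx[sz[1] + sz[2] + seq_len(sz[3])]),
       ratios = ratios, kind = "random", seed = as.integer(seed))
}

#' Bemis-Murcko scaffold of a molecule
#'
#' The molecular framework: ring systems plus the linkers connecting them,
#' obtained by iteratively pruning terminal (degree-1) atoms. Acyclic
#' molecules have an empty scaffold and all share the group \code{""}.
#'
#' @param x A SMILES string or \code{\linkS4class{MolGraph}}.
#' @return Canonical SMILES of the scaffold, or \code{""} for acyclic
#'   molecules.
#' @export
murckoScaffold <- function(x) {
  g <- if (is.character(x)) parseSmiles(x) else x
  keep <- rep(TRUE, g@nAtoms)
  deg <- vapply(seq_len(g@nAtoms), function(v)
    sum(g@bondOrigin == v), numeric(1))
  repeat {
    leaf <- which(keep & deg <= 1)
    if (length(leaf) == 0) break
    keep[leaf] <- FALSE
    for (v in leaf) {
      nb <- g@bondDest[g@bondOrigin == v]
      deg[nb] <- deg[nb] - 1
    }
    deg[!keep] <- 0
  }
  if (!any(keep)) return("")
  if (all(keep)) return(g@smiles)
  sub <- ChemmineR::atomsubset(g@sdf, atomrows = which(keep))
  ss <- methods::new("SDFset", SDF = list(sub), ID = "scaffold")
  smi <- tryCatch(suppressWarnings(as.character(ChemmineR::sdf2smiles(ss))),
                  error = function(e) NA_character_)
  if (is.na(smi) || !nzchar(smi)) return(g@smiles)
  canonicalSmiles(smi)
}

#' Scaffold-based train/validation/test split
#'
#' Groups molecules by Bemis-Murcko scaffold and fills the training set
#' with the largest groups first (ties broken by scaffold string), then the
#' validation set, then the test set. No scaffold group ever straddles two
#' subsets, so the test set probes generalization to unseen chemotypes.
#' Unparseable molecules are excluded with a warning.
#'
#' @param molecules Character vector of SMILES or list of
#'   \code{\linkS4class{MolGraph}}.
#' @param ratios Split ratios, default \code{c(0.8, 0.1, 0.1)}.
#' @return List as in \code{\link{randomSplit}} with \code{kind =
#'   "scaffold"} and a \code{scaffolds} character vector (NA for excluded
#'   molecules).
#' @export
scaffoldSplit <- function(molecules, ratios = c(0.8, 0.1, 0.1)) {
  n <- length(molecules)
  scaf <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    scaf[i] <- tryCatch(murckoScaffold(molecules[[i]]), error = function(e) {
      warning("excluding unparseable molecule at index ", i, call. = FALSE)
      NA_character_
    })
  }
  usable <- which(!is.na(scaf))
  groups <- split(usable, scaf[usable])
  ord <- order(-vapply(groups, length, integer(1)), names(groups))
  groups <- groups[ord]
  sz <- .splitSizes(length(usable), ratios)
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (grp in groups) {
    if (length(train) + length(grp) <= sz[1]) train <- c(train, grp)
    else if (length(val) + length(grp) <= sz[2]) val <- c(val, grp)
    else test <- c(test, grp)
  }
  list(train = sort(train), validation = sort(val), test = sort(test),
       ratios = ratios, kind = "scaffold", seed = NA_integer_,
       scaffolds = scaf)
}

#' k-fold cross-validation folds
#'
#' Shuffles indices once (seeded) and partitions them into k test folds;
#' fold i uses fold i as test, the next fold as validation and the rest as
#' training. Every index appears in exactly one test fold.
#'
#' @param n Number of molecules (>= k).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of k split lists (\code{train}/\code{validation}/
#'   \code{test}).
#' @export
kfoldCV <- function(n, k = 5L, seed = 0L) {
  stopifnot(n >= k)
  set.seed(seed)
  idx <- sample.int(n)
  fold <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    list(train = sort(idx[!(fold %in% c(i, j))]),
         validation = sort(idx[fold == j]),
         test = sort(idx[fold == i]),
         ratios = NA, kind = "kfold", seed = as.integer(seed), fold = i)
  })
}
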