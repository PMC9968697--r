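#' Number of heavy atoms
#' @param x A \code{\linkS4class{MolGraph}}.
#' @return Integer count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of undirected bonds
#' @param x A \code{\linkS4class{MolGraph}}.
#' @return Integer count.
#' @export
setGeneric("nBonds", function(x) standardGeneric("nBonds"))

#' Number of learnable parameters
#' @param x An \code{\linkS4class{ABTModel}}.
#' @return Integer total count of scalar weights.
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))

#' Directed bond list
#' @param x A \code{\linkS4class{MolGraph}}.
#' @return Integer 2N x 2 matrix of (origin, destination) atom indices.
#' @export
setGeneric("directedBonds", function(x) standardGeneric("directedBonds"))

#' @rdname nAtoms
setMethod("nAtoms", "MolGraph", function(x) x@nAtoms)

#' @rdname nBonds
setMethod("nBonds", "MolGraph", function(x) x@nBonds)

#' @rdname directedBonds
setMethod("directedBonds", "MolGraph", function(x)
  cbind(origin = x@bondOrigin, destination = x@bondDest))

#' @rdname nParams
setMethod("nParams", "ABTModel", function(x) {
  cnt <- function(p) if (is.list(p)) sum(vapply(p, cnt, numeric(1))) else length(p)
  as.integer(cnt(x@params))
})
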