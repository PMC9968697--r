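# Attention capture and similarity-map visualization of per-atom attention
# contributions on 2D depictions.

#' Capture atom-attention maps for one molecule
#'
#' Runs a single forward pass with capture hooks and collects the six
#' per-head row-stochastic M x M attention maps, their head-pair averages
#' (heads 1-2: adjacency bias; 3-4: distance; 5-6: Coulomb) and the overall
#' mean. Capture is passive: the forward computation is unchanged.
#'
#' @param model A trained \code{\linkS4class{ABTModel}} with atom
#'   attention.
#' @param molecule SMILES string or featurized
#'   \code{\linkS4class{MolGraph}}.
#' @return An \code{\linkS4class{AttentionRecord}}.
#' @export
captureAttention <- function(model, molecule) {
  cf <- model@config
  if (!cf$atomAttention)
    stop("no attention to capture: model was built without atom attention",
         call. = FALSE)
  g <- if (is.character(molecule)) featurizeMolecule(molecule) else molecule
  cap <- new.env(parent = emptyenv())
  cap$maps <- vector("list", cf$nHeads)
  tape <- ag_tape()
  p <- lapply_params_const(model@params, tape)
  prep <- .prepareMolecule(g, model)
  bondCap <- new.env(parent = emptyenv())
  bondCap$additiveWeights <- list()
  # the multihead capture collects the atom maps; bond-attention weights go
  # into the same env but only the atom maps are kept on the record
  capAll <- new.env(parent = emptyenv())
  capAll$maps <- vector("list", cf$nHeads)
  capAll$additiveWeights <- list()
  ag_forward_molecule(prep, p, cf, tape, training = FALSE, capture = capAll)
  maps <- capAll$maps
  if (any(vapply(maps, is.null, logical(1))))
    stop("no attention to capture", call. = FALSE)
  pairOf <- function(i, j) (maps[[i]] + maps[[j]]) / 2
  overall <- Reduce(`+`, maps) / length(maps)
  methods::new("AttentionRecord",
    smiles = g@smiles,
    heads = maps,
    pairAverages = list(adjacency = pairOf(1, 2),
                        distance = pairOf(3, 4),
                        coulomb = pairOf(5, 6)),
    overall = overall)
}

#' Per-atom attention contributions
#'
#' Collapses an M x M attention map to a centered per-atom vector: the
#' contribution of atom j is the mean attention it receives over query rows
#' minus 1/M, so uniform attention yields all-zero contributions. The
#' signed values drive the green (positive) / red (negative) coloring of
#' the similarity map. A row-mean alternative (attention paid rather than
#' received) is available.
#'
#' @param record An \code{\linkS4class{AttentionRecord}}.
#' @param group \code{"overall"}, \code{"adjacency"}, \code{"distance"} or
#'   \code{"coulomb"}.
#' @param mode \code{"column"} (attention received, default) or
#'   \code{"row"}.
#' @return Numeric length-M vector summing to 0.
#' @export
atomContributions <- function(record,
                              group = c("overall", "adjacency", "distance",
                                        "coulomb"),
                              mode = c("column", "row")) {
  group <- match.arg(group)
  mode <- match.arg(mode)
  map <- if (group == "overall") record@overall else
    record@pairAverages[[group]]
  m <- nrow(map)
  v <- if (mode == "column") colMeans(map) else rowMeans(map)
  unname(v - 1 / m)
}

#' Render a similarity map of atom contributions
#'
#' Draws the 2D depiction of the molecule with a diverging Gaussian-weight
#' overlay: green for positive contributions, red for negative, intensity
#' monotone in the absolute value, symmetric about zero. All-zero
#' contributions produce an uncolored depiction. Output is deterministic
#' for fixed input.
#'
#' @param molecule SMILES string or \code{\linkS4class{MolGraph}}.
#' @param contributions Numeric vector, one value per heavy atom.
#' @param outPath Output PNG path.
#' @param width,height Image size in pixels.
#' @param gridN Overlay raster resolution.
#' @return Invisibly, \code{outPath}.
#' @export
renderSimilarityMap <- function(molecule, contributions, outPath,
                                width = 600, height = 600, gridN = 160) {
  g <- if (is.character(molecule)) parseSmiles(molecule) else molecule
  if (length(contributions) != g@nAtoms)
    stop("contributions length must equal the atom count", call. = FALSE)
  xy <- g@coords2d
  if (g@nAtoms == 1L && all(xy == 0)) xy <- matrix(c(0, 0), 1)
  span <- max(apply(xy, 2, function(c) diff(range(c))), 1)
  pad <- 0.2 * span + 0.5
  xr <- range(xy[, 1]) + c(-pad, pad)
  yr <- range(xy[, 2]) + c(-pad, pad)
  # Gaussian width tied to the typical bond length of the depiction
  sigma <- if (g@nBonds > 0) {
    bl <- sqrt(rowSums((xy[g@bondOrigin, , drop = FALSE] -
                        xy[g@bondDest, , drop = FALSE]) ^ 2))
    0.45 * stats::median(bl)
  } else 0.45
  gx <- seq(xr[1], xr[2], length.out = gridN)
  gy <- seq(yr[1], yr[2], length.out = gridN)
  field <- matrix(0, gridN, gridN)
  for (v in seq_len(g@nAtoms)) {
    if (contributions[v] == 0) next
    dx2 <- (gx - xy[v, 1]) ^ 2
    dy2 <- (gy - xy[v, 2]) ^ 2
    field <- field + contributions[v] *
      exp(-(outer(dx2, dy2, "+")) / (2 * sigma ^ 2))
  }
  dir.create(dirname(outPath), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    grDevices::png(outPath, width = width, height = height, type = "cairo")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot open output path: ", outPath, call. = FALSE)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(NA, xlim = xr, ylim = yr, asp = 1, axes = FALSE,
                 xlab = "", ylab = "")
  zmax <- max(abs(field))
  if (zmax > 0) {
    pal <- grDevices::colorRampPalette(
      c("#B40426", "#FFFFFF", "#1B7837"))(255)
    graphics::image(gx, gy, field, zlim = c(-zmax, zmax), col = pal,
                    add = TRUE, useRaster = TRUE)
  }
  if (g@nBonds > 0) {
    fwd <- seq_len(g@nBonds) * 2L - 1L
    graphics::segments(xy[g@bondOrigin[fwd], 1], xy[g@bondOrigin[fwd], 2],
                       xy[g@bondDest[fwd], 1], xy[g@bondDest[fwd], 2],
                       lwd = 2)
  }
  lab <- ifelse(g@elements == "C" &
                  vapply(seq_len(g@nAtoms), function(v)
                    sum(g@bondOrigin == v) > 0, logical(1)),
                "", g@elements)
  show <- nzchar(lab)
  if (any(show))
    graphics::text(xy[show, 1], xy[show, 2], lab[show], cex = 1.4,
                   font = 2)
  invisible(outPath)
}

#' Contribution table for a molecule
#'
#' @param record An \code{\linkS4class{AttentionRecord}}.
#' @param graph The corresponding \code{\linkS4class{MolGraph}}.
#' @param group Passed to \code{\link{atomContributions}}.
#' @return data.frame with atom index, element and contribution.
#' @export
contributionTable <- function(record, graph, group = "overall") {
  data.frame(atom = seq_len(graph@nAtoms),
             element = graph@elements,
             contribution = atomContributions(record, group))
}
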