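# Dataset CSV input/output: first column `smiles`, remaining columns
# numeric targets; empty cells are missing targets.

#' Read a molecular property dataset
#'
#' @param path CSV path; first column must be named \code{smiles}, the
#'   remaining columns are numeric targets (empty cell = missing).
#' @return List with \code{smiles} (character) and \code{targets}
#'   (numeric matrix with task names).
#' @export
readDataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(tolower(names(df)[1]), "smiles"))
    stop("first column must be 'smiles'", call. = FALSE)
  targets <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(targets) <- "double"
  list(smiles = as.character(df[[1]]), targets = targets)
}

#' Write a dataset CSV
#'
#' @param path Output path.
#' @param smiles Character vector.
#' @param targets Numeric vector or matrix (columns named per task).
#' @return Invisibly, the path.
#' @export
writeDataset <- function(path, smiles, targets) {
  targets <- as.matrix(targets)
  if (is.null(colnames(targets)))
    colnames(targets) <- paste0("task", seq_len(ncol(targets)))
  df <- data.frame(smiles = smiles, targets, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
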