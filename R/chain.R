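# Chain objects: ordered C-alpha coordinates of one protein conformation.

#' Construct a chain of C-alpha coordinates
#'
#' A `chain` holds one coarse-grained conformation: one C-alpha position per
#' residue, indexed consecutively from 1. Original PDB residue numbers, if
#' any, are kept as display metadata only; every matrix built from a chain
#' uses the internal 1..n index.
#'
#' @param coords numeric n x 3 matrix of C-alpha coordinates in Angstrom,
#'   one row per residue in sequence order.
#' @param label free-text label (PDB id + chain id, or fixture name).
#' @param pdb_resno optional integer vector of original PDB residue numbers
#'   (metadata only).
#' @param resid optional character vector of residue names (metadata only).
#' @return an object of class `chain`.
#' @export
chain <- function(coords, label = "chain", pdb_resno = NULL, resid = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix")
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 3L)
    stop("chain too short: need at least 3 residues, got ", n)
  if (any(!is.finite(coords)))
    stop("coords contain non-finite values")
  if (!is.null(pdb_resno) && length(pdb_resno) != n)
    stop("pdb_resno must have one entry per residue")
  if (!is.null(resid) && length(resid) != n)
    stop("resid must have one entry per residue")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(coords = coords, n = n, label = as.character(label)[1],
         pdb_resno = pdb_resno, resid = resid),
    class = "chain")
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("<chain> %s: %d residues, Rg = %.2f A\n",
              x$label, x$n, radius_of_gyration(x)))
  invisible(x)
}

#' Number of residues in a chain
#' @param chain a `chain` object.
#' @return integer residue count.
#' @export
n_residues <- function(chain) {
  stopifnot(inherits(chain, "chain"))
  chain$n
}

#' Residue-index mapping table
#'
#' Maps internal consecutive indices 1..n to the residue numbering of the
#' source PDB file, so published residue labels (e.g. ALA16) can be
#' reconciled with matrix rows.
#'
#' @param chain a `chain` object.
#' @return data.frame with columns `index`, `pdb_resno`, `resid`.
#' @export
residue_table <- function(chain) {
  stopifnot(inherits(chain, "chain"))
  data.frame(
    index = seq_len(chain$n),
    pdb_resno = if (is.null(chain$pdb_resno)) seq_len(chain$n) else chain$pdb_resno,
    resid = if (is.null(chain$resid)) rep("UNK", chain$n) else chain$resid)
}

#' Root-mean-square deviation between two conformations
#'
#' Plain coordinate RMSD without superposition: the folding model works in
#' deviation variables with a fixed frame, so no fitting is wanted.
#'
#' @param a,b `chain` objects or n x 3 coordinate matrices of equal size.
#' @return RMSD in Angstrom.
#' @export
chain_rmsd <- function(a, b) {
  ca <- if (inherits(a, "chain")) a$coords else as.matrix(a)
  cb <- if (inherits(b, "chain")) b$coords else as.matrix(b)
  if (!all(dim(ca) == dim(cb)))
    stop("conformations have different sizes")
  sqrt(mean(rowSums((ca - cb)^2)))
}
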