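# PDB input/output for C-alpha chains (via bio3d).

#' Read a C-alpha chain from a PDB file
#'
#' Extracts one C-alpha coordinate per residue, in sequence order, from one
#' chain of one model. Alternate locations are resolved by highest occupancy
#' and then first-listed order. Residues are re-indexed 1..n internally; the
#' original PDB numbering is kept as metadata (see [residue_table()]).
#' Non-standard residues are accepted as long as they carry a CA atom — the
#' coarse-grained model needs nothing else.
#'
#' @param pdb_path path to a PDB file.
#' @param chain_id chain identifier; `NULL` takes the first chain in the file.
#' @param model_index 1-based model number for multi-model files (default the
#'   first model: the method needs a single native conformation).
#' @return a [chain()] object.
#' @export
read_ca_chain <- function(pdb_path, chain_id = NULL, model_index = 1L) {
  pdb <- bio3d::read.pdb(pdb_path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  atoms <- pdb$atom
  nmodel <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > nmodel)
    stop(sprintf("model %d not found (file has %d model(s))", model_index, nmodel))
  # coordinates of the requested model, one row per atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)

  chains_present <- unique(atoms$chain)
  if (is.null(chain_id)) {
    chain_id <- chains_present[1]
  } else if (!chain_id %in% chains_present) {
    stop(sprintf("chain not found: '%s' (file has: %s)", chain_id,
                 paste(chains_present, collapse = ", ")))
  }
  sel <- which(atoms$chain %in% chain_id & atoms$type %in% c("ATOM", "HETATM"))
  if (length(sel) == 0L) stop(sprintf("chain not found: '%s'", chain_id))
  at <- atoms[sel, , drop = FALSE]
  at$row <- sel

  # residue identity = resno + insertion code, in order of first appearance
  ins <- ifelse(is.na(at$insert), "", at$insert)
  rkey <- paste(at$resno, ins, sep = "|")
  rlev <- unique(rkey)

  ca_idx <- integer(0)
  missing_ca <- character(0)
  for (k in seq_along(rlev)) {
    rows <- which(rkey == rlev[k])
    ca <- rows[at$elety[rows] == "CA"]
    if (length(ca) == 0L) {
      missing_ca <- c(missing_ca,
                      sprintf("%s%s", at$resid[rows[1]], sub("\\|.*", "", rlev[k])))
      next
    }
    if (length(ca) > 1L) {
      occ <- at$o[ca]
      occ[is.na(occ)] <- 1
      ca <- ca[order(-occ, seq_along(ca))][1]  # highest occupancy, then first
    }
    ca_idx <- c(ca_idx, ca)
  }
  if (length(missing_ca) > 0L)
    stop("incomplete backbone: residue(s) lacking a CA record: ",
         paste(missing_ca, collapse = ", "))
  if (length(ca_idx) < 3L)
    stop("chain too short: need at least 3 residues, got ", length(ca_idx))

  coords <- xyz[at$row[ca_idx] , , drop = FALSE]
  chain(coords,
        label = paste0(basename(pdb_path), ":", chain_id),
        pdb_resno = at$resno[ca_idx],
        resid = at$resid[ca_idx])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a chain as a C-alpha-only PDB snapshot
#'
#' Emits one CA ATOM record per residue with 3-decimal coordinates and
#' sequential serials; the output is accepted by [read_ca_chain()] and
#' round-trips coordinates to within PDB precision (1e-3 Angstrom).
#'
#' @param chain a [chain()] object.
#' @param out_path output file path.
#' @return invisibly, `out_path`.
#' @export
write_snapshot <- function(chain, out_path) {
  stopifnot(inherits(chain, "chain"))
  n <- chain$n
  resid <- chain$resid %||% rep("ALA", n)
  bio3d::write.pdb(
    file = out_path,
    xyz = as.numeric(t(chain$coords)),
    type = rep("ATOM", n),
    resno = seq_len(n),
    resid = resid,
    eleno = seq_len(n),
    elety = rep("CA", n),
    chain = rep("A", n))
  invisible(out_path)
}
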