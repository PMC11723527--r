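#' Construct a single-chain structure model
#'
#' A `chain_model` holds one predicted protein chain: residues renumbered
#' 1..L, one-letter sequence, per-residue heavy-atom coordinates and
#' per-residue model confidence (pLDDT, 0-100).
#'
#' @param coords list of length L; each element a numeric matrix (n_atoms x 3)
#'   of heavy-atom coordinates in Angstrom.
#' @param sequence character vector of one-letter amino acid codes (length L),
#'   or a single string of length L.
#' @param plddt numeric vector of per-residue confidence values in \[0, 100\].
#' @param residue_ids original author residue numbers (kept as metadata;
#'   internal numbering is always 1..L).
#' @return an object of class `chain_model` with elements `L`, `sequence`,
#'   `coords`, `plddt`, `residue_ids`.
#' @export
chain_model <- function(coords, sequence = NULL, plddt = NULL,
                        residue_ids = NULL) {
  stopifnot(is.list(coords), length(coords) >= 1L)
  L <- length(coords)
  for (i in seq_len(L)) {
    m <- coords[[i]]
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) < 1L || anyNA(m))
      stop("residue ", i, " has no valid heavy-atom coordinates")
  }
  if (is.null(sequence)) sequence <- rep("X", L)
  if (length(sequence) == 1L && nchar(sequence) == L)
    sequence <- strsplit(sequence, "")[[1]]
  stopifnot(length(sequence) == L)
  if (is.null(plddt)) plddt <- rep(NA_real_, L)
  stopifnot(length(plddt) == L)
  if (is.null(residue_ids)) residue_ids <- seq_len(L)
  structure(list(L = L, sequence = sequence, coords = coords,
                 plddt = as.numeric(plddt),
                 residue_ids = as.integer(residue_ids)),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat("chain_model:", x$L, "residues,",
      sum(vapply(x$coords, nrow, 1L)), "heavy atoms\n")
  if (!all(is.na(x$plddt)))
    cat("  mean pLDDT:", round(mean(x$plddt), 1), "\n")
  invisible(x)
}

#' Load a predicted structure model from PDB or mmCIF
#'
#' Reads a single-chain model, renumbers residues 1..L preserving file order,
#' and takes the per-residue confidence (pLDDT) from the B-factor/confidence
#' field of the first atom of each residue (AFDB convention). Hydrogens and
#' waters are dropped; for alternate locations the first listed is kept.
#'
#' @param path path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @return a [chain_model].
#' @export
load_model <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
         else bio3d::read.pdb(path)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  atoms <- atoms[is.na(atoms$elesy) | toupper(atoms$elesy) != "H", , drop = FALSE]
  atoms <- atoms[!grepl("^H", trimws(atoms$elety)), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no polymer heavy atoms found in ", path)
  chains <- unique(atoms$chain)
  if (length(chains) > 1L)
    stop("multi-chain input not supported; chains present: ",
         paste(chains, collapse = ", "))
  # first-listed altloc only
  if (!is.null(atoms$alt)) {
    keep <- !duplicated(paste(atoms$resno, atoms$insert, atoms$elety))
    atoms <- atoms[keep, , drop = FALSE]
  }
  key <- paste(atoms$resno, atoms$insert)
  ukey <- unique(key)
  L <- length(ukey)
  idx <- match(key, ukey)
  coords <- vector("list", L)
  plddt <- numeric(L)
  seq3 <- character(L)
  rid <- integer(L)
  for (i in seq_len(L)) {
    sel <- which(idx == i)
    m <- cbind(atoms$x[sel], atoms$y[sel], atoms$z[sel])
    if (anyNA(m))
      stop("missing coordinates for residue ", atoms$resno[sel[1]])
    coords[[i]] <- m
    plddt[i] <- atoms$b[sel[1]]
    seq3[i] <- atoms$resid[sel[1]]
    rid[i] <- atoms$resno[sel[1]]
  }
  seq1 <- suppressWarnings(bio3d::aa321(seq3))
  seq1[is.na(seq1)] <- "X"
  chain_model(coords, sequence = seq1, plddt = plddt, residue_ids = rid)
}

#' Minimal heavy-atom distance matrix
#'
#' Entry (i, j) is the minimum Euclidean distance between any heavy atom of
#' residue i and any heavy atom of residue j; the diagonal is zero.
#'
#' @param model a [chain_model].
#' @return an L x L symmetric numeric matrix (Angstrom).
#' @export
distance_matrix <- function(model) {
  stopifnot(inherits(model, "chain_model"))
  na <- vapply(model$coords, nrow, 1L)
  coords <- do.call(rbind, model$coords)
  res <- rep.int(seq_len(model$L), na)
  .min_dist_matrix(coords, as.integer(res), model$L)
}

#' Contact criteria for boundary refinement
#'
#' Two residues are in contact when their minimal heavy-atom distance is
#' below `max_distance` and they are more than `min_sequence_separation`
#' residues apart in sequence.
#'
#' @param max_distance distance cutoff in Angstrom (default 6).
#' @param min_sequence_separation sequence-separation cutoff in residues
#'   (default 6); contacts require `|i - j| > min_sequence_separation`.
#' @return a `contact_config` list.
#' @export
contact_config <- function(max_distance = 6.0, min_sequence_separation = 6L) {
  stopifnot(max_distance > 0, min_sequence_separation > 0)
  structure(list(max_distance = max_distance,
                 min_sequence_separation = as.integer(min_sequence_separation)),
            class = "contact_config")
}

#' Per-residue spatial contacts
#'
#' @param model a [chain_model] (or a precomputed distance matrix via
#'   `dist_mat`).
#' @param cfg a [contact_config].
#' @param dist_mat optional precomputed [distance_matrix] output.
#' @return a list of length L; element i is the sorted integer vector of
#'   residues in contact with residue i. The relation is symmetric and
#'   irreflexive.
#' @export
residue_contacts <- function(model, cfg = contact_config(), dist_mat = NULL) {
  if (is.null(dist_mat)) dist_mat <- distance_matrix(model)
  L <- nrow(dist_mat)
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  adj <- dist_mat < cfg$max_distance & sep > cfg$min_sequence_separation
  lapply(seq_len(L), function(i) which(adj[i, ]))
}
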