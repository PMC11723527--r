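#' Load a predicted aligned error (PAE) matrix from AFDB-style JSON
#'
#' Accepts both public AFDB dialects: the flat
#' `"predicted_aligned_error"` nested-list form and the older
#' `"residue1"/"residue2"/"distance"` triplet form (either at the top level
#' or wrapped in a one-element list). The raw matrix may be asymmetric;
#' all downstream consumers use the symmetrized view
#' `sym(i,j) = min(raw(i,j), raw(j,i))`.
#'
#' @param path path to the PAE JSON file.
#' @param L declared chain length; the file must describe an L x L matrix.
#' @return a `pae_matrix` object: list with `raw` and `sym` L x L matrices.
#' @export
load_pae <- function(path, L) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.data.frame(obj) || (is.list(obj) && is.null(names(obj)) &&
                             length(obj) == 1L))
    obj <- as.list(if (is.data.frame(obj)) obj else obj[[1]])
  raw <- NULL
  if (!is.null(obj$predicted_aligned_error)) {
    pae <- obj$predicted_aligned_error
    if (is.list(pae)) pae <- do.call(rbind, pae)
    raw <- as.matrix(pae)
    # row index = scored residue i, column = aligned residue j
  } else if (!is.null(obj$residue1)) {
    i <- as.integer(unlist(obj$residue1))
    j <- as.integer(unlist(obj$residue2))
    d <- as.numeric(unlist(obj$distance))
    n <- max(i, j)
    raw <- matrix(NA_real_, n, n)
    raw[cbind(i, j)] <- d
  } else {
    stop("unrecognized PAE JSON dialect in ", path)
  }
  if (nrow(raw) != L || ncol(raw) != L)
    stop("PAE size ", nrow(raw), "x", ncol(raw), " does not match L = ", L)
  if (anyNA(raw)) stop("PAE matrix has missing entries")
  if (any(raw < 0)) stop("PAE matrix has negative entries")
  pae_matrix(raw)
}

#' Wrap a raw PAE matrix with its symmetrized view
#'
#' @param raw L x L non-negative matrix (possibly asymmetric).
#' @return `pae_matrix` with elements `raw`, `sym` (elementwise minimum of
#'   the matrix and its transpose) and `L`.
#' @export
pae_matrix <- function(raw) {
  raw <- as.matrix(raw)
  stopifnot(nrow(raw) == ncol(raw), all(raw >= 0))
  structure(list(raw = raw, sym = pmin(raw, t(raw)), L = nrow(raw)),
            class = "pae_matrix")
}

# Accept either a pae_matrix or a bare symmetric matrix in downstream code.
pae_sym <- function(pae) {
  if (inherits(pae, "pae_matrix")) pae$sym else pmin(pae, t(pae))
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat("pae_matrix: L =", x$L,
      " range [", round(min(x$sym), 2), ",", round(max(x$sym), 2), "]\n")
  invisible(x)
}
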