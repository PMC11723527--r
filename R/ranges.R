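#' Parse an ECOD-style residue range string
#'
#' Range strings are 1-based inclusive and comma-separated, with an optional
#' chain prefix, e.g. `"A:1-100,A:150-200"` or `"5-30"`. Single residues may
#' be written without a dash (`"A:17"`).
#'
#' @param x a single range string.
#' @return a data.frame with columns `chain` (NA when absent), `start`, `end`.
#' @export
parse_range_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  parts <- strsplit(trimws(x), ",", fixed = TRUE)[[1]]
  res <- lapply(parts, function(p) {
    p <- trimws(p)
    chain <- NA_character_
    if (grepl(":", p, fixed = TRUE)) {
      bits <- strsplit(p, ":", fixed = TRUE)[[1]]
      chain <- bits[1]
      p <- bits[2]
    }
    if (grepl("-", p, fixed = TRUE)) {
      se <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
    } else {
      se <- rep(as.integer(p), 2L)
    }
    if (anyNA(se) || length(se) != 2L || se[2] < se[1])
      stop("malformed range component: '", p, "'")
    data.frame(chain = chain, start = se[1], end = se[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Expand a range string into a sorted vector of residue indices
#' @inheritParams parse_range_string
#' @return integer vector of 1-based residue indices.
#' @export
range_string_to_residues <- function(x) {
  df <- parse_range_string(x)
  sort(unique(unlist(Map(seq.int, df$start, df$end))))
}

#' Format a residue index set as an ECOD-style range string
#'
#' Consecutive runs are collapsed to `start-end` components; discontinuous
#' sets yield comma-separated components.
#'
#' @param residues integer vector of 1-based residue indices.
#' @param chain optional chain id prefix.
#' @return a single range string.
#' @export
residues_to_range_string <- function(residues, chain = NULL) {
  r <- sort(unique(as.integer(residues)))
  if (length(r) == 0L) return("")
  breaks <- c(0L, which(diff(r) != 1L), length(r))
  comps <- vapply(seq_len(length(breaks) - 1L), function(k) {
    run <- r[(breaks[k] + 1L):breaks[k + 1L]]
    if (length(run) == 1L) as.character(run)
    else paste0(run[1], "-", run[length(run)])
  }, character(1))
  if (!is.null(chain)) comps <- paste0(chain, ":", comps)
  paste(comps, collapse = ",")
}

# Derive a child RNG seed from a run seed and a stream index, kept below
# 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  ((as.double(seed) %% 1e6) * 2039 + as.double(stream) * 9973 + 17) %% 2147483647
}

# Contiguous runs of a sorted integer vector, as a list of vectors.
residue_runs <- function(residues) {
  r <- sort(unique(as.integer(residues)))
  if (length(r) == 0L) return(list())
  breaks <- c(0L, which(diff(r) != 1L), length(r))
  lapply(seq_len(length(breaks) - 1L),
         function(k) r[(breaks[k] + 1L):breaks[k + 1L]])
}
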