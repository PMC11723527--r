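#' Secondary structure elements from DSSP codes
#'
#' Maximal runs of strand codes (`B`, `E`) of length >= 3 become strands;
#' maximal runs of helix codes (`G`, `H`, `I`) of length >= 6 become helices.
#' Shorter runs produce no element.
#'
#' @param ss_codes per-residue DSSP-alphabet string (or character vector) of
#'   length L; allowed characters: `H B E G I T S -` and space.
#' @param min_strand,min_helix run-length thresholds (defaults 3 and 6).
#' @return a data.frame with columns `kind` ("strand"/"helix"), `start`,
#'   `end` (1-based inclusive).
#' @export
secondary_structure <- function(ss_codes, min_strand = 3L, min_helix = 6L) {
  if (length(ss_codes) == 1L && nchar(ss_codes) > 1L)
    ss_codes <- strsplit(ss_codes, "")[[1]]
  bad <- setdiff(unique(ss_codes), c("H", "B", "E", "G", "I", "T", "S", "-", " "))
  if (length(bad))
    stop("invalid DSSP codes: ", paste(bad, collapse = " "))
  cls <- ifelse(ss_codes %in% c("B", "E"), "strand",
         ifelse(ss_codes %in% c("G", "H", "I"), "helix", "loop"))
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- (r$values == "strand" & r$lengths >= min_strand) |
          (r$values == "helix" & r$lengths >= min_helix)
  out <- data.frame(kind = r$values[keep], start = starts[keep],
                    end = ends[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read per-residue secondary structure codes from a DSSP output file
#'
#' Parses only the per-residue summary block of a classic-format DSSP file
#' (the lines following the `#  RESIDUE AA STRUCTURE ...` header); the
#' structure code is taken from column 17. Chain-break lines (`!`) are
#' skipped. Blank codes are returned as `-`.
#'
#' @param path path to a DSSP output file.
#' @return a single string of per-residue codes.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(hdr) == 0L) stop("not a DSSP summary file: ", path)
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  codes <- substr(body, 17, 17)
  codes[codes == " "] <- "-"
  paste(codes, collapse = "")
}

# Per-residue SSE id (NA for residues outside every element).
sse_ids <- function(sses, L) {
  ids <- rep(NA_integer_, L)
  if (nrow(sses) == 0L) return(ids)
  for (k in seq_len(nrow(sses))) ids[sses$start[k]:sses$end[k]] <- k
  ids
}
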