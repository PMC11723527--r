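# Readers and writers for hit tables, domain definition tables and parsed
# domain tables. All residue numbering in files is 1-based inclusive.

# Expand a comma-separated range string preserving component order (the
# pairing between q_res and h_res relies on order, so no sorting here).
expand_ranges_ordered <- function(x) {
  df <- parse_range_string(x)
  unlist(Map(seq.int, df$start, df$end), use.names = FALSE)
}

#' Read a pre-digested hits table
#'
#' Tab-separated with header and columns `source` (sequence|structure),
#' `ref_domain_id`, `score`, `q_res`, `h_res`. The residue columns are
#' comma-separated range strings (e.g. `"1-40,61-80"`); both expand to the
#' same length and are paired in order.
#'
#' @param path path to the TSV file.
#' @return list of [hit_alignment].
#' @export
read_hits_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    q <- expand_ranges_ordered(df$q_res[i])
    h <- expand_ranges_ordered(df$h_res[i])
    if (length(q) != length(h))
      stop("row ", i, ": q_res and h_res expand to different lengths")
    hit_alignment(df$source[i], df$ref_domain_id[i], df$score[i], q, h)
  })
}

#' Write hits to the pre-digested TSV dialect
#' @param hits list of [hit_alignment].
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  rows <- lapply(hits, function(h) {
    # compress runs that are consecutive in both query and hit numbering
    brk <- c(0L, which(diff(h$q_res) != 1L | diff(h$h_res) != 1L),
             length(h$q_res))
    qs <- hs <- character(0)
    for (k in seq_len(length(brk) - 1L)) {
      sel <- (brk[k] + 1L):brk[k + 1L]
      qs <- c(qs, paste0(h$q_res[sel[1]], "-", h$q_res[sel[length(sel)]]))
      hs <- c(hs, paste0(h$h_res[sel[1]], "-", h$h_res[sel[length(sel)]]))
    }
    data.frame(source = h$source, ref_domain_id = h$ref_domain_id,
               score = h$score, q_res = paste(qs, collapse = ","),
               h_res = paste(hs, collapse = ","), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read reference domain definitions
#'
#' Tab-separated with header and columns `domain_id` and `range`, the latter
#' an ECOD-style range string (optionally chain-prefixed, e.g.
#' `"A:1-100,A:150-200"`). Intervals must be non-overlapping; they are
#' sorted on read.
#'
#' @param path path to the TSV file.
#' @return list of definitions, each `list(domain_id, ranges)` where
#'   `ranges` is a data.frame with sorted `start`, `end` columns.
#' @export
read_domain_defs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    rng <- parse_range_string(df$range[i])
    rng <- rng[order(rng$start), c("start", "end")]
    if (nrow(rng) > 1L && any(rng$start[-1] <= rng$end[-nrow(rng)]))
      stop("overlapping intervals in definition of ", df$domain_id[i])
    rownames(rng) <- NULL
    list(domain_id = df$domain_id[i], ranges = rng)
  })
}

#' Parse an HHsuite .hhr result file into hit alignments
#'
#' Reads the alignment blocks (`No <k>` sections): the reference identifier
#' from the `>` line, the probability from the `Probab=` line, and the
#' query/template residue mapping from the paired `Q`/`T` alignment rows
#' (consensus, ss_pred, ss_dssp and ss_conf rows are skipped; gapped columns
#' produce no pair).
#'
#' @param path path to a `.hhr` file.
#' @return list of [hit_alignment] with `source = "sequence"`.
#' @export
read_hhr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^No\\s+[0-9]+", lines)
  if (length(starts) == 0L) return(list())
  bounds <- c(starts, length(lines) + 1L)
  skip_names <- c("Consensus", "ss_pred", "ss_dssp", "ss_conf")
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    idline <- grep("^>", block, value = TRUE)[1]
    ref_id <- sub("^>(\\S+).*", "\\1", idline)
    pline <- grep("Probab=", block, value = TRUE)[1]
    prob <- as.numeric(sub(".*Probab=([0-9.]+).*", "\\1", pline))
    q_res <- integer(0); h_res <- integer(0)
    arow <- grepl("^[QT] \\S+\\s+[0-9]+ ", block)
    for (ln in which(arow)) {
      m <- regmatches(block[ln],
        regexec("^([QT]) (\\S+)\\s+([0-9]+) (\\S+)\\s+[0-9]+", block[ln]))[[1]]
      if (length(m) == 0L || m[3] %in% skip_names) next
      if (m[2] == "Q") {
        qstart <- as.integer(m[4]); qseq <- strsplit(m[5], "")[[1]]
      } else {
        tstart <- as.integer(m[4]); tseq <- strsplit(m[5], "")[[1]]
        qi <- qstart; ti <- tstart
        for (col in seq_along(qseq)) {
          qgap <- qseq[col] == "-"; tgap <- tseq[col] == "-"
          if (!qgap && !tgap) {
            q_res <- c(q_res, qi); h_res <- c(h_res, ti)
          }
          if (!qgap) qi <- qi + 1L
          if (!tgap) ti <- ti + 1L
        }
      }
    }
    out[[k]] <- hit_alignment("sequence", ref_id, prob, q_res, h_res)
  }
  out
}

#' Read structural-alignment hits from a Dali-derived block table
#'
#' Tab-separated with header and columns `hit_id`, `z`, `q_start`, `q_end`,
#' `h_start`, `h_end`: one row per ungapped aligned block (query and hit
#' blocks must have equal length). Rows sharing a `hit_id` form one hit.
#'
#' @param path path to the TSV file.
#' @return list of [hit_alignment] with `source = "structure"`.
#' @export
read_dali <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ids <- unique(df$hit_id)
  lapply(ids, function(id) {
    rows <- df[df$hit_id == id, , drop = FALSE]
    q <- h <- integer(0)
    for (i in seq_len(nrow(rows))) {
      qb <- rows$q_start[i]:rows$q_end[i]
      hb <- rows$h_start[i]:rows$h_end[i]
      if (length(qb) != length(hb))
        stop("unequal block lengths for hit ", id)
      q <- c(q, qb); h <- c(h, hb)
    }
    hit_alignment("structure", id, rows$z[1], q, h)
  })
}

#' Write a domain set as a TSV of range strings
#'
#' Columns: `domain` (1-based index), `range` (ECOD-style 1-based inclusive
#' range string), `nres`.
#'
#' @param domains a [domain_set] or plain list of residue-index vectors.
#' @param path output path.
#' @export
write_domains_tsv <- function(domains, path) {
  doms <- if (inherits(domains, "domain_set")) domains$domains else domains
  df <- data.frame(
    domain = seq_along(doms),
    range = vapply(doms, residues_to_range_string, ""),
    nres = vapply(doms, length, 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a domain TSV back into a list of residue sets
#' @param path path written by [write_domains_tsv] (or the same dialect).
#' @return list of sorted integer residue vectors.
#' @export
read_domains_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(df$range, range_string_to_residues)
}
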