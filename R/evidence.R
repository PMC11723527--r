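#' Construct a homology hit alignment
#'
#' One hit of the query against a classified reference domain, from either a
#' sequence search (score = HHsuite probability, 0-100) or a structure search
#' (score = Dali Z-score, >= 0). The residue mapping is one-to-one in query
#' residues.
#'
#' @param source `"sequence"` or `"structure"`.
#' @param ref_domain_id reference domain identifier.
#' @param score hit score (HHprob for sequence, Z for structure).
#' @param q_res,h_res paired query/hit residue numbers (1-based).
#' @return a `hit_alignment` object.
#' @export
hit_alignment <- function(source, ref_domain_id, score, q_res, h_res) {
  source <- match.arg(source, c("sequence", "structure"))
  q_res <- as.integer(q_res); h_res <- as.integer(h_res)
  stopifnot(length(q_res) == length(h_res), score >= 0)
  if (anyDuplicated(q_res))
    stop("hit mapping is not one-to-one in query residues")
  if (source == "sequence" && score > 100)
    stop("sequence hit probability must be <= 100")
  structure(list(source = source, ref_domain_id = as.character(ref_domain_id),
                 score = as.numeric(score), q_res = q_res, h_res = h_res),
            class = "hit_alignment")
}

#' @export
print.hit_alignment <- function(x, ...) {
  cat(sprintf("hit_alignment[%s] %s score=%.2f, %d residues\n",
              x$source, x$ref_domain_id, x$score, length(x$q_res)))
  invisible(x)
}

#' Acceptability thresholds for homology hits
#'
#' The numeric criteria for an "acceptable" hit are database- and
#' pipeline-dependent; every threshold is exposed here and the defaults are
#' placeholders to be calibrated against the reference pipeline in use.
#'
#' @param seq_min_prob minimum HHsuite probability for sequence hits.
#' @param seq_min_len minimum aligned length for sequence hits.
#' @param struct_min_z minimum Dali Z for structure hits.
#' @param struct_min_len minimum aligned length for structure hits.
#' @return an `acceptability_config` list.
#' @export
acceptability_config <- function(seq_min_prob = 20, seq_min_len = 10,
                                 struct_min_z = 2, struct_min_len = 20) {
  stopifnot(seq_min_prob >= 0, seq_min_len >= 0,
            struct_min_z >= 0, struct_min_len >= 0)
  structure(list(seq_min_prob = seq_min_prob, seq_min_len = seq_min_len,
                 struct_min_z = struct_min_z, struct_min_len = struct_min_len),
            class = "acceptability_config")
}

#' Filter hits by per-source acceptability thresholds
#'
#' @param hits list of [hit_alignment].
#' @param cfg an [acceptability_config].
#' @return the surviving hits, order preserved.
#' @export
filter_acceptable <- function(hits, cfg = acceptability_config()) {
  keep <- vapply(hits, function(h) {
    n <- length(h$q_res)
    if (h$source == "sequence")
      h$score >= cfg$seq_min_prob && n >= cfg$seq_min_len
    else
      h$score >= cfg$struct_min_z && n >= cfg$struct_min_len
  }, logical(1))
  hits[keep]
}

#' Partition a whole-chain hit by reference domain definitions
#'
#' A search hit aligns the query to a whole reference chain; this splits it
#' into one hit per reference domain that receives at least one aligned
#' residue, restricting the mapping to pairs whose hit residue falls inside
#' that domain's ranges. The score is inherited.
#'
#' @param chain_hit a [hit_alignment] whose `h_res` live on the reference
#'   chain described by `defs`.
#' @param defs a list of reference domain definitions, each a list with
#'   `domain_id` and `ranges` (data.frame with `start`, `end`, 1-based
#'   inclusive, non-overlapping, sorted) -- see [read_domain_defs].
#' @return list of [hit_alignment], one per covered reference domain.
#' @export
partition_hit_by_reference_domains <- function(chain_hit, defs) {
  out <- list()
  for (d in defs) {
    rng <- d$ranges
    inside <- rep(FALSE, length(chain_hit$h_res))
    for (k in seq_len(nrow(rng)))
      inside <- inside | (chain_hit$h_res >= rng$start[k] &
                          chain_hit$h_res <= rng$end[k])
    if (any(inside)) {
      out[[length(out) + 1L]] <- hit_alignment(
        chain_hit$source, d$domain_id, chain_hit$score,
        chain_hit$q_res[inside], chain_hit$h_res[inside])
    }
  }
  out
}

#' Iterative masked structural alignment against one reference domain
#'
#' A structural aligner maps a reference domain onto at most one segment of
#' the query, so tandem copies of a domain are found one at a time: the
#' query residues aligned in one round are excluded, and the remainder is
#' re-aligned until the aligner finds nothing or too few residues remain.
#'
#' @param query a [chain_model] (only its length is required here; the
#'   aligner receives the remaining residue set).
#' @param hit_id reference domain identifier handed to the aligner.
#' @param aligner function `(query_residues, hit_id) -> hit_alignment or
#'   NULL`; it must only align within `query_residues`.
#' @param min_remaining stop when fewer query residues than this remain
#'   (default 20).
#' @param max_rounds safety cap on iterations (default 50).
#' @return list of [hit_alignment] with pairwise-disjoint query coverage.
#' @export
iterative_structural_alignment <- function(query, hit_id, aligner,
                                           min_remaining = 20L,
                                           max_rounds = 50L) {
  remaining <- seq_len(query$L)
  out <- list()
  for (round in seq_len(max_rounds)) {
    if (length(remaining) < min_remaining) break
    hit <- tryCatch(aligner(remaining, hit_id),
                    error = function(e)
                      stop("aligner failed at iteration ", round, ": ",
                           conditionMessage(e)))
    if (is.null(hit)) break
    if (!all(hit$q_res %in% remaining))
      stop("aligner returned residues outside the remaining set at iteration ",
           round)
    out[[length(out) + 1L]] <- hit
    remaining <- setdiff(remaining, hit$q_res)
  }
  out
}

#' Group ranked hits by query coverage overlap
#'
#' Greedy pass over hits in rank order (score descending, ties broken by
#' `ref_domain_id`): a hit joins the first existing group where its overlap
#' with the group's collective coverage is less than `overlap_frac` of the
#' hit's own coverage OR of the group's coverage; otherwise it starts a new
#' group.
#'
#' @param hits list of [hit_alignment], all from one source.
#' @param overlap_frac overlap fraction threshold (default 0.20).
#' @return list of groups; each group is a list with `hits` (members in
#'   admission order) and `coverage` (sorted union of member query residues).
#' @export
group_hits <- function(hits, overlap_frac = 0.20) {
  if (length(hits) == 0L) return(list())
  src <- unique(vapply(hits, `[[`, "", "source"))
  if (length(src) > 1L) stop("hits must come from a single source")
  ord <- order(-vapply(hits, `[[`, 0, "score"),
               vapply(hits, `[[`, "", "ref_domain_id"))
  hits <- hits[ord]
  groups <- list()
  for (h in hits) {
    cov <- unique(h$q_res)
    placed <- FALSE
    for (g in seq_along(groups)) {
      ov <- length(intersect(cov, groups[[g]]$coverage))
      if (ov < overlap_frac * length(cov) ||
          ov < overlap_frac * length(groups[[g]]$coverage)) {
        groups[[g]]$hits <- c(groups[[g]]$hits, list(h))
        groups[[g]]$coverage <- sort(union(groups[[g]]$coverage, cov))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      groups[[length(groups) + 1L]] <- list(hits = list(h),
                                            coverage = sort(cov))
  }
  groups
}

#' Squash a hit score into \[0, 1)
#'
#' Sequence probabilities (0-100) are divided by 100; structure Z-scores are
#' squashed as `z / (z + 10)`, a bounded monotone map that keeps the two
#' evidence sources on a comparable scale for the network.
#'
#' @param score numeric score(s).
#' @param source `"sequence"` or `"structure"`.
#' @return scaled score(s) in \[0, 1\].
#' @export
scale_hit_score <- function(score, source) {
  source <- match.arg(source, c("sequence", "structure"))
  if (source == "sequence") score / 100 else score / (score + 10)
}

#' Build evidence channel matrices from hit groups
#'
#' Each hit contributes an L x L matrix with its scaled score at (i, j) when
#' both residues are mapped query residues and 0 elsewhere; hits in a group
#' are merged by elementwise maximum. Groups are ranked by their best
#' member's scaled score (ties by `ref_domain_id`) and at most
#' `max_channels` matrices are returned.
#'
#' @param groups output of [group_hits] (one source).
#' @param L query length.
#' @param max_channels channel cap (default 10).
#' @return list of L x L matrices, best group first.
#' @export
build_evidence_channels <- function(groups, L, max_channels = 10L) {
  if (length(groups) == 0L) return(list())
  best_score <- vapply(groups, function(g)
    max(vapply(g$hits, function(h) scale_hit_score(h$score, h$source), 0)),
    0)
  best_id <- vapply(groups, function(g) {
    s <- vapply(g$hits, `[[`, 0, "score")
    g$hits[[which.max(s)]]$ref_domain_id
  }, "")
  ord <- order(-best_score, best_id)
  groups <- groups[ord][seq_len(min(length(groups), max_channels))]
  lapply(groups, function(g) {
    m <- matrix(0, L, L)
    for (h in g$hits) {
      v <- scale_hit_score(h$score, h$source)
      idx <- h$q_res
      m[idx, idx] <- pmax(m[idx, idx], v)
    }
    m
  })
}
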