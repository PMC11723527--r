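# Conversion of a same-domain probability matrix plus structural
# annotations into discrete domain definitions.

#' Disorder detection parameters
#'
#' A residue's "PAE neighbors" are residues at sequence separation >=
#' `min_sequence_separation` with symmetrized PAE below `pae_cutoff`. The
#' chain is tiled into non-overlapping `window`-residue segments; a segment
#' whose total neighbor count is <= `max_neighbors` is disordered.
#'
#' @param min_sequence_separation default 20 residues.
#' @param pae_cutoff default 6 Angstrom.
#' @param window default 5 residues.
#' @param max_neighbors default 10.
#' @return a `disorder_config`.
#' @export
disorder_config <- function(min_sequence_separation = 20L, pae_cutoff = 6.0,
                            window = 5L, max_neighbors = 10L) {
  stopifnot(min_sequence_separation > 0, pae_cutoff > 0, window > 0,
            max_neighbors >= 0)
  structure(list(min_sequence_separation = as.integer(min_sequence_separation),
                 pae_cutoff = pae_cutoff, window = as.integer(window),
                 max_neighbors = as.integer(max_neighbors)),
            class = "disorder_config")
}

#' Helical-linker detection parameters
#'
#' Reuses the disorder windowed test with two modifications: PAE neighbors
#' within the same secondary structure element are not counted, and a
#' window qualifies only if its fraction of candidate intra-domain residues
#' (residues covered by acceptable homology hits) is at most
#' `max_candidate_fraction`. Only windows intersecting a helix are
#' eligible (`helix_only = FALSE` relaxes this).
#'
#' @param max_candidate_fraction default 0.40.
#' @param disorder a [disorder_config] supplying the shared fields.
#' @param helix_only restrict to helix-intersecting windows (default TRUE).
#' @return a `linker_config`.
#' @export
linker_config <- function(max_candidate_fraction = 0.40,
                          disorder = disorder_config(), helix_only = TRUE) {
  stopifnot(max_candidate_fraction >= 0, max_candidate_fraction <= 1)
  structure(list(max_candidate_fraction = max_candidate_fraction,
                 disorder = disorder, helix_only = helix_only),
            class = "linker_config")
}

#' Segment clustering and domain-size parameters
#'
#' @param p_min minimum segment-pair mean same-domain probability for a
#'   pair to be considered (default 0.89, the grid-search optimum).
#' @param ratio_max within/between mean-probability ratio bound for merging
#'   (default 1.12, the grid-search optimum).
#' @param segment_len segment tile length (default 5 residues).
#' @param min_excluded_to_drop a segment with at least this many residues
#'   from disordered regions or helical linkers is dropped (default 3).
#' @param min_domain_size minimum residues per final domain (default 20).
#' @return a `cluster_config`.
#' @export
cluster_config <- function(p_min = 0.89, ratio_max = 1.12, segment_len = 5L,
                           min_excluded_to_drop = 3L, min_domain_size = 20L) {
  stopifnot(p_min > 0, p_min < 1, ratio_max > 1, segment_len > 0,
            min_domain_size > 0)
  structure(list(p_min = p_min, ratio_max = ratio_max,
                 segment_len = as.integer(segment_len),
                 min_excluded_to_drop = as.integer(min_excluded_to_drop),
                 min_domain_size = as.integer(min_domain_size)),
            class = "cluster_config")
}

#' Construct a domain set
#'
#' @param domains list of residue-index vectors (pairwise disjoint, possibly
#'   discontinuous in sequence).
#' @param L chain length.
#' @param provenance optional named list recording residues removed at each
#'   pipeline stage.
#' @return a `domain_set` with `domains`, `unassigned` and `provenance`.
#' @export
domain_set <- function(domains, L, provenance = list()) {
  domains <- lapply(domains, function(d) sort(unique(as.integer(d))))
  all_res <- unlist(domains)
  if (anyDuplicated(all_res)) stop("domains are not pairwise disjoint")
  if (length(all_res) && max(all_res) > L) stop("residue index exceeds L")
  structure(list(domains = domains, L = as.integer(L),
                 unassigned = setdiff(seq_len(L), all_res),
                 provenance = provenance),
            class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat("domain_set:", length(x$domains), "domains,",
      length(x$unassigned), "unassigned of", x$L, "residues\n")
  for (d in seq_along(x$domains))
    cat(sprintf("  %d: %s (%d res)\n", d,
                residues_to_range_string(x$domains[[d]]),
                length(x$domains[[d]])))
  invisible(x)
}

# Per-residue PAE-neighbor counts; same_sse (optional integer vector of SSE
# ids) suppresses neighbor pairs within one element.
pae_neighbor_counts <- function(pae, cfg, sse = NULL) {
  p <- pae_sym(pae)
  L <- nrow(p)
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  nb <- sep >= cfg$min_sequence_separation & p < cfg$pae_cutoff
  if (!is.null(sse)) {
    same <- outer(sse, sse, function(a, b) !is.na(a) & !is.na(b) & a == b)
    nb <- nb & !same
  }
  rowSums(nb)
}

# Tiled non-overlapping windows 1..L (trailing remnant kept short).
tile_windows <- function(L, window) {
  starts <- seq.int(1L, L, by = window)
  lapply(starts, function(s) s:min(s + window - 1L, L))
}

#' Detect disordered regions from the PAE matrix
#'
#' @param pae a [pae_matrix] or symmetric matrix.
#' @param cfg a [disorder_config].
#' @return sorted integer vector of disordered residues.
#' @export
detect_disorder <- function(pae, cfg = disorder_config()) {
  counts <- pae_neighbor_counts(pae, cfg)
  flagged <- integer(0)
  for (w in tile_windows(length(counts), cfg$window))
    if (sum(counts[w]) <= cfg$max_neighbors) flagged <- c(flagged, w)
  flagged
}

#' Detect flexible helical linkers between domains
#'
#' @param pae a [pae_matrix] or symmetric matrix.
#' @param sses secondary structure elements from [secondary_structure].
#' @param candidate_residues residues covered by acceptable homology hits
#'   ("candidate intra-domain residues").
#' @param cfg a [linker_config].
#' @return sorted integer vector of linker residues.
#' @export
detect_helical_linkers <- function(pae, sses, candidate_residues = integer(0),
                                   cfg = linker_config()) {
  dcfg <- cfg$disorder
  L <- if (inherits(pae, "pae_matrix")) pae$L else nrow(pae)
  ids <- sse_ids(sses, L)
  counts <- pae_neighbor_counts(pae, dcfg, sse = ids)
  helix_res <- integer(0)
  if (nrow(sses)) {
    hx <- sses[sses$kind == "helix", , drop = FALSE]
    helix_res <- unlist(Map(seq.int, hx$start, hx$end))
  }
  flagged <- integer(0)
  for (w in tile_windows(L, dcfg$window)) {
    if (sum(counts[w]) > dcfg$max_neighbors) next
    if (mean(w %in% candidate_residues) > cfg$max_candidate_fraction) next
    if (cfg$helix_only && !any(w %in% helix_res)) next
    flagged <- c(flagged, w)
  }
  flagged
}

#' Partition a chain into candidate segments
#'
#' Non-overlapping `segment_len`-residue tiles (trailing remnant kept as a
#' short segment); tiles with at least `min_excluded_to_drop` residues from
#' the excluded set (disorder or helical linkers) are dropped.
#'
#' @param L chain length.
#' @param excluded residues to exclude (disorder/linkers).
#' @param cfg a [cluster_config].
#' @return list of integer residue vectors (the kept segments).
#' @export
partition_segments <- function(L, excluded = integer(0),
                               cfg = cluster_config()) {
  Filter(function(w) sum(w %in% excluded) < cfg$min_excluded_to_drop,
         tile_windows(L, cfg$segment_len))
}

# Mean same-domain probability between every pair of segments (and each
# segment's own block mean on the diagonal).
segment_psame <- function(prob, segments) {
  n <- length(segments)
  S <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in a:n) {
      S[a, b] <- S[b, a] <- mean(prob[segments[[a]], segments[[b]]])
    }
  }
  S
}

# Mean Psame within a group; a singleton group's value is its own block
# mean (the paper leaves this case undefined).
group_within_mean <- function(S, members) {
  if (length(members) == 1L) return(S[members, members])
  pairs <- utils::combn(members, 2L)
  mean(S[cbind(pairs[1L, ], pairs[2L, ])])
}

group_cross_mean <- function(S, g1, g2)
  mean(S[g1, g2, drop = FALSE])

#' Greedy segment clustering on mean same-domain probabilities
#'
#' Segment pairs with mean probability (Psame) above `p_min` are processed
#' in descending order (ties by segment indices). Three scenarios: if
#' neither segment is grouped, the pair starts a new group; if exactly one
#' is grouped, the free segment joins that group when the ratio of the
#' group's within-mean to the segment-group cross-mean is below
#' `ratio_max`, and otherwise starts its own group; if both are in
#' different groups, the groups merge when either group's within-mean is
#' below `ratio_max` times the cross-mean. Segments never reaching any
#' considered pair stay ungrouped.
#'
#' @param prob L x L symmetric probability matrix.
#' @param segments list of residue vectors from [partition_segments].
#' @param cfg a [cluster_config].
#' @return list of clusters, each an integer vector of segment indices
#'   (ordered by first admission).
#' @export
cluster_segments <- function(prob, segments, cfg = cluster_config()) {
  n <- length(segments)
  if (n == 0L) return(list())
  S <- segment_psame(prob, segments)
  if (n == 1L) return(list())
  pairs <- which(upper.tri(S), arr.ind = TRUE)
  ps <- S[pairs]
  keep <- ps > cfg$p_min
  pairs <- pairs[keep, , drop = FALSE]
  ps <- ps[keep]
  ord <- order(-ps, pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  groups <- list()          # list of integer vectors of segment indices
  assignment <- rep(NA_integer_, n)
  for (r in seq_len(nrow(pairs))) {
    a <- unname(pairs[r, 1L]); b <- unname(pairs[r, 2L])
    ga <- assignment[a]; gb <- assignment[b]
    if (is.na(ga) && is.na(gb)) {
      groups[[length(groups) + 1L]] <- c(a, b)
      assignment[c(a, b)] <- length(groups)
    } else if (is.na(ga) || is.na(gb)) {
      free <- if (is.na(ga)) a else b
      g <- if (is.na(ga)) gb else ga
      within <- group_within_mean(S, groups[[g]])
      cross <- group_cross_mean(S, free, groups[[g]])
      if (within / cross < cfg$ratio_max) {
        groups[[g]] <- c(groups[[g]], free)
        assignment[free] <- g
      } else {
        groups[[length(groups) + 1L]] <- free
        assignment[free] <- length(groups)
      }
    } else if (ga != gb) {
      w1 <- group_within_mean(S, groups[[ga]])
      w2 <- group_within_mean(S, groups[[gb]])
      cross <- group_cross_mean(S, groups[[ga]], groups[[gb]])
      if (w1 < cfg$ratio_max * cross || w2 < cfg$ratio_max * cross) {
        groups[[ga]] <- c(groups[[ga]], groups[[gb]])
        assignment[groups[[gb]]] <- ga
        groups[[gb]] <- integer(0)
      }
    }
  }
  Filter(length, groups)
}

#' Contact-based boundary refinement and size filtering
#'
#' Sweeps run N- to C-terminal, removals before additions, until a fixed
#' point or `max_sweeps`. A boundary residue (terminus of a contiguous run
#' of a domain) is removed when it has strictly more contacts outside the
#' domain than inside; an unassigned residue sequence-adjacent to a domain
#' is added when it has strictly more contacts inside than outside.
#' Domains below `min_domain_size` residues are then dropped.
#'
#' @param clusters list of residue-index vectors (candidate domains).
#' @param contacts per-residue contact lists from [residue_contacts].
#' @param cfg a [cluster_config].
#' @param max_sweeps sweep cap (default 20).
#' @return a [domain_set].
#' @export
refine_boundaries <- function(clusters, contacts, cfg = cluster_config(),
                              max_sweeps = 20L) {
  L <- length(contacts)
  doms <- lapply(clusters, function(d) sort(unique(as.integer(d))))
  doms <- Filter(length, doms)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    # removals
    for (d in seq_along(doms)) {
      for (run in residue_runs(doms[[d]])) {
        for (r in unique(c(run[1], run[length(run)]))) {
          if (!r %in% doms[[d]]) next
          inside <- sum(contacts[[r]] %in% setdiff(doms[[d]], r))
          outside <- sum(!contacts[[r]] %in% doms[[d]])
          if (outside > inside) {
            doms[[d]] <- setdiff(doms[[d]], r)
            changed <- TRUE
          }
        }
      }
    }
    # additions
    assigned <- unlist(doms)
    for (d in seq_along(doms)) {
      cand <- integer(0)
      for (run in residue_runs(doms[[d]]))
        cand <- c(cand, run[1] - 1L, run[length(run)] + 1L)
      cand <- sort(unique(cand[cand >= 1L & cand <= L &
                                 !(cand %in% assigned)]))
      for (r in cand) {
        inside <- sum(contacts[[r]] %in% doms[[d]])
        outside <- sum(!contacts[[r]] %in% doms[[d]])
        if (inside > outside) {
          doms[[d]] <- sort(c(doms[[d]], r))
          assigned <- c(assigned, r)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  doms <- Filter(function(d) length(d) >= cfg$min_domain_size, doms)
  domain_set(doms, L)
}

#' Full probability-to-domains pipeline
#'
#' Runs disorder detection, helical-linker detection, segment partitioning,
#' greedy clustering, contact-based boundary refinement and the final size
#' filter, in that order, recording residues removed at each stage.
#'
#' @param model a [chain_model].
#' @param pae a [pae_matrix] (or symmetric PAE matrix).
#' @param ss_codes per-residue DSSP codes (string of length L).
#' @param hits list of [hit_alignment] (used for candidate intra-domain
#'   residues; may be empty).
#' @param prob L x L symmetric same-domain probability matrix.
#' @param cluster_cfg a [cluster_config].
#' @param disorder_cfg a [disorder_config].
#' @param linker_cfg a [linker_config].
#' @param contact_cfg a [contact_config].
#' @param accept_cfg an [acceptability_config] for the candidate residues.
#' @param dist_mat optional precomputed [distance_matrix] output.
#' @return a [domain_set] with a stage-by-stage provenance log.
#' @export
parse_domains <- function(model, pae, ss_codes, hits, prob,
                          cluster_cfg = cluster_config(),
                          disorder_cfg = disorder_config(),
                          linker_cfg = linker_config(disorder = disorder_cfg),
                          contact_cfg = contact_config(),
                          accept_cfg = acceptability_config(),
                          dist_mat = NULL) {
  L <- model$L
  stopifnot(nrow(prob) == L)
  disorder <- detect_disorder(pae, disorder_cfg)
  sses <- secondary_structure(ss_codes)
  candidates <- sort(unique(unlist(
    lapply(filter_acceptable(hits, accept_cfg), `[[`, "q_res"))))
  linkers <- detect_helical_linkers(pae, sses, candidates, linker_cfg)
  excluded <- sort(union(disorder, linkers))
  segments <- partition_segments(L, excluded, cluster_cfg)
  clusters <- cluster_segments(prob, segments, cluster_cfg)
  cluster_res <- lapply(clusters, function(g)
    sort(unlist(segments[g])))
  contacts <- residue_contacts(model, contact_cfg, dist_mat = dist_mat)
  refined <- refine_boundaries(cluster_res, contacts, cluster_cfg)
  refined$provenance <- list(
    disorder = disorder, helical_linkers = linkers,
    segments_kept = length(segments),
    clusters = length(clusters),
    pre_refinement = cluster_res)
  refined
}
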