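# Scoring predicted domain sets against reference definitions.

#' Intersection-over-union of two residue sets
#'
#' @param a,b integer residue vectors.
#' @return `|a n b| / |a u b|`; both sets empty is an error.
#' @export
iou <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("IoU of two empty sets is undefined")
  length(intersect(a, b)) / u
}

#' Per-reference detection, split count and best-match IoU
#'
#' A reference domain is detected when at least 50% of its residues are
#' assigned to predicted domains (collectively). The split count is the
#' number of predicted domains that each cover strictly more than 50% of
#' the reference's residues. The best match is the predicted domain with
#' the largest intersection.
#'
#' @param ref,pred [domain_set]s (or plain lists of residue vectors).
#' @param detect_frac detection coverage threshold (default 0.5, inclusive).
#' @param split_frac split-count coverage threshold (default 0.5, strict).
#' @return data.frame with one row per reference domain: `ref_domain`,
#'   `detected`, `n_split`, `best_iou`, `matched_pred`.
#' @export
detection <- function(ref, pred, detect_frac = 0.5, split_frac = 0.5) {
  refs <- if (inherits(ref, "domain_set")) ref$domains else ref
  preds <- if (inherits(pred, "domain_set")) pred$domains else pred
  pred_union <- unique(unlist(preds))
  rows <- lapply(seq_along(refs), function(k) {
    r <- refs[[k]]
    covered <- length(intersect(r, pred_union)) / length(r)
    inter <- vapply(preds, function(p) length(intersect(r, p)), 1L)
    n_split <- sum(inter > split_frac * length(r))
    if (length(preds) && max(inter) > 0L) {
      best <- which.max(inter)
      best_iou <- iou(r, preds[[best]])
    } else {
      best <- NA_integer_; best_iou <- 0
    }
    data.frame(ref_domain = k, detected = covered >= detect_frac,
               n_split = n_split, best_iou = best_iou,
               matched_pred = best)
  })
  do.call(rbind, rows)
}

#' Fraction of correctly predicted reference domains
#'
#' A reference domain is correct when some predicted domain shares strictly
#' more than `overlap` of BOTH domains' residues.
#'
#' @param refs,preds [domain_set]s or lists of residue vectors.
#' @param overlap mutual overlap threshold (default 0.75, strict).
#' @return fraction in \[0, 1\] (0 when there are no reference domains).
#' @export
correct_fraction <- function(refs, preds, overlap = 0.75) {
  refs <- if (inherits(refs, "domain_set")) refs$domains else refs
  preds <- if (inherits(preds, "domain_set")) preds$domains else preds
  if (length(refs) == 0L) return(0)
  ok <- vapply(refs, function(r) {
    any(vapply(preds, function(p) {
      i <- length(intersect(r, p))
      i > overlap * length(r) && i > overlap * length(p)
    }, logical(1)))
  }, logical(1))
  mean(ok)
}

#' Grid search for the clustering parameters
#'
#' Evaluates [correct_fraction] of the probability-to-domains conversion
#' over a grid of (`p_min`, `ratio_max`) values on a validation set with
#' known reference domains, and returns the argmax (ties: smallest `p_min`,
#' then smallest `ratio_max`).
#'
#' Each validation instance is a list with `prob` (L x L matrix), `truth`
#' (reference domains), `L`, and optionally `excluded` (residues excluded
#' before segmentation) and `contacts` (per-residue contact lists; when
#' present, boundary refinement is applied).
#'
#' @param instances list of validation instances.
#' @param p_min_grid,ratio_max_grid numeric grids (non-empty).
#' @param base_cfg a [cluster_config] supplying the remaining parameters.
#' @param overlap mutual overlap threshold for correctness (default 0.75).
#' @return list with `p_min`, `ratio_max`, `score` and the full `table`
#'   (data.frame of grid point scores).
#' @export
grid_search_xy <- function(instances, p_min_grid, ratio_max_grid,
                           base_cfg = cluster_config(), overlap = 0.75) {
  if (length(p_min_grid) == 0L || length(ratio_max_grid) == 0L)
    stop("empty parameter grid")
  grid <- expand.grid(p_min = sort(p_min_grid),
                      ratio_max = sort(ratio_max_grid))
  score_one <- function(x, y) {
    cfg <- base_cfg
    cfg$p_min <- x; cfg$ratio_max <- y
    mean(vapply(instances, function(inst) {
      excl <- if (is.null(inst$excluded)) integer(0) else inst$excluded
      segs <- partition_segments(inst$L, excl, cfg)
      clusters <- cluster_segments(inst$prob, segs, cfg)
      res <- lapply(clusters, function(g) sort(unlist(segs[g])))
      doms <- if (!is.null(inst$contacts))
        refine_boundaries(res, inst$contacts, cfg)$domains
      else Filter(function(d) length(d) >= cfg$min_domain_size, res)
      correct_fraction(inst$truth, doms, overlap = overlap)
    }, 0))
  }
  grid$score <- mapply(score_one, grid$p_min, grid$ratio_max)
  best <- grid[order(-grid$score, grid$p_min, grid$ratio_max), ][1L, ]
  list(p_min = best$p_min, ratio_max = best$ratio_max, score = best$score,
       table = grid)
}
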