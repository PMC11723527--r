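# Mapping L x L channel matrices into fixed-size square crops and back.
# The crop edge is 500 pixels throughout (the trained input size); residue
# coordinates are 1-based inclusive.

CROP_SIZE <- 500L
POSITION_SCALE <- 2000  # residue numbers are divided by this and clipped to 1

#' Construct a crop specification
#'
#' A crop holds one or two query segments placed on a `crop_size`-wide axis.
#' Padded crops (short proteins) have `pad_left` zero-filled positions on
#' the left; the remainder of the axis after the segments is right padding.
#'
#' @param segments list of one or two `c(start, end)` 1-based inclusive
#'   query intervals, non-overlapping and in sequence order.
#' @param pad_left number of left padding positions (padding case only).
#' @param crop_size crop edge length (default 500).
#' @return a `crop_spec` with a precomputed `pos_map`: for each crop axis
#'   position, the query residue it carries (NA for padding).
#' @export
crop_spec <- function(segments, pad_left = 0L, crop_size = CROP_SIZE) {
  if (is.numeric(segments)) segments <- list(segments)
  segments <- lapply(segments, as.integer)
  stopifnot(length(segments) %in% c(1L, 2L), pad_left >= 0)
  lens <- vapply(segments, function(s) s[2] - s[1] + 1L, 1L)
  if (any(lens < 1L)) stop("empty crop segment")
  if (sum(lens) + pad_left > crop_size)
    stop("segments plus padding exceed the crop size")
  if (length(segments) == 2L && segments[[2]][1] <= segments[[1]][2])
    stop("two-segment crops must be non-overlapping and in sequence order")
  pos_map <- rep(NA_integer_, crop_size)
  at <- pad_left + 1L
  for (s in segments) {
    n <- s[2] - s[1] + 1L
    pos_map[at:(at + n - 1L)] <- s[1]:s[2]
    at <- at + n
  }
  structure(list(segments = segments, pad_left = as.integer(pad_left),
                 crop_size = as.integer(crop_size), pos_map = pos_map),
            class = "crop_spec")
}

#' @export
print.crop_spec <- function(x, ...) {
  segs <- vapply(x$segments, function(s) paste0(s[1], "-", s[2]), "")
  cat("crop_spec:", paste(segs, collapse = " + "),
      if (x$pad_left > 0) paste0("(pad_left=", x$pad_left, ")") else "", "\n")
  invisible(x)
}

#' Number of crops for a long protein
#'
#' Piecewise rule on chain length: 1 crop up to 750 residues, 2 up to 1000,
#' 3 up to 1500, 4 up to 2000, 5 beyond.
#'
#' @param L chain length; must exceed the crop size (shorter chains go
#'   through the padding path).
#' @return integer crop count.
#' @export
crop_count <- function(L) {
  if (L <= CROP_SIZE)
    stop("L <= ", CROP_SIZE, ": use the padding path, not cropping")
  if (L <= 750) 1L else if (L <= 1000) 2L else if (L <= 1500) 3L
  else if (L <= 2000) 4L else 5L
}

#' Randomized training crops for one epoch
#'
#' Short proteins (L <= 500) produce one padded crop with a uniformly drawn
#' left pad in \[0, 500-L\]. Long proteins produce [crop_count] crops, each
#' independently either one 500-residue window (uniform start) or two
#' windows totalling 500 residues (lengths split uniformly with each
#' segment >= `min_segment`, the second strictly after the first).
#' Deterministic given `seed`.
#'
#' @param L chain length.
#' @param seed RNG seed for this draw.
#' @param min_segment minimum segment length for discontinuous crops
#'   (default 50).
#' @return list of [crop_spec].
#' @export
make_training_crops <- function(L, seed, min_segment = 50L) {
  set.seed(as.integer(seed %% 2147483647))
  if (L <= CROP_SIZE) {
    pad <- sample.int(CROP_SIZE - L + 1L, 1L) - 1L
    return(list(crop_spec(list(c(1L, L)), pad_left = pad)))
  }
  n <- crop_count(L)
  lapply(seq_len(n), function(k) {
    if (stats::runif(1) < 0.5) {
      s <- sample.int(L - CROP_SIZE + 1L, 1L)
      crop_spec(list(c(s, s + CROP_SIZE - 1L)))
    } else {
      pick <- function(v) v[sample.int(length(v), 1L)]   # length-1 safe
      l1 <- pick(seq.int(min_segment, CROP_SIZE - min_segment))
      l2 <- CROP_SIZE - l1
      s1 <- sample.int(L - CROP_SIZE + 1L, 1L)
      s2 <- pick(seq.int(s1 + l1, L - l2 + 1L))
      crop_spec(list(c(s1, s1 + l1 - 1L), c(s2, s2 + l2 - 1L)))
    }
  })
}

#' Systematic inference crops covering every residue pair
#'
#' Deterministic tiling for L > 500: continuous 500-residue windows at
#' stride 250 (final window clamped to end at L), plus two-segment crops
#' pairing each 250-residue tile with every later non-adjacent tile.
#' Together these cover every residue pair (i, j): pairs within 500
#' residues fall in a continuous window, farther pairs in the cross block
#' of a two-segment crop.
#'
#' @param L chain length (> 500).
#' @return list of [crop_spec].
#' @export
make_inference_crops <- function(L) {
  if (L <= CROP_SIZE)
    stop("L <= ", CROP_SIZE, ": use a single padded crop")
  stride <- CROP_SIZE %/% 2L
  win_starts <- unique(c(seq.int(1L, L - CROP_SIZE + 1L, by = stride),
                         L - CROP_SIZE + 1L))
  crops <- lapply(win_starts, function(s)
    crop_spec(list(c(s, s + CROP_SIZE - 1L))))
  tile_starts <- seq.int(1L, L, by = stride)
  n_tiles <- length(tile_starts)
  tiles <- lapply(tile_starts, function(s) c(s, min(s + stride - 1L, L)))
  for (i in seq_len(n_tiles)) {
    j <- i + 2L
    while (j <= n_tiles) {
      crops[[length(crops) + 1L]] <- crop_spec(list(tiles[[i]], tiles[[j]]))
      j <- j + 1L
    }
  }
  crops
}

#' Assemble per-protein input channels
#'
#' Runs the evidence pipeline (acceptability filter, grouping, channel
#' construction) and bundles the geometric matrices into the channel set the
#' network consumes.
#'
#' @param model a [chain_model].
#' @param pae a [pae_matrix] (the symmetrized view is used).
#' @param hits list of [hit_alignment] (both sources mixed; may be empty).
#' @param accept_cfg an [acceptability_config].
#' @param max_channels evidence channel cap per source (default 10).
#' @return a `feature_set`: list with `L`, `distance`, `pae`, `ev_seq`,
#'   `ev_struct` (lists of L x L matrices) and `candidate_residues`
#'   (query residues covered by any acceptable hit).
#' @export
featurize <- function(model, pae, hits = list(),
                      accept_cfg = acceptability_config(),
                      max_channels = 10L) {
  L <- model$L
  acc <- filter_acceptable(hits, accept_cfg)
  seq_hits <- Filter(function(h) h$source == "sequence", acc)
  str_hits <- Filter(function(h) h$source == "structure", acc)
  ev_seq <- build_evidence_channels(group_hits(seq_hits), L, max_channels)
  ev_struct <- build_evidence_channels(group_hits(str_hits), L, max_channels)
  cand <- sort(unique(unlist(lapply(acc, `[[`, "q_res"))))
  structure(list(L = L, distance = distance_matrix(model),
                 pae = pae_sym(pae), ev_seq = ev_seq, ev_struct = ev_struct,
                 candidate_residues = cand),
            class = "feature_set")
}

# Fixed channel layout consumed by the network: 24 channels.
N_CHANNELS <- 24L

#' Extract one crop from a feature set
#'
#' Maps the L x L channels into a `crop_size` x `crop_size` x 24 array
#' (channels: distance, PAE, position-i, position-j, 10 sequence-evidence,
#' 10 structure-evidence; missing evidence channels are zero). Cross-segment
#' blocks of two-segment crops carry the true (i, j) values. Position
#' channels carry the residue numbers divided by 2000 and clipped to 1.
#' Padded pixels are 0 in every channel and FALSE in the validity mask.
#'
#' @param features a `feature_set` from [featurize] (or a compatible list).
#' @param spec a [crop_spec].
#' @return list with `x` (array), `mask` (logical matrix), `spec`.
#' @export
extract_crop <- function(features, spec) {
  cs <- spec$crop_size
  x <- array(0, dim = c(cs, cs, N_CHANNELS))
  v <- which(!is.na(spec$pos_map))
  res <- spec$pos_map[v]
  if (max(res) > features$L) stop("crop spec exceeds chain length")
  x[v, v, 1L] <- features$distance[res, res]
  x[v, v, 2L] <- features$pae[res, res]
  posv <- pmin(res / POSITION_SCALE, 1)
  x[v, v, 3L] <- matrix(posv, length(v), length(v))         # position i (rows)
  x[v, v, 4L] <- matrix(posv, length(v), length(v), byrow = TRUE)
  for (k in seq_along(features$ev_seq))
    x[v, v, 4L + k] <- features$ev_seq[[k]][res, res]
  for (k in seq_along(features$ev_struct))
    x[v, v, 14L + k] <- features$ev_struct[[k]][res, res]
  mask <- matrix(FALSE, cs, cs)
  mask[v, v] <- TRUE
  list(x = x, mask = mask, spec = spec)
}

#' Assemble crop outputs into a full probability matrix
#'
#' Each valid pixel of each crop output is mapped back to its residue pair;
#' pairs covered by several crops are averaged, and the result is
#' symmetrized by averaging with its transpose.
#'
#' @param outputs list of crop output matrices (`crop_size` x `crop_size`).
#' @param specs list of matching [crop_spec].
#' @param L chain length.
#' @return L x L symmetric matrix.
#' @export
assemble_probability <- function(outputs, specs, L) {
  stopifnot(length(outputs) == length(specs))
  acc <- matrix(0, L, L)
  cnt <- matrix(0L, L, L)
  for (k in seq_along(specs)) {
    v <- which(!is.na(specs[[k]]$pos_map))
    res <- specs[[k]]$pos_map[v]
    acc[res, res] <- acc[res, res] + outputs[[k]][v, v]
    cnt[res, res] <- cnt[res, res] + 1L
  }
  if (any(cnt == 0L)) {
    miss <- which(cnt == 0L, arr.ind = TRUE)[1L, ]
    stop("residue pair (", miss[1], ", ", miss[2], ") is covered by no crop")
  }
  m <- acc / cnt
  (m + t(m)) / 2
}
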