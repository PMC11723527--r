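# Independent brute-force oracles. These deliberately use naive explicit
# loops and set arithmetic, sharing no code path with the package
# implementations they check.

oracle_min_dist <- function(coords_list) {
  L <- length(coords_list)
  out <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      best <- Inf
      for (a in seq_len(nrow(coords_list[[i]]))) {
        for (b in seq_len(nrow(coords_list[[j]]))) {
          d <- sqrt(sum((coords_list[[i]][a, ] - coords_list[[j]][b, ])^2))
          if (d < best) best <- d
        }
      }
      out[i, j] <- best
    }
  }
  out
}

oracle_contacts <- function(dist_mat, max_distance, min_sep) {
  L <- nrow(dist_mat)
  out <- vector("list", L)
  for (i in seq_len(L)) {
    ct <- integer(0)
    for (j in seq_len(L)) {
      if (abs(i - j) > min_sep && dist_mat[i, j] < max_distance)
        ct <- c(ct, j)
    }
    out[[i]] <- ct
  }
  out
}

oracle_neighbor_counts <- function(pae_sym, min_sep, cutoff) {
  L <- nrow(pae_sym)
  counts <- integer(L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (abs(i - j) >= min_sep && pae_sym[i, j] < cutoff)
        counts[i] <- counts[i] + 1L
    }
  }
  counts
}

oracle_disorder <- function(pae_sym, min_sep = 20, cutoff = 6,
                            window = 5, max_nb = 10) {
  counts <- oracle_neighbor_counts(pae_sym, min_sep, cutoff)
  L <- length(counts)
  flagged <- integer(0)
  s <- 1L
  while (s <= L) {
    w <- s:min(s + window - 1L, L)
    if (sum(counts[w]) <= max_nb) flagged <- c(flagged, w)
    s <- s + window
  }
  flagged
}

# Literal transcription of the greedy hit-grouping rule, on plain coverage
# sets. Hits must already be in rank order.
oracle_group_hits <- function(coverages, overlap_frac = 0.20) {
  group_cov <- list()
  membership <- list()
  for (h in seq_along(coverages)) {
    cov <- coverages[[h]]
    joined <- NA
    for (g in seq_along(group_cov)) {
      ov <- length(intersect(cov, group_cov[[g]]))
      test1 <- ov < overlap_frac * length(cov)
      test2 <- ov < overlap_frac * length(group_cov[[g]])
      if (test1 || test2) { joined <- g; break }
    }
    if (is.na(joined)) {
      group_cov[[length(group_cov) + 1L]] <- sort(unique(cov))
      membership[[length(membership) + 1L]] <- h
    } else {
      group_cov[[joined]] <- sort(unique(c(group_cov[[joined]], cov)))
      membership[[joined]] <- c(membership[[joined]], h)
    }
  }
  membership
}

# Independent transcription of the three-scenario segment clustering, on a
# precomputed segment-pair mean-probability matrix S.
oracle_cluster <- function(S, p_min, ratio_max) {
  n <- nrow(S)
  within_mean <- function(members) {
    if (length(members) == 1L) return(S[members, members])
    vals <- c()
    for (a in seq_along(members)) {
      for (b in seq_along(members)) {
        if (a < b) vals <- c(vals, S[members[a], members[b]])
      }
    }
    mean(vals)
  }
  cross_mean <- function(m1, m2) {
    vals <- c()
    for (a in m1) for (b in m2) vals <- c(vals, S[a, b])
    mean(vals)
  }
  df <- NULL
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a < b && S[a, b] > p_min)
        df <- rbind(df, data.frame(a = a, b = b, p = S[a, b]))
    }
  }
  if (is.null(df)) return(list())
  df <- df[order(-df$p, df$a, df$b), ]
  groups <- list()
  member_of <- rep(NA_integer_, n)
  for (r in seq_len(nrow(df))) {
    a <- df$a[r]; b <- df$b[r]
    ga <- member_of[a]; gb <- member_of[b]
    if (is.na(ga) && is.na(gb)) {
      groups[[length(groups) + 1L]] <- c(a, b)
      member_of[a] <- member_of[b] <- length(groups)
    } else if (is.na(ga) || is.na(gb)) {
      s <- if (is.na(ga)) a else b
      g <- if (is.na(ga)) gb else ga
      if (within_mean(groups[[g]]) / cross_mean(s, groups[[g]]) < ratio_max) {
        groups[[g]] <- c(groups[[g]], s)
        member_of[s] <- g
      } else {
        groups[[length(groups) + 1L]] <- s
        member_of[s] <- length(groups)
      }
    } else if (ga != gb) {
      p1 <- within_mean(groups[[ga]])
      p2 <- within_mean(groups[[gb]])
      p12 <- cross_mean(groups[[ga]], groups[[gb]])
      if (p1 < ratio_max * p12 || p2 < ratio_max * p12) {
        groups[[ga]] <- c(groups[[ga]], groups[[gb]])
        for (m in groups[[gb]]) member_of[m] <- ga
        groups[[gb]] <- integer(0)
      }
    }
  }
  groups[vapply(groups, length, 1L) > 0L]
}

oracle_detection <- function(refs, preds) {
  pred_union <- c()
  for (p in preds) pred_union <- union(pred_union, p)
  out <- NULL
  for (k in seq_along(refs)) {
    r <- refs[[k]]
    covered <- length(intersect(r, pred_union)) / length(r)
    nsplit <- 0L
    for (p in preds)
      if (length(intersect(r, p)) > 0.5 * length(r)) nsplit <- nsplit + 1L
    out <- rbind(out, data.frame(detected = covered >= 0.5,
                                 n_split = nsplit))
  }
  out
}

oracle_correct_fraction <- function(refs, preds, overlap = 0.75) {
  if (length(refs) == 0L) return(0)
  n_ok <- 0L
  for (r in refs) {
    ok <- FALSE
    for (p in preds) {
      i <- length(intersect(r, p))
      if (i > overlap * length(r) && i > overlap * length(p)) ok <- TRUE
    }
    if (ok) n_ok <- n_ok + 1L
  }
  n_ok / length(refs)
}

# Random residue partition into <= max_domains domains plus leftovers.
random_domains <- function(L, max_domains = 4L) {
  nd <- sample(1:max_domains, 1L)
  cuts <- sort(sample(seq_len(L - 1L), nd))
  bounds <- c(0L, cuts, L)
  doms <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    if (k > nd) break
    doms[[k]] <- (bounds[k] + 1L):bounds[k + 1L]
  }
  doms
}
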