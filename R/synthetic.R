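# Self-contained synthetic inputs with planted ground truth: toy chain
# models (compact random blobs joined by extended linkers), PAE matrices
# with block contrast, homology hit tables and noisy probability maps.
# Geometry is deliberately non-physical; the pipeline consumes distances
# and PAE, not chemistry.

#' Specification for one synthetic protein
#'
#' @param domain_sizes residue count per planted domain (each >= 20; sizes
#'   below ~45 interact with the 20-residue PAE-neighbor separation and can
#'   legitimately be flagged disordered by the parser).
#' @param linker_lengths linker length(s) between consecutive segments
#'   (recycled; default 10).
#' @param discontinuous when TRUE the first domain is split into two
#'   sequence segments that wrap the second domain (needs >= 2 domains).
#' @param jitter coordinate jitter (Angstrom) on linker atoms.
#' @param pae_low,pae_high PAE ranges (Angstrom) for same-domain and
#'   other pairs.
#' @param linker_ss DSSP code assigned to linker residues (`"-"` for coil;
#'   `"H"` plants helical linkers).
#' @param seed RNG seed fixing all randomness.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(domain_sizes = c(120L, 90L), linker_lengths = 10L,
                           discontinuous = FALSE, jitter = 0.5,
                           pae_low = c(2, 5), pae_high = c(15, 30),
                           linker_ss = "-", seed = 1L) {
  stopifnot(all(domain_sizes >= 20L), all(linker_lengths >= 0L),
            length(domain_sizes) >= 1L)
  if (discontinuous && length(domain_sizes) < 2L)
    stop("a discontinuous layout needs at least two domains")
  structure(list(domain_sizes = as.integer(domain_sizes),
                 linker_lengths = as.integer(linker_lengths),
                 discontinuous = discontinuous, jitter = jitter,
                 pae_low = pae_low, pae_high = pae_high,
                 linker_ss = linker_ss, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Compact self-avoiding jittered walk of n points inside a ball. A walk
# that traps itself in a dead end is restarted; packing is declared
# infeasible only when every restart fails.
blob_walk <- function(n, step = 3.8, min_sep = 3.0, max_try = 60L,
                      max_restart = 50L) {
  radius <- 2.9 * n^(1 / 3) + 2
  for (restart in seq_len(max_restart)) {
    pts <- matrix(0, n, 3)
    stuck <- FALSE
    for (i in 2:n) {
      ok <- FALSE
      for (tr in seq_len(max_try)) {
        dir <- stats::rnorm(3)
        cand <- pts[i - 1L, ] + step * dir / sqrt(sum(dir^2))
        if (sqrt(sum(cand^2)) > radius) next
        if (i > 2L) {
          prev <- pts[seq_len(i - 2L), , drop = FALSE]
          d2 <- (prev[, 1L] - cand[1L])^2 + (prev[, 2L] - cand[2L])^2 +
            (prev[, 3L] - cand[3L])^2
          if (min(d2) < min_sep^2) next
        }
        ok <- TRUE; break
      }
      if (!ok) { stuck <- TRUE; break }
      pts[i, ] <- cand
    }
    if (!stuck) return(pts)
  }
  stop("infeasible blob packing after ", max_restart, " restarts")
}

ss_pattern <- function(n) {
  unit <- c(rep("-", 2), rep("E", 5), rep("-", 3), rep("H", 8), rep("-", 2))
  rep(unit, length.out = n)
}

#' Generate one synthetic protein with planted domains
#'
#' Each domain is a compact random blob (intra-domain heavy-atom distances
#' mostly under ~15 A for typical sizes); blobs are translated so that
#' domains are at least 25 A apart, and linkers are extended segments
#' between them. PAE is low within domains and high between domains and on
#' linkers; pLDDT is high in domains and low on linkers; DSSP codes tile
#' strand/helix elements inside domains.
#'
#' @param spec a [synthetic_spec].
#' @return list with `model` ([chain_model]), `pae` ([pae_matrix]),
#'   `truth` ([domain_set]), `ss_codes` (string) and `spec`.
#' @export
make_protein <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nd <- length(spec$domain_sizes)
  nl <- max(nd - 1L, 1L)
  linkers <- rep(spec$linker_lengths, length.out = nl)
  # sequence layout: list of (kind, domain index or linker length) segments
  segs <- list()
  if (spec$discontinuous) {
    h1 <- spec$domain_sizes[1] %/% 2L
    segs <- list(list(kind = "dom", d = 1L, take = seq_len(h1)),
                 list(kind = "link", n = linkers[1]),
                 list(kind = "dom", d = 2L,
                      take = seq_len(spec$domain_sizes[2])),
                 list(kind = "link", n = linkers[min(2L, nl)]),
                 list(kind = "dom", d = 1L,
                      take = (h1 + 1L):spec$domain_sizes[1]))
    extra <- setdiff(seq_len(nd), 1:2)
    for (d in extra) {
      segs <- c(segs, list(list(kind = "link", n = linkers[min(d - 1L, nl)]),
                           list(kind = "dom", d = d,
                                take = seq_len(spec$domain_sizes[d]))))
    }
  } else {
    for (d in seq_len(nd)) {
      if (d > 1L)
        segs <- c(segs, list(list(kind = "link", n = linkers[d - 1L])))
      segs <- c(segs, list(list(kind = "dom", d = d,
                                take = seq_len(spec$domain_sizes[d]))))
    }
  }
  # spatial layout: blob per domain, centers spaced along x
  blobs <- lapply(spec$domain_sizes, blob_walk)
  radii <- vapply(spec$domain_sizes, function(n) 2.9 * n^(1 / 3) + 2, 0)
  cx <- cumsum(c(0, radii[-nd] + radii[-1L] + 25))
  for (d in seq_len(nd)) blobs[[d]][, 1L] <- blobs[[d]][, 1L] + cx[d]
  # walk the sequence layout, assigning CA positions
  L <- sum(vapply(segs, function(s)
    if (s$kind == "dom") length(s$take) else s$n, 1L))
  ca <- matrix(NA_real_, L, 3)
  kind <- character(L)
  domain_of <- rep(0L, L)
  at <- 0L
  for (s in segs) {
    if (s$kind == "dom") {
      idx <- at + seq_along(s$take)
      ca[idx, ] <- blobs[[s$d]][s$take, , drop = FALSE]
      kind[idx] <- "dom"; domain_of[idx] <- s$d
      at <- at + length(s$take)
    } else if (s$n > 0L) {
      idx <- at + seq_len(s$n)
      kind[idx] <- "link"
      at <- at + s$n
    }
  }
  # linker atoms: straight interpolation between flanking anchors + jitter
  for (run in residue_runs(which(kind == "link"))) {
    a0 <- if (run[1] > 1L) ca[run[1] - 1L, ] else ca[run[length(run)] + 1L, ]
    a1 <- if (run[length(run)] < L) ca[run[length(run)] + 1L, ] else a0
    tt <- seq_along(run) / (length(run) + 1L)
    for (k in seq_along(run))
      ca[run[k], ] <- a0 + tt[k] * (a1 - a0) +
        stats::rnorm(3, sd = spec$jitter)
  }
  coords <- lapply(seq_len(L), function(i) {
    dir <- stats::rnorm(3)
    rbind(ca[i, ], ca[i, ] + 1.5 * dir / sqrt(sum(dir^2)))
  })
  plddt <- ifelse(kind == "dom", stats::runif(L, 85, 95),
                  stats::runif(L, 30, 50))
  aa <- sample(c("A", "D", "E", "F", "G", "H", "I", "K", "L", "N", "Q",
                 "R", "S", "T", "V", "W", "Y"), L, replace = TRUE)
  model <- chain_model(coords, sequence = aa, plddt = plddt)
  # PAE: low within domains, high elsewhere; symmetric with zero diagonal
  same <- outer(domain_of, domain_of,
                function(a, b) a > 0 & b > 0 & a == b)
  pae <- matrix(stats::runif(L * L, spec$pae_high[1], spec$pae_high[2]), L, L)
  nlow <- sum(same)
  pae[same] <- stats::runif(nlow, spec$pae_low[1], spec$pae_low[2])
  pae <- (pae + t(pae)) / 2
  diag(pae) <- 0
  ss <- character(L)
  for (d in seq_len(nd)) ss[domain_of == d] <- ss_pattern(spec$domain_sizes[d])
  ss[kind == "link"] <- spec$linker_ss
  truth <- domain_set(lapply(seq_len(nd), function(d) which(domain_of == d)),
                      L)
  list(model = model, pae = pae_matrix(pae), truth = truth,
       ss_codes = paste(ss, collapse = ""), spec = spec)
}

#' Generate homology hits consistent with planted domains
#'
#' Per true domain, 1-5 hits covering 60-100% of it with high scores
#' (sequence probability 60-99, structure Z 8-30); optional decoy hits
#' straddle a domain boundary at low score.
#'
#' @param truth a [domain_set].
#' @param flavor `"sequence"`, `"structure"` or `"both"` (alternating).
#' @param n_decoys number of boundary-straddling low-score hits.
#' @param seed RNG seed.
#' @return list of [hit_alignment].
#' @export
make_hits <- function(truth, flavor = c("both", "sequence", "structure"),
                      n_decoys = 0L, seed = 1L) {
  flavor <- match.arg(flavor)
  set.seed(as.integer(seed %% 2147483647))
  hits <- list()
  src_cycle <- c("sequence", "structure")
  ci <- 0L
  for (d in seq_along(truth$domains)) {
    rd <- truth$domains[[d]]
    for (k in seq_len(sample(1:5, 1L))) {
      ci <- ci + 1L
      src <- switch(flavor, both = src_cycle[1L + ci %% 2L], flavor)
      n_cov <- max(1L, round(stats::runif(1, 0.6, 1.0) * length(rd)))
      s <- sample.int(length(rd) - n_cov + 1L, 1L)
      q <- rd[s:(s + n_cov - 1L)]
      score <- if (src == "sequence") stats::runif(1, 60, 99)
               else stats::runif(1, 8, 30)
      hits[[length(hits) + 1L]] <- hit_alignment(
        src, sprintf("ref_d%02d_h%02d", d, k), score,
        q, seq_len(n_cov) + sample(0:50, 1L))
    }
  }
  if (n_decoys > 0L && length(truth$domains) >= 2L) {
    for (k in seq_len(n_decoys)) {
      d <- sample.int(length(truth$domains) - 1L, 1L)
      a <- truth$domains[[d]]; b <- truth$domains[[d + 1L]]
      q <- c(utils::tail(a, 15L), utils::head(b, 15L))
      src <- if (k %% 2L == 0L) "sequence" else "structure"
      score <- if (src == "sequence") stats::runif(1, 20, 40)
               else stats::runif(1, 2, 5)
      hits[[length(hits) + 1L]] <- hit_alignment(
        src, sprintf("decoy_%02d", k), score, q, seq_along(q))
    }
  }
  hits
}

#' Generate a noisy planted probability matrix
#'
#' Stands in for the network when testing the probability-to-domains
#' conversion in isolation: same-domain pixels draw from a high Beta mode,
#' other pixels from a low mode, and `flip_rate` of pixels swap modes.
#' The output is symmetric with a high-mode diagonal.
#'
#' @param truth a [domain_set].
#' @param flip_rate mode-swap fraction in \[0, 0.5).
#' @param seed RNG seed.
#' @param shape_hi,shape_lo Beta shape pairs for the two modes.
#' @return L x L symmetric matrix in \[0, 1\].
#' @export
make_probability <- function(truth, flip_rate = 0, seed = 1L,
                             shape_hi = c(24, 1.5), shape_lo = c(1.5, 24)) {
  stopifnot(flip_rate >= 0, flip_rate < 0.5)
  set.seed(as.integer(seed %% 2147483647))
  L <- truth$L
  dom_id <- rep(0L, L)
  for (d in seq_along(truth$domains)) dom_id[truth$domains[[d]]] <- d
  same <- outer(dom_id, dom_id, function(a, b) a > 0 & b > 0 & a == b)
  ut <- upper.tri(same)
  n <- sum(ut)
  hi <- stats::rbeta(n, shape_hi[1], shape_hi[2])
  lo <- stats::rbeta(n, shape_lo[1], shape_lo[2])
  use_hi <- xor(same[ut], stats::runif(n) < flip_rate)
  m <- matrix(0, L, L)
  m[ut] <- ifelse(use_hi, hi, lo)
  m <- m + t(m)
  diag(m) <- stats::rbeta(L, shape_hi[1], shape_hi[2])
  m
}

#' Generate a seeded multi-protein suite with homology clusters
#'
#' Cycles through a fixed catalogue of domain architectures (single-domain,
#' two- and three-domain, and one discontinuous layout); each cluster holds
#' two proteins built from the same architecture with different seeds,
#' mimicking close homologs.
#'
#' @param n_proteins number of proteins (default 30; rounded up to an even
#'   count of two per cluster).
#' @param seed master seed.
#' @param with_features also run [featurize] on each protein (default TRUE).
#' @return list of suite entries: `model`, `pae`, `truth`, `ss_codes`,
#'   `hits`, `cluster_id` and (optionally) `features`.
#' @export
make_suite <- function(n_proteins = 30L, seed = 1L, with_features = TRUE) {
  archs <- list(
    list(sizes = c(130L), disc = FALSE),
    list(sizes = c(110L, 85L), disc = FALSE),
    list(sizes = c(90L, 70L, 60L), disc = FALSE),
    list(sizes = c(150L, 100L), disc = FALSE),
    list(sizes = c(100L, 80L), disc = TRUE))
  n_clusters <- ceiling(n_proteins / 2L)
  out <- list()
  for (cl in seq_len(n_clusters)) {
    arch <- archs[[1L + (cl - 1L) %% length(archs)]]
    for (j in 1:2) {
      if (length(out) >= n_proteins) break
      s <- derive_seed(seed, cl * 17L + j)
      spec <- synthetic_spec(domain_sizes = arch$sizes,
                             discontinuous = arch$disc, seed = s)
      prot <- make_protein(spec)
      hits <- make_hits(prot$truth, "both", n_decoys = 1L,
                        seed = derive_seed(s, 1L))
      entry <- list(model = prot$model, pae = prot$pae, truth = prot$truth,
                    ss_codes = prot$ss_codes, hits = hits,
                    cluster_id = sprintf("c%02d", cl))
      if (with_features)
        entry$features <- featurize(prot$model, prot$pae, hits)
      out[[length(out) + 1L]] <- entry
    }
  }
  out
}

#' Write a synthetic chain model as a minimal PDB file
#'
#' Two heavy atoms per residue (CA, CB), pLDDT in the B-factor column;
#' round-trips through [load_model].
#'
#' @param model a [chain_model].
#' @param path output path.
#' @param chain chain identifier (default "A").
#' @export
write_protein_pdb <- function(model, path, chain = "A") {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  aa123 <- function(a) {
    v <- suppressWarnings(bio3d::aa123(a))
    if (is.na(v)) "UNK" else v
  }
  for (i in seq_len(model$L)) {
    m <- model$coords[[i]]
    names_i <- c("CA", "CB", paste0("C", seq_len(max(0, nrow(m) - 2L)) + 1L))
    for (a in seq_len(nrow(m))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
        serial, names_i[a], aa123(model$sequence[i]), chain, i,
        m[a, 1], m[a, 2], m[a, 3], 1.0,
        ifelse(is.na(model$plddt[i]), 0, model$plddt[i]), "C"), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a PAE matrix as AFDB-style JSON
#'
#' @param pae a [pae_matrix] or plain matrix (the raw view is written).
#' @param path output path.
#' @param dialect `"nested"` (flat `predicted_aligned_error` lists) or
#'   `"triplet"` (`residue1`/`residue2`/`distance` vectors).
#' @export
write_pae_json <- function(pae, path, dialect = c("nested", "triplet")) {
  dialect <- match.arg(dialect)
  raw <- if (inherits(pae, "pae_matrix")) pae$raw else as.matrix(pae)
  L <- nrow(raw)
  obj <- if (dialect == "nested") {
    list(list(predicted_aligned_error =
                lapply(seq_len(L), function(i) raw[i, ]),
              max_predicted_aligned_error = max(raw)))
  } else {
    idx <- expand.grid(j = seq_len(L), i = seq_len(L))
    list(list(residue1 = idx$i, residue2 = idx$j,
              distance = raw[cbind(idx$i, idx$j)]))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
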