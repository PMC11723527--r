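# Small in-code fixture builders shared across test files.

# A chain_model with one atom per residue at given CA positions.
point_chain <- function(positions, plddt = NULL) {
  coords <- lapply(seq_len(nrow(positions)), function(i)
    matrix(positions[i, ], 1, 3))
  chain_model(coords, plddt = plddt)
}

# A random chain_model: n residues, n_atoms each, loosely packed.
random_chain <- function(n, n_atoms = 3L, spread = 12) {
  coords <- lapply(seq_len(n), function(i) {
    centre <- stats::runif(3, -spread, spread)
    m <- matrix(rep(centre, n_atoms), n_atoms, 3, byrow = TRUE)
    m + matrix(stats::rnorm(n_atoms * 3, sd = 1), n_atoms, 3)
  })
  chain_model(coords)
}

# Straight-line chain: residue i at (step*i, 0, 0), one atom.
line_chain <- function(n, step = 4) {
  point_chain(cbind(step * seq_len(n), 0, 0))
}

# Write a two-chain PDB file (for the multi-chain error path).
write_two_chain_pdb <- function(path) {
  lines <- c(
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            1, "A", 1, 0, 0, 0, 1, 90),
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            2, "B", 1, 5, 0, 0, 1, 90),
    "END")
  writeLines(lines, path)
  path
}

# Random hit list against an L-residue query.
random_hits <- function(n, L, source = "sequence") {
  lapply(seq_len(n), function(k) {
    len <- sample(10:60, 1L)
    s <- sample.int(L - len + 1L, 1L)
    score <- if (source == "sequence") stats::runif(1, 5, 100)
             else stats::runif(1, 0.5, 40)
    hit_alignment(source, sprintf("h%03d", k), score,
                  s:(s + len - 1L), seq_len(len))
  })
}

# Block probability matrix: value `hi` inside each domain block, `lo`
# elsewhere (constant, noise-free).
block_prob <- function(L, domains, hi = 0.95, lo = 0.05) {
  id <- rep(0L, L)
  for (d in seq_along(domains)) id[domains[[d]]] <- d
  m <- matrix(lo, L, L)
  same <- outer(id, id, function(a, b) a > 0 & b > 0 & a == b)
  m[same] <- hi
  diag(m) <- hi
  m
}
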