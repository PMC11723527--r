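test_that("disorder detection: saturated and empty neighbor regimes", {
  L <- 100L
  expect_equal(detect_disorder(matrix(30, L, L)), 1:L)   # no neighbors at all
  none <- matrix(1, L, L); diag(none) <- 0
  expect_length(detect_disorder(none), 0L)               # everyone well-packed
})

test_that("disorder detection matches the brute-force neighbor count", {
  set.seed(61)
  for (rep in 1:4) {
    L <- 100L
    pae <- matrix(runif(L * L, 15, 30), L, L)
    pae[1:60, 1:60] <- runif(3600, 2, 5)      # ordered block
    pae <- (pae + t(pae)) / 2; diag(pae) <- 0
    got <- detect_disorder(pae)
    want <- oracle_disorder(pae)
    expect_equal(got, want)
    expect_true(all(got > 60))                # only tail windows flagged
    expect_true(all(61:100 %in% got))
  }
})

# Fixture for linker tests: two ordered blocks joined by a helix whose only
# low-PAE partners are within itself.
linker_fixture <- function(L = 65L, helix = 26:40) {
  pae <- matrix(25, L, L)
  pae[1:25, 1:25] <- 3
  pae[41:L, 41:L] <- 3
  pae[helix, helix] <- 3
  pae <- (pae + t(pae)) / 2; diag(pae) <- 0
  ss <- rep("-", L)
  ss[2:24] <- "E"   # one long strand per block keeps blocks un-flagged
  ss[42:64] <- "E"
  ss[helix] <- "H"
  list(pae = pae, ss = paste(ss, collapse = ""))
}

test_that("helical linkers: isolated helix flagged, candidate fraction vetoes", {
  fx <- linker_fixture()
  sses <- secondary_structure(fx$ss)
  got <- detect_helical_linkers(fx$pae, sses, integer(0))
  # helix residues have no counted neighbors (same-SSE pairs excluded);
  # windows 26-30, 31-35, 36-40 intersect the helix
  expect_true(all(c(26:40) %in% got))
  expect_false(any(1:25 %in% got))

  # 3/5 candidate residues (0.6 > 0.4) veto a window
  got2 <- detect_helical_linkers(fx$pae, sses, candidate_residues = 26:28)
  expect_false(any(26:30 %in% got2))
  expect_true(all(31:40 %in% got2))

  # no SSEs at all: no helical linkers
  empty_sse <- secondary_structure(strrep("-", 65))
  expect_length(detect_helical_linkers(fx$pae, empty_sse, integer(0)), 0L)
})

test_that("segment partition tiles in fives and drops contaminated windows", {
  segs <- partition_segments(12L)
  expect_equal(segs, list(1:5, 6:10, 11:12))

  segs <- partition_segments(15L, excluded = c(6, 7, 8))   # 3 excluded: drop
  expect_equal(segs, list(1:5, 11:15))

  segs <- partition_segments(15L, excluded = c(6, 7))      # 2 excluded: keep
  expect_equal(segs, list(1:5, 6:10, 11:15))
})

test_that("segment clustering: block-diagonal and uniform limits", {
  L <- 60L
  segs <- partition_segments(L)
  two_block <- block_prob(L, list(1:30, 31:60), hi = 1.0, lo = 0.0)
  cl <- cluster_segments(two_block, segs)
  expect_length(cl, 2L)
  expect_equal(sort(unlist(segs[cl[[1]]])), 1:30)
  expect_equal(sort(unlist(segs[cl[[2]]])), 31:60)

  all_one <- matrix(1, L, L)
  cl <- cluster_segments(all_one, segs)
  expect_length(cl, 1L)
  expect_length(cl[[1]], length(segs))
})

test_that("segment clustering matches the transcription oracle on random instances", {
  set.seed(71)
  for (rep in 1:8) {
    n_seg <- 12L
    L <- n_seg * 5L
    segs <- partition_segments(L)
    nd <- sample(2:3, 1)
    doms <- random_domains(L, nd)
    prob <- make_probability(domain_set(doms, L), flip_rate = 0.08,
                             seed = 1000 + rep)
    got <- cluster_segments(prob, segs)
    S <- domainseg:::segment_psame(prob, segs)
    want <- oracle_cluster(S, 0.89, 1.12)
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("raising p_min never decreases the number of ungrouped segments", {
  set.seed(80)
  L <- 100L
  segs <- partition_segments(L)
  prob <- make_probability(domain_set(list(1:55, 56:100), L),
                           flip_rate = 0.1, seed = 4)
  prev_ungrouped <- -1L
  for (p_min in c(0.5, 0.7, 0.89, 0.97)) {
    cl <- cluster_segments(prob, segs, cluster_config(p_min = p_min))
    ungrouped <- length(segs) - length(unlist(cl))
    expect_gte(ungrouped, prev_ungrouped)
    prev_ungrouped <- ungrouped
  }
})

test_that("boundary refinement follows the contact majority rules", {
  # removal: boundary residue with 3 contacts inside, 5 outside
  contacts <- rep(list(integer(0)), 30)
  contacts[[10]] <- c(2, 3, 4, 21, 22, 23, 24, 25)
  doms <- refine_boundaries(list(1:10), contacts,
                            cluster_config(min_domain_size = 5L),
                            max_sweeps = 1L)
  expect_equal(doms$domains[[1]], 1:9)

  # addition: adjacent unassigned residue with 4 inside, 1 outside
  contacts <- rep(list(integer(0)), 30)
  contacts[[10]] <- c(2, 3, 4, 5, 6, 25)      # 5 in / 1 out: stays
  contacts[[11]] <- c(2, 3, 4, 5, 25)         # 4 in / 1 out: recruited
  doms <- refine_boundaries(list(1:10), contacts,
                            cluster_config(min_domain_size = 5L),
                            max_sweeps = 1L)
  expect_equal(doms$domains[[1]], 1:11)

  # size filter: 19-residue domain dies, 20-residue domain survives
  quiet <- rep(list(integer(0)), 60)
  ds <- refine_boundaries(list(1:19, 30:49), quiet, cluster_config())
  expect_length(ds$domains, 1L)
  expect_equal(ds$domains[[1]], 30:49)
})

test_that("full parsing pipeline recovers planted domains", {
  prot <- make_protein(synthetic_spec(domain_sizes = c(100L, 80L), seed = 19L))
  hits <- make_hits(prot$truth, "both", seed = 20L)
  prob <- make_probability(prot$truth, flip_rate = 0.05, seed = 21L)
  ds <- parse_domains(prot$model, prot$pae, prot$ss_codes, hits, prob)
  expect_length(ds$domains, 2L)
  ev <- detection(prot$truth, ds)
  expect_true(all(ev$detected))
  expect_true(all(ev$best_iou >= 0.9))
  # residue conservation and disjointness
  assigned <- unlist(ds$domains)
  expect_false(anyDuplicated(assigned) > 0)
  expect_setequal(c(assigned, ds$unassigned), seq_len(prot$model$L))
})

test_that("an all-disordered chain parses to no domains", {
  prot <- make_protein(synthetic_spec(domain_sizes = c(60L, 50L), seed = 23L))
  flat <- matrix(30, prot$model$L, prot$model$L)   # PAE high everywhere
  prob <- make_probability(prot$truth, seed = 3L)
  ds <- parse_domains(prot$model, pae_matrix(flat), prot$ss_codes, list(), prob)
  expect_length(ds$domains, 0L)
  expect_equal(ds$unassigned, seq_len(prot$model$L))
})

test_that("a single compact domain yields one near-full-length domain", {
  prot <- make_protein(synthetic_spec(domain_sizes = 150L, seed = 29L))
  prob <- make_probability(prot$truth, flip_rate = 0.03, seed = 30L)
  ds <- parse_domains(prot$model, prot$pae, prot$ss_codes, list(), prob)
  expect_length(ds$domains, 1L)
  expect_gte(length(ds$domains[[1]]), 130L)
})

test_that("domain TSV round trips discontinuous domains", {
  ds <- domain_set(list(c(5:60, 120:150), 61:119), 160L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_domains_tsv(ds, path)
  back <- read_domains_tsv(path)
  expect_equal(back, ds$domains)
})
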