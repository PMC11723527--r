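test_that("whole-chain hits are partitioned cleanly by reference domains", {
  defs <- list(list(domain_id = "A", ranges = data.frame(start = 1, end = 100)),
               list(domain_id = "B", ranges = data.frame(start = 101, end = 200)))
  hit <- hit_alignment("sequence", "chainX", 95, 1:200, 1:200)
  parts <- partition_hit_by_reference_domains(hit, defs)
  expect_length(parts, 2L)
  expect_equal(vapply(parts, function(h) length(h$q_res), 1L), c(100L, 100L))
  expect_equal(parts[[1]]$ref_domain_id, "A")
  expect_equal(parts[[1]]$score, 95)

  small <- hit_alignment("sequence", "chainX", 80, 201:211, 50:60)
  parts <- partition_hit_by_reference_domains(small, defs[1])
  expect_length(parts, 1L)
  expect_length(parts[[1]]$q_res, 11L)

  expect_equal(partition_hit_by_reference_domains(hit, list()), list())
})

test_that("partition pair counts equal a per-pair membership oracle", {
  set.seed(21)
  defs <- list(
    list(domain_id = "d1", ranges = data.frame(start = c(1, 120), end = c(60, 160))),
    list(domain_id = "d2", ranges = data.frame(start = 61, end = 119)))
  for (rep in 1:5) {
    h_res <- sample(1:170, 80)
    hit <- hit_alignment("structure", "chainY", 12, seq_along(h_res), h_res)
    parts <- partition_hit_by_reference_domains(hit, defs)
    for (d in defs) {
      want <- 0L
      for (r in h_res) {
        for (k in seq_len(nrow(d$ranges)))
          if (r >= d$ranges$start[k] && r <= d$ranges$end[k])
            want <- want + 1L
      }
      got <- Filter(function(p) p$ref_domain_id == d$domain_id, parts)
      expect_equal(if (length(got)) length(got[[1]]$q_res) else 0L, want)
    }
  }
})

test_that("iterative alignment peels tandem copies with disjoint coverage", {
  query <- line_chain(200)
  # aligner that finds the domain at 1-100, then at 101-200, then nothing
  script <- list(1:100, 101:200)
  round <- 0L
  aligner <- function(remaining, hit_id) {
    round <<- round + 1L
    if (round > length(script)) return(NULL)
    hit_alignment("structure", hit_id, 15, script[[round]],
                  seq_along(script[[round]]))
  }
  hits <- iterative_structural_alignment(query, "dX", aligner)
  expect_length(hits, 2L)
  covs <- lapply(hits, `[[`, "q_res")
  expect_length(intersect(covs[[1]], covs[[2]]), 0L)

  expect_equal(iterative_structural_alignment(
    query, "dX", function(rem, id) NULL), list())
})

test_that("iterative alignment stops below the residue floor and propagates failures", {
  query <- line_chain(100)
  greedy <- function(remaining, hit_id) {
    take <- utils::head(remaining, 45)
    hit_alignment("structure", hit_id, 10, take, seq_along(take))
  }
  hits <- iterative_structural_alignment(query, "d", greedy)
  # 100 -> 55 -> 10 remaining (< 20): two rounds only
  expect_length(hits, 2L)
  all_cov <- unlist(lapply(hits, `[[`, "q_res"))
  expect_false(anyDuplicated(all_cov) > 0)

  expect_error(
    iterative_structural_alignment(query, "d",
                                   function(rem, id) stop("dali crashed")),
    "iteration 1")
})

test_that("acceptability filter applies per-source thresholds", {
  zero <- acceptability_config(0, 0, 0, 0)
  hits <- c(random_hits(10, 150, "sequence"), random_hits(10, 150, "structure"))
  expect_equal(filter_acceptable(hits, zero), hits)

  weak <- hit_alignment("sequence", "w", 10, 1:30, 1:30)
  expect_length(filter_acceptable(list(weak), acceptability_config()), 0L)

  set.seed(9)
  mixed <- c(random_hits(10, 150, "sequence"), random_hits(10, 150, "structure"))
  cfg <- acceptability_config(20, 10, 2, 20)
  got <- filter_acceptable(mixed, cfg)
  want <- Filter(function(h) {
    if (h$source == "sequence") h$score >= 20 && length(h$q_res) >= 10
    else h$score >= 2 && length(h$q_res) >= 20
  }, mixed)
  expect_equal(got, want)
})

test_that("hit grouping obeys the 20% overlap rule", {
  h1 <- hit_alignment("sequence", "a", 90, 1:50, 1:50)
  h2 <- hit_alignment("sequence", "b", 80, 1:50, 1:50)
  expect_length(group_hits(list(h1, h2)), 2L)     # identical coverage

  h3 <- hit_alignment("sequence", "c", 70, 60:100, 1:41)
  g <- group_hits(list(h1, h3))                   # disjoint coverage
  expect_length(g, 1L)
  expect_length(g[[1]]$hits, 2L)
})

test_that("hit grouping matches the independent greedy oracle", {
  set.seed(77)
  for (rep in 1:6) {
    hits <- random_hits(10, 200, "sequence")
    ord <- order(-vapply(hits, `[[`, 0, "score"),
                 vapply(hits, `[[`, "", "ref_domain_id"))
    ranked <- hits[ord]
    got <- group_hits(hits)
    want <- oracle_group_hits(lapply(ranked, `[[`, "q_res"))
    expect_length(got, length(want))
    for (g in seq_along(want)) {
      got_ids <- vapply(got[[g]]$hits, `[[`, "", "ref_domain_id")
      want_ids <- vapply(ranked[want[[g]]], `[[`, "", "ref_domain_id")
      expect_equal(got_ids, want_ids)
    }
  }
})

test_that("evidence channels carry scaled scores on coverage blocks", {
  h <- hit_alignment("sequence", "a", 90, 1:50, 1:50)
  ch <- build_evidence_channels(group_hits(list(h)), L = 100)
  expect_length(ch, 1L)
  expect_equal(ch[[1]][1:50, 1:50], matrix(0.9, 50, 50))
  expect_true(all(ch[[1]][51:100, ] == 0))
  expect_true(all(ch[[1]][, 51:100] == 0))

  # overlapping group members: elementwise max wins
  h1 <- hit_alignment("sequence", "a", 80, 1:40, 1:40)
  h2 <- hit_alignment("sequence", "b", 60, 90:120, 1:31)
  grp <- list(list(hits = list(h1, h2), coverage = sort(c(1:40, 90:120))))
  ch <- build_evidence_channels(grp, L = 150)
  expect_equal(ch[[1]][10, 20], 0.8)
  expect_equal(ch[[1]][95, 100], 0.6)
  expect_equal(ch[[1]], t(ch[[1]]))
})

test_that("the evidence channel cap keeps the 10 best groups", {
  # 15 hits with identical coverage: each fails the overlap tests -> 15 groups
  hits <- lapply(1:15, function(k)
    hit_alignment("structure", sprintf("h%02d", k), 40 - k, 1:10, 1:10))
  groups <- group_hits(hits)
  expect_length(groups, 15L)
  ch <- build_evidence_channels(groups, L = 50)
  expect_length(ch, 10L)
  # best group (z=39) leads; weakest retained beats every dropped one
  expect_equal(max(ch[[1]]), scale_hit_score(39, "structure"))
  expect_equal(max(ch[[10]]), scale_hit_score(30, "structure"))
})

test_that("structure scores squash as z/(z+10)", {
  expect_equal(scale_hit_score(10, "structure"), 0.5)
  expect_equal(scale_hit_score(0, "structure"), 0)
  expect_equal(scale_hit_score(55, "sequence"), 0.55)
})

test_that("hits TSV dialect round trips", {
  set.seed(14)
  hits <- c(random_hits(4, 120, "sequence"), random_hits(3, 120, "structure"))
  # one discontinuous mapping
  hits[[8]] <- hit_alignment("sequence", "disc", 75,
                             c(5:20, 41:60), c(101:116, 120:139))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, path)
  back <- read_hits_tsv(path)
  expect_length(back, length(hits))
  for (k in seq_along(hits)) {
    expect_equal(back[[k]]$q_res, hits[[k]]$q_res)
    expect_equal(back[[k]]$h_res, hits[[k]]$h_res)
    expect_equal(back[[k]]$score, hits[[k]]$score, tolerance = 1e-6)
    expect_equal(back[[k]]$source, hits[[k]]$source)
  }
})

test_that("hhr alignment blocks parse into residue mappings", {
  lines <- c(
    "Query         test_query",
    "Match_columns 120",
    "",
    " No Hit                             Prob E-value",
    "  1 e4xxxA1                         99.8 1.2E-30",
    "",
    "No 1",
    ">e4xxxA1 some classified domain",
    "Probab=99.80  E-value=1.2e-30  Score=120.00  Aligned_cols=12",
    "",
    "Q ss_pred             CCHHHHHHH",
    "Q test_query       10 AKLM-EFGH   17 (120)",
    "Q Consensus        10 aklm.efgh   17 (120)",
    "T e4xxxA1           3 AK-MWEFGH   10 (95)",
    "T ss_dssp             CCHHHHHHH",
    "")
  path <- withr::local_tempfile(fileext = ".hhr")
  writeLines(lines, path)
  hits <- read_hhr(path)
  expect_length(hits, 1L)
  h <- hits[[1]]
  expect_equal(h$ref_domain_id, "e4xxxA1")
  expect_equal(h$score, 99.8)
  expect_equal(h$source, "sequence")
  # columns: A-A, K-K, L-gap, M-M, gap-W, E-E, F-F, G-G, H-H
  expect_equal(h$q_res, c(10L, 11L, 13L, 14L, 15L, 16L, 17L))
  expect_equal(h$h_res, c(3L, 4L, 5L, 7L, 8L, 9L, 10L))
})

test_that("Dali block tables parse into structure hits", {
  df <- data.frame(hit_id = c("d1", "d1", "d2"), z = c(18.2, 18.2, 4.1),
                   q_start = c(5L, 40L, 80L), q_end = c(20L, 55L, 99L),
                   h_start = c(1L, 30L, 10L), h_end = c(16L, 45L, 29L))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- read_dali(path)
  expect_length(hits, 2L)
  expect_equal(hits[[1]]$q_res, c(5:20, 40:55))
  expect_equal(hits[[1]]$h_res, c(1:16, 30:45))
  expect_equal(hits[[1]]$score, 18.2)
  expect_equal(hits[[2]]$source, "structure")
})

test_that("domain definition tables parse and reject overlapping ranges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("domain_id\trange",
               "dA\tA:1-100,A:150-200",
               "dB\tA:101-149"), path)
  defs <- read_domain_defs(path)
  expect_length(defs, 2L)
  expect_equal(defs[[1]]$ranges$start, c(1L, 150L))
  writeLines(c("domain_id\trange", "bad\t1-50,40-80"), path)
  expect_error(read_domain_defs(path), "overlapping")
})

test_that("range strings round trip through residue sets", {
  expect_equal(range_string_to_residues("A:1-3,A:7"), c(1:3, 7L))
  expect_equal(residues_to_range_string(c(1:3, 7L)), "1-3,7")
  expect_equal(residues_to_range_string(c(5:10, 12:20), chain = "A"),
               "A:5-10,A:12-20")
  set.seed(3)
  for (rep in 1:10) {
    r <- sort(sample(1:300, 80))
    expect_equal(range_string_to_residues(residues_to_range_string(r)), r)
  }
})
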