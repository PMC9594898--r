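lib2 <- function(seed = 131) {
  set.seed(seed)
  consA <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
  consB <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                 collapse = "")
  repeat_library(c(famA = consA, famB = consB))
}

test_that("reads explained by called insertions are discarded, others kept", {
  g <- small_repeat_genome(copies = 0, contig_len = 60000)
  calls <- tibble::tibble(contig = "contig_01", site = 30000L, called = TRUE)
  verbatim <- extract_interval(g, "contig_01", 30000L, 30350L)
  far <- extract_interval(g, "contig_01", 5000L, 5350L)
  reads <- tibble::tibble(id = c("hit", "far"), seq = c(verbatim, far))
  out <- discard_called(reads, calls, g, flank = 2000)
  expect_equal(out$in_called, c(TRUE, FALSE))

  # empty call set retains everything
  none <- discard_called(reads, calls[0, ], g)
  expect_false(any(none$in_called))

  # a 15%-diverged copy of the flank stays below the identity gate
  set.seed(132)
  b <- strsplit(verbatim, "")[[1]]
  hit <- which(stats::runif(length(b)) < 0.15)
  b[hit] <- vapply(b[hit], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  diverged <- paste(b, collapse = "")
  # oracle: global pairwise identity of the diverged read vs the flank
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(diverged), Biostrings::DNAString(verbatim),
    type = "global")
  expect_lt(Biostrings::pid(al) / 100, 0.9)
  out2 <- discard_called(tibble::tibble(id = "div", seq = diverged),
                         calls, g)
  expect_false(out2$in_called)
})

test_that("family assignment picks the best-scoring family, ties lexicographic", {
  lib <- lib2()
  readA <- substr(lib$families[["famA"]], 301, 800)  # 500 bp of famA
  set.seed(133)
  noise <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
  reads <- tibble::tibble(id = c("a", "junk"), seq = c(readA, noise))
  got <- assign_repeat(reads, lib, min_score = 30)
  expect_equal(got$family, c("famA", NA))

  # tie: two families with identical consensus; "A_first" wins over "B_second"
  tie_lib <- repeat_library(c(B_second = lib$families[["famA"]],
                              A_first = lib$families[["famA"]]))
  tie <- assign_repeat(tibble::tibble(id = "t", seq = readA), tie_lib, 30)
  expect_equal(tie$family, "A_first")

  # scores agree with direct alignment against every family
  direct <- vapply(lib$families, function(f) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(readA), Biostrings::DNAString(f),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE),
      gapOpening = 1, gapExtension = 1))
  }, numeric(1))
  expect_equal(got$assign_score[1], max(direct))

  # an external hit table satisfies the same contract
  hits <- tibble::tibble(read_id = c("a", "a", "junk"),
                         family = c("famA", "famB", "famB"),
                         score = c(100, 40, 10))
  ext <- assign_repeat(reads, lib, min_score = 30, hits = hits)
  expect_equal(ext$family, c("famA", NA))
})

test_that("within-family identity clustering separates diverged copies", {
  lib <- lib2()
  cons <- lib$families[["famA"]]
  prefix_reads <- function(base, n, label) {
    tibble::tibble(
      id = sprintf("%s_%02d", label, seq_len(n)),
      seq = vapply(seq_len(n), function(i) substr(base, 1, 250 + 10 * i),
                   character(1)),
      family = "famA"
    )
  }
  set.seed(134)
  b <- strsplit(cons, "")[[1]]
  hit <- which(stats::runif(length(b)) < 0.2)
  b[hit] <- vapply(b[hit], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  diverged <- paste(b, collapse = "")

  reads <- dplyr::bind_rows(prefix_reads(cons, 5, "orig"),
                            prefix_reads(diverged, 5, "div"))
  out <- cluster_by_identity(reads)
  expect_equal(dplyr::n_distinct(out$rep_cluster), 2)
  expect_equal(dplyr::n_distinct(out$rep_cluster[grepl("orig", out$id)]), 1)

  # oracle: connected components of the pairwise identity >= 0.9 graph
  n <- nrow(reads)
  adj <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    adj[i, j] <- seq_identity(reads$seq[i], reads$seq[j]) >= 0.9
  }
  expect_equal(length(unique(oracle_components(adj))), 2)

  single <- cluster_by_identity(tibble::tibble(id = "solo",
                                               seq = substr(cons, 1, 300),
                                               family = "famA"))
  expect_equal(single$rep_cluster, "famA_c01")
})

test_that("the 50% coverage rule and shape filter gate unanchored calls", {
  lib <- lib2()
  cons <- lib$families[["famA"]]
  mk_cluster <- function(n, label = "r", from = 500) {
    tibble::tibble(
      id = sprintf("%s%02d", label, seq_len(n)),
      seq = vapply(seq_len(n), function(i)
        substr(cons, from, from + 260 + 7 * i), character(1)),
      family = "famA", rep_cluster = "famA_c01"
    )
  }
  cfg <- pipeline_config()
  # anchored dedup counts {10, 20, 30} -> mean 20 -> threshold 10
  expect_true(call_unanchored(mk_cluster(10), lib, mean(c(10, 20, 30)), cfg)$called)
  expect_false(call_unanchored(mk_cluster(9), lib, mean(c(10, 20, 30)), cfg)$called)

  # empty cluster set -> no peaks
  empty <- call_unanchored(mk_cluster(0)[0, ], lib, 20, cfg)
  expect_equal(nrow(empty), 0)

  # bimodal pileup on the consensus fails the shape filter despite coverage
  two_blocks <- dplyr::bind_rows(
    mk_cluster(8, "left", from = 1),
    mk_cluster(8, "right", from = 1600)
  ) |> dplyr::mutate(rep_cluster = "famA_c01")
  res <- call_unanchored(two_blocks, lib, 20, cfg)
  expect_gte(res$dedup_count, res$coverage_threshold[1])
  expect_gte(res$rss, 1)
  expect_false(res$called)

  # putative flag is always set
  expect_true(all(call_unanchored(mk_cluster(10), lib, 20, cfg)$putative))
})

test_that("a planted in-repeat insertion yields exactly one family peak", {
  fam <- repeat_families("LINE_sim", 2000, 10, 0)
  g <- build_synthetic_genome(fam, c(120000, 120000), seed = 141)
  g <- plant_insertions(g, 4, fraction_in_repeats = 0, seed = 142)
  g <- plant_insertions(g, 1, fraction_in_repeats = 1, repeat_margin = 450,
                        seed = 143)
  cfg_sim <- read_sim_config(length_mean = 280, length_sd = 20,
                             reads_per_site = 8, seed = 144)
  sim <- simulate_junction_reads(g, cfg_sim)
  run <- run_pipeline(sim$reads, g, default_structure(cfg_sim),
                      pipeline_config(min_len = 100))
  expect_equal(sum(run$calls$called), 4)
  expect_equal(sum(run$unanchored$called), 1)
  expect_equal(run$unanchored$family[run$unanchored$called], "LINE_sim")
  # no peak for a family with zero assigned reads
  expect_false("famB" %in% run$unanchored$family)
})
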