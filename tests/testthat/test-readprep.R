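make_read <- function(id, seq, q = 15) {
  tibble::tibble(id = id, seq = seq,
                 qual = vapply(nchar(seq), function(n)
                   paste(rep(intToUtf8(q + 33), n), collapse = ""), character(1)))
}

test_that("quality and length filters are strictly exclusive", {
  reads <- dplyr::bind_rows(
    make_read("len200_q15", strrep("A", 200), 15),   # length == 200: out
    make_read("len201_q10", strrep("A", 201), 10),   # mean q == 10: out
    make_read("len201_q11", strrep("A", 201), 11),   # both strict: in
    make_read("len500_q30", strrep("A", 500), 30)
  )
  kept <- quality_length_filter(reads)
  expect_setequal(kept$id, c("len201_q11", "len500_q30"))
  empty <- quality_length_filter(reads[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("noiseless extraction recovers every planted UMI and fragment", {
  g <- small_repeat_genome(copies = 0, contig_len = 50000)
  g <- plant_insertions(g, 4, seed = 61)
  cfg <- read_sim_config(reads_per_site = 5, length_mean = 260,
                         length_sd = 15, seed = 62)
  sim <- simulate_junction_reads(g, cfg)
  proc <- demultiplex_and_extract(sim$reads, default_structure(cfg))
  expect_true(all(proc$status == "ok"))
  expect_identical(proc$umi, sim$truth$umi)
  # fragment must equal the planted genomic flank, payload-first
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    flank <- if (tr$strand == "+") {
      extract_interval(g, tr$contig, tr$site, tr$site + tr$flank_len)
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        extract_interval(g, tr$contig, tr$site - tr$flank_len, tr$site))))
    }
    expect_identical(proc$fragment[i], flank)
  }
})

test_that("element matching honours the per-element edit budget", {
  adapter <- "ACGTGGTCATTACGCAGGTA"  # 20 nt -> floor(0.1 * 20) = 2 edits
  st <- read_structure(adapter, c(bc = "ACGTACGTAC"), 12,
                       "TTGGCCAAGGTTCCAAGGTT", max_error_fraction = 0.10)
  umi <- strrep("T", 12)
  tail <- paste0("ACGTACGTAC", umi, "TTGGCCAAGGTTCCAAGGTT", strrep("G", 80))
  mutate_at <- function(seq, k) {
    b <- strsplit(seq, "")[[1]]
    pos <- c(3, 9, 15)[seq_len(k)]
    b[pos] <- vapply(b[pos], function(x) setdiff(c("A", "C", "G", "T"), x)[1],
                     character(1))
    paste(b, collapse = "")
  }
  for (k in 0:3) {
    ad_mut <- mutate_at(adapter, k)
    # exhaustive oracle: the edit distance really is k
    expect_equal(as.integer(utils::adist(ad_mut, adapter)), k)
    res <- demultiplex_and_extract(make_read("r", paste0(ad_mut, tail)), st)
    if (k <= 2) {
      expect_equal(res$status, "ok", info = paste("k =", k))
    } else {
      expect_equal(res$status, "no adapter")
    }
  }
  # missing payload end is rejected with its own reason
  res <- demultiplex_and_extract(
    make_read("r", paste0(adapter, "ACGTACGTAC", umi, strrep("G", 80))), st)
  expect_equal(res$status, "no payload")
})

test_that("UMI clustering matches a connected-components oracle on a hub set", {
  base_frag <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  other_frag <- substr(strrep("GATTACA", 20), 1, 100)
  flip <- function(u, pos) {
    b <- strsplit(u, "")[[1]]
    b[pos] <- setdiff(c("A", "C", "G", "T"), b[pos])[1]
    paste(b, collapse = "")
  }
  u1 <- "AAAAAAAAAAAA"; u2 <- "CCCCCCCCCCCC"; u3 <- "GGGGGGGGGGGG"
  proc <- tibble::tibble(
    id = sprintf("r%02d", 1:10),
    status = "ok",
    barcode_id = "bc01",
    umi = c(u1, flip(u1, 1), flip(u1, 12),      # hub + two spokes
            u2, flip(u2, 5),                    # hub + spoke
            u3, u3,                             # identical pair
            "TTTTTTTTTTTT",                     # singleton
            u1, u2),                            # same UMIs, other locus
    fragment = c(rep(base_frag, 8), other_frag, other_frag),
    mean_q = c(30, 20, 20, 30, 20, 30, 29, 30, 30, 30)  # hubs first
  )
  cl <- cluster_umis(proc)
  expect_equal(sum(cl$size), 10)

  # oracle: connected components under (umi dist <= 1 AND identity >= 0.9)
  adj <- matrix(FALSE, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    same_locus <- proc$fragment[i] == proc$fragment[j]
    adj[i, j] <- utils::adist(proc$umi[i], proc$umi[j]) <= 1 && same_locus
  }
  comp <- oracle_components(adj)
  got <- integer(10)
  for (k in seq_len(nrow(cl))) got[match(cl$member_ids[[k]], proc$id)] <- k
  # identical partitions (up to label renaming)
  expect_equal(length(unique(comp)), nrow(cl))
  expect_true(all(tapply(got, comp, dplyr::n_distinct) == 1))
})

test_that("duplicating a processed read grows one cluster and adds none", {
  proc <- tibble::tibble(
    id = c("a", "b", "c"),
    status = "ok", barcode_id = "bc01",
    umi = c("ACACACACACAC", "GTGTGTGTGTGT", "TTTTTTTTAAAA"),
    fragment = c(strrep("ACGGT", 30), strrep("TTGCA", 30), strrep("GGATC", 30)),
    mean_q = c(30, 25, 20)
  )
  base <- cluster_umis(proc)
  for (k in c(1, 7, 50)) {
    dup <- proc[rep(2, k), ]
    dup$id <- sprintf("b_dup%02d", seq_len(k))
    grown <- cluster_umis(dplyr::bind_rows(proc, dup))
    expect_equal(nrow(grown), nrow(base))
    expect_equal(sort(grown$size, decreasing = TRUE)[1], 1 + k)
    expect_equal(sum(grown$size), 3 + k)
  }
})

test_that("plurality consensus equals a column-majority oracle", {
  expect_identical(plurality_consensus(rep("ACGTACGT", 5)), "ACGTACGT")

  # single substitution in one of three members is outvoted
  expect_identical(
    plurality_consensus(c("AAAAAAAAAA", "AAAAAAAAAA", "AAAATAAAAA")),
    "AAAAAAAAAA"
  )

  set.seed(71)
  truth <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
  noisy <- vapply(1:20, function(i) {
    b <- strsplit(truth, "")[[1]]
    hit <- which(stats::runif(200) < 0.05)
    b[hit] <- vapply(b[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(b, collapse = "")
  }, character(1))
  cons <- plurality_consensus(noisy)

  # oracle: per-column plurality over the (equal-length) members, ties
  # broken alphabetically as documented for equal weights
  mat <- do.call(rbind, strsplit(noisy, ""))
  oracle <- paste(apply(mat, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[tb == max(tb)][1]
  }), collapse = "")
  expect_identical(cons, oracle)
  expect_equal(hamming(cons, truth), hamming(oracle, truth))
})

test_that("reads are partitioned across rejection bins and clusters", {
  g <- small_repeat_genome(copies = 0, contig_len = 40000)
  g <- plant_insertions(g, 3, seed = 81)
  cfg <- read_sim_config(reads_per_site = 6, length_mean = 260, seed = 82)
  sim <- simulate_junction_reads(g, cfg)
  junk <- make_read(sprintf("junk%02d", 1:5),
                    vapply(1:5, function(i) {
                      set.seed(90 + i)
                      paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                            collapse = "")
                    }, character(1)), 20)
  reads <- dplyr::bind_rows(sim$reads[, c("id", "seq", "qual")], junk)
  proc <- demultiplex_and_extract(reads, default_structure(cfg))
  clusters <- cluster_umis(proc)
  n_rejected <- sum(proc$status != "ok")
  expect_gt(n_rejected, 0)
  expect_equal(n_rejected + sum(clusters$size), nrow(reads))
  expect_true(all(c("no adapter") %in%
                    extraction_summary(proc)$status[
                      extraction_summary(proc)$n > 0]))
})
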