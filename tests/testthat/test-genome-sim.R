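test_that("repeat planting: empty families, zero divergence, divergence load", {
  g0 <- build_synthetic_genome(NULL, 20000, seed = 1)
  expect_equal(nrow(g0$repeats), 0)
  expect_equal(sum(Biostrings::width(g0$contigs)), 20000)

  g2 <- build_synthetic_genome(repeat_families("fam", 800, 2, 0),
                               40000, seed = 2)
  seqs <- vapply(seq_len(2), function(i) {
    r <- g2$repeats[i, ]
    extract_interval(g2, r$contig, r$start, r$end)
  }, character(1))
  expect_identical(seqs[1], seqs[2])
  expect_identical(seqs[1], unname(g2$consensi[["fam"]]))

  # divergence 0.05 over 1000 bp: per-copy Hamming distance to consensus
  # within 3 binomial SDs of 50, counted base by base
  gd <- build_synthetic_genome(repeat_families("div", 1000, 6, 0.05),
                               60000, seed = 3)
  dists <- vapply(seq_len(6), function(i) {
    r <- gd$repeats[i, ]
    hamming(extract_interval(gd, r$contig, r$start, r$end),
            unname(gd$consensi[["div"]]))
  }, numeric(1))
  sd3 <- 3 * sqrt(1000 * 0.05 * 0.95)
  expect_true(all(abs(dists - 50) <= sd3))
})

test_that("genome construction is deterministic and annotation lies in bounds", {
  fam <- repeat_families(c("a", "b"), c(500, 300), c(3, 4), c(0.02, 0.1))
  g1 <- build_synthetic_genome(fam, c(x = 30000, y = 30000), seed = 7)
  g2 <- build_synthetic_genome(fam, c(x = 30000, y = 30000), seed = 7)
  expect_identical(as.character(g1$contigs), as.character(g2$contigs))
  expect_identical(g1$repeats, g2$repeats)
  lens <- stats::setNames(Biostrings::width(g1$contigs), names(g1$contigs))
  expect_true(all(g1$repeats$start >= 0))
  expect_true(all(g1$repeats$end <= lens[g1$repeats$contig]))
  expect_true(all(g1$repeats$start < g1$repeats$end))
  expect_error(build_synthetic_genome(repeat_families("big", 5000, 10, 0),
                                      20000, seed = 1),
               "do not fit")
})

test_that("plant_insertions places the requested fraction inside repeats", {
  g <- build_synthetic_genome(repeat_families("fam", 1000, 20, 0),
                              c(1000000), seed = 11)
  g0 <- plant_insertions(g, 0, seed = 1)
  expect_equal(nrow(g0$insertions), 0)

  in_repeat_scan <- function(genome) {
    vapply(genome$insertions$site, function(s) {
      any(genome$repeats$start <= s & s < genome$repeats$end)
    }, logical(1))
  }

  g1 <- plant_insertions(g, 10, fraction_in_repeats = 1, seed = 2)
  expect_equal(sum(in_repeat_scan(g1)), 10)

  g5 <- plant_insertions(g, 50, fraction_in_repeats = 0.5,
                         min_distance = 200, seed = 3)
  expect_equal(nrow(g5$insertions), 50)
  expect_equal(sum(in_repeat_scan(g5)), 25)
  expect_equal(anyDuplicated(paste(g5$insertions$contig, g5$insertions$site)), 0)
})

test_that("noiseless junction reads are exact structure + flank concatenations", {
  g <- small_repeat_genome(copies = 0, contig_len = 50000)
  g <- plant_insertions(g, 3, seed = 21)
  cfg <- read_sim_config(length_mean = 250, length_sd = 20,
                         reads_per_site = 2, seed = 22)
  sim <- simulate_junction_reads(g, cfg)
  expect_equal(nrow(sim$reads), 6)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    flank <- if (tr$strand == "+") {
      extract_interval(g, tr$contig, tr$site, tr$site + tr$flank_len)
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        extract_interval(g, tr$contig, tr$site - tr$flank_len, tr$site)
      )))
    }
    expected <- paste0(cfg$adapter, cfg$barcodes[[1]], tr$umi,
                       cfg$payload_end, flank)
    if (tr$flipped) {
      expected <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(expected)))
    }
    expect_identical(sim$reads$seq[sim$reads$id == tr$read_id], expected)
  }
})

test_that("read counts and flank-length moments match the configured model", {
  g <- small_repeat_genome(copies = 0, contig_len = 60000)
  # inject a central site so truncation cannot distort the length moments
  g$insertions <- tibble::tibble(payload_id = "p1", contig = "contig_01",
                                 site = 30000L, strand = "+",
                                 in_repeat = FALSE)
  cfg <- read_sim_config(length_mean = 1000, length_sd = 25,
                         n_reads = 500, seed = 31)
  expect_equal(nrow(simulate_junction_reads(g, cfg)$reads), 500)

  cfg2 <- read_sim_config(length_mean = 1000, length_sd = 25,
                          n_reads = 10000, seed = 32)
  fl <- simulate_junction_reads(g, cfg2)$truth$flank_len
  expect_lt(abs(mean(fl) - 1000) / 1000, 0.01)
  expect_lt(abs(sd(fl) - 25) / 25, 0.10)
})

test_that("position reads follow the length model and replicate layout", {
  g <- small_repeat_genome(copies = 0, contig_len = 80000)
  sim <- simulate_position_reads(g, n_sites = 100, replicates = 10,
                                 length_mean = 40, length_sd = 0, seed = 41)
  expect_equal(nrow(sim$truth), 1000)
  # sd = 0: every read is exactly length_mean unless clipped at a contig edge
  key <- paste(sim$truth$replicate, sim$truth$site_id)
  rkey <- paste(sim$reads$replicate, sim$reads$site_id)
  central <- sim$truth$position > 50 & sim$truth$position < 79950
  lens <- nchar(sim$reads$seq)[match(key, rkey)]
  expect_true(all(lens[central] == 40))

  sim2 <- simulate_position_reads(g, n_sites = 1000, replicates = 1,
                                  length_mean = 250, length_sd = 10,
                                  reads_per_site = 1, seed = 42)
  lens2 <- nchar(sim2$reads$seq)
  pos <- sim2$truth$position[match(sim2$reads$site_id, sim2$truth$site_id)]
  ok <- pos > 300 & pos < 79700  # away from contig edges
  expect_lt(abs(sd(lens2[ok]) - 10) / 10, 0.10)
})

test_that("score_detection applies the tolerance boundary exactly", {
  truth <- tibble::tibble(contig = "c", position = c(1000L, 5000L))
  hit_at <- function(site) tibble::tibble(contig = "c", site = site)

  expect_true(all(score_detection(truth, hit_at(c(1000, 5000)))$detected))
  expect_false(any(score_detection(truth, hit_at(integer(0)))$detected))
  # boundary: +tolerance detected, +tolerance+1 not (checked by enumeration)
  for (tol in c(0, 5, 20)) {
    s <- score_detection(truth[1, ], hit_at(1000L + tol), tolerance = tol)
    expect_true(s$detected)
    s2 <- score_detection(truth[1, ], hit_at(1000L + tol + 1L), tolerance = tol)
    expect_false(s2$detected)
    expect_equal(abs(1000 - (1000 + tol + 1)) > tol, !s2$detected)
  }
  # shrinking tolerance never gains detections
  set.seed(43)
  calls <- tibble::tibble(contig = "c",
                          site = sample.int(10000, 50))
  truth2 <- tibble::tibble(contig = "c", position = sample.int(10000, 30))
  rates <- vapply(c(100, 50, 20, 10, 5, 0), function(tol) {
    mean(score_detection(truth2, calls, tolerance = tol)$detected)
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("pcr_amplify duplicates molecules and records their identity", {
  g <- small_repeat_genome(copies = 0, contig_len = 30000)
  g <- plant_insertions(g, 2, seed = 51)
  sim <- simulate_junction_reads(g, read_sim_config(reads_per_site = 3, seed = 52))
  amp <- pcr_amplify(sim, max_factor = 10, seed = 53)
  expect_gte(nrow(amp$reads), nrow(sim$reads))
  expect_equal(n_distinct(amp$truth$molecule_id), nrow(sim$reads))
  # duplicates are exact copies of their molecule
  one <- amp$truth$molecule_id[1]
  dup_seqs <- amp$reads$seq[amp$truth$molecule_id == one]
  expect_equal(n_distinct(dup_seqs), 1)
})
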