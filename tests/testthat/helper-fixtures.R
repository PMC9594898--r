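# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately use a different computational route than the
# implementation they check.

suppressPackageStartupMessages({
  library(dplyr)
  library(purrr)
})

# structure matching read_sim_config defaults
default_structure <- function(cfg = read_sim_config()) {
  read_structure(
    adapter = cfg$adapter, barcodes = cfg$barcodes,
    umi_length = cfg$umi_length, payload_end = cfg$payload_end
  )
}

# a small genome with one zero-divergence repeat family
small_repeat_genome <- function(copies = 4, copy_len = 1500,
                                contig_len = c(60000, 60000), seed = 101) {
  build_synthetic_genome(
    repeat_families("repfam", copy_len, copies, 0),
    contig_len, seed = seed
  )
}

extract_interval <- function(genome, contig, start, end) {
  substr(as.character(genome$contigs[[contig]]), start + 1L, end)
}

# direct base-by-base mismatch count between equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force RSS grid enumeration via stats::dbeta (the implementation
# computes log densities with lgamma in chunked matrix form)
oracle_beta_grid <- function(coverage, step = 0.1, bounds = c(0.1, 50)) {
  L <- length(coverage)
  x <- (seq_len(L) - 0.5) / L
  d <- coverage * L / sum(coverage)
  grid <- seq(bounds[1], bounds[2], by = step)
  nb <- length(grid)
  xx <- rep(x, times = nb)
  bb <- rep(grid, each = L)
  best <- Inf
  for (a in grid) {
    f <- stats::dbeta(xx, a, bb)
    rss <- colSums(matrix((rep(d, times = nb) - f)^2, nrow = L)) / L
    m <- min(rss)
    if (m < best) best <- m
  }
  best
}

# all-pairs Mann-Whitney AUC
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# connected components over an adjacency predicate matrix
oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# sweep-line interval union allowing gaps <= max_gap (checks form_peaks)
oracle_union_groups <- function(starts, ends, max_gap = 0) {
  ord <- order(starts, ends)
  group <- integer(length(starts))
  cur <- 0L
  cur_end <- -Inf
  for (i in ord) {
    if (starts[i] > cur_end + max_gap) {
      cur <- cur + 1L
      cur_end <- ends[i]
    } else {
      cur_end <- max(cur_end, ends[i])
    }
    group[i] <- cur
  }
  group
}

# seed derivation mirrored from the package (kept in sync manually so the
# LOD sampling oracle can replay the pipeline's binomial draws)
oracle_child_seed <- function(seed, offset) {
  (as.integer(seed) * 1103L + as.integer(offset) * 12289L) %% 2147483562L
}
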