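# Putative peak calling in repetitive regions, for reads that cannot be
# uniquely anchored: discard reads explained by already-called insertions,
# classify the rest to a repeat family, cluster within family by identity,
# then apply the coverage (50% of anchored mean) and shape filters.

#' Build a repeat family library
#'
#' @param consensi Named character vector or named
#'   [Biostrings::DNAStringSet] of family consensus sequences, or a
#'   `synthetic_genome` (its planted family consensuses are used).
#' @return A list of class `repeat_library` with element `families`
#'   (named character).
#' @export
repeat_library <- function(consensi) {
  if (inherits(consensi, "synthetic_genome")) consensi <- consensi$consensi
  if (inherits(consensi, "DNAStringSet")) {
    consensi <- stats::setNames(as.character(consensi), names(consensi))
  }
  if (length(consensi) == 0 || is.null(names(consensi)) ||
      any(!nzchar(names(consensi))) || anyDuplicated(names(consensi))) {
    abort("repeat library needs uniquely named, nonempty consensus sequences")
  }
  if (any(nchar(consensi) == 0)) abort("consensus sequences must be nonempty")
  structure(list(families = consensi), class = "repeat_library")
}

# local alignment score (match +1, mismatch -1, gaps -1) of read vs subject
local_align <- function(read, subject) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = identity_submat(),
    gapOpening = 1, gapExtension = 1
  )
  list(score = Biostrings::score(al),
       start = BiocGenerics::start(Biostrings::subject(al)),
       end = BiocGenerics::end(Biostrings::subject(al)),
       nmatch = Biostrings::nmatch(al),
       width = Biostrings::nchar(al))
}

#' Discard unanchored reads that belong to called insertions
#'
#' Each unanchored read is aligned against the reference flank (`flank` bp
#' per side) of every called insertion; reads matching any flank with
#' identity >= `min_identity` over at least half their length are flagged as
#' already explained and discarded from the unanchored pool.
#'
#' @param reads Tibble of unanchored fragments (`id`/`cluster_id` +
#'   `seq`/`fragment`/`consensus` columns).
#' @param calls Insertion-call tibble (rows with `called == TRUE` are used;
#'   columns `contig`, `site`).
#' @param genome Reference (`synthetic_genome` or `DNAStringSet`).
#' @param flank Flank half-width in bp (default 2000).
#' @param min_identity Identity threshold (default 0.9).
#' @param min_cover Minimum fraction of the read length that must align
#'   (default 0.5).
#' @return The read tibble with a logical `in_called` column; retained reads
#'   are the rows with `in_called == FALSE`.
#' @export
discard_called <- function(reads, calls, genome, flank = 2000,
                           min_identity = 0.9, min_cover = 0.5) {
  contigs <- if (inherits(genome, "synthetic_genome")) genome$contigs else genome
  id_col <- intersect(c("cluster_id", "query_id", "id"), names(reads))[1]
  seq_col <- intersect(c("consensus", "fragment", "seq"), names(reads))[1]
  if ("called" %in% names(calls)) calls <- filter(calls, .data$called)
  if (nrow(calls) == 0 || nrow(reads) == 0) {
    reads$in_called <- rep(FALSE, nrow(reads))
    return(reads)
  }
  contig_chr <- stats::setNames(as.character(contigs), names(contigs))
  flanks <- vapply(seq_len(nrow(calls)), function(i) {
    cs <- contig_chr[[calls$contig[i]]]
    substr(cs, max(calls$site[i] - flank + 1L, 1L),
           min(calls$site[i] + flank, nchar(cs)))
  }, character(1))
  flank_dna <- lapply(flanks, Biostrings::DNAString)

  # a read matching a flank at >= 0.9 identity over >= half its length must
  # share an exact stretch of ~15 bp with it; exact-seed screening avoids a
  # full local alignment against every flank for clearly unrelated reads
  seed_k <- 15L
  seeds_of <- function(sq) {
    L <- nchar(sq)
    if (L < seed_k) return(sq)
    offs <- unique(c(1L, as.integer((L - seed_k) / 2) + 1L, L - seed_k + 1L))
    vapply(offs, function(o) substr(sq, o, o + seed_k - 1L), character(1))
  }
  seed_hit <- function(seeds, fl) {
    any(vapply(seeds, function(s)
      length(Biostrings::matchPattern(s, fl)) > 0, logical(1)))
  }

  check_one <- function(sq) {
    for (ori_seq in c(sq, revcomp(sq))) {
      seeds <- seeds_of(ori_seq)
      for (fi in seq_along(flank_dna)) {
        if (!seed_hit(seeds, flank_dna[[fi]])) next
        hit <- local_align(ori_seq, flanks[[fi]])
        if (hit$width >= min_cover * nchar(sq) &&
            hit$nmatch / hit$width >= min_identity) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  reads$in_called <- vapply(unname(reads[[seq_col]]), check_one, logical(1),
                            USE.NAMES = FALSE)
  reads
}

#' Assign unanchored reads to repeat families
#'
#' Backend contract: either a precomputed hit table (e.g. from an external
#' profile-HMM search; columns `read_id`, `family`, `score`) is consumed, or
#' the built-in classifier scores each read by local alignment against every
#' family consensus and assigns the best family with score >= `min_score`
#' (ties broken lexicographically by family name). Reads below threshold are
#' left unassigned (`family = NA`).
#'
#' @param reads Tibble of retained unanchored fragments.
#' @param library A [repeat_library()].
#' @param min_score Minimum alignment score (default 30).
#' @param hits Optional external hit table.
#' @return The read tibble with `family` and `assign_score` columns.
#' @export
assign_repeat <- function(reads, library, min_score = 30, hits = NULL) {
  stopifnot(inherits(library, "repeat_library"))
  id_col <- intersect(c("cluster_id", "query_id", "id"), names(reads))[1]
  seq_col <- intersect(c("consensus", "fragment", "seq"), names(reads))[1]
  if (nrow(reads) == 0) {
    reads$family <- character(0)
    reads$assign_score <- numeric(0)
    return(reads)
  }
  if (!is.null(hits)) {
    best <- hits |>
      filter(.data$score >= min_score) |>
      group_by(.data$read_id) |>
      arrange(desc(.data$score), .data$family, .by_group = TRUE) |>
      slice(1) |>
      ungroup()
    reads$family <- best$family[match(reads[[id_col]], best$read_id)]
    reads$assign_score <- best$score[match(reads[[id_col]], best$read_id)]
    return(reads)
  }
  fam_names <- sort(names(library$families))
  res <- map(reads[[seq_col]], function(sq) {
    scores <- vapply(fam_names, function(f) {
      max(local_align(sq, library$families[[f]])$score,
          local_align(revcomp(sq), library$families[[f]])$score)
    }, numeric(1))
    best <- which.max(scores)  # first max = lexicographically first family
    if (scores[best] < min_score) {
      list(family = NA_character_, score = max(scores))
    } else {
      list(family = fam_names[best], score = scores[best])
    }
  })
  reads$family <- map_chr(res, "family")
  reads$assign_score <- map_dbl(res, "score")
  reads
}

#' Cluster same-family reads by pairwise identity
#'
#' Greedy centroid clustering within each repeat family: reads are visited
#' longest first (ties by id) and join the first centroid with ends-free
#' identity >= `min_identity`, otherwise found a new cluster. Determines
#' whether a family's reads belong to one putative peak or several.
#'
#' @param reads Assigned read tibble (non-NA `family`).
#' @param min_identity Identity threshold (default 0.9).
#' @return The read tibble with a `rep_cluster` column
#'   (`<family>_c<number>`).
#' @export
cluster_by_identity <- function(reads, min_identity = 0.9) {
  id_col <- intersect(c("cluster_id", "query_id", "id"), names(reads))[1]
  seq_col <- intersect(c("consensus", "fragment", "seq"), names(reads))[1]
  reads$rep_cluster <- NA_character_
  for (fam in unique(stats::na.omit(reads$family))) {
    idx <- which(reads$family == fam)
    ord <- idx[order(-nchar(reads[[seq_col]][idx]), reads[[id_col]][idx])]
    cent <- integer(0)
    for (i in ord) {
      joined <- FALSE
      for (ci in seq_along(cent)) {
        if (seq_identity(reads[[seq_col]][i],
                         reads[[seq_col]][cent[ci]]) >= min_identity) {
          reads$rep_cluster[i] <- sprintf("%s_c%02d", fam, ci)
          joined <- TRUE
          break
        }
      }
      if (!joined) {
        cent <- c(cent, i)
        reads$rep_cluster[i] <- sprintf("%s_c%02d", fam, length(cent))
      }
    }
  }
  reads
}

#' Call putative unanchored peaks
#'
#' A family cluster becomes a putative peak when (i) its deduplicated
#' coverage (number of member UMI clusters) is at least
#' `unanchored_coverage_fraction` times the mean deduplicated coverage of
#' the anchored insertion calls (inclusive; a configured floor stands in
#' when no anchored calls exist), and (ii) the pileup of its members on the
#' family consensus coordinates passes the beta shape filter. Unanchored
#' peaks are always flagged putative: they name a repeat family, not a
#' genomic coordinate.
#'
#' @param reads Clustered read tibble from [cluster_by_identity()].
#' @param library A [repeat_library()].
#' @param anchored_mean_coverage Mean `dedup_count` of the anchored calls.
#' @param config A [pipeline_config()].
#' @return Tibble with one row per family cluster: `family`, `rep_cluster`,
#'   `n_members`, `dedup_count`, `coverage_threshold`, `rss`, `called`,
#'   `putative` (always TRUE).
#' @export
call_unanchored <- function(reads, library, anchored_mean_coverage,
                            config = pipeline_config()) {
  stopifnot(inherits(library, "repeat_library"))
  if (is.null(anchored_mean_coverage) || !is.finite(anchored_mean_coverage) ||
      anchored_mean_coverage <= 0) {
    anchored_mean_coverage <- config$unanchored_coverage_floor /
      config$unanchored_coverage_fraction
  }
  thr <- config$unanchored_coverage_fraction * anchored_mean_coverage
  seq_col <- intersect(c("consensus", "fragment", "seq"), names(reads))[1]
  reads <- filter(reads, !is.na(.data$rep_cluster))
  if (nrow(reads) == 0) {
    return(tibble(family = character(), rep_cluster = character(),
                  n_members = integer(), dedup_count = integer(),
                  coverage_threshold = numeric(), rss = numeric(),
                  called = logical(), putative = logical()))
  }
  groups <- split(seq_len(nrow(reads)), reads$rep_cluster)
  rows <- imap(groups, function(idx, cl) {
    fam <- reads$family[idx[1]]
    dedup <- length(idx)
    rss <- NA_real_
    pass_shape <- FALSE
    if (dedup >= thr) {
      cov <- consensus_pileup(reads[[seq_col]][idx], library$families[[fam]])
      if (!is.null(cov) && length(cov) >= 3) {
        rss <- beta_shape_rss(cov)$rss
        pass_shape <- rss < config$rss_threshold
      }
    }
    tibble(family = fam, rep_cluster = cl, n_members = length(idx),
           dedup_count = dedup, coverage_threshold = thr, rss = rss,
           called = dedup >= thr && pass_shape, putative = TRUE)
  })
  arrange(list_rbind(rows), .data$family, .data$rep_cluster)
}

# pile member reads onto family-consensus coordinates via local alignment
consensus_pileup <- function(seqs, consensus) {
  iv <- map(seqs, function(sq) {
    h1 <- local_align(sq, consensus)
    h2 <- local_align(revcomp(sq), consensus)
    h <- if (h1$score >= h2$score) h1 else h2
    if (h$score <= 0) NULL else c(h$start, h$end)
  })
  iv <- iv[!vapply(iv, is.null, logical(1))]
  if (length(iv) == 0) return(NULL)
  lo <- min(map_int(iv, function(v) as.integer(v[1])))
  hi <- max(map_int(iv, function(v) as.integer(v[2])))
  cov <- integer(hi - lo + 1L)
  for (v in iv) {
    a <- v[1] - lo + 1L
    b <- v[2] - lo + 1L
    cov[a:b] <- cov[a:b] + 1L
  }
  cov
}
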