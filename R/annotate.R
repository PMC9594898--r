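# Annotation of insertion calls (repeat overlap, genomic features) and
# ROC-AUC association of insertion sites with interval feature tracks.

# family of the repeat interval with the largest overlap of the probe
# [site - window, site + window + 1) (ties lexicographic); "non-repeat"
# when none overlaps. Vectorised over sites.
overlap_family <- function(contig, site, repeats, window = 10) {
  if (nrow(repeats) == 0) return(rep("non-repeat", length(site)))
  probe <- GenomicRanges::GRanges(
    contig,
    IRanges::IRanges(start = pmax(site - window, 0) + 1L,
                     end = site + window + 1L)
  )
  rep_gr <- GenomicRanges::GRanges(
    repeats$contig,
    IRanges::IRanges(start = repeats$start + 1L, end = repeats$end),
    family = repeats$family
  )
  hits <- GenomicRanges::findOverlaps(probe, rep_gr)
  out <- rep("non-repeat", length(site))
  if (length(hits) == 0) return(out)
  ov <- GenomicRanges::pintersect(probe[S4Vectors::queryHits(hits)],
                                  rep_gr[S4Vectors::subjectHits(hits)])
  cand <- tibble(
    i = S4Vectors::queryHits(hits),
    family = rep_gr$family[S4Vectors::subjectHits(hits)],
    width = BiocGenerics::width(ov)
  ) |>
    arrange(.data$i, desc(.data$width), .data$family) |>
    distinct(.data$i, .keep_all = TRUE)
  out[cand$i] <- cand$family
  out
}

#' Annotate insertion calls with overlapping repeat families
#'
#' An insertion is considered to fall in a repetitive region when the
#' window site +/- `window` bp (a `2*window + 1` bp probe) intersects a
#' repeat interval; the family with the largest overlap wins, ties broken
#' lexicographically.
#'
#' @param calls Tibble with `contig` and `site` columns.
#' @param repeats Repeat annotation tibble (contig, start, end, family;
#'   0-based half-open).
#' @param window Half-width of the probe in bp (default 10).
#' @return `calls` with a `repeat_family` column ("non-repeat" when none).
#' @export
annotate_repeats <- function(calls, repeats, window = 10) {
  stopifnot(window >= 0)
  calls$repeat_family <- if (nrow(calls) == 0) character(0) else
    overlap_family(calls$contig, calls$site, repeats, window)
  calls
}

#' Label insertion sites with genomic features
#'
#' Assigns each site one label with fixed priority
#' exon > promoter > intron > intergenic. A promoter is the `promoter_width`
#' bp window upstream of a gene's transcription start (strand aware);
#' introns are gene-body positions not covered by an exon.
#'
#' @param calls Tibble with `contig` and `site` columns.
#' @param genes Gene-body tibble: contig, start, end (0-based half-open),
#'   strand, gene_id.
#' @param exons Exon tibble: contig, start, end, gene_id.
#' @param promoter_width Promoter window in bp upstream of the TSS
#'   (default 2000).
#' @return `calls` with a `feature` column.
#' @export
annotate_features <- function(calls, genes, exons, promoter_width = 2000) {
  lab <- function(contig, site) {
    inside <- function(tbl) {
      any(tbl$contig == contig & tbl$start <= site & site < tbl$end)
    }
    if (inside(exons)) return("exon")
    prom <- genes |>
      mutate(
        pstart = if_else(.data$strand == "+",
                         pmax(.data$start - promoter_width, 0), .data$end),
        pend = if_else(.data$strand == "+",
                       .data$start, .data$end + promoter_width)
      )
    if (any(prom$contig == contig & prom$pstart <= site & site < prom$pend)) {
      return("promoter")
    }
    if (inside(genes)) return("intron")
    "intergenic"
  }
  calls$feature <- if (nrow(calls) == 0) character(0) else
    vapply(seq_len(nrow(calls)),
           function(i) lab(calls$contig[i], calls$site[i]), character(1))
  calls
}

#' Draw random genomic positions as negative controls
#'
#' Positions are sampled uniformly over contigs weighted by length,
#' excluding positions within `window` bp of a contig edge so that every
#' negative has full window support.
#'
#' @param genome `synthetic_genome` or named `DNAStringSet`, or a named
#'   numeric vector of contig lengths.
#' @param n Number of positions.
#' @param window Edge exclusion in bp.
#' @param seed Integer seed.
#' @return Tibble `contig`, `site`.
#' @export
random_positions <- function(genome, n, window = 0, seed) {
  seed <- check_seed(seed)
  lens <- if (inherits(genome, "synthetic_genome")) contig_lengths_of(genome)
  else if (inherits(genome, "DNAStringSet"))
    stats::setNames(Biostrings::width(genome), names(genome))
  else genome
  window <- as.integer(window)
  usable <- pmax(lens - 2L * window, 0L)
  if (all(usable == 0)) abort("no contig is wider than twice the window")
  withr::local_seed(seed)
  ci <- sample.int(length(lens), n, replace = TRUE, prob = usable)
  site <- vapply(ci, function(i) {
    window + sample.int(usable[i], 1) - 1L
  }, integer(1))
  tibble(contig = names(lens)[ci], site = as.integer(site))
}

# number of feature intervals intersecting [site - window, site + window]
feature_window_scores <- function(contig, site, track, window) {
  if (nrow(track) == 0) return(rep(0L, length(site)))
  probe <- GenomicRanges::GRanges(
    contig,
    IRanges::IRanges(start = pmax(site - window, 0) + 1L,
                     end = site + window + 1L)
  )
  tr <- GenomicRanges::GRanges(
    track$contig, IRanges::IRanges(start = track$start + 1L, end = track$end)
  )
  GenomicRanges::countOverlaps(probe, tr)
}

#' Rank-based (Mann-Whitney) ROC AUC
#'
#' AUC computed from ranks: the probability that a random positive score
#' exceeds a random negative score, ties counting one half. Identical to the
#' normalised Mann-Whitney U statistic.
#'
#' @param pos,neg Numeric score vectors (each nonempty).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' mann_whitney_auc(c(0, 2), c(1, 1))  # 0.5
mann_whitney_auc <- function(pos, neg) {
  stopifnot(length(pos) >= 1, length(neg) >= 1)
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Association of insertion sites with a feature track (ROC AUC)
#'
#' Scores every insertion site and `n_random` random negative positions by
#' the number of feature intervals within +/- `window` bp, then computes the
#' rank-based (Mann-Whitney) area under the ROC curve, ties contributing
#' one half. AUC > 0.5 indicates positive association of insertions with
#' the feature, AUC < 0.5 negative association.
#'
#' @param sites Tibble of insertion sites (`contig`, `site`).
#' @param track Feature track tibble (contig, start, end; 0-based
#'   half-open), e.g. one BED track per chromatin feature.
#' @param genome Reference for drawing negatives.
#' @param n_random Number of random negatives (default 10000).
#' @param window Window half-width in bp (default 100000, i.e. +/- 100 kb).
#' @param seed Integer seed for the negatives.
#' @param feature Feature name carried into the result.
#' @return Tibble `feature`, `auc`, `n_pos`, `n_neg`.
#' @export
feature_assoc_auc <- function(sites, track, genome, n_random = 10000,
                              window = 100000, seed = 1,
                              feature = "feature") {
  if (nrow(sites) == 0) abort("no insertion sites supplied")
  neg <- random_positions(genome, n_random, window = window, seed = seed)
  pos_scores <- feature_window_scores(sites$contig, sites$site, track, window)
  neg_scores <- feature_window_scores(neg$contig, neg$site, track, window)
  tibble(
    feature = feature,
    auc = mann_whitney_auc(pos_scores, neg_scores),
    n_pos = length(pos_scores),
    n_neg = length(neg_scores)
  )
}
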