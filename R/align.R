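# Fragment-to-reference alignment, anchored/unanchored classification,
# junction coordinates and BED export.
#
# The built-in aligner is a deterministic seed-and-extend matcher meant for
# synthetic references: exact k-mer seeds taken from the fragment start,
# middle and end (both orientations) are matched in batch against every
# contig (Biostrings PDict), candidate placements are scored by edit
# distance, and the number of co-optimal placements defines uniqueness
# (mapq surrogate 60 when the optimum is unique, else 0). An external
# long-read mapper can stand behind the same contract in production.

#' Align fragments to a reference genome
#'
#' @param fragments Tibble of query sequences: columns `id` + `seq`, or a
#'   [consensus_fragments()] table (columns `cluster_id` + `consensus`).
#' @param genome A `synthetic_genome` or named [Biostrings::DNAStringSet].
#' @param preset `"long"` (31-mer seeds) or `"short"` (15-mer seeds).
#' @param seed_length Override the preset's seed k-mer length.
#' @param max_edit_frac Candidate placements farther than this edit-distance
#'   fraction of the fragment length from the best are not counted as
#'   co-optimal (strict co-optimum: 0).
#' @return Tibble with one row per fragment: `query_id`, `mapped`, `contig`,
#'   `start`, `end` (0-based half-open), `strand`, `mapq`, `n_secondary`,
#'   `edit_dist`. Unmapped fragments are retained with `mapped = FALSE`.
#' @export
align_fragments <- function(fragments, genome, preset = c("long", "short"),
                            seed_length = NULL, max_edit_frac = 0) {
  preset <- match.arg(preset)
  k <- seed_length %||% if (preset == "long") 31L else 15L
  contigs <- if (inherits(genome, "synthetic_genome")) genome$contigs else genome
  stopifnot(inherits(contigs, "DNAStringSet"))

  qid <- fragments[[if ("query_id" %in% names(fragments)) "query_id"
                    else if ("cluster_id" %in% names(fragments)) "cluster_id"
                    else "id"]]
  qseq <- fragments[[if ("consensus" %in% names(fragments)) "consensus"
                     else if ("fragment" %in% names(fragments)) "fragment"
                     else "seq"]]
  n <- length(qid)
  if (n == 0) return(empty_alignments())

  # collect seeds: (fragment, orientation, offset within oriented fragment)
  seed_tbl <- list()
  seqs_fwd <- qseq
  seqs_rev <- revcomp(qseq)
  for (i in seq_len(n)) {
    L <- nchar(qseq[i])
    if (L < k) next
    offs <- unique(c(0L, as.integer(floor((L - k) / 2)), L - k))
    for (ori in c("+", "-")) {
      s <- if (ori == "+") seqs_fwd[i] else seqs_rev[i]
      for (o in offs) {
        seed_tbl[[length(seed_tbl) + 1]] <-
          list(frag = i, ori = ori, off = o, kmer = substr(s, o + 1L, o + k))
      }
    }
  }
  if (length(seed_tbl) == 0) return(unmapped_tbl(qid))
  seeds <- tibble(
    frag = map_int(seed_tbl, function(x) as.integer(x$frag)),
    ori = map_chr(seed_tbl, "ori"),
    off = map_int(seed_tbl, function(x) as.integer(x$off)),
    kmer = map_chr(seed_tbl, "kmer")
  ) |> filter(!grepl("[^ACGT]", .data$kmer))

  kmers <- unique(seeds$kmer)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  hits <- list()
  for (ci in seq_along(contigs)) {
    m <- Biostrings::matchPDict(pd, contigs[[ci]])
    st <- BiocGenerics::start(m)  # IntegerList per kmer
    nh <- lengths(st)
    if (sum(nh) == 0) next
    hits[[length(hits) + 1]] <- tibble(
      kmer = rep(kmers, nh),
      contig = names(contigs)[ci],
      hit_start = unlist(st) - 1L  # 0-based
    )
  }
  if (length(hits) == 0) return(unmapped_tbl(qid))
  hits <- list_rbind(hits)

  cand <- seeds |>
    inner_join(hits, by = "kmer", relationship = "many-to-many") |>
    mutate(place = .data$hit_start - .data$off) |>
    distinct(.data$frag, .data$ori, .data$contig, .data$place)

  clens <- stats::setNames(Biostrings::width(contigs), names(contigs))
  contig_chr <- stats::setNames(as.character(contigs), names(contigs))
  cand_rows <- split(seq_len(nrow(cand)), cand$frag)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cc <- cand[cand_rows[[as.character(i)]] %||% integer(0), ]
    if (nrow(cc) == 0) {
      out[[i]] <- unmapped_row(qid[i])
      next
    }
    L <- nchar(qseq[i])
    nc <- nrow(cc)
    starts <- integer(nc)
    ends <- integer(nc)
    exact <- logical(nc)
    windows <- character(nc)
    usable <- logical(nc)
    for (j in seq_len(nc)) {
      s0 <- max(cc$place[j], 0L)
      e0 <- min(cc$place[j] + L, clens[[cc$contig[j]]])
      starts[j] <- s0; ends[j] <- e0
      usable[j] <- (e0 - s0) >= min(k, L)
      if (!usable[j]) next
      windows[j] <- substr(contig_chr[[cc$contig[j]]], s0 + 1L, e0)
      q <- if (cc$ori[j] == "+") seqs_fwd[i] else seqs_rev[i]
      exact[j] <- identical(q, windows[j])
    }
    if (any(exact) && max_edit_frac == 0) {
      # exact placements exist: only they can be co-optimal, skip the
      # expensive edit-distance pass over the remaining candidates
      d <- ifelse(exact, 0, Inf)
    } else {
      d <- rep(Inf, nc)
      for (j in seq_len(nc)) {
        if (!usable[j]) next
        q <- if (cc$ori[j] == "+") seqs_fwd[i] else seqs_rev[i]
        d[j] <- if (exact[j]) 0 else as.numeric(utils::adist(q, windows[j]))
      }
    }
    best <- min(d)
    if (!is.finite(best)) {
      out[[i]] <- unmapped_row(qid[i])
      next
    }
    co <- which(d <= best + max_edit_frac * L)
    # primary: deterministic — best distance, then contig, strand, place
    ord <- co[order(d[co], cc$contig[co], cc$ori[co], cc$place[co])]
    p <- ord[1]
    out[[i]] <- tibble(
      query_id = qid[i], mapped = TRUE,
      contig = cc$contig[p], start = starts[p], end = ends[p],
      strand = cc$ori[p],
      mapq = if (length(co) == 1) 60L else 0L,
      n_secondary = length(co) - 1L,
      edit_dist = d[p]
    )
  }
  list_rbind(out)
}

empty_alignments <- function() {
  tibble(query_id = character(), mapped = logical(), contig = character(),
         start = integer(), end = integer(), strand = character(),
         mapq = integer(), n_secondary = integer(), edit_dist = numeric())
}

unmapped_row <- function(id) {
  tibble(query_id = id, mapped = FALSE, contig = NA_character_,
         start = NA_integer_, end = NA_integer_, strand = NA_character_,
         mapq = 0L, n_secondary = 0L, edit_dist = NA_real_)
}

unmapped_tbl <- function(ids) list_rbind(map(ids, unmapped_row))

#' Classify alignments into anchored and unanchored reads
#'
#' Anchored: mapped, no secondary alignments, and mapping quality strictly
#' greater than `min_mapq`. Everything else (unmapped, multi-mapping, or low
#' mapping quality) is unanchored. The two classes partition the input.
#'
#' @param alignments Tibble from [align_fragments()] (or SAM ingestion).
#' @param min_mapq Mapping-quality threshold (exclusive; default 30).
#' @return The input with an `anchor_class` column ("anchored"/"unanchored").
#' @export
classify_alignments <- function(alignments, min_mapq = 30) {
  mutate(alignments, anchor_class = if_else(
    .data$mapped & .data$n_secondary == 0 & .data$mapq > min_mapq,
    "anchored", "unanchored"
  ))
}

#' Junction coordinates of payload-first alignments
#'
#' Fragments are payload-first oriented (the genomic junction is fragment
#' position 0), so a plus-strand alignment places the junction at the
#' interval start and a minus-strand alignment at the interval end.
#'
#' @param alignments Tibble of mapped alignments.
#' @return Tibble `query_id`, `contig`, `site` (0-based), `strand` (plus any
#'   `replicate` column carried through).
#' @export
junction_sites <- function(alignments) {
  al <- filter(alignments, .data$mapped)
  keep <- intersect(c("query_id", "contig", "strand", "replicate"), names(al))
  al |>
    mutate(site = if_else(.data$strand == "+", .data$start, .data$end)) |>
    select(all_of(keep), "site") |>
    relocate("site", .after = "contig")
}

#' Export mapped alignments as BED6
#'
#' One line per mapped alignment — contig, start, end (0-based half-open),
#' query id, mapq, strand — sorted by contig then start.
#'
#' @param alignments Alignment tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_bed <- function(alignments, path) {
  al <- alignments |>
    filter(.data$mapped) |>
    arrange(.data$contig, .data$start)
  gr <- GenomicRanges::GRanges(
    al$contig, IRanges::IRanges(start = al$start + 1L, end = al$end),
    strand = al$strand
  )
  S4Vectors::mcols(gr)$name <- al$query_id
  S4Vectors::mcols(gr)$score <- al$mapq
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Import a BED6 file as an alignment-style tibble
#'
#' @param path BED file path.
#' @return Tibble `query_id`, `mapped`, `contig`, `start`, `end`, `strand`,
#'   `mapq`, `n_secondary`, `edit_dist` (the last two NA/0 placeholders).
#' @export
import_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  if (length(gr) == 0) return(empty_alignments())
  tibble(
    query_id = S4Vectors::mcols(gr)$name %||% as.character(seq_along(gr)),
    mapped = TRUE,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    mapq = as.integer(S4Vectors::mcols(gr)$score %||% NA_integer_),
    n_secondary = 0L,
    edit_dist = NA_real_
  )
}
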