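# Read preparation: QC filtering, structure enforcement/trimming, UMI
# clustering and consensus building.

#' Filter reads by mean quality and length
#'
#' Keeps reads whose mean per-base Phred quality is strictly greater than
#' `min_mean_q` and whose length is strictly greater than `min_len` (both
#' comparisons strict, matching the pipeline's QC convention).
#'
#' @param reads Tibble with columns `id`, `seq`, `qual` (and optionally a
#'   precomputed `mean_q`).
#' @param min_mean_q Minimum mean Phred quality (exclusive; default 10).
#' @param min_len Minimum read length in bp (exclusive; default 200).
#' @return The kept rows, with `mean_q` filled in.
#' @export
quality_length_filter <- function(reads, min_mean_q = 10, min_len = 200) {
  stopifnot(min_mean_q >= 0, min_len >= 0)
  if (nrow(reads) == 0) {
    reads$mean_q <- numeric(0)
    return(reads)
  }
  if (!"mean_q" %in% names(reads)) reads$mean_q <- mean_phred(reads$qual)
  filter(reads, .data$mean_q > min_mean_q, nchar(.data$seq) > min_len)
}

#' Describe the expected junction-read structure
#'
#' A structured junction read is adapter + barcode + UMI + payload end +
#' genomic fragment, observed in either orientation. Each sequence element is
#' located allowing up to `floor(max_error_fraction * nchar(element))` edits.
#'
#' @param adapter Ligated adapter sequence.
#' @param barcodes Named character vector of sample barcodes.
#' @param umi_length UMI length in nt (default 12).
#' @param payload_end Payload terminal sequence adjacent to the genomic
#'   junction.
#' @param max_error_fraction Per-element edit tolerance as a fraction of the
#'   element length (default 0.1; must be < 0.5).
#' @param barcode_max_edits Maximum barcode edit distance (default 1);
#'   equidistant barcode matches within tolerance are rejected as ambiguous.
#' @return A list of class `read_structure`.
#' @export
read_structure <- function(adapter, barcodes, umi_length = 12, payload_end,
                           max_error_fraction = 0.1, barcode_max_edits = 1) {
  stopifnot(nchar(adapter) > 0, length(barcodes) > 0, all(nchar(barcodes) > 0),
            nchar(payload_end) > 0, umi_length > 0,
            max_error_fraction >= 0, max_error_fraction < 0.5)
  if (is.null(names(barcodes))) {
    names(barcodes) <- sprintf("bc%02d", seq_along(barcodes))
  }
  structure(list(
    adapter = adapter, barcodes = barcodes,
    umi_length = as.integer(umi_length), payload_end = payload_end,
    max_error_fraction = max_error_fraction,
    barcode_max_edits = as.integer(barcode_max_edits)
  ), class = "read_structure")
}

# Best approximate occurrence of `pattern` in `subject` within max_edits;
# returns list(start, end) of the match or NULL.
find_element <- function(pattern, subject, max_edits, from = 1L) {
  sub <- substr(subject, from, nchar(subject))
  if (nchar(sub) < 1) return(NULL)
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(sub),
                                max.mismatch = max_edits, with.indels = TRUE)
  if (length(m) == 0) return(NULL)
  # leftmost occurrence: structure elements appear in fixed order
  i <- which.min(BiocGenerics::start(m))
  list(start = BiocGenerics::start(m)[i] + from - 1L,
       end = BiocGenerics::end(m)[i] + from - 1L)
}

element_tolerance <- function(seq, frac) as.integer(floor(nchar(seq) * frac))

#' Demultiplex structured reads and extract UMI and genomic fragment
#'
#' Locates the adapter in either read orientation (within the per-element
#' edit tolerance), assigns the closest barcode (ambiguous or distant
#' barcodes are rejected), extracts the UMI adjacent to the barcode, requires
#' the payload end downstream of the UMI, and trims everything payload-ward
#' of the junction. The emitted fragment is payload-first oriented: the
#' genomic junction is at fragment position 0.
#'
#' @param reads Tibble with `id`, `seq`, `qual` (QC-filtered).
#' @param structure A [read_structure()].
#' @return A tibble with one row per input read: columns `id`, `status`
#'   ("ok" or a rejection reason: "no adapter", "no barcode",
#'   "ambiguous barcode", "no umi", "no payload", "empty fragment"),
#'   `barcode_id`, `umi`, `fragment`, `mean_q`. Processed reads are the rows
#'   with `status == "ok"`.
#' @export
demultiplex_and_extract <- function(reads, structure) {
  stopifnot(inherits(structure, "read_structure"))
  ad_tol <- element_tolerance(structure$adapter, structure$max_error_fraction)
  pe_tol <- element_tolerance(structure$payload_end, structure$max_error_fraction)
  if (!"mean_q" %in% names(reads)) reads$mean_q <- mean_phred(reads$qual)

  one <- function(seq) {
    hit <- find_element(structure$adapter, seq, ad_tol)
    if (is.null(hit)) {
      rc <- revcomp(seq)
      hit <- find_element(structure$adapter, rc, ad_tol)
      if (is.null(hit)) return(list(status = "no adapter"))
      seq <- rc
    }
    pos <- hit$end + 1L
    # barcode: compare the window after the adapter against the barcode set
    bcl <- nchar(structure$barcodes)
    if (pos + max(bcl) - 1L > nchar(seq)) return(list(status = "no barcode"))
    d <- vapply(seq_along(structure$barcodes), function(i) {
      edit_distance(substr(seq, pos, pos + bcl[i] - 1L), structure$barcodes[[i]])
    }, integer(1))
    best <- which(d == min(d))
    if (min(d) > structure$barcode_max_edits) return(list(status = "no barcode"))
    if (length(best) > 1) return(list(status = "ambiguous barcode"))
    pos <- pos + bcl[best]
    umi <- substr(seq, pos, pos + structure$umi_length - 1L)
    if (nchar(umi) < structure$umi_length) return(list(status = "no umi"))
    pos <- pos + structure$umi_length
    pe <- find_element(structure$payload_end, seq, pe_tol, from = pos)
    if (is.null(pe)) return(list(status = "no payload"))
    fragment <- substr(seq, pe$end + 1L, nchar(seq))
    if (nchar(fragment) == 0) return(list(status = "empty fragment"))
    list(status = "ok", barcode_id = names(structure$barcodes)[best],
         umi = umi, fragment = fragment)
  }

  res <- map(reads$seq, one)
  tibble(
    id = reads$id,
    status = map_chr(res, "status"),
    barcode_id = map_chr(res, function(x) x$barcode_id %||% NA_character_),
    umi = map_chr(res, function(x) x$umi %||% NA_character_),
    fragment = map_chr(res, function(x) x$fragment %||% NA_character_),
    mean_q = reads$mean_q
  )
}

#' Summarise rejection reasons from extraction
#'
#' @param processed Output of [demultiplex_and_extract()].
#' @return Tibble of `status`, `n`.
#' @export
extraction_summary <- function(processed) {
  count(processed, .data$status, name = "n")
}

#' Cluster processed reads by UMI into molecule groups
#'
#' Greedy centroid clustering: reads are visited in order of descending mean
#' quality (ties by id); a read joins the first existing cluster whose
#' centroid UMI is within `max_umi_edits` edits and whose centroid fragment
#' has ends-free identity >= `min_fragment_identity` (see [seq_identity()]);
#' otherwise it founds a new cluster. Every read belongs to exactly one
#' cluster. Reads from different barcodes are clustered separately.
#'
#' @param processed Tibble from [demultiplex_and_extract()]; only rows with
#'   `status == "ok"` are used.
#' @param max_umi_edits Maximum UMI edit distance to a centroid (default 1).
#' @param min_fragment_identity Minimum fragment identity to the centroid
#'   fragment (default 0.9).
#' @return Tibble with one row per cluster: `cluster_id`, `barcode_id`,
#'   `umi` (centroid), `size`, `member_ids` (list column), `fragments` (list
#'   column of member fragments, centroid first) and `member_mean_q` (list
#'   column of member mean qualities, used as consensus tie-break weights).
#' @export
cluster_umis <- function(processed, max_umi_edits = 1,
                         min_fragment_identity = 0.9) {
  ok <- processed |>
    filter(.data$status == "ok") |>
    arrange(desc(.data$mean_q), .data$id)
  out <- vector("list", 0)
  for (bc in unique(ok$barcode_id)) {
    sub <- ok[ok$barcode_id == bc, ]
    cent_umi <- character(0)
    cent_frag <- character(0)
    members <- list()
    frags <- list()
    quals <- list()
    for (i in seq_len(nrow(sub))) {
      assigned <- NA_integer_
      if (length(cent_umi)) {
        cand <- which(as.integer(utils::adist(sub$umi[i], cent_umi)) <= max_umi_edits)
        for (j in cand) {
          if (seq_identity(sub$fragment[i], cent_frag[j]) >= min_fragment_identity) {
            assigned <- j
            break
          }
        }
      }
      if (is.na(assigned)) {
        cent_umi <- c(cent_umi, sub$umi[i])
        cent_frag <- c(cent_frag, sub$fragment[i])
        members[[length(cent_umi)]] <- sub$id[i]
        frags[[length(cent_umi)]] <- sub$fragment[i]
        quals[[length(cent_umi)]] <- sub$mean_q[i]
      } else {
        members[[assigned]] <- c(members[[assigned]], sub$id[i])
        frags[[assigned]] <- c(frags[[assigned]], sub$fragment[i])
        quals[[assigned]] <- c(quals[[assigned]], sub$mean_q[i])
      }
    }
    if (length(cent_umi)) {
      out[[length(out) + 1]] <- tibble(
        barcode_id = bc, umi = cent_umi,
        size = lengths(members),
        member_ids = members, fragments = frags, member_mean_q = quals
      )
    }
  }
  res <- if (length(out)) list_rbind(out) else
    tibble(barcode_id = character(), umi = character(), size = integer(),
           member_ids = list(), fragments = list(), member_mean_q = list())
  res |>
    mutate(cluster_id = sprintf("umi_%05d", row_number()), .before = 1)
}

#' Plurality consensus of a set of fragments
#'
#' Size-1 clusters return the member fragment verbatim. Larger clusters are
#' aligned (ends-free) to the longest member and the plurality base is taken
#' per column of the longest member's coordinates; ties are broken by the
#' highest summed member quality, then alphabetically. Columns where a gap
#' wins are dropped.
#'
#' @param fragments Character vector of member fragments.
#' @param weights Optional per-member quality weights used for tie-breaking
#'   (defaults to 1 per member).
#' @return The consensus sequence (character scalar).
#' @export
plurality_consensus <- function(fragments, weights = NULL) {
  stopifnot(length(fragments) >= 1)
  if (length(fragments) == 1) return(fragments[[1]])
  if (length(unique(fragments)) == 1) return(fragments[[1]])
  if (is.null(weights)) weights <- rep(1, length(fragments))
  ref_i <- which.max(nchar(fragments))
  ref <- fragments[[ref_i]]
  L <- nchar(ref)
  # votes[base, column]; "-" collects deletion votes
  alphabet <- c(DNA_BASES, "-")
  votes <- matrix(0, nrow = 5, ncol = L, dimnames = list(alphabet, NULL))
  for (i in seq_along(fragments)) {
    if (i == ref_i) {
      rb <- strsplit(ref, "")[[1]]
      ok <- rb %in% alphabet
      for (j in which(ok)) {
        votes[match(rb[j], alphabet), j] <- votes[match(rb[j], alphabet), j] + weights[i]
      }
      next
    }
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(fragments[[i]]), Biostrings::DNAString(ref),
      type = "overlap", substitutionMatrix = identity_submat(),
      gapOpening = 4, gapExtension = 1
    )
    # subject = ref; clip to the aligned subject window, count only there
    s_start <- BiocGenerics::start(Biostrings::subject(al))
    aligned_mem <- as.character(Biostrings::alignedPattern(al))
    aligned_ref <- as.character(Biostrings::alignedSubject(al))
    ra <- strsplit(aligned_ref, "")[[1]]
    ma <- strsplit(aligned_mem, "")[[1]]
    col <- cumsum(ra != "-") + s_start - 1L
    keep <- ra != "-" & ma %in% alphabet
    idx <- cbind(match(ma[keep], alphabet), col[keep])
    for (r in seq_len(nrow(idx))) {
      votes[idx[r, 1], idx[r, 2]] <- votes[idx[r, 1], idx[r, 2]] + weights[i]
    }
  }
  cons <- vapply(seq_len(L), function(j) {
    v <- votes[, j]
    if (all(v == 0)) return(substr(ref, j, j))
    winners <- names(v)[v == max(v)]
    if (length(winners) > 1) winners <- sort(winners)[1]
    winners
  }, character(1))
  paste(cons[cons != "-"], collapse = "")
}

#' Add consensus fragments to UMI clusters
#'
#' @param clusters Output of [cluster_umis()].
#' @return The cluster tibble with a `consensus` character column.
#' @export
consensus_fragments <- function(clusters) {
  clusters$consensus <- map2(clusters$fragments, clusters$member_mean_q,
                             function(f, q) plurality_consensus(f, q)) |>
    unlist()
  clusters
}

`%||%` <- function(a, b) if (is.null(a)) b else a
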