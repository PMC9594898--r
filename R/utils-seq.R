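#' @importFrom rlang .data abort warn .env
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap list_rbind
NULL

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read and write FASTQ / FASTA as tibbles
#'
#' Thin wrappers around Biostrings readers. Reads are represented throughout
#' the package as tibbles with columns `id`, `seq` and (for FASTQ) `qual`
#' (Phred+33 string) plus a derived `mean_q` column.
#'
#' @param path File path.
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @return `read_fastq()` returns a tibble with columns `id`, `seq`, `qual`,
#'   `mean_q`; `read_fasta()` one with `id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  tibble(
    id = names(x),
    seq = as.character(x),
    qual = as.character(Biostrings::quality(x))
  ) |>
    mutate(mean_q = mean_phred(.data$qual))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

#' @rdname read_fastq
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = names(x), seq = as.character(x))
}

#' @rdname read_fastq
#' @param seqs Named character vector or tibble with `id`, `seq`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    x <- Biostrings::DNAStringSet(seqs$seq)
    names(x) <- seqs$id
  } else {
    x <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Phred+33 helpers ------------------------------------------------------

phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(utf8ToInt(q)) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(pmin(pmax(v, 0L), 93L) + 33L), character(1))
}

#' Mean per-base Phred quality of each read
#'
#' Arithmetic mean of the per-base Phred scores decoded from a Phred+33
#' quality string (the quantity thresholded by [quality_length_filter()]).
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @return Numeric vector of mean qualities.
#' @export
mean_phred <- function(qual) {
  vapply(phred_to_int(qual), function(v) {
    if (length(v) == 0) return(0)
    mean(v)
  }, numeric(1))
}

# Pairwise identity -----------------------------------------------------

#' Pairwise sequence identity (ends-free)
#'
#' Identity between two sequences defined as matched columns divided by the
#' alignment length excluding terminal gaps, computed from an ends-free
#' (overlap) global alignment. Under this definition a read that is a prefix
#' of another read of the same origin has identity 1, which is the behaviour
#' needed when gating UMI clusters whose members differ only in flank length.
#'
#' @param a,b Sequences (character scalars).
#' @param min_overlap_frac The aligned overlap must span at least this
#'   fraction of the shorter sequence; shorter overlaps are penalised by
#'   dividing the match count by the required minimum width instead
#'   (default 0.9). Prevents unrelated sequences from scoring high identity
#'   over a tiny corner overlap.
#' @return Identity in \[0, 1\].
#' @export
seq_identity <- function(a, b, min_overlap_frac = 0.9) {
  if (identical(a, b)) return(1)
  na <- nchar(a); nb <- nchar(b)
  if (na == 0 || nb == 0) return(0)
  # prefix fast path
  if (na != nb) {
    s <- if (na < nb) a else b
    l <- if (na < nb) b else a
    if (substr(l, 1, nchar(s)) == s) return(1)
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "overlap",
    substitutionMatrix = identity_submat(),
    gapOpening = 1, gapExtension = 1
  )
  w <- Biostrings::nchar(al)  # aligned width excluding clipped ends
  if (w == 0) return(0)
  Biostrings::nmatch(al) / max(w, ceiling(min_overlap_frac * min(na, nb)))
}

identity_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE
      )
    }
    m
  }
})

# Levenshtein distance between short strings (UMIs, barcodes)
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer")
  }
  as.integer(seed)
}

# Deterministic child seeds derived from one master seed, kept within
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1103L + as.integer(offset) * 12289L) %% 2147483562L
}
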