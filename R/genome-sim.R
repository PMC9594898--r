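# Synthetic genomes and read simulation.
#
# All coordinates are 0-based half-open internally; an insertion `site` is
# the 0-based reference coordinate of the base adjacent to the payload
# junction. The genome sequence itself is never edited: junction reads are
# synthesised as payload structure + reference flank starting at the site,
# which is exactly what a junction-capture library observes.

#' Describe repeat families for a synthetic genome
#'
#' Builds the family table consumed by [build_synthetic_genome()]. Each
#' family gets a random consensus of `consensus_length` bases; `copy_number`
#' diverged copies are planted per family, each base substituted
#' independently with probability `divergence`.
#'
#' @param name Family names (unique).
#' @param consensus_length Consensus length in bp (> 0).
#' @param copy_number Copies to plant (>= 0).
#' @param divergence Per-base substitution probability in \[0, 0.3\].
#' @return A tibble with one row per family.
#' @export
#' @examples
#' repeat_families("LINE_sim", 2000, 10, 0.05)
repeat_families <- function(name, consensus_length, copy_number, divergence = 0) {
  fam <- tibble(
    name = as.character(name),
    consensus_length = as.integer(consensus_length),
    copy_number = as.integer(copy_number),
    divergence = as.numeric(divergence)
  )
  if (anyDuplicated(fam$name)) abort("repeat family names must be unique")
  if (any(fam$consensus_length <= 0)) abort("consensus_length must be > 0")
  if (any(fam$copy_number < 0)) abort("copy_number must be >= 0")
  if (any(fam$divergence < 0 | fam$divergence > 0.3)) {
    abort("divergence must lie in [0, 0.3]")
  }
  fam
}

#' Build a synthetic multi-contig genome with planted repeat families
#'
#' Background sequence is i.i.d. uniform A/C/G/T (maximally mappable), into
#' which diverged copies of each repeat family are planted at random
#' non-overlapping positions. The returned object carries the contigs, the
#' repeat annotation (0-based half-open, family in `family`), the family
#' consensus sequences, and an (initially empty) planted-insertion truth set.
#'
#' @param families Tibble from [repeat_families()], or NULL for no repeats.
#' @param contig_lengths Named (or unnamed) integer vector of contig lengths.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An object of class `synthetic_genome`: a list with elements
#'   `contigs` (named [Biostrings::DNAStringSet]), `repeats` (tibble:
#'   contig, start, end, family, copy), `consensi` (named character),
#'   `insertions` (tibble truth set).
#' @export
#' @examples
#' g <- build_synthetic_genome(repeat_families("rep1", 500, 4), 50000, seed = 1)
#' g$repeats
build_synthetic_genome <- function(families = NULL, contig_lengths, seed) {
  seed <- check_seed(seed)
  if (is.null(families)) {
    families <- repeat_families(character(), integer(), integer(), numeric())
  }
  nm <- names(contig_lengths)
  contig_lengths <- as.integer(contig_lengths)
  names(contig_lengths) <- if (is.null(nm)) {
    sprintf("contig_%02d", seq_along(contig_lengths))
  } else {
    nm
  }
  total_repeat <- sum(families$consensus_length * families$copy_number)
  if (total_repeat >= sum(contig_lengths)) {
    abort("planted repeats do not fit: total repeat length exceeds genome size")
  }

  withr::local_seed(seed)
  contigs <- vapply(contig_lengths, random_dna, character(1))

  consensi <- stats::setNames(
    vapply(families$consensus_length, random_dna, character(1)),
    families$name
  )

  occupied <- lapply(contigs, function(x) IRanges::IRanges())
  ann <- list()
  for (i in seq_len(nrow(families))) {
    fam <- families[i, ]
    cons <- consensi[[fam$name]]
    L <- fam$consensus_length
    for (copy in seq_len(fam$copy_number)) {
      placed <- FALSE
      for (try in 1:2000) {
        ci <- sample.int(length(contigs), 1,
                         prob = pmax(contig_lengths - L, 0))
        if (contig_lengths[ci] < L) next
        start0 <- sample.int(contig_lengths[ci] - L + 1L, 1) - 1L
        cand <- IRanges::IRanges(start0 + 1L, start0 + L)
        if (length(IRanges::findOverlaps(cand, occupied[[ci]])) == 0) {
          occupied[[ci]] <- c(occupied[[ci]], cand)
          seq_copy <- diverge_sequence(cons, fam$divergence)
          substr(contigs[ci], start0 + 1L, start0 + L) <- seq_copy
          ann[[length(ann) + 1]] <- tibble(
            contig = names(contig_lengths)[ci],
            start = start0, end = start0 + L,
            family = fam$name, copy = copy
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf("could not place copy %d of family %s: genome too full",
                      copy, fam$name))
      }
    }
  }

  repeats <- if (length(ann)) list_rbind(ann) else
    tibble(contig = character(), start = integer(), end = integer(),
           family = character(), copy = integer())
  repeats <- arrange(repeats, .data$contig, .data$start)

  dna <- Biostrings::DNAStringSet(contigs)
  names(dna) <- names(contig_lengths)
  structure(
    list(
      contigs = dna,
      repeats = repeats,
      consensi = consensi,
      insertions = empty_insertions()
    ),
    class = "synthetic_genome"
  )
}

empty_insertions <- function() {
  tibble(payload_id = character(), contig = character(), site = integer(),
         strand = character(), in_repeat = logical())
}

diverge_sequence <- function(seq, divergence) {
  if (divergence == 0) return(seq)
  b <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(b)) < divergence)
  if (length(hit)) {
    b[hit] <- vapply(b[hit], function(x) sample(setdiff(DNA_BASES, x), 1),
                     character(1))
  }
  paste(b, collapse = "")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome> %d contig(s), %s bp; %d repeat copies (%d families); %d planted insertions\n",
    length(x$contigs), format(sum(Biostrings::width(x$contigs)), big.mark = ","),
    nrow(x$repeats), length(x$consensi), nrow(x$insertions)
  ))
  invisible(x)
}

contig_lengths_of <- function(genome) {
  stats::setNames(Biostrings::width(genome$contigs), names(genome$contigs))
}

#' Plant payload insertions into a synthetic genome
#'
#' Adds `n` insertion sites to the genome's truth table. A fraction of the
#' sites (rounded) is placed inside annotated repeat intervals, the rest in
#' unique (non-repeat) sequence. The contig sequence is not modified; the
#' truth sites drive [simulate_junction_reads()].
#'
#' @param genome A `synthetic_genome`.
#' @param n Number of insertions.
#' @param fraction_in_repeats Proportion of sites planted inside repeats.
#' @param payload Payload identifier prefix for `payload_id`.
#' @param min_distance Minimum pairwise distance between planted sites (bp);
#'   keeps independently planted junction peaks from merging.
#' @param repeat_margin When planting inside a repeat, minimum distance of
#'   the site from the repeat interval's edges (bp); with margin larger than
#'   the read length, junction reads cannot escape into unique flank.
#' @param seed Integer seed.
#' @return The genome with `n` rows appended to `insertions` (columns
#'   payload_id, contig, site, strand, in_repeat).
#' @export
plant_insertions <- function(genome, n, fraction_in_repeats = 0,
                             payload = "payload", min_distance = 1000,
                             repeat_margin = 0, seed) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (fraction_in_repeats < 0 || fraction_in_repeats > 1) {
    abort("fraction_in_repeats must lie in [0, 1]")
  }
  if (n == 0) return(genome)
  seed <- check_seed(seed)
  withr::local_seed(seed)

  n_rep <- round(n * fraction_in_repeats)
  n_uni <- n - n_rep
  lens <- contig_lengths_of(genome)
  reps <- genome$repeats

  if (n_rep > 0 && nrow(reps) == 0) {
    abort("fraction_in_repeats > 0 but the genome has no repeat annotation")
  }

  taken <- genome$insertions[, c("contig", "site")]
  ok_distance <- function(contig, site) {
    prior <- taken$site[taken$contig == contig]
    length(prior) == 0 || min(abs(prior - site)) >= min_distance
  }

  draw_repeat_site <- function() {
    usable <- reps[(reps$end - reps$start) > 2 * repeat_margin + 1, ]
    if (nrow(usable) == 0) abort("no repeat interval wide enough for repeat_margin")
    for (try in 1:5000) {
      r <- usable[sample.int(nrow(usable), 1), ]
      lo <- r$start + repeat_margin
      hi <- r$end - repeat_margin - 1L
      site <- lo + sample.int(hi - lo + 1L, 1) - 1L
      if (ok_distance(r$contig, site)) return(list(contig = r$contig, site = site))
    }
    abort("could not place insertion inside repeats: too crowded")
  }

  rep_gr <- repeats_granges(genome)
  draw_unique_site <- function() {
    for (try in 1:5000) {
      ci <- sample.int(length(lens), 1, prob = lens)
      site <- sample.int(lens[ci], 1) - 1L
      probe <- GenomicRanges::GRanges(names(lens)[ci],
                                      IRanges::IRanges(site + 1L, site + 1L))
      in_rep <- length(GenomicRanges::findOverlaps(probe, rep_gr)) > 0
      if (!in_rep && ok_distance(names(lens)[ci], site)) {
        return(list(contig = names(lens)[ci], site = site))
      }
    }
    abort("could not place insertion in unique sequence: too crowded")
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    in_rep <- i <= n_rep
    pos <- if (in_rep) draw_repeat_site() else draw_unique_site()
    taken <- bind_rows(taken, tibble(contig = pos$contig, site = pos$site))
    rows[[i]] <- tibble(
      payload_id = sprintf("%s_%03d", payload, nrow(genome$insertions) + i),
      contig = pos$contig,
      site = as.integer(pos$site),
      strand = sample(c("+", "-"), 1),
      in_repeat = in_rep
    )
  }
  genome$insertions <- bind_rows(genome$insertions, list_rbind(rows))
  genome
}

repeats_granges <- function(genome) {
  r <- genome$repeats
  GenomicRanges::GRanges(
    r$contig, IRanges::IRanges(start = r$start + 1L, end = pmax(r$end, r$start + 1L)),
    family = r$family
  )
}

#' Configure the junction-read simulator
#'
#' Captures the structured-read model: each molecule is
#' adapter + barcode + UMI + payload end + genomic flank, the flank starting
#' at the insertion site and extending in the insertion's strand orientation
#' with length drawn from Normal(`length_mean`, `length_sd`) (resampled to be
#' >= 1, truncated at contig boundaries). Sequencing errors are applied per
#' base at the given mismatch/insertion/deletion rates; base qualities are a
#' constant Phred `base_quality` with optional integer jitter. Each simulated
#' read is one molecule with its own random UMI; use [pcr_amplify()] to add
#' PCR duplicates.
#'
#' @param adapter,payload_end Structure element sequences.
#' @param barcodes Named character vector of sample barcodes.
#' @param barcode_id Which barcode the simulated sample carries (default the
#'   first).
#' @param umi_length UMI length in nt (default 12).
#' @param length_mean,length_sd Flank length distribution (bp).
#' @param reads_per_site Reads simulated per truth insertion (ignored when
#'   `n_reads` given).
#' @param n_reads Total reads, allocated uniformly at random across sites.
#' @param error_rates Named numeric: mismatch, insertion, deletion rates.
#' @param base_quality,quality_jitter Quality model (Phred).
#' @param seed Integer seed.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(adapter = "AGATACGGCGACCACCGA",
                            barcodes = c(bc01 = "ACGTACGTAC"),
                            barcode_id = names(barcodes)[1],
                            umi_length = 12,
                            payload_end = "TTGTACAAGTAAAGCGGCCG",
                            length_mean = 300, length_sd = 25,
                            reads_per_site = 10, n_reads = NULL,
                            error_rates = c(mismatch = 0, insertion = 0, deletion = 0),
                            base_quality = 12, quality_jitter = 0,
                            seed = 1) {
  stopifnot(length_mean > 0, length_sd >= 0, umi_length > 0,
            nchar(adapter) > 0, nchar(payload_end) > 0, length(barcodes) > 0)
  er <- c(mismatch = 0, insertion = 0, deletion = 0)
  er[names(error_rates)] <- error_rates
  if (any(er < 0 | er >= 1)) abort("error rates must lie in [0, 1)")
  structure(list(
    adapter = adapter, barcodes = barcodes, barcode_id = barcode_id,
    umi_length = as.integer(umi_length), payload_end = payload_end,
    length_mean = length_mean, length_sd = length_sd,
    reads_per_site = reads_per_site, n_reads = n_reads,
    error_rates = er, base_quality = as.integer(base_quality),
    quality_jitter = as.integer(quality_jitter), seed = check_seed(seed)
  ), class = "read_sim_config")
}

truncated_normal_lengths <- function(n, mean, sd) {
  if (sd == 0) return(rep(as.integer(round(mean)), n))
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- as.integer(round(stats::rnorm(length(todo), mean, sd)))
    ok <- draw >= 1
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

apply_read_errors <- function(seq, rates) {
  if (all(rates == 0)) return(seq)
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  keep <- stats::runif(n) >= rates[["deletion"]]
  sub <- stats::runif(n) < rates[["mismatch"]]
  b[sub & keep] <- vapply(b[sub & keep],
                          function(x) sample(setdiff(DNA_BASES, x), 1),
                          character(1))
  ins <- stats::runif(n) < rates[["insertion"]]
  pieces <- b
  pieces[ins] <- paste0(pieces[ins], vapply(which(ins), function(i)
    sample(DNA_BASES, 1), character(1)))
  pieces[!keep] <- sub("^.", "", pieces[!keep])
  paste(pieces, collapse = "")
}

#' Simulate structured junction reads from planted insertions
#'
#' @param genome A `synthetic_genome` with a nonempty insertion truth set.
#' @param config A [read_sim_config()].
#' @return A list of class `junction_sim` with `reads` (tibble id, seq, qual,
#'   mean_q) and `truth` (tibble read_id, payload_id, contig, site, strand,
#'   umi, barcode_id, flank_len, truncated, flipped). `flipped` records reads
#'   emitted as the reverse complement of the molecule (sequencing strand is
#'   drawn uniformly).
#' @export
simulate_junction_reads <- function(genome, config) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(config, "read_sim_config"))
  ins <- genome$insertions
  if (nrow(ins) == 0) abort("genome has no planted insertions")
  withr::local_seed(config$seed)

  if (!is.null(config$n_reads)) {
    idx <- sample.int(nrow(ins), config$n_reads, replace = TRUE)
  } else {
    idx <- rep(seq_len(nrow(ins)), each = config$reads_per_site)
  }
  n <- length(idx)
  lens <- contig_lengths_of(genome)
  contig_chr <- stats::setNames(as.character(genome$contigs),
                                names(genome$contigs))
  flank_len <- truncated_normal_lengths(n, config$length_mean, config$length_sd)
  umis <- vapply(seq_len(n), function(i) random_dna(config$umi_length),
                 character(1))
  barcode <- config$barcodes[[config$barcode_id]]
  prefix <- paste0(config$adapter, barcode)

  rows <- vector("list", n)
  for (k in seq_len(n)) {
    site <- ins$site[idx[k]]
    contig <- ins$contig[idx[k]]
    strand <- ins$strand[idx[k]]
    clen <- lens[[contig]]
    if (strand == "+") {
      from <- site + 1L
      to <- min(site + flank_len[k], clen)
      flank <- substr(contig_chr[[contig]], from, to)
    } else {
      from <- max(site - flank_len[k] + 1L, 1L)
      to <- site
      flank <- revcomp(substr(contig_chr[[contig]], from, to))
    }
    truncated <- nchar(flank) < flank_len[k]
    molecule <- paste0(prefix, umis[k], config$payload_end, flank)
    observed <- apply_read_errors(molecule, config$error_rates)
    flipped <- stats::runif(1) < 0.5
    if (flipped) observed <- revcomp(observed)
    q <- config$base_quality +
      (if (config$quality_jitter > 0)
        sample(-config$quality_jitter:config$quality_jitter,
               nchar(observed), replace = TRUE) else 0L)
    rows[[k]] <- tibble(
      read_id = sprintf("read_%06d", k),
      payload_id = ins$payload_id[idx[k]],
      contig = contig, site = site, strand = strand,
      umi = umis[k], barcode_id = config$barcode_id,
      flank_len = nchar(flank), truncated = truncated, flipped = flipped,
      seq = observed, qual = int_to_phred(list(rep(q, length.out = nchar(observed))))
    )
  }
  truth <- list_rbind(rows)
  reads <- truth |>
    transmute(id = .data$read_id, seq = .data$seq, qual = .data$qual) |>
    mutate(mean_q = mean_phred(.data$qual))
  structure(list(
    reads = reads,
    truth = select(truth, -"seq", -"qual")
  ), class = "junction_sim")
}

#' Simulate PCR duplication of junction-read molecules
#'
#' Each molecule (read) of a [simulate_junction_reads()] result is duplicated
#' k times, k drawn uniformly from `1:max_factor`, producing exact duplicate
#' reads sharing the molecule's UMI. The truth table gains a `molecule_id`
#' column; UMI deduplication should recover the original molecule counts.
#'
#' @param sim A `junction_sim`.
#' @param max_factor Maximum per-molecule duplication factor.
#' @param seed Integer seed.
#' @return A `junction_sim` with amplified reads and expanded truth.
#' @export
pcr_amplify <- function(sim, max_factor = 50, seed) {
  stopifnot(inherits(sim, "junction_sim"))
  seed <- check_seed(seed)
  withr::local_seed(seed)
  k <- sample.int(max_factor, nrow(sim$reads), replace = TRUE)
  idx <- rep(seq_len(nrow(sim$reads)), times = k)
  reads <- sim$reads[idx, ]
  truth <- sim$truth[idx, ]
  truth$molecule_id <- truth$read_id
  dup <- stats::ave(seq_along(idx), idx, FUN = seq_along)
  ids <- sprintf("%s_dup%02d", reads$id, dup)
  reads$id <- ids
  truth$read_id <- ids
  structure(list(reads = reads, truth = truth), class = "junction_sim")
}

#' Simulate plain reads around random genomic positions
#'
#' The read-length impact design: for each replicate, `n_sites` positions are
#' sampled uniformly over the genome (contigs weighted by length) and
#' `reads_per_site` reads are generated extending from each position on a
#' uniformly drawn strand, lengths Normal(`length_mean`, `length_sd`)
#' truncated at >= 1 and clipped at contig boundaries. Reads carry no
#' adapter/UMI structure (the study maps raw junction flanks).
#'
#' @param genome A `synthetic_genome`.
#' @param n_sites Positions per replicate.
#' @param replicates Number of replicates.
#' @param length_mean,length_sd Read length distribution (bp).
#' @param reads_per_site Reads per position (default 1).
#' @param seed Integer seed.
#' @return List with `reads` (tibble id, seq, replicate) and `truth`
#'   (tibble replicate, site_id, contig, position, strand, read_id).
#' @export
simulate_position_reads <- function(genome, n_sites, replicates = 1,
                                    length_mean, length_sd,
                                    reads_per_site = 1, seed) {
  stopifnot(inherits(genome, "synthetic_genome"), n_sites * replicates >= 1)
  seed <- check_seed(seed)
  withr::local_seed(seed)
  lens <- contig_lengths_of(genome)

  # all positions are drawn before any read length so that two simulations
  # sharing a seed target identical locations regardless of length settings
  # (the study design compares read lengths at the same junctions)
  sites <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    ci <- sample.int(length(lens), n_sites, replace = TRUE, prob = lens)
    pos <- vapply(ci, function(i) sample.int(lens[i], 1) - 1L, integer(1))
    strand <- sample(c("+", "-"), n_sites, replace = TRUE)
    sites[[r]] <- tibble(replicate = r, s = seq_len(n_sites),
                         contig = names(lens)[ci], position = pos,
                         strand = strand)
  }
  sites <- list_rbind(sites)

  contig_chr <- stats::setNames(as.character(genome$contigs),
                                names(genome$contigs))
  rows <- vector("list", nrow(sites) * reads_per_site)
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    contig <- sites$contig[i]
    cs <- contig_chr[[contig]]
    clen <- nchar(cs)
    L <- truncated_normal_lengths(reads_per_site, length_mean, length_sd)
    for (j in seq_len(reads_per_site)) {
      if (sites$strand[i] == "+") {
        sq <- substr(cs, sites$position[i] + 1L,
                     min(sites$position[i] + L[j], clen))
      } else {
        sq <- revcomp(substr(cs, max(sites$position[i] - L[j] + 1L, 1L),
                             sites$position[i]))
      }
      k <- k + 1L
      rows[[k]] <- tibble(
        replicate = sites$replicate[i],
        site_id = sprintf("rep%02d_site%04d", sites$replicate[i], sites$s[i]),
        contig = contig, position = sites$position[i],
        strand = sites$strand[i],
        read_id = sprintf("pos_r%02d_s%04d_%02d", sites$replicate[i],
                          sites$s[i], j),
        seq = sq
      )
    }
  }
  truth <- list_rbind(rows)
  list(
    reads = transmute(truth, id = .data$read_id, seq = .data$seq,
                      replicate = .data$replicate, site_id = .data$site_id),
    truth = distinct(select(truth, -"seq"),
                     .data$replicate, .data$site_id, .keep_all = TRUE) |>
      select("replicate", "site_id", "contig", "position", "strand")
  )
}

#' Score detection of truth sites by calls or alignments
#'
#' A truth site counts as detected when at least one call lies on the same
#' contig (and in the same replicate, when both tables carry a `replicate`
#' column) within `tolerance` bp of it. Each site is additionally labelled
#' with the repeat family overlapping site +/- 10 bp ("non-repeat" if none),
#' so missed sites can be broken down by repeat class.
#'
#' @param truth Tibble with `contig` and `position` (or `site`) columns.
#' @param calls Tibble with `contig` and `site` (or `position`) columns —
#'   insertion calls or [junction_sites()] of passing alignments.
#' @param tolerance Maximum distance in bp (default 20).
#' @param repeat_annotation Optional repeat tibble (contig, start, end,
#'   family) for the missed-site classification.
#' @return The truth tibble with `detected` (logical), `nearest` (distance to
#'   the nearest same-contig call, NA if none) and `repeat_family` columns.
#' @export
score_detection <- function(truth, calls, tolerance = 20,
                            repeat_annotation = NULL) {
  stopifnot(tolerance >= 0)
  pos_col <- if ("position" %in% names(truth)) "position" else "site"
  call_col <- if ("site" %in% names(calls)) "site" else "position"
  by_rep <- "replicate" %in% names(truth) && "replicate" %in% names(calls)

  nearest <- vapply(seq_len(nrow(truth)), function(i) {
    sel <- calls$contig == truth$contig[i]
    if (by_rep) sel <- sel & calls$replicate == truth$replicate[i]
    d <- abs(calls[[call_col]][sel] - truth[[pos_col]][i])
    if (length(d) == 0) NA_real_ else min(d)
  }, numeric(1))

  out <- truth
  out$nearest <- nearest
  out$detected <- !is.na(nearest) & nearest <= tolerance
  out$repeat_family <- if (is.null(repeat_annotation) || nrow(repeat_annotation) == 0) {
    "non-repeat"
  } else {
    overlap_family(truth$contig, truth[[pos_col]], repeat_annotation, window = 10)
  }
  out
}

#' Write a synthetic genome to disk as plain-text files
#'
#' FASTA contigs, BED6 repeat annotation (family in the name column) and a
#' TSV insertion truth table.
#'
#' @param genome A `synthetic_genome`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(genome$contigs, fa)
  bed <- file.path(dir, "repeats.bed")
  readr::write_tsv(
    transmute(genome$repeats, .data$contig, .data$start, .data$end,
              name = .data$family, score = 0L, strand = "+"),
    bed, col_names = FALSE
  )
  tsv <- file.path(dir, "insertions.tsv")
  readr::write_tsv(genome$insertions, tsv)
  invisible(c(fasta = fa, repeats = bed, insertions = tsv))
}
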