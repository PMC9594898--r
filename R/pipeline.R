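# End-to-end orchestration: prep -> align -> classify -> anchored calls ->
# unanchored calls -> report; plus the read-length impact study and the
# in-silico limit-of-detection dilution series.

#' Run the full insertion-mapping pipeline
#'
#' Executes QC filtering, structure enforcement/trimming, UMI clustering and
#' consensus, mapping, anchored/unanchored classification, anchored peak
#' calling with the beta shape filter, and unanchored putative peak calling,
#' in that order. All thresholds come from `config`. The returned report
#' partitions every input read into exactly one terminal bin.
#'
#' @param reads Read tibble (`id`, `seq`, `qual`) or a FASTQ path.
#' @param genome Reference: `synthetic_genome` or named `DNAStringSet`.
#' @param structure A [read_structure()].
#' @param config A [pipeline_config()].
#' @param library Optional [repeat_library()] for unanchored calling; when
#'   NULL and `genome` is synthetic, the genome's planted family consensuses
#'   are used; otherwise unanchored reads stay unassigned.
#' @param outdir Optional output directory; when given, mapped reads BED,
#'   calls TSV/BED, cluster table, unanchored peak TSV and a JSON run report
#'   are written.
#' @return A list of class `insertmap_run`: `calls` (candidate evaluation
#'   tibble, calls are rows with `called`), `unanchored` (putative peak
#'   tibble), `alignments`, `clusters`, `processed`, `report` (list),
#'   `config`.
#' @export
run_pipeline <- function(reads, genome, structure, config = pipeline_config(),
                         library = NULL, outdir = NULL) {
  if (is.character(reads)) {
    if (!file.exists(reads)) abort(sprintf("input FASTQ not found: %s", reads))
    reads <- read_fastq(reads)
  }
  n_input <- nrow(reads)

  qc <- quality_length_filter(reads, config$min_mean_q, config$min_len)
  n_qc_failed <- n_input - nrow(qc)
  if (nrow(qc) == 0) abort("no reads survive quality/length filtering")

  processed <- demultiplex_and_extract(qc, structure)
  ok <- filter(processed, .data$status == "ok")
  n_structure_rejected <- nrow(processed) - nrow(ok)

  clusters <- cluster_umis(processed, config$max_umi_edits,
                           config$min_fragment_identity) |>
    consensus_fragments()

  alignments <- align_fragments(clusters, genome, preset = config$preset) |>
    classify_alignments(config$min_mapq)

  anchored <- filter(alignments, .data$anchor_class == "anchored")
  peaks <- form_peaks(anchored, config$max_gap)
  calls <- call_insertions(peaks, anchored, config)
  called <- filter(calls, .data$called)

  # unanchored branch (on cluster consensus fragments)
  un_ids <- alignments$query_id[alignments$anchor_class == "unanchored"]
  un <- clusters[clusters$cluster_id %in% un_ids,
                 c("cluster_id", "consensus", "size")]
  if (is.null(library) && inherits(genome, "synthetic_genome") &&
      length(genome$consensi)) {
    library <- repeat_library(genome)
  }
  un <- discard_called(un, called, genome, flank = config$discard_flank,
                       min_identity = config$min_identity)
  retained <- filter(un, !.data$in_called)
  if (!is.null(library)) {
    assigned <- assign_repeat(retained, library, config$min_assign_score) |>
      cluster_by_identity(config$min_identity)
    unanchored_peaks <- call_unanchored(
      assigned, library,
      anchored_mean_coverage = if (nrow(called)) mean(called$dedup_count) else NULL,
      config = config
    )
  } else {
    assigned <- mutate(retained, family = NA_character_,
                       rep_cluster = NA_character_)
    unanchored_peaks <- call_unanchored(assigned,
                                        repeat_library(c(none = "N")),
                                        NULL, config)
  }

  size_of <- stats::setNames(clusters$size, clusters$cluster_id)
  n_anchored <- sum(size_of[anchored$query_id])
  n_un_discarded <- sum(size_of[un$cluster_id[un$in_called]])
  n_un_assigned <- sum(size_of[assigned$cluster_id[!is.na(assigned$family)]])
  n_unassigned <- sum(size_of[assigned$cluster_id[is.na(assigned$family)]])

  report <- list(
    input = n_input,
    qc_failed = n_qc_failed,
    structure_rejected = n_structure_rejected,
    anchored = unname(n_anchored),
    unanchored_discarded = unname(n_un_discarded),
    unanchored_assigned = unname(n_un_assigned),
    unassigned = unname(n_unassigned),
    calls_anchored = nrow(called),
    calls_unanchored_putative = sum(unanchored_peaks$called),
    config = unclass(config),
    seed = config$seed,
    version = as.character(utils::packageVersion("insertmap"))
  )
  validate_report(report)

  run <- structure(list(
    calls = calls, unanchored = unanchored_peaks, alignments = alignments,
    clusters = clusters, processed = processed, report = report,
    config = config
  ), class = "insertmap_run")

  if (!is.null(outdir)) write_run(run, outdir)
  run
}

validate_report <- function(report) {
  terminal <- report$qc_failed + report$structure_rejected + report$anchored +
    report$unanchored_discarded + report$unanchored_assigned +
    report$unassigned
  if (terminal != report$input) {
    abort(sprintf("read accounting violated: terminal bins sum to %d, input %d",
                  terminal, report$input))
  }
  invisible(report)
}

#' @export
print.insertmap_run <- function(x, ...) {
  r <- x$report
  cat("<insertmap_run>\n")
  cat(sprintf("  reads: %d in | %d QC-failed | %d structure-rejected\n",
              r$input, r$qc_failed, r$structure_rejected))
  cat(sprintf("  reads: %d anchored | %d in called | %d repeat-assigned | %d unassigned\n",
              r$anchored, r$unanchored_discarded, r$unanchored_assigned,
              r$unassigned))
  cat(sprintf("  calls: %d anchored, %d unanchored (putative)\n",
              r$calls_anchored, r$calls_unanchored_putative))
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x An `insertmap_run`.
#' @param ... Unused.
#' @return A one-row tibble of the report counts.
#' @export
glance.insertmap_run <- function(x, ...) {
  r <- x$report
  tibble(
    input = r$input, qc_failed = r$qc_failed,
    structure_rejected = r$structure_rejected, anchored = r$anchored,
    unanchored_discarded = r$unanchored_discarded,
    unanchored_assigned = r$unanchored_assigned, unassigned = r$unassigned,
    calls_anchored = r$calls_anchored,
    calls_unanchored_putative = r$calls_unanchored_putative
  )
}

write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  export_bed(run$alignments, file.path(outdir, "mapped_reads.bed"))
  readr::write_tsv(select(run$calls, -any_of(c("member_ids", "coverage"))),
                   file.path(outdir, "calls.tsv"))
  called <- filter(run$calls, .data$called)
  readr::write_tsv(
    transmute(called, .data$contig, start = .data$site,
              end = .data$site + 1L, name = .data$peak_id,
              score = .data$dedup_count, strand = .data$strand),
    file.path(outdir, "calls.bed"), col_names = FALSE
  )
  readr::write_tsv(
    run$clusters |>
      mutate(member_ids = map_chr(.data$member_ids, paste, collapse = ",")) |>
      select("cluster_id", "barcode_id", "umi", "size", "member_ids",
             "consensus"),
    file.path(outdir, "clusters.tsv")
  )
  readr::write_tsv(mutate(run$unanchored, label = "putative"),
                   file.path(outdir, "unanchored_peaks.tsv"))
  jsonlite::write_json(run$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Read-length impact study
#'
#' For each read-length setting, simulates reads around random genomic
#' positions, maps and classifies them, and scores which truth positions are
#' recovered by anchored junction coordinates (peak calling is not applied).
#' Missed positions are labelled with the repeat family at the site
#' +/- 10 bp, so gains from longer reads can be attributed to repeat
#' classes.
#'
#' @param genome A `synthetic_genome`.
#' @param lengths Named list of `c(mean, sd)` read-length settings, e.g.
#'   `list(short = c(250, 10), long = c(1000, 25))`.
#' @param n_sites Positions per replicate (default 100).
#' @param replicates Replicates per setting (default 10).
#' @param reads_per_site Reads per position (default 1).
#' @param tolerance Detection tolerance in bp (default 20).
#' @param min_mapq Anchoring threshold (default 30).
#' @param seed Integer seed.
#' @return A list of class `length_study`: `detection` (per-site tibble with
#'   `length_label`) and `summary` (per length x replicate detected counts).
#' @export
run_length_study <- function(genome, lengths = list(short = c(250, 10),
                                                    long = c(1000, 25)),
                             n_sites = 100, replicates = 10,
                             reads_per_site = 1, tolerance = 20,
                             min_mapq = 30, seed = 1) {
  stopifnot(length(lengths) >= 2)
  seed <- check_seed(seed)
  if (is.null(names(lengths))) {
    names(lengths) <- vapply(lengths, function(x) sprintf("len%d", x[1]),
                             character(1))
  }
  det <- vector("list", length(lengths))
  for (k in seq_along(lengths)) {
    lm <- lengths[[k]][1]
    lsd <- lengths[[k]][2]
    # shared seed across settings: every read length is simulated at the
    # same truth locations, as the study design requires
    sim <- simulate_position_reads(genome, n_sites, replicates,
                                   length_mean = lm, length_sd = lsd,
                                   reads_per_site = reads_per_site,
                                   seed = derive_seed(seed, 0))
    aln <- align_fragments(sim$reads, genome,
                           preset = if (lm < 200) "short" else "long") |>
      classify_alignments(min_mapq)
    sites <- junction_sites(filter(aln, .data$anchor_class == "anchored"))
    sites$replicate <- sim$reads$replicate[match(sites$query_id,
                                                 sim$reads$id)]
    scored <- score_detection(sim$truth, sites, tolerance,
                              repeat_annotation = genome$repeats)
    scored$length_label <- names(lengths)[k]
    det[[k]] <- scored
  }
  detection <- list_rbind(det)
  summary <- detection |>
    group_by(.data$length_label, .data$replicate) |>
    summarise(n_sites = n(), detected = sum(.data$detected),
              fraction = mean(.data$detected), .groups = "drop")
  structure(list(detection = detection, summary = summary,
                 lengths = lengths),
            class = "length_study")
}

#' Sites gained by a longer read length
#'
#' @param study A `length_study`.
#' @param long,short Length labels to compare (defaults: last and first).
#' @return Tibble of truth sites detected at `long` but not at `short`.
#' @export
length_study_gains <- function(study, long = NULL, short = NULL) {
  labs <- unique(study$detection$length_label)
  long <- long %||% labs[length(labs)]
  short <- short %||% labs[1]
  d <- study$detection
  key <- c("replicate", "site_id")
  inner_join(
    filter(d, .data$length_label == long, .data$detected),
    filter(d, .data$length_label == short, !.data$detected) |>
      select(all_of(key)),
    by = key
  )
}

#' In-silico limit-of-detection dilution series
#'
#' Mixes junction reads of a minor single-insertion sample into a major
#' single-insertion sample at each dilution ratio, keeping total depth
#' fixed: the number of minor molecules is a binomial draw with success
#' probability r/(1+r) at ratio r. The full pipeline is run on each mixture
#' and the minor site counts as detected when an anchored call lies within
#' `tolerance` bp of it with `dedup_count >= min_dedup` (the study's calling
#' depth threshold).
#'
#' @param major,minor `junction_sim` objects, each simulated from a
#'   single-insertion genome; their pools must hold at least `total_reads`
#'   molecules.
#' @param genome Reference shared by both fixtures.
#' @param structure A [read_structure()].
#' @param dilutions Minor:major ratios (default 1, 1/10, ..., 1/10000).
#' @param total_reads Total molecules per mixture (default 1500).
#' @param min_dedup Minimum deduplicated coverage for the minor call
#'   (default 4).
#' @param tolerance Site-matching tolerance in bp (default 20).
#' @param config A [pipeline_config()].
#' @param seed Integer seed driving the binomial sampling.
#' @return A tibble of class `lod_study`: `dilution`, `n_minor`, `n_major`,
#'   `minor_called`; attribute `min_dedup`.
#' @export
run_lod_study <- function(major, minor, genome, structure,
                          dilutions = c(1, 0.1, 0.01, 0.001, 0.0001),
                          total_reads = 1500, min_dedup = 4, tolerance = 20,
                          config = pipeline_config(), seed = 1) {
  stopifnot(inherits(major, "junction_sim"), inherits(minor, "junction_sim"),
            all(dilutions > 0), all(dilutions <= 1))
  seed <- check_seed(seed)
  minor_site <- distinct(minor$truth, .data$contig, .data$site)
  if (nrow(minor_site) != 1) abort("minor fixture must carry one insertion")

  rows <- vector("list", length(dilutions))
  for (k in seq_along(dilutions)) {
    r <- dilutions[k]
    withr::local_seed(derive_seed(seed, k))
    n_minor <- stats::rbinom(1, total_reads, r / (1 + r))
    n_minor <- min(n_minor, nrow(minor$reads))
    n_major <- total_reads - n_minor
    if (n_major > nrow(major$reads)) {
      abort("major fixture pool smaller than requested depth")
    }
    mix <- bind_rows(
      if (n_minor > 0) {
        m <- minor$reads[sample.int(nrow(minor$reads), n_minor), ]
        m$id <- paste0("minor_", m$id)
        m
      },
      {
        M <- major$reads[sample.int(nrow(major$reads), n_major), ]
        M$id <- paste0("major_", M$id)
        M
      }
    )
    run <- run_pipeline(mix, genome, structure, config)
    called <- filter(run$calls, .data$called)
    hit <- called |>
      filter(.data$contig == minor_site$contig,
             abs(.data$site - minor_site$site) <= tolerance,
             .data$dedup_count >= min_dedup)
    rows[[k]] <- tibble(dilution = r, n_minor = n_minor, n_major = n_major,
                        minor_called = nrow(hit) > 0)
  }
  out <- list_rbind(rows)
  attr(out, "min_dedup") <- min_dedup
  class(out) <- c("lod_study", class(out))
  out
}

#' Minimal detectable dilution of an LOD study
#'
#' @param study A `lod_study` tibble.
#' @return The smallest dilution ratio at which the minor site was called
#'   (NA when never called).
#' @export
lod_minimal_ratio <- function(study) {
  det <- study$dilution[study$minor_called]
  if (length(det) == 0) NA_real_ else min(det)
}
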