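# Candidate peak formation, beta-density coverage-shape filtering, and
# insertion calling.

#' Pipeline thresholds and tunables
#'
#' One flat configuration object holding every threshold the pipeline
#' applies; all values are defaults, never hard-coded downstream.
#'
#' @param min_mean_q QC: minimum mean read quality (exclusive; 10).
#' @param min_len QC: minimum read length in bp (exclusive; 200).
#' @param min_mapq Anchoring: minimum mapping quality (exclusive; 30).
#' @param rss_threshold Shape filter: maximum beta-fit RSS (exclusive; 1).
#' @param max_gap Peak formation: maximum gap between member intervals (0).
#' @param unanchored_coverage_fraction Fraction of the anchored mean
#'   deduplicated coverage an unanchored cluster must reach (inclusive; 0.5).
#' @param unanchored_coverage_floor Coverage floor used when no anchored
#'   calls exist (2).
#' @param repeat_window Repeat-overlap annotation window in bp (10).
#' @param assoc_window Feature-association window in bp (100000).
#' @param n_random_negatives Random negative positions for association
#'   (10000).
#' @param max_umi_edits,min_fragment_identity UMI clustering gates (1, 0.9).
#' @param min_identity Unanchored clustering / discard identity gate (0.9).
#' @param discard_flank Flank extracted around called insertions when
#'   discarding unanchored reads that belong to them (bp per side; 2000).
#' @param min_assign_score Minimum local-alignment score for repeat-family
#'   assignment (30).
#' @param preset Mapping preset, "long" or "short".
#' @param seed Integer seed for every stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_mean_q = 10, min_len = 200, min_mapq = 30,
                            rss_threshold = 1, max_gap = 0,
                            unanchored_coverage_fraction = 0.5,
                            unanchored_coverage_floor = 2,
                            repeat_window = 10, assoc_window = 100000,
                            n_random_negatives = 10000,
                            max_umi_edits = 1, min_fragment_identity = 0.9,
                            min_identity = 0.9, discard_flank = 2000,
                            min_assign_score = 30,
                            preset = "long", seed = 1) {
  cfg <- list(
    min_mean_q = min_mean_q, min_len = min_len, min_mapq = min_mapq,
    rss_threshold = rss_threshold, max_gap = max_gap,
    unanchored_coverage_fraction = unanchored_coverage_fraction,
    unanchored_coverage_floor = unanchored_coverage_floor,
    repeat_window = repeat_window, assoc_window = assoc_window,
    n_random_negatives = n_random_negatives,
    max_umi_edits = max_umi_edits,
    min_fragment_identity = min_fragment_identity,
    min_identity = min_identity, discard_flank = discard_flank,
    min_assign_score = min_assign_score,
    preset = preset, seed = check_seed(seed)
  )
  nums <- vapply(cfg[setdiff(names(cfg), "preset")], is.numeric, logical(1))
  if (!all(nums)) abort("all thresholds must be numeric")
  if (any(unlist(cfg[c("min_mean_q", "min_len", "min_mapq", "rss_threshold",
                       "repeat_window", "assoc_window")]) < 0)) {
    abort("thresholds must be >= 0")
  }
  if (cfg$unanchored_coverage_fraction < 0 || cfg$unanchored_coverage_fraction > 1) {
    abort("unanchored_coverage_fraction must lie in [0, 1]")
  }
  structure(cfg, class = "pipeline_config")
}

#' Group anchored alignments into candidate peaks
#'
#' Candidate peaks are maximal sets of alignments whose reference intervals
#' form a connected union, allowing gaps of at most `max_gap` bp; the peak
#' interval is the union span and `coverage` the per-base read depth across
#' it.
#'
#' @param alignments Mapped alignment tibble (typically the anchored set).
#' @param max_gap Maximum gap between member intervals (default 0: intervals
#'   must touch or overlap).
#' @return Tibble with `peak_id`, `contig`, `start`, `end` (0-based
#'   half-open), `n_members`, `member_ids` (list), `coverage` (list of
#'   integer depth vectors of length `end - start`).
#' @export
form_peaks <- function(alignments, max_gap = 0) {
  al <- filter(alignments, .data$mapped)
  if (nrow(al) == 0) {
    return(tibble(peak_id = character(), contig = character(),
                  start = integer(), end = integer(), n_members = integer(),
                  member_ids = list(), coverage = list()))
  }
  gr <- GenomicRanges::GRanges(
    al$contig, IRanges::IRanges(start = al$start + 1L, end = al$end)
  )
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                               with.revmap = TRUE, ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  rows <- vector("list", length(red))
  for (p in seq_along(red)) {
    members <- revmap[[p]]
    p_start <- BiocGenerics::start(red)[p]  # 1-based
    p_end <- BiocGenerics::end(red)[p]
    cov <- integer(p_end - p_start + 1L)
    for (m in members) {
      a <- al$start[m] + 1L - p_start + 1L
      b <- al$end[m] - p_start + 1L
      cov[a:b] <- cov[a:b] + 1L
    }
    rows[[p]] <- tibble(
      peak_id = sprintf("peak_%04d", p),
      contig = as.character(GenomicRanges::seqnames(red))[p],
      start = p_start - 1L, end = p_end,
      n_members = length(members),
      member_ids = list(al$query_id[members]),
      coverage = list(cov)
    )
  }
  list_rbind(rows)
}

# Beta-density RSS objective -------------------------------------------
#
# Positions are mapped to bin midpoints x_i = (i - 0.5)/L and the coverage
# vector is normalised to a discrete density d_i = c_i * L / sum(c), so that
# sum(d_i)/L = 1 and the statistic is invariant to coverage scaling. The
# objective is RSS(a, b) = mean((d_i - dbeta(x_i; a, b))^2).

beta_rss_objective <- function(coverage) {
  L <- length(coverage)
  x <- (seq_len(L) - 0.5) / L
  d <- coverage * L / sum(coverage)
  list(x = x, d = d, lx = log(x), l1x = log1p(-x), L = L)
}

# RSS for all (alpha, beta) grid pairs, chunked over alpha; log-densities
# are computed directly via lgamma to keep this path independent of
# stats::dbeta-based oracles.
grid_rss <- function(obj, alphas, betas) {
  best <- c(rss = Inf, alpha = NA_real_, beta = NA_real_)
  bm1 <- betas - 1
  M1 <- outer(obj$l1x, bm1)           # L x nb
  for (a in alphas) {
    logf <- (a - 1) * obj$lx + M1 +
      rep(lgamma(a + betas) - lgamma(a) - lgamma(betas), each = obj$L)
    f <- exp(logf)
    rss <- colMeans((obj$d - f)^2)
    j <- which.min(rss)
    if (rss[j] < best[["rss"]]) {
      best <- c(rss = rss[j], alpha = a, beta = betas[j])
    }
  }
  best
}

#' Fit a beta density to a coverage profile by least squares
#'
#' The shape statistic of the peak filter: coverage positions are mapped to
#' bin midpoints of (0, 1), the profile is normalised to a discrete density
#' (making the statistic invariant to coverage scaling), and beta-density
#' parameters are chosen to minimise the mean squared residual. The
#' optimiser is a bounded grid over alpha, beta in `bounds` at `grid_step`,
#' optionally followed by multistart local refinement (L-BFGS-B from the
#' best grid points); both stages are deterministic.
#'
#' @param coverage Integer/numeric depth vector (length >= 3, some depth > 0).
#' @param grid_step Grid spacing for the parameter search (default 1).
#' @param bounds Lower/upper bound for both parameters (default c(0.1, 50)).
#' @param refine Run local refinement after the grid stage (default TRUE).
#' @return An object of class `beta_shape_fit`: list with `alpha`, `beta`,
#'   `rss`, `n` (profile length), `coverage`, `refined`.
#' @export
#' @examples
#' prof <- dbeta((1:200 - 0.5) / 200, 2, 5)
#' fit <- beta_shape_rss(prof)
#' fit$rss
beta_shape_rss <- function(coverage, grid_step = 1, bounds = c(0.1, 50),
                           refine = TRUE) {
  coverage <- as.numeric(coverage)
  if (length(coverage) < 3) abort("coverage must have length >= 3")
  if (all(coverage == 0)) abort("coverage is all zero")
  if (any(coverage < 0)) abort("coverage must be non-negative")
  obj <- beta_rss_objective(coverage)
  grid <- seq(bounds[1], bounds[2], by = grid_step)
  best <- grid_rss(obj, grid, grid)

  rss_fun <- function(p) {
    f <- exp(lgamma(p[1] + p[2]) - lgamma(p[1]) - lgamma(p[2]) +
               (p[1] - 1) * obj$lx + (p[2] - 1) * obj$l1x)
    mean((obj$d - f)^2)
  }

  if (refine) {
    starts <- unique(rbind(
      c(best[["alpha"]], best[["beta"]]),
      c(1, 1),
      moment_start(obj, bounds)
    ))
    for (s in seq_len(nrow(starts))) {
      o <- tryCatch(
        stats::optim(starts[s, ], rss_fun, method = "L-BFGS-B",
                     lower = bounds[1], upper = bounds[2]),
        error = function(e) NULL
      )
      if (!is.null(o) && o$value < best[["rss"]]) {
        best <- c(rss = o$value, alpha = o$par[1], beta = o$par[2])
      }
    }
  }

  structure(list(
    alpha = unname(best[["alpha"]]), beta = unname(best[["beta"]]),
    rss = unname(best[["rss"]]), n = obj$L, coverage = coverage,
    refined = refine
  ), class = "beta_shape_fit")
}

# method-of-moments start from the profile treated as a histogram
moment_start <- function(obj, bounds) {
  w <- obj$d / sum(obj$d)
  mu <- sum(w * obj$x)
  v <- sum(w * (obj$x - mu)^2)
  if (v <= 0 || mu <= 0 || mu >= 1) return(c(1, 1))
  common <- mu * (1 - mu) / v - 1
  p <- c(mu * common, (1 - mu) * common)
  pmin(pmax(p, bounds[1]), bounds[2])
}

#' @export
print.beta_shape_fit <- function(x, ...) {
  cat(sprintf("<beta_shape_fit> alpha = %.3f, beta = %.3f, rss = %.4g (L = %d)\n",
              x$alpha, x$beta, x$rss, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a beta shape fit
#'
#' @param x A `beta_shape_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (term, estimate); `glance()`: one
#'   row with `rss`, `alpha`, `beta`, `n`, `refined`.
#' @export
tidy.beta_shape_fit <- function(x, ...) {
  tibble(term = c("alpha", "beta"), estimate = c(x$alpha, x$beta))
}

#' @rdname tidy.beta_shape_fit
#' @export
glance.beta_shape_fit <- function(x, ...) {
  tibble(rss = x$rss, alpha = x$alpha, beta = x$beta, n = x$n,
         refined = x$refined)
}

#' Call insertions from candidate peaks
#'
#' Fits the beta shape statistic to every candidate's coverage profile and
#' calls a peak when its RSS is strictly below `config$rss_threshold`.
#' Degenerate peaks (span < 3 bp) bypass the fit and are rejected
#' (`rss = NA`, `degenerate = TRUE`). The call site is the modal member
#' junction coordinate (ties toward the smaller coordinate), the strand the
#' modal member strand (ties to "+"), and `dedup_count` the number of
#' distinct UMI clusters among members (the number of members when each
#' member is already a cluster consensus).
#'
#' @param peaks [form_peaks()] output.
#' @param alignments The alignment tibble the peaks were formed from (used
#'   for member junction coordinates and strands).
#' @param config A [pipeline_config()].
#' @return Tibble with one row per candidate: `peak_id`, `contig`, `site`,
#'   `strand`, `dedup_count`, `n_members`, `rss`, `alpha`, `beta`,
#'   `degenerate`, `called`. Calls are the rows with `called == TRUE`.
#' @export
call_insertions <- function(peaks, alignments, config = pipeline_config()) {
  js <- junction_sites(alignments)
  rows <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    members <- peaks$member_ids[[i]]
    mj <- js[js$query_id %in% members, ]
    site <- modal_value(mj$site)
    strand <- modal_value(mj$strand, prefer = "+")
    cov <- peaks$coverage[[i]]
    degenerate <- length(cov) < 3
    fit <- if (degenerate) NULL else beta_shape_rss(cov)
    rows[[i]] <- tibble(
      peak_id = peaks$peak_id[i], contig = peaks$contig[i],
      site = as.integer(site), strand = strand,
      dedup_count = if ("cluster_id" %in% names(alignments)) {
        n_distinct(alignments$cluster_id[alignments$query_id %in% members])
      } else {
        length(unique(members))
      },
      n_members = peaks$n_members[i],
      rss = if (degenerate) NA_real_ else fit$rss,
      alpha = if (degenerate) NA_real_ else fit$alpha,
      beta = if (degenerate) NA_real_ else fit$beta,
      degenerate = degenerate
    )
  }
  out <- if (length(rows)) list_rbind(rows) else
    tibble(peak_id = character(), contig = character(), site = integer(),
           strand = character(), dedup_count = integer(),
           n_members = integer(), rss = numeric(), alpha = numeric(),
           beta = numeric(), degenerate = logical())
  mutate(out, called = !.data$degenerate & .data$rss < config$rss_threshold)
}

# modal value; ties broken toward the smallest (numeric) or `prefer`
modal_value <- function(x, prefer = NULL) {
  if (length(x) == 0) return(if (is.null(prefer)) NA else prefer)
  tb <- table(x)
  winners <- names(tb)[tb == max(tb)]
  if (!is.null(prefer) && prefer %in% winners) return(prefer)
  w <- sort(winners)[1]
  if (is.numeric(x)) as.numeric(w) else w
}

#' Evaluate the shape filter over a grid of RSS thresholds
#'
#' Given labelled coverage profiles (true insertion peaks versus negatives),
#' computes each profile's RSS once and reports the true/false positive rate
#' of the rule `rss < t` for every threshold in `thresholds`. This is the
#' calibration design used to set the default threshold.
#'
#' @param labelled Tibble with list column `coverage` and logical `is_true`.
#' @param thresholds Numeric vector of candidate thresholds.
#' @return Tibble `threshold`, `tpr`, `fpr`, `n_pos`, `n_neg`.
#' @export
evaluate_shape_threshold <- function(labelled, thresholds) {
  stopifnot(any(labelled$is_true), any(!labelled$is_true))
  rss <- map_dbl(labelled$coverage, function(cv) beta_shape_rss(cv)$rss)
  n_pos <- sum(labelled$is_true)
  n_neg <- sum(!labelled$is_true)
  tibble(
    threshold = thresholds,
    tpr = map_dbl(thresholds, function(t) sum(rss[labelled$is_true] < t) / n_pos),
    fpr = map_dbl(thresholds, function(t) sum(rss[!labelled$is_true] < t) / n_neg),
    n_pos = n_pos, n_neg = n_neg
  )
}
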