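# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_tile geom_boxplot labs theme_minimal scale_fill_gradient2 facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a beta shape fit over its normalised coverage profile
#'
#' @param object A `beta_shape_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beta_shape_fit <- function(object, ...) {
  L <- object$n
  x <- (seq_len(L) - 0.5) / L
  df <- tibble(
    x = x,
    density = object$coverage * L / sum(object$coverage),
    fitted = stats::dbeta(x, object$alpha, object$beta)
  )
  ggplot(df, aes(x = .data$x)) +
    geom_col(aes(y = .data$density), width = 1 / L,
             fill = "grey70", colour = NA) +
    geom_line(aes(y = .data$fitted), colour = "#4059ad", linewidth = 0.9) +
    labs(x = "relative position in peak", y = "normalised coverage density",
         title = sprintf("beta(%.2f, %.2f) fit, RSS = %.3g",
                         object$alpha, object$beta, object$rss)) +
    theme_minimal()
}

#' Plot per-replicate detection fractions of a read-length study
#'
#' @param object A `length_study`.
#' @param ... Unused.
#' @return A ggplot (boxplot of detection fraction by read-length setting).
#' @export
autoplot.length_study <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$length_label, y = .data$fraction)) +
    geom_boxplot(fill = "grey85", outlier.shape = NA) +
    geom_point(position = ggplot2::position_jitter(width = 0.08, seed = 1),
               colour = "#4059ad") +
    labs(x = "read length setting", y = "fraction of sites detected") +
    theme_minimal()
}

#' Heat-map of feature-association AUCs
#'
#' @param assoc Tibble of [feature_assoc_auc()] rows (optionally with a
#'   `sample` column for multi-sample heat maps).
#' @return A ggplot tile map centred at AUC 0.5 (positive association blue,
#'   negative red).
#' @export
plot_association <- function(assoc) {
  if (!"sample" %in% names(assoc)) assoc$sample <- "sample"
  ggplot(assoc, aes(x = .data$sample, y = .data$feature,
                    fill = .data$auc)) +
    geom_tile(colour = "white") +
    scale_fill_gradient2(midpoint = 0.5, limits = c(0, 1),
                         low = "#b2182b", mid = "white", high = "#2166ac") +
    labs(x = NULL, y = NULL, fill = "AUC") +
    theme_minimal()
}

#' Plot the coverage profile of one candidate peak
#'
#' @param peaks [form_peaks()] output.
#' @param peak_id Which peak to draw.
#' @return A ggplot of per-base depth across the peak interval.
#' @export
plot_peak_coverage <- function(peaks, peak_id) {
  i <- match(peak_id, peaks$peak_id)
  if (is.na(i)) abort(sprintf("unknown peak_id: %s", peak_id))
  cov <- peaks$coverage[[i]]
  df <- tibble(pos = peaks$start[i] + seq_along(cov) - 1L, depth = cov)
  ggplot(df, aes(x = .data$pos, y = .data$depth)) +
    geom_col(width = 1, fill = "grey40") +
    labs(x = sprintf("%s position (bp)", peaks$contig[i]), y = "read depth",
         title = peak_id) +
    theme_minimal()
}
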