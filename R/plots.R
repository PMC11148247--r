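#' Plot per-sample dosage-ratio profiles
#'
#' Line plot of dosage ratios across ROIs, one line per sample, with the
#' deletion/duplication calling thresholds drawn as horizontal guides. A
#' heterozygous deletion shows as a run of points near 0.5.
#'
#' @param ratios Dosage-ratio tibble from [normalize_depth()].
#' @param del_max,dup_min Thresholds to draw (defaults as in [call_cnv()]).
#' @return A ggplot object.
#' @export
plot_dosage_ratios <- function(ratios, del_max = 0.65, dup_min = 1.35) {
  roi_ids <- setdiff(names(ratios), "sample_id")
  long <- tidyr::pivot_longer(ratios, dplyr::all_of(roi_ids),
                              names_to = "roi", values_to = "ratio")
  long$roi <- factor(long$roi, levels = roi_ids)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$roi, y = .data$ratio,
                                     group = .data$sample_id,
                                     colour = .data$sample_id)) +
    ggplot2::geom_hline(yintercept = c(del_max, 1, dup_min),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = "grey50") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "region of interest", y = "dosage ratio",
                  colour = "sample") +
    ggplot2::theme_minimal()
}

#' Plot the recombinant-exclusion ladder of a shared core
#'
#' Shared haplotype span as carriers are greedily excluded: the x axis is
#' the number of haplotypes still sharing, the y axis the physical span of
#' their common core.
#'
#' @param x A `core_result` from [shared_core()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot core_result
#' @export
autoplot.core_result <- function(x, ...) {
  ggplot2::ggplot(x$ladder, ggplot2::aes(x = .data$n, y = .data$span_mb)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "haplotypes sharing", y = "shared span (Mb)") +
    ggplot2::theme_minimal()
}

#' Plot per-marker founder-age estimates
#'
#' Dot plot of the per-marker age estimates (generations) against marker
#' distance to the variant, with the aggregate mean drawn as a horizontal
#' line and excluded markers shown hollow at zero.
#'
#' @param x A `founder_age` object from [estimate_age()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot founder_age
#' @export
autoplot.founder_age <- function(x, ...) {
  mk <- x$markers
  mk$d_cm <- if ("d_morgans" %in% names(mk)) mk$d_morgans * 100 else NA_real_
  ggplot2::ggplot(mk, ggplot2::aes(x = .data$d_cm, y = .data$t,
                                   shape = .data$included)) +
    ggplot2::geom_hline(yintercept = x$t_generations, colour = "steelblue") +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "marker distance to variant (cM)",
                  y = "estimated age (generations)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot penetrance by subgroup
#'
#' Bar chart of phenotype-positive fractions for a set of cohort subgroups
#' (e.g. per sex, or per age threshold), annotated with affected/total.
#'
#' @param penetrance_tbl A tibble with columns `group`, `n_affected`,
#'   `n_total` (e.g. built by binding [penetrance()] rows).
#' @return A ggplot object.
#' @export
plot_penetrance <- function(penetrance_tbl) {
  stopifnot(all(c("group", "n_affected", "n_total") %in% names(penetrance_tbl)))
  df <- mutate(penetrance_tbl,
               percent = 100 * .data$n_affected / .data$n_total,
               label = sprintf("%d/%d", .data$n_affected, .data$n_total))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4) +
    ggplot2::ylim(0, 105) +
    ggplot2::labs(x = NULL, y = "penetrance (%)") +
    ggplot2::theme_minimal()
}
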