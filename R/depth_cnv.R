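#' Normalise a read-depth count matrix to dosage ratios
#'
#' Implements the cross-sample read-depth strategy used for CNV detection on
#' targeted panels: the raw read count of each region of interest (ROI) is
#' first normalised within each sample against that sample's control ROIs
#' (per-sample factor = median raw count over control ROIs), then compared
#' across all samples of the run (per-ROI run reference = median of the
#' normalised values). The resulting dosage ratio is ~1 for a diploid
#' region, ~0.5 over a heterozygous deletion, and ~1.5 over a heterozygous
#' duplication.
#'
#' @param counts Count tibble: a `sample_id` column plus one non-negative
#'   integer column per ROI, ROIs ordered by genomic position.
#' @param control_rois Character vector of control ROI names (a non-empty
#'   subset of the ROI columns).
#'
#' @return A tibble of the same shape with dosage ratios in place of counts,
#'   carrying attributes `control_rois`, `sample_factors` and
#'   `roi_reference`.
#' @export
#' @examples
#' m <- simulate_depth(n_samples = 4, roi_ids = paste0("E", 1:5),
#'                     control_rois = c("E1", "E5"), mean_depth = 100,
#'                     deleted_rois = list(S1 = c("E2", "E3", "E4")))
#' normalize_depth(m, c("E1", "E5"))
normalize_depth <- function(counts, control_rois) {
  stopifnot(is.data.frame(counts), "sample_id" %in% names(counts))
  roi_ids <- setdiff(names(counts), "sample_id")
  if (length(control_rois) == 0) {
    fh_abort("control ROI set must be non-empty", "founderhap_domain_error")
  }
  missing <- setdiff(control_rois, roi_ids)
  if (length(missing) > 0) {
    fh_abort(paste0("control ROI(s) not in matrix: ", toString(missing)),
             "founderhap_schema_error")
  }
  if (nrow(counts) < 2) {
    fh_abort("read-depth normalisation needs >= 2 samples in the run (no cross-sample reference)",
             "founderhap_domain_error")
  }
  m <- as.matrix(counts[, roi_ids])
  if (any(m < 0)) fh_abort("counts must be non-negative", "founderhap_domain_error")
  factors <- apply(m[, control_rois, drop = FALSE], 1, median)
  zero <- which(factors <= 0)
  if (length(zero) > 0) {
    fh_abort(
      sprintf("sample %s has no reads over the control ROIs",
              counts$sample_id[zero[1]]),
      "founderhap_zero_controls"
    )
  }
  normed <- m / factors
  reference <- apply(normed, 2, median)
  ratio <- sweep(normed, 2, reference, "/")
  out <- bind_cols(tibble(sample_id = counts$sample_id), as_tibble(ratio))
  attr(out, "control_rois") <- control_rois
  attr(out, "sample_factors") <- setNames(factors, counts$sample_id)
  attr(out, "roi_reference") <- reference
  out
}

#' Call copy-number variants from dosage ratios
#'
#' Scans each sample's dosage-ratio profile for maximal contiguous runs of
#' ROIs whose ratio falls at or below `del_max` (deletions) or at or above
#' `dup_min` (duplications). A heterozygous deletion halves the dosage
#' (ratio ~0.5) and a heterozygous duplication raises it to ~1.5; the
#' default guard bands 0.65/1.35 sit midway between those signals and the
#' diploid ratio of 1. Control ROIs are never called and break runs.
#'
#' @param ratios Dosage-ratio tibble from [normalize_depth()].
#' @param del_max Upper ratio bound for a deletion call (default 0.65).
#' @param dup_min Lower ratio bound for a duplication call (default 1.35).
#' @param min_rois Minimum run length to report (default 1).
#'
#' @return A tibble of calls: `sample_id`, `first_roi`, `last_roi`,
#'   `n_rois`, `type` (`"deletion"`/`"duplication"`), `mean_ratio`. Zero
#'   rows when no CNV is detected.
#' @export
call_cnv <- function(ratios, del_max = 0.65, dup_min = 1.35, min_rois = 1L) {
  stopifnot(is.data.frame(ratios), "sample_id" %in% names(ratios))
  if (!(del_max > 0 && del_max < 1 && dup_min > 1)) {
    fh_abort("thresholds must satisfy 0 < del_max < 1 < dup_min",
             "founderhap_domain_error")
  }
  roi_ids <- setdiff(names(ratios), "sample_id")
  control_rois <- attr(ratios, "control_rois") %||% character(0)
  m <- as.matrix(ratios[, roi_ids])
  calls <- purrr::map(seq_len(nrow(m)), function(i) {
    state <- unname(ifelse(m[i, ] <= del_max, "deletion",
                           ifelse(m[i, ] >= dup_min, "duplication", "neutral")))
    state[roi_ids %in% control_rois] <- "neutral"
    rl <- rle(state)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values != "neutral" & rl$lengths >= min_rois
    if (!any(keep)) return(NULL)
    tibble(
      sample_id = ratios$sample_id[i],
      first_roi = roi_ids[starts[keep]],
      last_roi = roi_ids[ends[keep]],
      n_rois = rl$lengths[keep],
      type = rl$values[keep],
      mean_ratio = map_dbl(which(keep), function(k) {
        mean(m[i, starts[k]:ends[k]])
      })
    )
  })
  out <- list_rbind(purrr::compact(calls))
  if (nrow(out) == 0) {
    out <- tibble(
      sample_id = character(), first_roi = character(),
      last_roi = character(), n_rois = integer(),
      type = character(), mean_ratio = numeric()
    )
  }
  out
}

#' Deletion span from breakpoint coordinates
#'
#' Size of a deletion given its two breakpoint coordinates, as the absolute
#' coordinate difference `|start - end|`. This is the coordinate-difference
#' convention (an inclusive base count over 1-based fully-closed HGVS
#' coordinates would be one larger); it is orientation-insensitive, so
#' breakpoints may be given in either order, including the descending order
#' conventional for HGVS `g.` deletion notation.
#'
#' @param start,end Positive breakpoint coordinates (bp); vectorised.
#'
#' @return Span(s) in base pairs.
#' @export
#' @examples
#' deletion_span(47360721, 47357175) # 3546
deletion_span <- function(start, end) {
  if (any(start <= 0 | end <= 0)) {
    fh_abort("breakpoint coordinates must be positive", "founderhap_domain_error")
  }
  if (any(start == end)) {
    fh_abort("breakpoints must differ (start == end)", "founderhap_domain_error")
  }
  abs(start - end)
}
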