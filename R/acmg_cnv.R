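#' Segregation evidence points for a copy-number loss
#'
#' Point value of the co-segregation evidence criterion in the ClinGen
#' point-based CNV interpretation framework: 0.45 points for 7 or more
#' observed segregations of the CNV with disease, 0.30 for 5-6, 0.15 for
#' 3-4, and nothing below 3. The tier table is data-driven and can be
#' replaced (e.g. to track a revised standard).
#'
#' @param n_segregations Number of observed segregations (>= 0); vectorised.
#' @param tiers Tier table: a data frame with columns `min_n` and `points`,
#'   default loaded from the packaged ClinGen table.
#'
#' @return Points awarded (numeric).
#' @export
#' @examples
#' segregation_points(19) # 0.45
#' segregation_points(4)  # 0.15
segregation_points <- function(n_segregations,
                               tiers = acmg_segregation_tiers()) {
  if (any(n_segregations < 0)) {
    fh_abort("number of segregations must be non-negative",
             "founderhap_domain_error")
  }
  tiers <- tiers[order(tiers$min_n), ]
  vapply(n_segregations, function(n) {
    hit <- tiers$points[tiers$min_n <= n]
    if (length(hit) == 0) 0 else hit[length(hit)]
  }, numeric(1))
}

#' @rdname segregation_points
#' @param path Optional path to a JSON tier table (array of objects with
#'   `min_n` and `points`).
#' @export
acmg_segregation_tiers <- function(path = NULL) {
  path <- path %||% system.file("extdata", "acmg_segregation_tiers.json",
                                package = "founderhap", mustWork = TRUE)
  as_tibble(jsonlite::fromJSON(path))
}

#' @rdname classify_cnv
#' @param path Optional path to a JSON threshold table (array of objects
#'   with `min_score`, `label`, `class`).
#' @export
acmg_class_thresholds <- function(path = NULL) {
  path <- path %||% system.file("extdata", "acmg_class_thresholds.json",
                                package = "founderhap", mustWork = TRUE)
  as_tibble(jsonlite::fromJSON(path))
}

#' Point-based ACMG/ClinGen copy-number-loss classification
#'
#' Sums the evidence points of a copy-number-loss evidence set and maps the
#' total onto the five-class scale of the ClinGen CNV interpretation
#' standard: total >= 0.99 pathogenic (class 5), 0.90-0.98 likely
#' pathogenic (4), -0.89-0.89 uncertain significance (3), -0.98 - -0.90
#' likely benign (2), <= -0.99 benign (1). The threshold table is
#' data-driven and replaceable.
#'
#' @param evidence A data frame with columns `criterion` (unique ids, e.g.
#'   `"1A"`, `"2E"`, `"4F/5D"`), `points` (numeric), and optionally `note`
#'   (free-text justification, e.g. recording sequence-level sub-evidence
#'   such as PVS1 or PP1). An empty evidence set yields a VUS at 0 points.
#' @param thresholds Class threshold table; see [acmg_class_thresholds()].
#'
#' @return An object of class `cnv_classification`: list with `evidence`,
#'   `total` and one-row `classification` tibble (`label`, `class`).
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   criterion = c("1A", "2E", "3A", "4F/5D"),
#'   points = c(0, 0.9, 0, 0.45)
#' )
#' classify_cnv(ev)
classify_cnv <- function(evidence = NULL, thresholds = acmg_class_thresholds()) {
  if (is.null(evidence) || nrow(evidence) == 0) {
    evidence <- tibble(criterion = character(), points = numeric())
  }
  stopifnot(all(c("criterion", "points") %in% names(evidence)))
  if (anyDuplicated(evidence$criterion)) {
    fh_abort("duplicate evidence criterion ids", "founderhap_duplicate_criterion")
  }
  total <- sum(evidence$points)
  thresholds <- thresholds[order(-thresholds$min_score), ]
  row <- which(thresholds$min_score <= total)[1]
  structure(
    list(
      evidence = as_tibble(evidence),
      total = total,
      classification = tibble(
        label = thresholds$label[row],
        class = as.integer(thresholds$class[row])
      )
    ),
    class = "cnv_classification"
  )
}

#' @export
print.cnv_classification <- function(x, ...) {
  cat(sprintf("CNV classification: %s (class %d), total %.2f points\n",
              x$classification$label, x$classification$class, x$total))
  if (nrow(x$evidence) > 0) print(x$evidence)
  invisible(x)
}

#' Count observed segregations in a cohort
#'
#' An observed segregation is a phenotype-positive relative who also carries
#' the variant (genotype-positive); probands are excluded as the
#' ascertainment events.
#'
#' @param cohort Cohort tibble with `role`, `genotype` and `hcm_phenotype`
#'   columns.
#'
#' @return Integer count.
#' @export
#' @examples
#' count_segregations(build_cohort_fixture()) # 19
count_segregations <- function(cohort) {
  needed <- c("role", "genotype", "hcm_phenotype")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    fh_abort(paste0("cohort is missing column(s): ", toString(missing)),
             "founderhap_schema_error")
  }
  sum(cohort$role == "relative" & cohort$hcm_phenotype &
        cohort$genotype == "G+", na.rm = TRUE)
}
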