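#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a founder-age estimate
#'
#' @param x A `founder_age` object from [estimate_age()].
#' @param ... Unused.
#' @return The per-marker tibble (`marker_id`, `pd1`, `pn2`, `r`, `t`,
#'   `included`, `reason`).
#' @method tidy founder_age
#' @export
tidy.founder_age <- function(x, ...) x$markers

#' @rdname tidy.founder_age
#' @return For `glance()`: a one-row tibble with `t_generations`, `n_used`,
#'   `n_excluded`.
#' @method glance founder_age
#' @export
glance.founder_age <- function(x, ...) {
  tibble(
    t_generations = x$t_generations,
    n_used = x$n_used,
    n_excluded = x$n_excluded
  )
}

#' Tidy a shared-core result
#'
#' @param x A `core_result` object from [shared_core()].
#' @param ... Unused.
#' @return The recombinant-exclusion ladder tibble (`n`, `first`, `last`,
#'   `span_mb`, `dropped`).
#' @method tidy core_result
#' @export
tidy.core_result <- function(x, ...) x$ladder

#' @rdname tidy.core_result
#' @return For `glance()`: one row with `n_haplotypes`, `span_mb`,
#'   `first_marker`, `last_marker`.
#' @method glance core_result
#' @export
glance.core_result <- function(x, ...) {
  tibble(
    n_haplotypes = x$core$n_haplotypes,
    span_mb = x$core$span_mb,
    first_marker = ifelse(is.na(x$core$first), NA_character_,
                          x$map$marker_id[x$core$first]),
    last_marker = ifelse(is.na(x$core$last), NA_character_,
                         x$map$marker_id[x$core$last])
  )
}

#' Tidy a CNV classification
#'
#' @param x A `cnv_classification` object from [classify_cnv()].
#' @param ... Unused.
#' @return The evidence tibble.
#' @method tidy cnv_classification
#' @export
tidy.cnv_classification <- function(x, ...) x$evidence

#' @rdname tidy.cnv_classification
#' @return For `glance()`: one row with `total`, `label`, `class`.
#' @method glance cnv_classification
#' @export
glance.cnv_classification <- function(x, ...) {
  tibble(
    total = x$total,
    label = x$classification$label,
    class = x$classification$class
  )
}

#' Tidy a sex-stratified penetrance result
#'
#' @param x A `sex_penetrance` object from [sex_stratified_penetrance()].
#' @param ... Unused.
#' @return The per-sex tibble.
#' @method tidy sex_penetrance
#' @export
tidy.sex_penetrance <- function(x, ...) x$by_sex

#' @rdname tidy.sex_penetrance
#' @return For `glance()`: one row with the comparison `method`,
#'   `statistic`, `p_value` (all `NA` when only one sex is present).
#' @method glance sex_penetrance
#' @export
glance.sex_penetrance <- function(x, ...) {
  if (is.null(x$test)) {
    tibble(method = NA_character_, statistic = NA_real_, p_value = NA_real_)
  } else {
    x$test
  }
}
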