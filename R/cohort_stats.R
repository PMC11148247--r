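# Shared filter for the cohort analytics: restrict by role, genotype and a
# minimum current age. NULL keeps everyone.
filter_cohort <- function(cohort, role = NULL, genotype = NULL, min_age = 0) {
  out <- cohort
  if (!is.null(role)) out <- dplyr::filter(out, .data$role %in% !!role)
  if (!is.null(genotype)) out <- dplyr::filter(out, .data$genotype %in% !!genotype)
  if (min_age > 0) out <- dplyr::filter(out, .data$age_current >= !!min_age)
  out
}

#' Penetrance of the phenotype in a cohort subgroup
#'
#' Fraction of individuals with the HCM phenotype among those passing the
#' group filter and an optional minimum current age, e.g. the penetrance
#' among genotype-positive relatives aged 50 or older.
#'
#' @param cohort Cohort tibble (see [build_cohort_fixture()] for the column
#'   dictionary).
#' @param role Optional filter: `"proband"`, `"relative"` or both.
#' @param genotype Optional filter: `"G+"`, `"G-"` or both.
#' @param min_age Minimum current age (years); default 0 (no threshold).
#'
#' @return A one-row tibble: `n_affected`, `n_total`, `fraction`, `percent`
#'   (rounded to one decimal for reporting).
#' @export
#' @examples
#' penetrance(build_cohort_fixture(), role = "relative", genotype = "G+",
#'            min_age = 50)
penetrance <- function(cohort, role = NULL, genotype = NULL, min_age = 0) {
  sub <- filter_cohort(cohort, role, genotype, min_age)
  if (nrow(sub) == 0) {
    fh_abort("no individuals left after filtering", "founderhap_empty_group")
  }
  n_aff <- sum(sub$hcm_phenotype, na.rm = TRUE)
  tibble(
    n_affected = n_aff,
    n_total = nrow(sub),
    fraction = n_aff / nrow(sub),
    percent = round(100 * n_aff / nrow(sub), 1)
  )
}

#' Sex-stratified penetrance with a 2x2 comparison
#'
#' Penetrance per sex within a cohort subgroup, plus a chi-square (or, when
#' any expected cell count falls below 5, Fisher exact) comparison of the
#' two sexes' affected fractions. The chi-square is computed without
#' continuity correction by default (see [compare_groups()]).
#'
#' @inheritParams penetrance
#' @param correct Apply the Yates continuity correction to the chi-square;
#'   default `FALSE`.
#'
#' @return An object of class `sex_penetrance`: a list with `by_sex` (tibble
#'   of `sex`, `n_affected`, `n_total`, `fraction`, `percent`) and `test`
#'   (one-row tibble of `method`, `statistic`, `p_value`, or `NULL` when
#'   only one sex is present). Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
sex_stratified_penetrance <- function(cohort, role = NULL, genotype = NULL,
                                      min_age = 0, correct = FALSE) {
  sub <- filter_cohort(cohort, role, genotype, min_age)
  if (nrow(sub) == 0) {
    fh_abort("no individuals left after filtering", "founderhap_empty_group")
  }
  by_sex <- sub |>
    group_by(sex = .data$sex) |>
    summarise(
      n_affected = sum(.data$hcm_phenotype, na.rm = TRUE),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      fraction = .data$n_affected / .data$n_total,
      percent = round(100 * .data$fraction, 1)
    ) |>
    arrange(dplyr::desc(.data$sex)) # M first
  test <- NULL
  if (nrow(by_sex) == 2) {
    tab <- rbind(
      by_sex$n_affected,
      by_sex$n_total - by_sex$n_affected
    )
    test <- two_by_two_test(tab, correct = correct)
  }
  structure(list(by_sex = by_sex, test = test), class = "sex_penetrance")
}

#' @export
print.sex_penetrance <- function(x, ...) {
  print(x$by_sex)
  if (!is.null(x$test)) {
    cat(sprintf("%s: statistic = %.3f, p = %.4g\n",
                x$test$method, x$test$statistic, x$test$p_value))
  }
  invisible(x)
}

# 2x2 association test: chi-square (no continuity correction unless asked),
# falling back to Fisher's exact test when any expected count is below 5.
two_by_two_test <- function(tab, correct = FALSE) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- fisher.test(tab)
    tibble(method = "Fisher exact", statistic = NA_real_,
           p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    tibble(method = "chi-square", statistic = unname(ct$statistic),
           p_value = ct$p.value)
  }
}

#' Outcome counts and composite prevalence in a cohort subgroup
#'
#' Counts each recorded cardiac outcome and the predefined composite
#' (death, transplantation, life-threatening arrhythmia, heart-failure
#' hospitalisation or septal reduction) among individuals with outcome
#' follow-up in the filtered subgroup, together with the median follow-up.
#'
#' @inheritParams penetrance
#'
#' @return A tibble with one row per outcome (`outcome`, `n_events`,
#'   `n_total`, `percent`), the composite as the last row, carrying the
#'   median follow-up in attribute `median_followup_years`.
#' @export
#' @examples
#' outcome_summary(build_cohort_fixture(), genotype = "G+")
outcome_summary <- function(cohort, role = NULL, genotype = NULL, min_age = 0) {
  sub <- filter_cohort(cohort, role, genotype, min_age)
  sub <- dplyr::filter(sub, .data$has_outcome_followup)
  if (nrow(sub) == 0) {
    fh_abort("no individuals with outcome follow-up after filtering",
             "founderhap_empty_group")
  }
  sub <- add_composite_outcome(sub)
  flags <- c(
    cardiac_death = "outcome_cardiac_death",
    heart_transplant = "outcome_htx",
    life_threatening_arrhythmia = "outcome_lta",
    hf_hospitalization = "outcome_hf_hosp",
    septal_reduction = "outcome_septal",
    device = "outcome_device",
    composite = "composite_outcome"
  )
  out <- tibble(
    outcome = names(flags),
    n_events = unname(vapply(flags, function(f) sum(sub[[f]]), integer(1))),
    n_total = nrow(sub)
  ) |>
    mutate(percent = round(100 * .data$n_events / .data$n_total, 1))
  attr(out, "median_followup_years") <- median(sub$followup_years, na.rm = TRUE)
  out
}

#' Compare a variable between two cohort groups
#'
#' Two-group comparison in the style of a clinical baseline table:
#' categorical (logical or factor/character) variables are compared by
#' chi-square without continuity correction, falling back to Fisher's exact
#' test when any expected cell count is below 5; continuous variables by
#' unpaired t-test when both groups pass a Shapiro normality check (alpha
#' 0.05), otherwise Mann-Whitney U. Two-sided throughout.
#'
#' @param cohort Cohort tibble.
#' @param variable Name of the column to compare (string).
#' @param group_var Column defining groups (default `"role"`).
#' @param groups Length-2 character vector of group levels to compare
#'   (default the two most frequent levels, in order of appearance).
#' @param correct Yates continuity correction for the chi-square; default
#'   `FALSE`.
#' @param force_test Override the automatic test choice: one of `"chi-square"`,
#'   `"fisher"`, `"t"`, `"mann-whitney"`, or `NULL` (automatic).
#'
#' @return A one-row tibble: `variable`, `group1`, `group2`, `n1`, `n2`,
#'   `summary1`, `summary2` (count (%) or mean +/- sd), `test`, `statistic`,
#'   `p_value`.
#' @export
#' @examples
#' compare_groups(build_cohort_fixture(), "symptomatic",
#'                group_var = "role", groups = c("proband", "relative"))
compare_groups <- function(cohort, variable, group_var = "role",
                           groups = NULL, correct = FALSE,
                           force_test = NULL) {
  if (!variable %in% names(cohort)) {
    fh_abort(paste0("unknown variable: ", variable), "founderhap_schema_error")
  }
  g <- cohort[[group_var]]
  if (is.null(groups)) groups <- unique(g)[seq_len(2)]
  stopifnot(length(groups) == 2)
  x1 <- cohort[[variable]][g == groups[1]]
  x2 <- cohort[[variable]][g == groups[2]]
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  if (length(x1) == 0 || length(x2) == 0) {
    fh_abort("variable is all-missing in one of the groups",
             "founderhap_empty_group")
  }
  categorical <- is.logical(cohort[[variable]]) ||
    is.character(cohort[[variable]]) || is.factor(cohort[[variable]])
  if (categorical) {
    # 2 x k contingency table over observed levels
    lev <- sort(unique(c(x1, x2)))
    tab <- rbind(
      vapply(lev, function(l) sum(x1 == l), integer(1)),
      vapply(lev, function(l) sum(x2 == l), integer(1))
    )
    test <- force_test %||%
      (if (any(outer(rowSums(tab), colSums(tab)) / sum(tab) < 5)) "fisher"
       else "chi-square")
    res <- if (test == "fisher") {
      ft <- fisher.test(tab)
      list(method = "Fisher exact", statistic = NA_real_, p = ft$p.value)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = correct))
      list(method = "chi-square", statistic = unname(ct$statistic),
           p = ct$p.value)
    }
    summarise_cat <- function(x) {
      if (is.logical(x)) {
        sprintf("%d (%.1f%%)", sum(x), 100 * mean(x))
      } else {
        paste(vapply(lev, function(l) sum(x == l), integer(1)), collapse = "/")
      }
    }
    s1 <- summarise_cat(x1); s2 <- summarise_cat(x2)
  } else {
    normal <- length(x1) >= 3 && length(x2) >= 3 &&
      length(unique(x1)) > 1 && length(unique(x2)) > 1 &&
      shapiro.test(x1)$p.value >= 0.05 && shapiro.test(x2)$p.value >= 0.05
    test <- force_test %||% (if (normal) "t" else "mann-whitney")
    res <- if (test == "t") {
      tt <- t.test(x1, x2)
      list(method = "t", statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(x1, x2, exact = FALSE))
      list(method = "Mann-Whitney", statistic = unname(wt$statistic),
           p = wt$p.value)
    }
    s1 <- sprintf("%.1f +/- %.1f", mean(x1), sd(x1))
    s2 <- sprintf("%.1f +/- %.1f", mean(x2), sd(x2))
  }
  tibble(
    variable = variable,
    group1 = as.character(groups[1]), group2 = as.character(groups[2]),
    n1 = length(x1), n2 = length(x2),
    summary1 = s1, summary2 = s2,
    test = res$method, statistic = res$statistic, p_value = res$p
  )
}

#' Index an echocardiographic measure to body surface area
#'
#' Wall thicknesses and atrial diameters scale with body size; dividing by
#' body surface area (m^2) makes them comparable across sexes and statures.
#'
#' @param value Measurement (mm or cm); vectorised.
#' @param bsa Body surface area in m^2 (> 0); vectorised.
#'
#' @return `value / bsa`, in the measurement's unit per m^2.
#' @export
#' @examples
#' bsa_index(20, 2.0) # 10 mm/m^2
bsa_index <- function(value, bsa) {
  if (any(bsa <= 0, na.rm = TRUE)) {
    fh_abort("body surface area must be positive", "founderhap_domain_error")
  }
  value / bsa
}

#' Nearest-age matching without replacement
#'
#' Selects, for each index individual, the unused comparison individual with
#' the closest current age (greedy, processing index individuals in order of
#' their age), yielding an age-matched comparison subgroup.
#'
#' @param cohort Cohort tibble.
#' @param index_filter,pool_filter Logical vectors (or expressions evaluated
#'   in `cohort`) selecting the index group and the matching pool.
#' @param n_matches Number of matches to return (default: size of the
#'   smaller of pool and index group).
#'
#' @return The matched subset of the pool rows.
#' @export
match_by_age <- function(cohort, index_filter, pool_filter,
                         n_matches = NULL) {
  idx <- which(index_filter)
  pool <- which(pool_filter)
  if (length(idx) == 0 || length(pool) == 0) {
    fh_abort("empty index group or matching pool", "founderhap_empty_group")
  }
  n_matches <- n_matches %||% min(length(idx), length(pool))
  idx <- idx[order(cohort$age_current[idx])]
  used <- integer(0)
  for (i in idx) {
    if (length(used) >= n_matches) break
    avail <- setdiff(pool, used)
    if (length(avail) == 0) break
    used <- c(used, avail[which.min(abs(cohort$age_current[avail] -
                                          cohort$age_current[i]))])
  }
  cohort[used, ]
}
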