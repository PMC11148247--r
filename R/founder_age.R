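#' Haldane map function
#'
#' Converts a genetic distance in Morgans into a recombination fraction under
#' the Haldane (no-interference) model, `r = (1 - exp(-2 d)) / 2`. The
#' recombination fraction is the per-meiosis probability of an odd number of
#' crossovers between two loci; it increases monotonically with distance and
#' saturates at 1/2 for unlinked loci.
#'
#' @param d Genetic distance in Morgans (cM / 100); non-negative, vectorised.
#'
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
#' @examples
#' haldane_r(0)      # 0
#' haldane_r(0.01)   # ~0.0099
#' haldane_r(10)     # ~0.5
haldane_r <- function(d) {
  if (any(d < 0)) {
    fh_abort("genetic distance d must be non-negative", "founderhap_domain_error")
  }
  (1 - exp(-2 * d)) / 2
}

#' Single-marker founder-variant age estimate
#'
#' Linkage-disequilibrium decay dating of a founder variant from one flanking
#' marker. If the founder chromosome carried a marker allele whose frequency
#' among carrier haplotypes is `Pd1` after `t` generations of recombination at
#' fraction `r` per meiosis, while the allele's background frequency on
#' non-carrier haplotypes is `Pn2`, then the expected decay is
#' `Pd1 = (1 - r)^t + (1 - (1 - r)^t) * Pn2`, which inverts to
#'
#' `t = ln((Pd1 - Pn2) / (1 - Pn2)) / ln(1 - r)`.
#'
#' @param pd1 Frequency of the founder marker allele among variant-carrying
#'   haplotypes, in `(0, 1)`. `pd1 = 1` is degenerate: the formula would date
#'   the variant to age 0 regardless of `r`, so it is rejected (see
#'   [estimate_age()] for the exclusion pathway).
#' @param pn2 Frequency of the founder marker allele among non-carrier
#'   haplotypes, in `[0, 1)`; must be below `pd1`.
#' @param r Recombination fraction between the marker and the variant, in
#'   `(0, 0.5)`; usually derived from physical distance via [haldane_r()].
#'
#' @return Estimated age in generations (vectorised over the inputs).
#' @seealso [estimate_age()] for multi-marker averaging with exclusions,
#'   [to_calendar()] for conversion to calendar years.
#' @export
#' @examples
#' marker_age(0.9, 0.2, 0.05) # ~2.60
#' # exact inversion of the decay model:
#' g <- 4; r <- 0.1; pn2 <- 0.25
#' marker_age((1 - r)^g + (1 - (1 - r)^g) * pn2, pn2, r) # 4
marker_age <- function(pd1, pn2, r) {
  n <- max(length(pd1), length(pn2), length(r))
  pd1 <- rep_len(pd1, n); pn2 <- rep_len(pn2, n); r <- rep_len(r, n)
  if (any(r <= 0 | r >= 0.5)) {
    fh_abort("recombination fraction r must lie in (0, 0.5)", "founderhap_domain_error")
  }
  if (any(pn2 < 0 | pn2 >= 1)) {
    fh_abort("Pn2 must lie in [0, 1)", "founderhap_domain_error")
  }
  if (any(pd1 >= 1)) {
    fh_abort(
      "Pd1 = 1: fully preserved marker allele is degenerate for LD dating (estimated age would be 0)",
      "founderhap_degenerate_marker"
    )
  }
  if (any(pd1 <= pn2)) {
    fh_abort(
      "Pd1 <= Pn2: marker shows no excess founder-allele sharing (uninformative)",
      "founderhap_uninformative_marker"
    )
  }
  log((pd1 - pn2) / (1 - pn2)) / log(1 - r)
}

# Non-throwing per-marker evaluation used by estimate_age().
marker_age_status <- function(pd1, pn2, r) {
  if (!is.finite(r) || r <= 0 || r >= 0.5) {
    return(list(t = NA_real_, included = FALSE, reason = "r outside (0, 0.5)"))
  }
  if (!is.finite(pd1) || !is.finite(pn2) || pn2 < 0 || pn2 >= 1) {
    return(list(t = NA_real_, included = FALSE, reason = "invalid frequencies"))
  }
  if (pd1 >= 1) {
    return(list(t = NA_real_, included = FALSE, reason = "degenerate (Pd1 = 1)"))
  }
  if (pd1 <= pn2) {
    return(list(t = NA_real_, included = FALSE, reason = "uninformative (Pd1 <= Pn2)"))
  }
  list(t = marker_age(pd1, pn2, r), included = TRUE, reason = NA_character_)
}

#' Multi-marker founder-variant age estimate
#'
#' Applies [marker_age()] to every marker in a frequency table, excludes
#' markers on which the estimator is undefined (fully preserved founder
#' allele, `Pd1 = 1`; or no excess sharing, `Pd1 <= Pn2`), and aggregates the
#' remaining per-marker estimates by their unweighted arithmetic mean.
#'
#' @param freqs A data frame with one row per marker and columns `marker_id`,
#'   `pd1`, `pn2`, and either `r` (recombination fraction) or `d_morgans`
#'   (distance to the variant in Morgans, converted via [haldane_r()]).
#'   See [marker_frequencies()] to derive such a table from phased
#'   haplotypes.
#'
#' @return An object of class `founder_age`: a list with `markers` (the input
#'   augmented with `r`, `t`, `included`, `reason`), `t_generations` (the
#'   aggregate estimate), `n_used` and `n_excluded`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' freqs <- tibble::tibble(
#'   marker_id = c("A", "B"),
#'   pd1 = c(0.742075, 0.9), pn2 = c(0.25, 0.2),
#'   r = c(0.1, 0.05)
#' )
#' est <- estimate_age(freqs)
#' est$t_generations
estimate_age <- function(freqs) {
  stopifnot(is.data.frame(freqs), nrow(freqs) >= 1)
  freqs <- as_tibble(freqs)
  if (!"marker_id" %in% names(freqs)) {
    freqs$marker_id <- paste0("marker_", seq_len(nrow(freqs)))
  }
  if (!all(c("pd1", "pn2") %in% names(freqs))) {
    fh_abort("freqs must have columns pd1 and pn2", "founderhap_schema_error")
  }
  if (!"r" %in% names(freqs)) {
    if (!"d_morgans" %in% names(freqs)) {
      fh_abort("freqs must have either an r or a d_morgans column",
               "founderhap_schema_error")
    }
    freqs$r <- haldane_r(freqs$d_morgans)
  }
  status <- pmap(
    list(freqs$pd1, freqs$pn2, freqs$r),
    marker_age_status
  )
  markers <- freqs |>
    mutate(
      t = map_dbl(status, "t"),
      included = purrr::map_lgl(status, "included"),
      reason = map_chr(status, "reason")
    )
  if (!any(markers$included)) {
    fh_abort("no informative markers: all were excluded from the age estimate",
             "founderhap_no_informative_markers")
  }
  structure(
    list(
      markers = markers,
      t_generations = mean(markers$t[markers$included]),
      n_used = sum(markers$included),
      n_excluded = sum(!markers$included)
    ),
    class = "founder_age"
  )
}

#' @export
print.founder_age <- function(x, ...) {
  cat(sprintf(
    "Founder-variant age estimate: %.2f generations (mean of %d markers; %d excluded)\n",
    x$t_generations, x$n_used, x$n_excluded
  ))
  print(x$markers)
  invisible(x)
}

#' Convert a generation-scale age to calendar years
#'
#' A founder event dated at `t` generations happened roughly
#' `t * span_years` years before the present-day carriers' average age is
#' anchored, i.e. `years_ago = t * span_years + anchor_age_years`. With the
#' conventional 25-year generation and an anchor at the carriers' mean age,
#' `t = 5` dates the event 188 years back.
#'
#' @param t Age in generations (non-negative).
#' @param span_years Assumed years per generation; default 25.
#' @param anchor_age_years Mean current age of the sampled carriers, added so
#'   the clock starts at their birth cohort; default 63.
#' @param reference_year Calendar year from which `years_ago` is counted
#'   back; default the current year.
#'
#' @return A tibble with columns `t`, `years_ago` and `founder_year`.
#' @export
#' @examples
#' to_calendar(5, reference_year = 2023) # 188 years ago, ~1835
to_calendar <- function(t, span_years = 25, anchor_age_years = 63,
                        reference_year = as.integer(format(Sys.Date(), "%Y"))) {
  if (any(t < 0)) fh_abort("t must be non-negative", "founderhap_domain_error")
  years_ago <- t * span_years + anchor_age_years
  tibble(
    t = t,
    years_ago = years_ago,
    founder_year = reference_year - years_ago
  )
}

#' Per-marker founder-allele frequencies from phased haplotypes
#'
#' Derives the frequency table consumed by [estimate_age()] from carrier and
#' non-carrier haplotypes: `pd1` is the frequency of the founder allele
#' (the modal allele among carriers, see [infer_founder_alleles()]) on
#' carrier haplotypes; `pn2` its frequency on non-carrier haplotypes (or a
#' supplied population frequency); `d_morgans` the marker-variant distance on
#' the genetic map.
#'
#' @param haps Wide haplotype tibble (`haplotype_id`, `carrier`,
#'   `allele_<marker>` columns; 0 codes a missing allele).
#' @param map Marker map (see [marker_map()]).
#' @param variant_bp Physical position of the variant (bp).
#' @param pn2 Optional numeric vector of population founder-allele
#'   frequencies (one per marker, map order). When omitted, `pn2` is
#'   estimated from the non-carrier haplotypes in `haps`.
#'
#' @return A tibble with columns `marker_id`, `founder_allele`, `pd1`,
#'   `pn2`, `d_morgans`, `r`.
#' @export
marker_frequencies <- function(haps, map, variant_bp, pn2 = NULL) {
  map <- validate_marker_map(map)
  carriers <- dplyr::filter(haps, .data$carrier == 1)
  if (nrow(carriers) == 0) {
    fh_abort("no carrier haplotypes", "founderhap_domain_error")
  }
  founder <- infer_founder_alleles(carriers, map)
  cm <- hap_allele_matrix(carriers, map)
  pd1 <- vapply(seq_len(nrow(map)), function(j) {
    a <- cm[, j]
    a <- a[a != 0L]
    mean(a == founder$allele[j])
  }, numeric(1))
  if (is.null(pn2)) {
    noncar <- dplyr::filter(haps, .data$carrier == 0)
    if (nrow(noncar) == 0) {
      fh_abort(
        "no non-carrier haplotypes in `haps`; supply pn2 explicitly",
        "founderhap_domain_error"
      )
    }
    nm <- hap_allele_matrix(noncar, map)
    pn2 <- vapply(seq_len(nrow(map)), function(j) {
      a <- nm[, j]
      a <- a[a != 0L]
      if (length(a) == 0) NA_real_ else mean(a == founder$allele[j])
    }, numeric(1))
  }
  d <- marker_d_morgans(map, variant_bp)
  tibble(
    marker_id = map$marker_id,
    founder_allele = founder$allele,
    pd1 = pd1,
    pn2 = rep_len(pn2, nrow(map)),
    d_morgans = d,
    r = haldane_r(d)
  )
}

#' Probability of observing the founder haplotype by chance
#'
#' Given the population frequencies of the intragenic SNP alleles that make
#' up the shared genetic background, the probability that one random
#' haplotype matches the founder configuration is the product over SNPs of
#' the allele frequency (where the founder haplotype carries the minor
#' allele, state `"present"`) or its complement (state `"absent"`). The
#' probability that all `n` unrelated index patients carry it by chance is
#' that product raised to the `n`-th power, computed in log space.
#'
#' @param snps A data frame with columns `freq` (population allele frequency,
#'   strictly inside `(0, 1)`) and `founder_state` (`"present"` or
#'   `"absent"`), optionally `snp_id`. See [intragenic_snp_table()] for the
#'   packaged gnomAD-frequency table.
#' @param n_individuals Number of unrelated carriers observed (>= 1).
#'
#' @return A tibble with one row: `p_haplotype` (single-haplotype match
#'   probability), `log10_p_cohort`, `p_cohort` (`p_haplotype ^ n`), and
#'   `n_individuals`.
#' @export
#' @examples
#' haplotype_match_probability(
#'   tibble::tibble(freq = 0.5, founder_state = "present"), 1
#' )
haplotype_match_probability <- function(snps, n_individuals) {
  stopifnot(is.data.frame(snps), n_individuals >= 1)
  if (!all(c("freq", "founder_state") %in% names(snps))) {
    fh_abort("snps must have columns freq and founder_state",
             "founderhap_schema_error")
  }
  if (any(snps$freq <= 0 | snps$freq >= 1)) {
    fh_abort("degenerate SNP: frequencies must lie strictly in (0, 1)",
             "founderhap_domain_error")
  }
  state <- tolower(snps$founder_state)
  if (!all(state %in% c("present", "absent"))) {
    fh_abort("founder_state must be 'present' or 'absent'",
             "founderhap_schema_error")
  }
  term <- ifelse(state == "present", snps$freq, 1 - snps$freq)
  log_p <- sum(log(term))
  tibble(
    p_haplotype = exp(log_p),
    log10_p_cohort = n_individuals * log_p / log(10),
    p_cohort = exp(n_individuals * log_p),
    n_individuals = as.integer(n_individuals)
  )
}

#' Packaged intragenic SNP frequency table
#'
#' Six intragenic *MYBPC3* SNPs defining the shared genetic background of the
#' founder haplotype, with gnomAD v4 population allele frequencies (overall
#' and non-Finnish European) and the founder-haplotype state of each allele.
#'
#' @param population `"nfe"` (non-Finnish European, default) or `"all"`.
#'
#' @return A tibble with columns `snp_id`, `position`, `freq`,
#'   `founder_state`.
#' @export
intragenic_snp_table <- function(population = c("nfe", "all")) {
  population <- match.arg(population)
  path <- system.file("extdata", "mybpc3_intragenic_snps.tsv",
                      package = "founderhap", mustWork = TRUE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  tibble(
    snp_id = tbl$snp_id,
    position = tbl$position,
    freq = if (population == "nfe") tbl$freq_nfe else tbl$freq_all,
    founder_state = tbl$founder_state
  )
}
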