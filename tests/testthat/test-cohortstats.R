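cohort <- build_cohort_fixture(seed = 1L)

test_that("penetrance reproduces the fixture's headline fractions", {
  p50 <- penetrance(cohort, role = "relative", genotype = "G+", min_age = 50)
  expect_equal(c(p50$n_affected, p50$n_total), c(11L, 14L))
  expect_equal(p50$percent, 78.6)
  pall <- penetrance(cohort, role = "relative", genotype = "G+")
  expect_equal(c(pall$n_affected, pall$n_total), c(19L, 37L))
  expect_equal(pall$percent, 51.4)
  # age-cumulative fixture: penetrance does not fall as the cut rises
  expect_gte(p50$fraction, pall$fraction)
  expect_error(
    penetrance(cohort, role = "relative", genotype = "G+", min_age = 200),
    class = "founderhap_empty_group"
  )
})

test_that("sex-stratified penetrance reproduces the male/female split and its chi-square", {
  sp <- sex_stratified_penetrance(cohort, role = "relative", genotype = "G+")
  by_sex <- tidy(sp)
  expect_equal(by_sex$sex, c("M", "F"))
  expect_equal(by_sex$n_affected, c(11L, 8L))
  expect_equal(by_sex$n_total, c(14L, 23L))
  expect_equal(by_sex$percent, c(78.6, 34.8))
  g <- glance(sp)
  expect_equal(g$method, "chi-square")
  # closed-form 2x2 oracle, no continuity correction
  expect_equal(g$statistic, chisq_2x2_closed_form(11, 3, 8, 15))
  expect_equal(g$p_value, 0.010, tolerance = 0.05)
  expect_lt(abs(g$p_value - 0.010), 0.001)
  # all-affected toy cohort: both sexes 100%, comparison degenerate at p = 1
  toy <- tibble::tibble(
    role = "relative", genotype = "G+", sex = rep(c("M", "F"), each = 4),
    age_current = 40, hcm_phenotype = TRUE
  )
  toy_sp <- sex_stratified_penetrance(toy)
  expect_true(all(tidy(toy_sp)$fraction == 1))
  expect_equal(glance(toy_sp)$p_value, 1)
  # one sex absent: per-sex result with comparison omitted
  one <- sex_stratified_penetrance(dplyr::filter(cohort, sex == "F"))
  expect_null(one$test)
})

test_that("outcome summary counts components and composite over the follow-up denominator", {
  all_carriers <- outcome_summary(cohort, genotype = "G+")
  comp <- dplyr::filter(all_carriers, outcome == "composite")
  expect_equal(c(comp$n_events, comp$n_total), c(12L, 59L))
  expect_equal(comp$percent, 20.3)
  pro <- outcome_summary(cohort, role = "proband")
  expect_equal(dplyr::filter(pro, outcome == "composite")$percent, 33.3)
  over50 <- outcome_summary(cohort, genotype = "G+", min_age = 50)
  comp50 <- dplyr::filter(over50, outcome == "composite")
  expect_equal(c(comp50$n_events, comp50$n_total), c(11L, 38L))
  expect_equal(comp50$percent, 28.9)
  # device is reported but not part of the composite
  dev <- dplyr::filter(all_carriers, outcome == "device")
  expect_equal(dev$n_events, 7L)
  expect_true(!is.null(attr(all_carriers, "median_followup_years")))
})

test_that("group comparison picks the right test and reproduces printed significance", {
  carriers <- dplyr::filter(cohort, genotype == "G+")
  sym <- compare_groups(carriers, "symptomatic", group_var = "role",
                        groups = c("proband", "relative"))
  expect_equal(sym$test, "chi-square")
  expect_equal(sym$statistic, chisq_2x2_closed_form(12, 12, 5, 32),
               tolerance = 1e-12)
  expect_equal(sym$statistic, 9.64, tolerance = 0.001)
  expect_lt(abs(sym$p_value - 0.002), 0.0005)
  # identical groups: p = 1
  same <- dplyr::bind_rows(
    dplyr::mutate(carriers, role = "a"),
    dplyr::mutate(carriers, role = "b")
  )
  expect_equal(compare_groups(same, "symptomatic", groups = c("a", "b"))$p_value, 1)
  # continuous variable routes through t or Mann-Whitney
  age <- compare_groups(carriers, "age_current", group_var = "role",
                        groups = c("proband", "relative"))
  expect_true(age$test %in% c("t", "Mann-Whitney"))
  expect_lt(age$p_value, 0.001)
  expect_error(
    compare_groups(dplyr::mutate(carriers, ghost = NA_real_), "ghost"),
    class = "founderhap_empty_group"
  )
})

test_that("small expected counts fall back to Fisher's exact test", {
  carriers <- dplyr::filter(cohort, genotype == "G+")
  dev <- compare_groups(carriers, "outcome_device", group_var = "role",
                        groups = c("proband", "relative"))
  expect_equal(dev$test, "Fisher exact") # 7 events overall: expected cell < 5
  expect_lt(dev$p_value, 0.05)
  # a well-filled table keeps the chi-square
  hcm <- compare_groups(dplyr::filter(cohort, role == "relative"),
                        "hcm_phenotype", group_var = "genotype",
                        groups = c("G-", "G+"))
  expect_equal(hcm$test, "chi-square")
  expect_lt(hcm$p_value, 0.001)
})

test_that("BSA indexing divides by body surface area and rejects nonpositive areas", {
  expect_equal(bsa_index(20, 2.0), 10)
  expect_equal(bsa_index(18.6, 2.0), 9.3)
  expect_equal(bsa_index(0, 1.8), 0)
  expect_error(bsa_index(20, 0), class = "founderhap_domain_error")
})

test_that("nearest-age matching returns an age-comparable subgroup without replacement", {
  probands <- cohort$role == "proband"
  pool <- cohort$role == "relative" & cohort$genotype == "G+"
  matched <- match_by_age(cohort, probands, pool, n_matches = 16)
  expect_equal(nrow(matched), 16)
  expect_true(all(matched$genotype == "G+") && all(matched$role == "relative"))
  expect_equal(anyDuplicated(matched$id), 0)
  # matched relatives should skew much older than the full relative pool
  expect_gt(mean(matched$age_current), mean(cohort$age_current[pool]))
})
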