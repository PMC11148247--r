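test_that("descent with zero recombination retains the founder allele everywhere", {
  map <- marker_map("M1", "chr1", 2e6)
  haps <- simulate_descent(map, variant_bp = 2e6, founder_alleles = 4L,
                           pop_freqs = 0.3, g = 1, n_carriers = 100,
                           seed = 1)
  expect_true(all(haps$allele_M1[haps$carrier == 1] == 4L))
})

test_that("founder-allele retention converges to the closed-form probability", {
  # r = 0.1 at d = ln(0.8)/-2 Morgans; expected carrier frequency
  # 0.9^4 + (1 - 0.9^4) * 0.25 = 0.7421
  d <- -log(1 - 2 * 0.1) / 2
  map <- marker_map("M1", "chr1", round(2e6 + d * 1e8))
  n <- 100000
  haps <- simulate_descent(map, variant_bp = 2e6, founder_alleles = 1L,
                           pop_freqs = 0.25, g = 4, n_carriers = n, seed = 13)
  r_actual <- haldane_r(marker_d_morgans(map, 2e6))
  p_expect <- (1 - r_actual)^4 + (1 - (1 - r_actual)^4) * 0.25
  p_obs <- mean(haps$allele_M1[haps$carrier == 1] == 1L)
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(p_obs - p_expect), 3 * se)
  expect_equal(p_expect, 0.7421, tolerance = 1e-3)
})

test_that("non-carrier haplotypes draw from the background frequency", {
  map <- marker_map("M1", "chr1", 5e6)
  haps <- simulate_descent(map, variant_bp = 2e6, founder_alleles = 2L,
                           pop_freqs = 0.4, g = 3, n_carriers = 10,
                           n_noncarriers = 20000, seed = 5)
  p <- mean(haps$allele_M1[haps$carrier == 0] == 2L)
  expect_lt(abs(p - 0.4), 3 * sqrt(0.4 * 0.6 / 20000))
})

test_that("descent simulation is reproducible and warns on uninformative markers", {
  map <- marker_map(c("M1", "M2"), "chr1", c(3e6, 5e6))
  a <- simulate_descent(map, 2e6, c(1L, 2L), c(0.2, 0.3), g = 2,
                        n_carriers = 50, n_noncarriers = 50, seed = 99)
  b <- simulate_descent(map, 2e6, c(1L, 2L), c(0.2, 0.3), g = 2,
                        n_carriers = 50, n_noncarriers = 50, seed = 99)
  expect_identical(a, b)
  expect_error(
    simulate_descent(map, 2e6, 1L, 1.5, g = 2, n_carriers = 5, seed = 1),
    class = "founderhap_domain_error"
  )
  # zero distance with a fixed background allele carries no dating signal
  map0 <- marker_map("M1", "chr1", 2e6)
  expect_warning(
    simulate_descent(map0, 2e6, 1L, 1.0, g = 1, n_carriers = 5, seed = 1),
    regexp = "uninformative"
  )
})

test_that("noiseless depth simulation is exact, integer and reproducible", {
  m <- simulate_depth(4, paste0("E", 1:5), c("E1", "E5"), 100,
                      deleted_rois = list(S1 = c("E2", "E3", "E4")))
  expect_equal(unlist(m[m$sample_id == "S1", -1], use.names = FALSE),
               c(100L, 50L, 50L, 50L, 100L))
  expect_true(all(vapply(m[-1], is.integer, logical(1))))
  m2 <- simulate_depth(4, paste0("E", 1:5), c("E1", "E5"), 100,
                       deleted_rois = list(S1 = c("E2", "E3", "E4")))
  expect_identical(m, m2)
  # poisson mode reproducible under the seed
  p1 <- simulate_depth(4, paste0("E", 1:5), c("E1", "E5"), 100,
                       noise = "poisson", seed = 4)
  p2 <- simulate_depth(4, paste0("E", 1:5), c("E1", "E5"), 100,
                       noise = "poisson", seed = 4)
  expect_identical(p1, p2)
  # control ROIs must never be deleted; empty control set refused
  expect_error(
    simulate_depth(4, paste0("E", 1:5), "E2", 100,
                   deleted_rois = list(S1 = c("E2", "E3"))),
    class = "founderhap_domain_error"
  )
  expect_error(
    simulate_depth(4, paste0("E", 1:5), character(0), 100),
    class = "founderhap_domain_error"
  )
})

test_that("cohort fixture satisfies every integer constraint, for any seed", {
  for (seed in c(1L, 7L, 123L)) {
    co <- build_cohort_fixture(seed)
    expect_equal(nrow(co), 83)
    pro <- dplyr::filter(co, role == "proband")
    gplus <- dplyr::filter(co, role == "relative", genotype == "G+")
    gminus <- dplyr::filter(co, role == "relative", genotype == "G-")
    expect_equal(nrow(pro), 24)
    expect_equal(nrow(gplus), 37)
    expect_equal(nrow(gminus), 22)
    expect_true(all(pro$hcm_phenotype))
    expect_true(all(pro$genotype == "G+"))
    expect_equal(sum(pro$sex == "M"), 13)
    expect_equal(sum(gplus$sex == "M"), 14)
    expect_equal(sum(gminus$sex == "M"), 7)
    expect_equal(sum(gplus$hcm_phenotype), 19)
    expect_equal(sum(gplus$hcm_phenotype & gplus$sex == "M"), 11)
    expect_equal(sum(gplus$hcm_phenotype & gplus$sex == "F"), 8)
    expect_equal(sum(gplus$age_current >= 50), 14)
    expect_equal(sum(gplus$age_current >= 50 & gplus$hcm_phenotype), 11)
    expect_equal(sum(gminus$hcm_phenotype), 1)
    expect_equal(sum(pro$symptomatic), 12)
    expect_equal(sum(gplus$symptomatic), 5)
    # hypertension / smoking blocks
    expect_equal(sum(gplus$aht, na.rm = TRUE), 14)
    expect_equal(sum(gplus$aht & gplus$hcm_phenotype, na.rm = TRUE), 11)
    expect_equal(sum(is.na(gplus$aht)), 3)
    expect_equal(sum(gplus$smoker, na.rm = TRUE), 7)
    expect_equal(sum(gplus$smoker & gplus$hcm_phenotype, na.rm = TRUE), 4)
    # outcome denominators and component counts
    expect_equal(sum(pro$has_outcome_followup), 24)
    expect_equal(sum(gplus$has_outcome_followup), 35)
    comp <- add_composite_outcome(co)
    expect_equal(sum(comp$composite_outcome[comp$role == "proband"]), 8)
    expect_equal(
      sum(comp$composite_outcome[comp$role == "relative" & comp$genotype == "G+"]), 4
    )
    expect_equal(sum(pro$outcome_lta), 3)
    expect_equal(sum(gplus$outcome_lta), 0)
    expect_equal(sum(pro$outcome_hf_hosp), 7)
    expect_equal(sum(gplus$outcome_hf_hosp), 2)
    expect_equal(sum(pro$outcome_septal), 3)
    expect_equal(sum(gplus$outcome_septal), 1)
    expect_equal(sum(pro$outcome_htx), 1)
    expect_equal(sum(gplus$outcome_htx), 1)
    expect_equal(sum(pro$outcome_device), 6)
    expect_equal(sum(gplus$outcome_device), 1)
    expect_equal(sum(co$outcome_cardiac_death), 0)
    # carriers aged >= 50: 38, with 11 composite events
    car50 <- dplyr::filter(comp, genotype == "G+", age_current >= 50)
    expect_equal(nrow(car50), 38)
    expect_equal(sum(car50$composite_outcome), 11)
    expect_equal(sum(pro$additional_variant), 11)
    expect_equal(sum(gplus$additional_variant), 11)
    # age ranges respected
    expect_true(all(pro$age_current >= 50 & pro$age_current <= 87))
    expect_true(all(gplus$age_current >= 1 & gplus$age_current <= 84))
  }
})

test_that("cohort fixture is deterministic given the seed", {
  expect_identical(build_cohort_fixture(42L), build_cohort_fixture(42L))
  a <- build_cohort_fixture(1L)
  b <- build_cohort_fixture(2L)
  # counts identical, continuous columns differ
  expect_identical(a$hcm_phenotype, b$hcm_phenotype)
  expect_false(identical(a$age_current, b$age_current))
})
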