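#' Canonical synthetic cohort fixture
#'
#' Builds a deterministic 83-individual cohort table reproducing the printed
#' count structure of the founder-variant study cohort: 24 probands (all
#' phenotype-positive, 13 male) and 59 genetically tested first-degree
#' relatives, of whom 37 are genotype-positive (14 male, 19 with an HCM
#' phenotype) and 22 genotype-negative (7 male, exactly 1 phenocopy). Among
#' G+ relatives, 14 are aged >= 50 of whom 11 have the phenotype; 11 of the
#' 14 males and 8 of the 23 females are phenotype-positive. Outcome
#' follow-up covers the 24 probands and 35 of the 37 G+ relatives, with 8
#' and 4 composite events respectively (life-threatening arrhythmia 3/0,
#' heart-failure hospitalisation 7/2, septal reduction 3/1, heart
#' transplantation 1/1, device 6/1, cardiac deaths 0), placing 11 composite
#' events among the 38 carriers aged >= 50. Symptomatic at diagnosis: 12
#' probands and 5 G+ relatives. Hypertension and smoking sub-blocks follow
#' the printed environmental-factor breakdown (14 hypertensive G+ relatives
#' of whom 11 phenotype-positive; 7 smokers of whom 4 phenotype-positive;
#' 3 relatives without risk-factor data, 1 of them phenotype-positive).
#'
#' All integer marginals are hard-coded by construction and identical for
#' every seed; only the continuous columns (ages, BMI, follow-up) are drawn,
#' as sorted seeded normal deviates truncated to the printed ranges so the
#' age >= 50 counts hold exactly.
#'
#' @param seed Integer seed for the continuous columns.
#'
#' @return A tibble with one row per individual and columns `id`,
#'   `family_id`, `role` (`proband`/`relative`), `genotype` (`G+`/`G-`),
#'   `sex` (`M`/`F`), `age_current`, `age_clinical_dx`, `age_genetic_dx`,
#'   `hcm_phenotype`, `symptomatic`, `aht`, `smoker`, `bmi`,
#'   `followup_years`, `has_outcome_followup`, `outcome_cardiac_death`,
#'   `outcome_htx`, `outcome_lta`, `outcome_hf_hosp`, `outcome_septal`,
#'   `outcome_device`, `additional_variant`.
#' @export
#' @examples
#' cohort <- build_cohort_fixture(seed = 1)
#' table(cohort$role, cohort$genotype)
build_cohort_fixture <- function(seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  # Sorted seeded normal deviates clamped to a range; deterministic given
  # the seed, and the range clamp makes age-threshold counts exact.
  draw <- function(n, mean, sd, lo, hi) {
    if (n == 0) return(numeric(0))
    sort(pmin(hi, pmax(lo, round(rnorm(n, mean, sd), 1))))
  }

  ## --- probands: 24, all G+, all phenotype-positive, 13 male, all >= 50 ---
  pro <- tibble(
    id = sprintf("P%02d", 1:24),
    family_id = sprintf("F%02d", 1:24),
    role = "proband",
    genotype = "G+",
    sex = rep(c("M", "F"), c(13, 11)),
    hcm_phenotype = TRUE,
    symptomatic = rep(c(TRUE, FALSE), c(12, 12)),
    aht = rep(c(TRUE, FALSE), c(12, 12)),
    smoker = rep(c(TRUE, FALSE), c(6, 18)),
    additional_variant = rep(c(TRUE, FALSE), c(11, 13)),
    has_outcome_followup = TRUE,
    outcome_cardiac_death = FALSE,
    outcome_htx = c(TRUE, rep(FALSE, 23)),
    outcome_lta = rep(c(TRUE, FALSE), c(3, 21)),
    outcome_hf_hosp = rep(c(TRUE, FALSE), c(7, 17)),
    outcome_septal = rep(c(FALSE, TRUE, FALSE), c(5, 3, 16)),
    outcome_device = rep(c(TRUE, FALSE), c(6, 18))
  )
  pro$age_current <- draw(24, 63, 10, 50, 87)
  pro$age_genetic_dx <- pmin(pro$age_current, draw(24, 62, 10, 40, 85))
  pro$age_clinical_dx <- pmin(pro$age_genetic_dx, draw(24, 51, 16, 25, 80))
  pro$bmi <- draw(24, 26.5, 3.5, 19, 36)
  pro$followup_years <- draw(24, 8, 5, 1, 22)

  ## --- G+ relatives: 37 (14 M / 23 F); joint sex x age>=50 x phenotype
  ## cross-tabulation chosen to satisfy every printed marginal exactly:
  ## males 11/14 affected, age>=50 11/14 affected, 19 affected in total.
  gplus <- tibble(
    sex = rep(c("M", "F"), c(14, 23)),
    age50 = c(rep(TRUE, 8), rep(FALSE, 6),        # males: 8 aged >= 50
              rep(TRUE, 6), rep(FALSE, 17)),      # females: 6 aged >= 50
    hcm_phenotype = c(
      rep(c(TRUE, FALSE), c(7, 1)),               # M >= 50: 7 of 8 affected
      rep(c(TRUE, FALSE), c(4, 2)),               # M <  50: 4 of 6 affected
      rep(c(TRUE, FALSE), c(4, 2)),               # F >= 50: 4 of 6 affected
      rep(c(TRUE, FALSE), c(4, 13))               # F <  50: 4 of 17 affected
    )
  )
  gplus$id <- sprintf("R%02d", seq_len(37))
  gplus$family_id <- sprintf("F%02d", rep_len(1:24, 37))
  gplus$role <- "relative"
  gplus$genotype <- "G+"
  # Symptomatic: 5, all among the phenotype-positive.
  aff_idx <- which(gplus$hcm_phenotype)
  gplus$symptomatic <- FALSE
  gplus$symptomatic[aff_idx[1:5]] <- TRUE
  # Risk-factor block: 34 assessed (3 missing, of whom 1 affected).
  unaff_idx <- which(!gplus$hcm_phenotype)
  missing_rf <- c(aff_idx[19], unaff_idx[17:18])
  assessed_aff <- setdiff(aff_idx, missing_rf)     # 18 affected assessed
  assessed_unaff <- setdiff(unaff_idx, missing_rf) # 16 unaffected assessed
  gplus$aht <- FALSE
  gplus$aht[c(assessed_aff[1:11], assessed_unaff[1:3])] <- TRUE   # 14, 11 affected
  gplus$smoker <- FALSE
  gplus$smoker[c(assessed_aff[1:4], assessed_unaff[1:3])] <- TRUE # 7, 4 affected
  gplus$aht[missing_rf] <- NA
  gplus$smoker[missing_rf] <- NA
  gplus$additional_variant <- FALSE
  gplus$additional_variant[seq(1, 37, length.out = 11)] <- TRUE   # 11 carriers
  # Outcome follow-up: 35 of 37 (two unaffected young females lack it).
  no_fu <- tail(which(!gplus$hcm_phenotype & !gplus$age50 & gplus$sex == "F"), 2)
  gplus$has_outcome_followup <- TRUE
  gplus$has_outcome_followup[no_fu] <- FALSE
  # Component outcomes: HF hospitalisation 2, septal reduction 1, HTx 1,
  # device 1, no life-threatening arrhythmia, no deaths. Three composite
  # events among the >= 50, one below 50 (so carriers >= 50 total 11).
  gplus$outcome_cardiac_death <- FALSE
  gplus$outcome_lta <- FALSE
  gplus$outcome_htx <- FALSE
  gplus$outcome_hf_hosp <- FALSE
  gplus$outcome_septal <- FALSE
  gplus$outcome_device <- FALSE
  aff50 <- which(gplus$hcm_phenotype & gplus$age50)        # 11 individuals
  aff_young <- which(gplus$hcm_phenotype & !gplus$age50)   # 8 individuals
  gplus$outcome_hf_hosp[aff50[1:2]] <- TRUE
  gplus$outcome_septal[aff50[3]] <- TRUE
  gplus$outcome_htx[aff_young[1]] <- TRUE
  gplus$outcome_device[aff50[1]] <- TRUE
  # Ages: >= 50 stratum on [50, 84], younger stratum on [1, 49].
  gplus$age_current <- NA_real_
  gplus$age_current[gplus$age50] <- draw(sum(gplus$age50), 62, 12, 50, 84)
  gplus$age_current[!gplus$age50] <- draw(sum(!gplus$age50), 30, 14, 1, 49)
  gplus$age_genetic_dx <- pmin(gplus$age_current, draw(37, 40, 21, 1, 80))
  gplus$age_clinical_dx <- NA_real_
  gplus$age_clinical_dx[aff_idx] <-
    pmin(gplus$age_current[aff_idx], draw(19, 45, 21, 5, 80))
  gplus$bmi <- NA_real_
  gplus$bmi[aff_idx] <- draw(19, 25.7, 3.4, 18, 34)
  gplus$bmi[unaff_idx] <- draw(18, 23.9, 2.9, 17, 32)
  gplus$followup_years <- NA_real_
  gplus$followup_years[gplus$has_outcome_followup] <-
    draw(35, 4.5, 4, 1, 20)
  gplus$age50 <- NULL

  ## --- G- relatives: 22 (7 M), exactly one phenocopy, no outcome data ---
  gminus <- tibble(
    id = sprintf("N%02d", seq_len(22)),
    family_id = sprintf("F%02d", rep_len(1:22, 22)),
    role = "relative",
    genotype = "G-",
    sex = rep(c("M", "F"), c(7, 15)),
    hcm_phenotype = c(TRUE, rep(FALSE, 21)),
    symptomatic = FALSE,
    aht = rep(c(TRUE, FALSE), c(3, 19)),
    smoker = rep(c(TRUE, FALSE), c(5, 17)),
    additional_variant = FALSE,
    has_outcome_followup = FALSE,
    outcome_cardiac_death = FALSE, outcome_htx = FALSE,
    outcome_lta = FALSE, outcome_hf_hosp = FALSE,
    outcome_septal = FALSE, outcome_device = FALSE
  )
  gminus$age_current <- draw(22, 34.7, 14.7, 5, 70)
  gminus$age_genetic_dx <- pmin(gminus$age_current, draw(22, 32, 15, 1, 70))
  gminus$age_clinical_dx <- NA_real_
  gminus$age_clinical_dx[1] <- gminus$age_current[1]
  gminus$bmi <- draw(22, 24, 3, 17, 32)
  gminus$followup_years <- NA_real_

  cols <- c(
    "id", "family_id", "role", "genotype", "sex", "age_current",
    "age_clinical_dx", "age_genetic_dx", "hcm_phenotype", "symptomatic",
    "aht", "smoker", "bmi", "followup_years", "has_outcome_followup",
    "outcome_cardiac_death", "outcome_htx", "outcome_lta",
    "outcome_hf_hosp", "outcome_septal", "outcome_device",
    "additional_variant"
  )
  bind_rows(pro[cols], gplus[cols], gminus[cols])
}

#' Composite cardiac outcome flag
#'
#' The predefined composite outcome is the union of cardiac death, heart
#' transplantation, life-threatening arrhythmia, heart-failure
#' hospitalisation and septal reduction therapy. Device implantation is
#' reported separately and is *not* part of the composite.
#'
#' @param cohort A cohort tibble with the `outcome_*` flag columns.
#'
#' @return The input with an added logical `composite_outcome` column.
#' @export
add_composite_outcome <- function(cohort) {
  needed <- c("outcome_cardiac_death", "outcome_htx", "outcome_lta",
              "outcome_hf_hosp", "outcome_septal")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    fh_abort(paste0("cohort is missing outcome column(s): ", toString(missing)),
             "founderhap_schema_error")
  }
  mutate(
    cohort,
    composite_outcome = .data$outcome_cardiac_death | .data$outcome_htx |
      .data$outcome_lta | .data$outcome_hf_hosp | .data$outcome_septal
  )
}
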