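test_that("configuration invariants are enforced", {
  expect_error(sim_config(age_band_weights = c(1, 1, 1, 1, 1)), "sum to 1")
  expect_error(sim_config(photo_vcdr_availability = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(photo_vcdr_availability = 0.5), "sum to 1")
  expect_error(sim_config(iop_glaucoma_mixture = list(
    means = c(12, 28, 50), sds = c(3, 5, 6), weights = c(0.5, 0.5, 0.5))),
    "sum to 1")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("generation is reproducible given the seed", {
  cfg <- sim_config(n_clusters = 8)
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(a$cohort$participants, b$cohort$participants)
  expect_identical(a$cohort$eyes, b$cohort$eyes)
  expect_identical(a$cohort$vf, b$cohort$vf)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a$cohort$eyes, c$cohort$eyes))
})

test_that("zero latent prevalence leaves only the documented FP floor", {
  cfg <- sim_config(true_prevalence_by_band = rep(0, 5), n_clusters = 60)
  sim <- generate_cohort(cfg, seed = 3)
  expect_equal(sum(sim$truth$true_glaucoma), 0)
  expect_true(all(sim$truth$true_type == "none"))
  dx <- classify_cohort(sim$cohort, published_thresholds())
  # percentile-defined cutoffs leave ~1-2% of normal persons classifiable;
  # diagnosed prevalence must stay below that false-positive ceiling
  expect_lt(100 * mean(dx$persons$glaucoma), 2.5)
})

test_that("full availability means no censoring", {
  cfg <- sim_config(n_clusters = 6, photo_vcdr_availability = 1,
                    clinical_fallback = 0, no_disc_grade = 0,
                    vf_availability_given_needed = 1,
                    iop_availability = 1, vh_availability = 1,
                    gonio_missing_fraction = 0)
  sim <- generate_cohort(cfg, seed = 5)
  ee <- sim$cohort$eyes
  det <- ee$exam_level == "detailed"
  expect_true(all(!is.na(ee$photo_vcdr[det])))
  expect_true(all(!is.na(ee$iop_mmhg[det])))
  expect_true(all(!is.na(ee$vh_grade[det])))
  expect_true(all(ee$disc_seen))
  expect_true(all(is.na(sim$cohort$vf$untestable_reason)))
})

test_that("missingness mechanisms hit their configured rates", {
  sim <- generate_cohort(sim_config(), seed = 14)
  ee <- sim$cohort$eyes
  det <- ee$exam_level == "detailed"
  none <- is.na(ee$photo_vcdr) & is.na(ee$clinical_vcdr)
  expect_lt(abs(mean(!is.na(ee$photo_vcdr[det])) - 0.66), 0.03)
  expect_lt(abs(mean(none[det]) - 0.135), 0.015)
  expect_true(all(is.na(ee$photo_vcdr[!det])))
  # censored eyes carry a reason label
  expect_true(all(!is.na(ee$no_photo_reason[det & is.na(ee$photo_vcdr)])))
  # roughly 40% of screening tests are untestable
  scr <- sim$cohort$vf[sim$cohort$vf$mode == "screening", ]
  expect_lt(abs(mean(!is.na(scr$untestable_reason)) - 0.4), 0.03)
})

test_that("non-glaucomatous IOP has the calibrated high-pressure tail", {
  sim <- generate_cohort(sim_config(), seed = 15)
  m <- match(sim$cohort$eyes$person_id, sim$truth$person_id)
  normal_eye <- !sim$truth$true_glaucoma[m]
  iop <- sim$cohort$eyes$iop_mmhg[normal_eye]
  # IOP ~ N(14, 4) recorded to the nearest mmHg: P(> 21) = 1 - phi(1.875)
  analytic <- 100 * (1 - pnorm(21.5, 14, 4))
  expect_lt(abs(100 * mean(iop > 21, na.rm = TRUE) - analytic), 0.7)
  expect_lt(abs(mean(iop, na.rm = TRUE) - 14), 0.2)
})

test_that("glaucomatous IOP follows the trimodal mixture", {
  sim <- generate_cohort(sim_config(n_clusters = 500), seed = 16)
  m <- match(sim$cohort$eyes$person_id, sim$truth$person_id)
  tr <- sim$truth[m, ]
  aff <- tr$true_glaucoma &
    (tr$affected_side == "both" |
       substr(tr$affected_side, 1, 1) == sim$cohort$eyes$side)
  iop <- sim$cohort$eyes$iop_mmhg[which(aff)]
  expect_lt(abs(mean(iop, na.rm = TRUE) - 23.3), 1)
  # three components leave visible mass near 12, 28 and 50 mmHg
  expect_gt(mean(iop >= 45, na.rm = TRUE), 0.08)
  expect_gt(mean(iop <= 16, na.rm = TRUE), 0.3)
})

test_that("simulated fields grade as intended by true status", {
  set.seed(23)
  cfg <- sim_config(vf_availability_given_needed = 1)
  grades_normal <- replicate(400, {
    rec <- generate_vf_record(FALSE, 0.4, cfg)
    as.character(interpret_vf(rec))
  })
  usable <- grades_normal != "not_usable"
  expect_gte(mean(grades_normal[usable] %in% c("normal", "unlikely")), 0.9)
  grades_bad <- replicate(200, {
    rec <- generate_vf_record(TRUE, 0.9, cfg)
    as.character(interpret_vf(rec))
  })
  expect_gt(mean(grades_bad == "definite"), 0.5)
  # zero availability means no record
  cfg0 <- sim_config(vf_availability_given_needed = 0)
  expect_null(generate_vf_record(TRUE, 0.9, cfg0))
})

test_that("truth is conserved and prevalence responds to its dial", {
  cfg <- sim_config(n_clusters = 50)
  sim <- generate_cohort(cfg, seed = 31)
  expect_setequal(sim$truth$person_id, sim$cohort$participants$person_id)
  expect_equal(nrow(sim$truth), nrow(sim$cohort$participants))
  # doubling the latent prevalence roughly doubles true cases
  cfg2 <- sim_config(n_clusters = 50,
                     true_prevalence_by_band = 2 * c(1.9, 3.6, 6.4, 10.8,
                                                     14.7))
  sim2 <- generate_cohort(cfg2, seed = 31)
  expect_gt(sum(sim2$truth$true_glaucoma),
            1.5 * sum(sim$truth$true_glaucoma))
})

test_that("cluster identifiers and demographics are structurally sound", {
  sim <- generate_cohort(sim_config(n_clusters = 20), seed = 9)
  pp <- sim$cohort$participants
  expect_equal(length(unique(pp$cluster_id)), 20)
  expect_true(all(table(pp$cluster_id) == 45))
  expect_true(all(pp$age_years >= 40))
  expect_equal(nrow(validate_cohort(sim$cohort)), 0)
  expect_equal(sum(pp$normative), floor(nrow(pp) / 7))
})
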