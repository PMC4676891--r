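test_that("effective VCDR prefers the photographic grade", {
  e <- effective_vcdr(c(0.8, NA, NA), c(0.6, 0.5, NA))
  expect_equal(e$value, c(0.8, 0.5, NA))
  expect_equal(e$source, c("image", "clinical", "none"))
})

test_that("asymmetry is the absolute fellow-eye difference", {
  expect_equal(vcdr_asymmetry(0.7, 0.6), 0.1)
  expect_equal(vcdr_asymmetry(0.4, 0.4), 0)
  expect_true(is.na(vcdr_asymmetry(0.5, NA)))
})

test_that("Van Herick grades group into angle-closure risk", {
  expect_equal(vh_angle_group(c(0, 2, 3, 4)),
               c("closure_likely", "closure_likely", "open", "open"))
  expect_true(is.na(vh_angle_group(NA)))
  expect_error(vh_angle_group(5), "0-4")
})

test_that("the gonioscopy indication is a disjunction of four criteria", {
  expect_true(needs_gonioscopy(20, 0.3, 0, 4))
  expect_true(needs_gonioscopy(14, 0.6, 0, 4))
  expect_true(needs_gonioscopy(14, 0.3, 0.2, 4))
  expect_true(needs_gonioscopy(14, 0.3, 0, 2))
  expect_false(needs_gonioscopy(14, 0.3, 0, 4))
  expect_false(needs_gonioscopy(NA, NA, NA, NA))
})

test_that("eyes classify into the four evidence categories", {
  th <- published_thresholds()
  eye <- function(photo = NA, clinical = NA, iop = 14L, rapd = FALSE,
                  oedema = FALSE, disc = TRUE, va = "6/6") {
    list(photo_vcdr = photo, clinical_vcdr = clinical, iop_mmhg = iop,
         rapd = rapd, corneal_oedema = oedema, disc_seen = disc,
         presenting_va = va)
  }
  # structural + functional evidence
  r <- classify_eye(eye(photo = 0.70), thresholds = th,
                    vf_grade = "definite")
  expect_equal(r$category, "1")
  expect_equal(r$evidence_basis, "vcdr")
  expect_equal(r$vcdr_source, "image")
  # asymmetry route into category 1
  r <- classify_eye(eye(photo = 0.55), fellow_vcdr = 0.45,
                    fellow_source = "image", thresholds = th,
                    vf_grade = "possible")
  expect_equal(r$category, "1")
  expect_equal(r$evidence_basis, "vcdr_asymmetry")
  # advanced structural damage without usable fields
  r <- classify_eye(eye(photo = 0.75), thresholds = th,
                    vf_grade = "not_usable")
  expect_equal(r$category, "2")
  # the same eye with a normal field is not glaucomatous
  r <- classify_eye(eye(photo = 0.70), thresholds = th, vf_grade = "normal")
  expect_equal(r$category, "none")
  expect_false(r$glaucoma)
  # compelling-evidence level 2b
  r <- classify_eye(eye(photo = 0.50, iop = 30L, rapd = TRUE),
                    thresholds = th, vf_grade = "unlikely")
  expect_equal(r$category, "2b")
  expect_equal(r$evidence_basis, "iop_va")
  # end-stage surrogate: disc not seen, blind eye with high pressure
  r <- classify_eye(eye(iop = 30L, disc = FALSE, va = "1/60"),
                    thresholds = th, vf_grade = "not_usable")
  expect_equal(r$category, "3")
  expect_equal(r$vcdr_source, "none")
  # category 3 via glaucoma history
  r <- classify_eye(eye(iop = 14L, disc = FALSE, va = "6/6"),
                    thresholds = th, vf_grade = "not_usable",
                    surgery_history = TRUE)
  expect_equal(r$category, "3")
  expect_equal(r$evidence_basis, "history")
  # clinical fallback uses the clinical-scale cutoffs
  r <- classify_eye(eye(clinical = 0.60), thresholds = th,
                    vf_grade = "probable")
  expect_equal(r$category, "1")
  expect_equal(r$vcdr_source, "clinical")
  # mixed-source asymmetry compares against the clinical cutoffs
  r <- classify_eye(eye(photo = 0.55), fellow_vcdr = 0.40,
                    fellow_source = "clinical", thresholds = th,
                    vf_grade = "possible")
  expect_equal(r$category, "none")  # 0.15 < clinical-scale 0.20
})

test_that("person aggregation takes the highest level of evidence", {
  r1 <- list(glaucoma = TRUE, category = "1")
  r2 <- list(glaucoma = TRUE, category = "2")
  none <- list(glaucoma = FALSE, category = "none")
  expect_equal(classify_person(r1, none)$category, "1")
  expect_true(classify_person(r1, none)$glaucoma)
  expect_equal(classify_person(r2, r1)$category, "1")
  expect_equal(classify_person(list(category = "2b"),
                               list(category = "3"))$category, "2b")
  p <- classify_person(none, none)
  expect_false(p$glaucoma)
  expect_equal(p$category, "none")
  expect_false(classify_person(r1, none, known_glaucoma = FALSE)$aware)
  expect_true(classify_person(r1, none, known_glaucoma = TRUE)$aware)
})

test_that("glaucoma type follows secondary causes then angle morphology", {
  expect_equal(classify_type("none", "open"), "POAG")
  expect_equal(classify_type("none", "closed"), "PACG")
  expect_equal(classify_type("couching", "open"), "secondary")
  expect_equal(classify_type(c("none", "trauma"), NA), "secondary")
  expect_equal(classify_type("none", NA), "unclassified")
})

test_that("classify_eye matches a literal truth-table oracle on a grid", {
  th <- published_thresholds()
  grid <- expand.grid(
    vcdr = c(seq(0, 1, 0.05), NA),
    vf = c("normal", "definite", "probable", "possible", "unlikely",
           "not_usable"),
    iop = c(10L, 28L, 40L),
    rapd = c(FALSE, TRUE),
    disc = c(FALSE, TRUE),
    asym = c(NA, 0.1, 0.2),
    blind = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  grid$source <- ifelse(is.na(grid$vcdr), "none", "image")
  grid$asym_scale <- ifelse(is.na(grid$asym), "none", "image")
  # disc_seen is consistent with having a VCDR grade
  grid$disc <- grid$disc & !is.na(grid$vcdr)
  got <- glaucsurv:::classify_eyes_impl(data.frame(
    vcdr = grid$vcdr, vcdr_source = grid$source, asym = grid$asym,
    asym_scale = grid$asym_scale, iop = grid$iop, rapd = grid$rapd,
    oedema = FALSE, disc_seen = grid$disc,
    va_logmar = ifelse(grid$blind, 1.78, 0), vf_grade = grid$vf,
    surgery_history = FALSE, known_glaucoma = FALSE,
    stringsAsFactors = FALSE), th)
  want <- vapply(seq_len(nrow(grid)), function(i) {
    oracle_classify_eye(grid$vcdr[i], grid$source[i], grid$asym[i],
                        grid$asym_scale[i], grid$iop[i], grid$rapd[i],
                        FALSE, grid$disc[i],
                        if (grid$blind[i]) 1.78 else 0, grid$vf[i],
                        FALSE, FALSE, th)
  }, character(1))
  expect_equal(got$category, want)
  expect_equal(got$glaucoma, want != "none")
})

test_that("raising VCDR never changes a diagnosed eye back to none", {
  th <- published_thresholds()
  set.seed(21)
  vf_grades <- c("normal", "definite", "probable", "possible", "unlikely",
                 "not_usable")
  for (i in 1:200) {
    v <- sample(seq(0, 0.9, 0.05), 1)
    vf <- sample(vf_grades, 1)
    base <- glaucsurv:::classify_eyes_impl(data.frame(
      vcdr = v, vcdr_source = "image", asym = NA_real_,
      asym_scale = "none", iop = 14L, rapd = FALSE, oedema = FALSE,
      disc_seen = TRUE, va_logmar = 0, vf_grade = vf,
      surgery_history = FALSE, known_glaucoma = FALSE), th)
    up <- glaucsurv:::classify_eyes_impl(data.frame(
      vcdr = v + 0.05, vcdr_source = "image", asym = NA_real_,
      asym_scale = "none", iop = 14L, rapd = FALSE, oedema = FALSE,
      disc_seen = TRUE, va_logmar = 0, vf_grade = vf,
      surgery_history = FALSE, known_glaucoma = FALSE), th)
    if (base$glaucoma && base$category %in% c("1", "2")) {
      expect_true(up$glaucoma)
    }
  }
})

test_that("classified cohorts partition diagnosed persons by type", {
  sim <- generate_cohort(sim_config(n_clusters = 40), seed = 8)
  dx <- classify_cohort(sim$cohort, published_thresholds())
  pers <- dx$persons
  g <- pers[pers$glaucoma, ]
  expect_true(all(g$type %in% c("POAG", "PACG", "secondary",
                                "unclassified")))
  expect_true(all(pers$type[!pers$glaucoma] == "not_applicable"))
  tab <- type_tabulation(dx)
  expect_equal(tab$n[tab$type == "all"],
               sum(tab$n[tab$type != "all"]))
  ev <- evidence_tabulation(dx)
  expect_equal(ev$participants[ev$category == "total"],
               sum(ev$participants[ev$category != "total"]))
  expect_equal(ev$participants[ev$category == "total"], nrow(g))
  # each diagnosed eye carries exactly one category
  de <- dx$eyes[dx$eyes$glaucoma, ]
  expect_true(all(de$category %in% c("1", "2", "2b", "3")))
})
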