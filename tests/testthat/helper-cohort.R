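# tiny in-code cohort fixtures

fixture_participant <- function(person_id, cluster_id = "C1", age = 55,
                                sex = "female", known = FALSE,
                                surgery = FALSE, normative = FALSE) {
  data.frame(person_id = person_id, cluster_id = cluster_id,
             age_years = age, sex = sex, ethnicity = "Hausa",
             literate = TRUE, residence = "rural", known_glaucoma = known,
             glaucoma_surgery_history = surgery, normative = normative,
             stringsAsFactors = FALSE)
}

fixture_eye <- function(person_id, side, photo = NA_real_,
                        clinical = NA_real_, iop = 14L, vh = 3L,
                        gonio = NA_character_, va = "6/6",
                        cause = "none", rapd = FALSE, oedema = FALSE,
                        disc_seen = TRUE, exam = "detailed") {
  data.frame(person_id = person_id, side = side, photo_vcdr = photo,
             clinical_vcdr = clinical, iop_mmhg = iop, vh_grade = vh,
             gonioscopy = gonio, presenting_va = va,
             secondary_cause = cause, rapd = rapd, corneal_oedema = oedema,
             disc_seen = disc_seen, exam_level = exam,
             stringsAsFactors = FALSE)
}

fixture_cohort <- function() {
  pp <- rbind(fixture_participant("P1"),
              fixture_participant("P2", age = 72),
              fixture_participant("P3", cluster_id = "C2", age = 48))
  ee <- rbind(fixture_eye("P1", "R", photo = 0.40, clinical = 0.35),
              fixture_eye("P1", "L", photo = 0.45, clinical = 0.40),
              fixture_eye("P2", "R", photo = 0.80, clinical = 0.70,
                          iop = 30L, gonio = "open", va = "6/60"),
              fixture_eye("P2", "L", photo = 0.55, clinical = 0.50),
              fixture_eye("P3", "R", clinical = 0.30, exam = "basic"),
              fixture_eye("P3", "L", clinical = 0.30, exam = "basic"))
  survey_cohort(pp, ee)
}

# a defect map for the standard 17-zone geometry with given zones set
map17 <- function(at = integer(0), level = 1L) {
  m <- integer(17)
  m[at] <- level
  m
}
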