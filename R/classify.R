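#' Effective VCDR of an eye
#'
#' Photographic (image) grading takes precedence; clinical grading is the
#' fallback when no photo grade exists.
#'
#' @param photo_vcdr,clinical_vcdr numeric vectors (NA = absent).
#' @return data.frame with `value` and `source`
#'   (`"image"`/`"clinical"`/`"none"`).
#' @export
effective_vcdr <- function(photo_vcdr, clinical_vcdr) {
  value <- ifelse(!is.na(photo_vcdr), photo_vcdr, clinical_vcdr)
  source <- ifelse(!is.na(photo_vcdr), "image",
                   ifelse(!is.na(clinical_vcdr), "clinical", "none"))
  data.frame(value = value, source = source, stringsAsFactors = FALSE)
}

#' Absolute VCDR asymmetry between fellow eyes
#'
#' @param right_value,left_value effective VCDR of each eye.
#' @return `|right - left|`, NA when either is absent.
#' @export
vcdr_asymmetry <- function(right_value, left_value) {
  abs(right_value - left_value)
}

#' Group a Van Herick grade into angle status
#'
#' Grades 0-2 indicate closed or likely-to-close angles, 3-4 open angles.
#' @param vh_grade integer vector in 0..4.
#' @return character vector `"closure_likely"` / `"open"` (NA propagated).
#' @export
vh_angle_group <- function(vh_grade) {
  bad <- !is.na(vh_grade) & !vh_grade %in% 0:4
  if (any(bad)) stop("Van Herick grade outside 0-4")
  ifelse(is.na(vh_grade), NA_character_,
         ifelse(vh_grade <= 2, "closure_likely", "open"))
}

#' Does an eye meet the field indication for gonioscopy?
#'
#' Gonioscopy was indicated at detailed examination when IOP >= 20 mmHg,
#' VCDR >= 0.6, VCDR asymmetry >= 0.2, or Van Herick grade 0-2.
#'
#' @param iop_mmhg,vcdr,asymmetry,vh_grade eye measurements (NA = absent;
#'   an absent measurement cannot trigger the indication).
#' @return logical vector.
#' @export
needs_gonioscopy <- function(iop_mmhg, vcdr, asymmetry, vh_grade) {
  ge <- function(x, cut) !is.na(x) & x >= cut - 1e-9
  ge(iop_mmhg, 20) | ge(vcdr, 0.6) | ge(asymmetry, 0.2) |
    (!is.na(vh_grade) & vh_grade <= 2)
}

.category_levels <- c("1", "2", "2b", "3", "none")

# vectorized ISGEO eye classification; df columns: vcdr, vcdr_source, asym,
# asym_scale, iop, rapd, oedema, disc_seen, va_logmar, vf_grade,
# surgery_history, known_glaucoma
classify_eyes_impl <- function(df, thresholds) {
  stopifnot(inherits(thresholds, "diagnostic_thresholds"))
  th <- thresholds
  v975 <- unname(th$vcdr_975[df$vcdr_source])
  v995 <- unname(th$vcdr_995[df$vcdr_source])
  a975 <- unname(th$asym_975[df$asym_scale])
  a995 <- unname(th$asym_995[df$asym_scale])
  ge <- function(x, cut) !is.na(x) & !is.na(cut) & x >= cut - 1e-9
  vcdr_975 <- ge(df$vcdr, v975); vcdr_995 <- ge(df$vcdr, v995)
  asym_975 <- ge(df$asym, a975); asym_995 <- ge(df$asym, a995)
  iop_high <- !is.na(df$iop) & df$iop >= th$iop_995 - 1e-9
  vf_typical <- df$vf_grade %in% c("definite", "probable", "possible")
  vf_unusable <- df$vf_grade == "not_usable"
  disc_seen <- isTRUE_vec(df$disc_seen)
  compelling <- isTRUE_vec(df$rapd) | isTRUE_vec(df$oedema)

  cat1 <- (vcdr_975 | asym_975) & vf_typical
  cat2 <- (vcdr_995 | asym_995) & vf_unusable
  cat2b <- !cat1 & !cat2 & disc_seen & !is.na(df$vcdr) & !vcdr_975 &
    iop_high & compelling & df$vf_grade != "normal"
  hist <- isTRUE_vec(df$surgery_history) | isTRUE_vec(df$known_glaucoma)
  cat3 <- !cat1 & !cat2 & !cat2b & !disc_seen & is.na(df$vcdr) &
    vf_unusable & ((is_blind_va(df$va_logmar) & iop_high) | hist)

  category <- rep("none", nrow(df))
  category[cat3] <- "3"; category[cat2b] <- "2b"
  category[cat2] <- "2"; category[cat1] <- "1"
  basis <- rep(NA_character_, nrow(df))
  basis[cat1] <- ifelse(vcdr_975[cat1], "vcdr", "vcdr_asymmetry")
  basis[cat2] <- ifelse(vcdr_995[cat2], "vcdr", "vcdr_asymmetry")
  basis[cat2b] <- "iop_va"
  basis[cat3] <- ifelse(is_blind_va(df$va_logmar[cat3]) & iop_high[cat3],
                        "iop_va", "history")
  src <- df$vcdr_source
  src[category == "3"] <- "none"
  src[category == "none"] <- df$vcdr_source[category == "none"]
  data.frame(glaucoma = category != "none", category = category,
             evidence_basis = basis, vcdr_source = src,
             stringsAsFactors = FALSE)
}

#' Classify a single eye into an ISGEO glaucoma category
#'
#' Categories (highest level of evidence wins):
#' * **1** structural and functional evidence: effective VCDR at or above
#'   the 97.5th percentile for its measurement scale, or VCDR asymmetry at
#'   or above its 97.5th percentile, together with a typical field defect
#'   (grade `definite`, `probable` or `possible`);
#' * **2** advanced structural damage (VCDR or asymmetry at the 99.5th
#'   percentile) when no usable field result exists;
#' * **2b** disc seen with VCDR below the 97.5th percentile but compelling
#'   evidence: IOP at the 99.5th percentile (28 mmHg) with RAPD or corneal
#'   oedema, fields anything but normal;
#' * **3** disc not seen and fields unusable, with either blindness (VA
#'   worse than 3/60) plus IOP at the 99.5th percentile, or a history of
#'   glaucoma surgery / prior diagnosis.
#'
#' Threshold scale follows the VCDR source (image vs clinical); a
#' mixed-source asymmetry is compared against the wider clinical-scale
#' asymmetry cutoffs.
#'
#' @param eye named list or one-row data.frame with `photo_vcdr`,
#'   `clinical_vcdr`, `iop_mmhg`, `rapd`, `corneal_oedema`, `disc_seen`,
#'   `presenting_va`.
#' @param fellow_vcdr,fellow_source effective VCDR (and its source) of the
#'   fellow eye, for asymmetry.
#' @param thresholds a [diagnostic_thresholds()] object.
#' @param vf_grade the eye's field grade from [interpret_vf()].
#' @param surgery_history,known_glaucoma person-level history flags.
#' @return list with `glaucoma`, `category` (`"1"`, `"2"`, `"2b"`, `"3"`,
#'   `"none"`), `evidence_basis`, `vcdr_source`.
#' @export
classify_eye <- function(eye, fellow_vcdr = NA_real_,
                         fellow_source = "none",
                         thresholds = published_thresholds(),
                         vf_grade = "not_usable",
                         surgery_history = FALSE, known_glaucoma = FALSE) {
  eff <- effective_vcdr(eye$photo_vcdr, eye$clinical_vcdr)
  asym <- if (!is.na(eff$value) && !is.na(fellow_vcdr)) {
    vcdr_asymmetry(eff$value, fellow_vcdr)
  } else NA_real_
  asym_scale <- if (is.na(asym)) "none" else if (eff$source == "image" &&
    identical(fellow_source, "image")) "image" else "clinical"
  df <- data.frame(
    vcdr = eff$value, vcdr_source = eff$source, asym = asym,
    asym_scale = asym_scale, iop = na_or(eye$iop_mmhg),
    rapd = isTRUE(eye$rapd), oedema = isTRUE(eye$corneal_oedema),
    disc_seen = isTRUE(eye$disc_seen),
    va_logmar = if (is.null(eye$presenting_va)) NA_real_ else
      va_to_logmar(eye$presenting_va),
    vf_grade = vf_grade, surgery_history = surgery_history,
    known_glaucoma = known_glaucoma, stringsAsFactors = FALSE)
  as.list(classify_eyes_impl(df, thresholds))
}

na_or <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else x

#' Aggregate two eye diagnoses to a person diagnosis
#'
#' A person has glaucoma if either eye does; the person's category is the
#' eye category with the highest level of evidence (1 > 2 > 2b > 3).
#'
#' @param right,left lists from [classify_eye()] (either may be NULL for a
#'   missing eye).
#' @param known_glaucoma self-reported history, for awareness.
#' @return list with `glaucoma`, `category`, `aware`.
#' @export
classify_person <- function(right = NULL, left = NULL,
                            known_glaucoma = FALSE) {
  cats <- c(if (!is.null(right)) right$category else "none",
            if (!is.null(left)) left$category else "none")
  best <- .category_levels[min(match(cats, .category_levels))]
  glaucoma <- best != "none"
  list(glaucoma = glaucoma, category = best,
       aware = isTRUE(known_glaucoma) && glaucoma)
}

#' Assign the glaucoma type of a diagnosed person
#'
#' A recorded secondary cause in any diagnosed eye overrides angle
#' morphology; otherwise the gonioscopic angle of the defining eye decides
#' primary open-angle (open) versus primary angle-closure (closed) glaucoma,
#' and an eye without gonioscopy stays unclassified.
#'
#' @param secondary_causes character vector of secondary-cause codes of the
#'   diagnosed eye(s) (`"none"` when absent).
#' @param defining_gonioscopy gonioscopy result of the defining eye
#'   (`"open"`, `"closed"` or NA).
#' @return `"secondary"`, `"POAG"`, `"PACG"` or `"unclassified"`.
#' @export
classify_type <- function(secondary_causes, defining_gonioscopy) {
  sec <- secondary_causes[!is.na(secondary_causes) &
                            secondary_causes != "none"]
  if (length(sec)) return("secondary")
  if (is.na(defining_gonioscopy)) return("unclassified")
  switch(defining_gonioscopy, open = "POAG", closed = "PACG",
         stop("gonioscopy must be 'open' or 'closed'"))
}

#' Visual field grades for every eye of a cohort
#'
#' Decodes the per-zone probability-level codes of the `vf` table, applies
#' the mode-specific reliability rules, grades usable tests on the PDP/TDP
#' plots, and resolves one grade per eye with threshold results taking
#' precedence over screening results.
#'
#' @param vf the `vf` table of a [survey_cohort()].
#' @param zones zone geometry.
#' @return data.frame with `person_id`, `side`, `vf_grade`.
#' @export
vf_grades_by_eye <- function(vf, zones = fdt_c20_zones()) {
  if (is.null(vf) || !nrow(vf)) {
    return(data.frame(person_id = character(0), side = character(0),
                      vf_grade = character(0), stringsAsFactors = FALSE))
  }
  nz <- nrow(zones)
  codes <- vf_level_codes()
  decode <- function(prefix) {
    cols <- sprintf("%s_z%02d", prefix, seq_len(nz))
    missing_cols <- setdiff(cols, names(vf))
    if (length(missing_cols)) stop("vf table lacks columns: ",
                                   paste(missing_cols, collapse = ", "))
    m <- matrix(NA_integer_, nrow(vf), nz)
    for (j in seq_len(nz)) m[, j] <- codes[as.character(vf[[cols[j]]])]
    m
  }
  pdp <- decode("pdp"); tdp <- decode("tdp")
  complete <- rowSums(is.na(pdp)) == 0 & rowSums(is.na(tdp)) == 0
  untestable <- !is.na(vf$untestable_reason)
  lid <- isTRUE_vec(vf$lid_artefact)
  reliable <- ifelse(vf$mode == "threshold",
                     vf$fixation_errors <= 2 & vf$false_positives <= 2,
                     vf$fixation_errors <= 1 & vf$false_positives <= 1)
  usable <- complete & !untestable & !lid & isTRUE_vec(reliable)
  grade <- rep("not_usable", nrow(vf))
  if (any(usable)) {
    grade[usable] <- grade_defect_maps(pdp[usable, , drop = FALSE],
                                       tdp[usable, , drop = FALSE],
                                       zones = zones)
  }
  # threshold beats screening, usable beats unusable
  pref <- ifelse(usable, 0L, 2L) + ifelse(vf$mode == "threshold", 0L, 1L)
  ord <- order(vf$person_id, vf$side, pref)
  v <- vf[ord, c("person_id", "side")]
  v$vf_grade <- grade[ord]
  v[!duplicated(paste(v$person_id, v$side)), , drop = FALSE]
}

#' Classify every eye and person of a cohort
#'
#' Runs the full diagnostic algorithm: field grading per eye, effective
#' VCDR with clinical fallback, fellow-eye asymmetry (mixed-source
#' asymmetry uses the clinical-scale cutoffs), ISGEO eye categories,
#' person-level aggregation (highest level of evidence) and glaucoma type
#' assignment.
#'
#' @param cohort a [survey_cohort()].
#' @param thresholds a [diagnostic_thresholds()] object.
#' @param zones zone geometry for field grading.
#' @return list of class `glaucoma_diagnosis` with data.frames `persons`
#'   (one row per participant: diagnosis, category, basis, type, awareness,
#'   better-eye acuity category) and `eyes` (one row per eye record).
#' @export
classify_cohort <- function(cohort, thresholds = published_thresholds(),
                            zones = fdt_c20_zones()) {
  stopifnot(inherits(cohort, "survey_cohort"))
  pp <- cohort$participants
  ee <- cohort$eyes
  vfg <- vf_grades_by_eye(cohort$vf, zones)
  key <- paste(ee$person_id, ee$side)
  m <- match(key, paste(vfg$person_id, vfg$side))
  vf_grade <- ifelse(is.na(m), "not_usable", vfg$vf_grade[m])

  eff <- effective_vcdr(ee$photo_vcdr, ee$clinical_vcdr)
  fellow_key <- paste(ee$person_id, ifelse(ee$side == "R", "L", "R"))
  fm <- match(fellow_key, key)
  fellow_value <- eff$value[fm]
  fellow_source <- ifelse(is.na(fm), "none", eff$source[fm])
  asym <- vcdr_asymmetry(eff$value, fellow_value)
  asym_scale <- ifelse(is.na(asym), "none",
                       ifelse(eff$source == "image" &
                                fellow_source == "image",
                              "image", "clinical"))
  pm <- match(ee$person_id, pp$person_id)
  va_logmar <- va_to_logmar(ee$presenting_va)
  eye_df <- data.frame(
    vcdr = eff$value, vcdr_source = eff$source, asym = asym,
    asym_scale = asym_scale, iop = ee$iop_mmhg,
    rapd = ee$rapd, oedema = ee$corneal_oedema, disc_seen = ee$disc_seen,
    va_logmar = va_logmar, vf_grade = vf_grade,
    surgery_history = pp$glaucoma_surgery_history[pm],
    known_glaucoma = pp$known_glaucoma[pm], stringsAsFactors = FALSE)
  res <- classify_eyes_impl(eye_df, thresholds)
  eyes_out <- data.frame(
    person_id = ee$person_id, side = ee$side, glaucoma = res$glaucoma,
    category = res$category, evidence_basis = res$evidence_basis,
    vcdr_source = res$vcdr_source, vcdr = eff$value, asym = asym,
    iop_mmhg = ee$iop_mmhg, vf_grade = vf_grade, va_logmar = va_logmar,
    gonioscopy = ee$gonioscopy, secondary_cause = ee$secondary_cause,
    stringsAsFactors = FALSE)

  # person-level aggregation
  cat_rank <- match(eyes_out$category, .category_levels)
  vcdr_key <- ifelse(is.na(eyes_out$vcdr), -1, eyes_out$vcdr)
  ord <- order(eyes_out$person_id, cat_rank, -vcdr_key,
               eyes_out$side != "R")
  eo <- eyes_out[ord, ]
  first <- !duplicated(eo$person_id)
  best <- eo[first, c("person_id", "category", "evidence_basis",
                      "vcdr_source", "side", "gonioscopy")]
  names(best)[5] <- "defining_side"
  pm2 <- match(pp$person_id, best$person_id)
  category <- ifelse(is.na(pm2), "none", best$category[pm2])
  glaucoma <- category != "none"

  sec_by_person <- tapply(
    ifelse(eyes_out$glaucoma &
             !is.na(eyes_out$secondary_cause) &
             eyes_out$secondary_cause != "none", 1L, 0L),
    eyes_out$person_id, sum)
  has_secondary <- as.vector(sec_by_person[pp$person_id]) > 0
  has_secondary[is.na(has_secondary)] <- FALSE
  gonio <- best$gonioscopy[pm2]
  type <- rep("not_applicable", nrow(pp))
  type[glaucoma] <- ifelse(has_secondary[glaucoma], "secondary",
                           ifelse(is.na(gonio[glaucoma]), "unclassified",
                                  ifelse(gonio[glaucoma] == "open",
                                         "POAG", "PACG")))
  # better-eye presenting acuity
  va_by_person <- tapply(va_logmar, ee$person_id,
                         function(v) if (all(is.na(v))) NA_real_ else
                           min(v, na.rm = TRUE))
  va_better <- as.vector(va_by_person[pp$person_id])
  persons <- data.frame(
    person_id = pp$person_id, cluster_id = pp$cluster_id,
    age_years = pp$age_years, sex = pp$sex, ethnicity = pp$ethnicity,
    literate = pp$literate, residence = pp$residence,
    glaucoma = glaucoma, category = category,
    evidence_basis = ifelse(is.na(pm2), NA, best$evidence_basis[pm2]),
    vcdr_source = ifelse(is.na(pm2), NA, best$vcdr_source[pm2]),
    defining_side = ifelse(is.na(pm2), NA, best$defining_side[pm2]),
    type = type,
    aware = glaucoma & isTRUE_vec(pp$known_glaucoma),
    va_better_logmar = va_better,
    visual_status = ifelse(is.na(va_better), NA_character_,
                           ifelse(is_blind_va(va_better),
                                  "blind", "not_blind")),
    stringsAsFactors = FALSE)
  structure(list(persons = persons, eyes = eyes_out,
                 thresholds = thresholds),
            class = "glaucoma_diagnosis")
}

#' @export
print.glaucoma_diagnosis <- function(x, ...) {
  n <- nrow(x$persons); g <- sum(x$persons$glaucoma)
  cat("Glaucoma diagnosis:", g, "of", n, "participants",
      sprintf("(%.2f%%)\n", 100 * g / n))
  print(table(category = x$persons$category[x$persons$glaucoma]))
  invisible(x)
}

#' Tabulate diagnosed persons and eyes by level of evidence
#'
#' @param dx a [classify_cohort()] result.
#' @return data.frame with one row per (category, basis) cell and totals of
#'   diagnosed persons and eyes.
#' @export
evidence_tabulation <- function(dx) {
  stopifnot(inherits(dx, "glaucoma_diagnosis"))
  cells <- list(c("1", "vcdr"), c("1", "vcdr_asymmetry"),
                c("2", "vcdr"), c("2", "vcdr_asymmetry"),
                c("2b", NA), c("3", NA))
  pers <- dx$persons[dx$persons$glaucoma, ]
  eyes <- dx$eyes[dx$eyes$glaucoma, ]
  out <- do.call(rbind, lapply(cells, function(cl) {
    pk <- pers$category == cl[1] &
      (is.na(cl[2]) | pers$evidence_basis == cl[2])
    ek <- eyes$category == cl[1] &
      (is.na(cl[2]) | eyes$evidence_basis == cl[2])
    data.frame(category = cl[1],
               basis = ifelse(is.na(cl[2]), "all", cl[2]),
               participants = sum(pk), eyes = sum(ek),
               stringsAsFactors = FALSE)
  }))
  rbind(out, data.frame(category = "total", basis = "all",
                        participants = nrow(pers), eyes = nrow(eyes)))
}

#' Tabulate diagnosed persons by glaucoma type
#'
#' @param dx a [classify_cohort()] result.
#' @return data.frame of counts and percentages by type, with a total row.
#' @export
type_tabulation <- function(dx) {
  stopifnot(inherits(dx, "glaucoma_diagnosis"))
  pers <- dx$persons[dx$persons$glaucoma, ]
  types <- c("POAG", "PACG", "secondary", "unclassified")
  n <- vapply(types, function(t) sum(pers$type == t), integer(1))
  out <- data.frame(type = c("all", types),
                    n = c(nrow(pers), unname(n)),
                    stringsAsFactors = FALSE)
  out$pct <- round(100 * out$n / nrow(pers), 1)
  out
}
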