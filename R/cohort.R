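#' Survey cohort container
#'
#' A cohort is three related tables keyed by `person_id` (eyes additionally
#' by `side`, `"R"` or `"L"`):
#'
#' * `participants`: `person_id`, `cluster_id`, `age_years`, `sex`
#'   (`male`/`female`), `ethnicity`, `literate`, `residence`
#'   (`rural`/`urban`), `known_glaucoma`, `glaucoma_surgery_history`, and
#'   optionally `normative` (the 1-in-7 systematic subsample flag);
#' * `eyes`: `person_id`, `side`, `photo_vcdr` (0.05 steps), `clinical_vcdr`,
#'   `iop_mmhg`, `vh_grade` (0-4), `gonioscopy` (`open`/`closed`),
#'   `presenting_va` (logMAR or Snellen code), `secondary_cause`, `rapd`,
#'   `corneal_oedema`, `disc_seen`, `exam_level` (`basic`/`detailed`);
#' * `vf`: one row per eye and test mode with reliability indices, per-zone
#'   probability-level codes for the PDP and TDP plots (`pdp_z01`...,
#'   `tdp_z01`..., codes `0`/`5`/`2`/`1`/`05`), `lid_artefact` and
#'   `untestable_reason`.
#'
#' Files are comma-separated UTF-8 with `.` decimal separator; an empty cell
#' means absent.
#'
#' @param participants,eyes,vf data.frames as above (`vf` may be NULL).
#' @return object of class `survey_cohort`.
#' @export
survey_cohort <- function(participants, eyes, vf = NULL) {
  req_p <- c("person_id", "cluster_id", "age_years", "sex", "ethnicity",
             "literate", "residence", "known_glaucoma",
             "glaucoma_surgery_history")
  req_e <- c("person_id", "side", "photo_vcdr", "clinical_vcdr", "iop_mmhg",
             "vh_grade", "gonioscopy", "presenting_va", "secondary_cause",
             "rapd", "corneal_oedema", "disc_seen", "exam_level")
  miss_p <- setdiff(req_p, names(participants))
  miss_e <- setdiff(req_e, names(eyes))
  if (length(miss_p)) stop("participants table lacks: ",
                           paste(miss_p, collapse = ", "))
  if (length(miss_e)) stop("eyes table lacks: ", paste(miss_e, collapse = ", "))
  dup <- participants$person_id[duplicated(participants$person_id)]
  if (length(dup)) stop("duplicate person_id: ",
                        paste(unique(dup), collapse = ", "))
  orphan <- setdiff(eyes$person_id, participants$person_id)
  if (length(orphan)) stop("eye rows reference unknown person_id: ",
                           paste(utils::head(unique(orphan), 5), collapse = ", "))
  bad_vcdr <- which(!is.na(eyes$photo_vcdr) &
                      (eyes$photo_vcdr < 0 | eyes$photo_vcdr > 1))
  bad_cvcdr <- which(!is.na(eyes$clinical_vcdr) &
                       (eyes$clinical_vcdr < 0 | eyes$clinical_vcdr > 1))
  bad_iop <- which(!is.na(eyes$iop_mmhg) & eyes$iop_mmhg < 0)
  bad <- c(bad_vcdr, bad_cvcdr, bad_iop)
  if (length(bad)) {
    stop("out-of-range VCDR/IOP in eyes rows: ",
         paste(sort(unique(bad)), collapse = ", "))
  }
  if (!is.null(vf) && nrow(vf)) {
    orphan_vf <- setdiff(vf$person_id, participants$person_id)
    if (length(orphan_vf)) stop("vf rows reference unknown person_id: ",
                                paste(utils::head(unique(orphan_vf), 5),
                                      collapse = ", "))
  }
  structure(list(participants = participants, eyes = eyes,
                 vf = if (is.null(vf)) empty_vf_table() else vf),
            class = "survey_cohort")
}

#' @export
print.survey_cohort <- function(x, ...) {
  cat("Survey cohort:", nrow(x$participants), "participants in",
      length(unique(x$participants$cluster_id)), "clusters;",
      nrow(x$eyes), "eye records;", nrow(x$vf), "visual field tests\n")
  invisible(x)
}

empty_vf_table <- function(zones = fdt_c20_zones()) {
  base <- data.frame(person_id = character(0), side = character(0),
                     mode = character(0), fixation_errors = integer(0),
                     false_positives = integer(0),
                     lid_artefact = logical(0),
                     untestable_reason = character(0))
  for (p in c("pdp", "tdp")) {
    for (z in seq_len(nrow(zones))) {
      base[[sprintf("%s_z%02d", p, z)]] <- character(0)
    }
  }
  base
}

known_cohort_columns <- function() {
  list(
    participants = c("person_id", "cluster_id", "age_years", "sex",
                     "ethnicity", "literate", "residence", "known_glaucoma",
                     "glaucoma_surgery_history", "normative"),
    eyes = c("person_id", "side", "photo_vcdr", "clinical_vcdr", "iop_mmhg",
             "vh_grade", "gonioscopy", "presenting_va", "secondary_cause",
             "rapd", "corneal_oedema", "disc_seen", "exam_level",
             "no_photo_reason"))
}

read_csv_na <- function(path) {
  utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

#' Read a survey cohort from delimited text files
#'
#' @param participants_path,eyes_path,vf_path CSV file paths (`vf_path`
#'   optional). Unknown columns are kept but flagged with a warning;
#'   duplicate identifiers, orphan eye rows and out-of-range VCDR/IOP raise
#'   errors listing the offending rows.
#' @return a [survey_cohort()].
#' @export
read_cohort <- function(participants_path, eyes_path, vf_path = NULL) {
  pp <- read_csv_na(participants_path)
  ee <- read_csv_na(eyes_path)
  known <- known_cohort_columns()
  extra <- c(setdiff(names(pp), known$participants),
             setdiff(names(ee), known$eyes))
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  }
  for (col in c("literate", "known_glaucoma", "glaucoma_surgery_history",
                "normative")) {
    if (col %in% names(pp)) pp[[col]] <- as.logical(pp[[col]])
  }
  for (col in c("rapd", "corneal_oedema", "disc_seen")) {
    if (col %in% names(ee)) ee[[col]] <- as.logical(ee[[col]])
  }
  for (col in c("presenting_va", "gonioscopy", "secondary_cause",
                "no_photo_reason")) {
    if (col %in% names(ee)) ee[[col]] <- as.character(ee[[col]])
  }
  vf <- NULL
  if (!is.null(vf_path)) {
    # probability-level codes must stay textual ("05" is not the number 5)
    vf <- utils::read.csv(vf_path, na.strings = c("", "NA"),
                          colClasses = "character",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    for (col in c("fixation_errors", "false_positives")) {
      if (col %in% names(vf)) vf[[col]] <- as.integer(vf[[col]])
    }
    if ("lid_artefact" %in% names(vf)) {
      vf$lid_artefact <- as.logical(vf$lid_artefact)
    }
    if (!"untestable_reason" %in% names(vf)) {
      vf$untestable_reason <- NA_character_
    }
  }
  survey_cohort(pp, ee, vf)
}

#' Write a survey cohort to delimited text files
#'
#' Emits `participants.csv`, `eyes.csv` and `vf.csv` in `dir`; a cohort
#' written and re-read reproduces every field.
#'
#' @param cohort a [survey_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "survey_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$eyes, file.path(dir, "eyes.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$vf, file.path(dir, "vf.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}

issue <- function(person_id, field, rule, message) {
  data.frame(person_id = person_id, field = field, rule = rule,
             message = message, stringsAsFactors = FALSE)
}

#' Validate a cohort against the recording rules
#'
#' Reports (never raises, never mutates) one row per issue: under-age
#' participants, missing eye records, empty cluster identifiers, photo VCDR
#' off the 0.05 grid, Van Herick grades outside 0-4, unparseable acuity
#' codes, and gonioscopy recorded without any disc assessment.
#'
#' @param cohort a [survey_cohort()].
#' @return data.frame with columns `person_id`, `field`, `rule`, `message`
#'   (zero rows when clean).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "survey_cohort"))
  pp <- cohort$participants
  ee <- cohort$eyes
  out <- list()
  under <- which(!is.na(pp$age_years) & pp$age_years < 40)
  if (length(under)) {
    out[[length(out) + 1]] <- issue(pp$person_id[under], "age_years",
      "age_minimum", "participants must be aged 40 years or above")
  }
  no_cluster <- which(is.na(pp$cluster_id) | pp$cluster_id == "")
  if (length(no_cluster)) {
    out[[length(out) + 1]] <- issue(pp$person_id[no_cluster], "cluster_id",
      "cluster_required", "cluster_id is empty")
  }
  eyeless <- setdiff(pp$person_id, ee$person_id)
  if (length(eyeless)) {
    out[[length(out) + 1]] <- issue(eyeless, "eyes", "eye_record_required",
      "examined participant has no eye record")
  }
  off_grid <- which(!is.na(ee$photo_vcdr) &
                      abs(ee$photo_vcdr / 0.05 -
                            round(ee$photo_vcdr / 0.05)) > 1e-6)
  if (length(off_grid)) {
    out[[length(out) + 1]] <- issue(ee$person_id[off_grid], "photo_vcdr",
      "vcdr_grid", "photo VCDR must be recorded to the nearest 0.05")
  }
  bad_vh <- which(!is.na(ee$vh_grade) & !ee$vh_grade %in% 0:4)
  if (length(bad_vh)) {
    out[[length(out) + 1]] <- issue(ee$person_id[bad_vh], "vh_grade",
      "vh_range", "Van Herick grade must be 0-4")
  }
  bad_side <- which(!ee$side %in% c("R", "L"))
  if (length(bad_side)) {
    out[[length(out) + 1]] <- issue(ee$person_id[bad_side], "side",
      "side_code", "eye side must be R or L")
  }
  va_ok <- vapply(ee$presenting_va, function(v) {
    if (is.na(v)) return(TRUE)
    !inherits(try(va_to_logmar(v), silent = TRUE), "try-error")
  }, logical(1))
  if (any(!va_ok)) {
    out[[length(out) + 1]] <- issue(ee$person_id[!va_ok], "presenting_va",
      "va_parseable", "unparseable visual acuity code")
  }
  gonio_incons <- which(!is.na(ee$gonioscopy) &
                          !isTRUE_vec(ee$disc_seen) &
                          is.na(ee$photo_vcdr) & is.na(ee$clinical_vcdr))
  if (length(gonio_incons)) {
    out[[length(out) + 1]] <- issue(ee$person_id[gonio_incons], "gonioscopy",
      "gonioscopy_implies_disc_assessment",
      "gonioscopy recorded but no disc assessment of any kind")
  }
  if (!length(out)) {
    return(issue(character(0), character(0), character(0), character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
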