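#' Run the full survey analysis pipeline
#'
#' Orchestrates simulate (or load) -> derive thresholds -> grade fields ->
#' classify -> prevalence / agreement / blindness summaries, mirroring the
#' diagnostic flow of the survey protocol. Deterministic given the seed.
#'
#' @param cohort a [survey_cohort()]; by default one is simulated from
#'   `config`.
#' @param config a [sim_config()] used when `cohort` is NULL.
#' @param seed master seed for simulation.
#' @param thresholds `"derive"` (from the cohort's normative subsample),
#'   `"published"`, a path to a thresholds YAML file, or a
#'   [diagnostic_thresholds()] object.
#' @param standard_population data.frame or CSV path (`age_band`,
#'   `population`) for direct standardization; NULL skips it.
#' @param out_dir if non-NULL, writes `diagnosis.csv`,
#'   `diagnosis_eyes.csv`, `prevalence.csv`, `subgroups.csv`,
#'   `evidence_tabulation.csv`, `type_tabulation.csv`, `flow_counts.csv`,
#'   `thresholds.yaml` and (when standardizing) `standardized.csv`.
#' @return list of class `glaucsurv_report`: `cohort`, `truth` (when
#'   simulated), `thresholds`, `diagnosis`, `flow_counts`, `evidence_tab`,
#'   `type_tab`, `prevalence` (crude, by age band, by subgroup),
#'   `standardized`, `agreement` (clinical vs image VCDR; Van Herick vs
#'   gonioscopy in glaucomatous eyes), `blindness`.
#' @export
run_pipeline <- function(cohort = NULL, config = sim_config(),
                         seed = config$seed, thresholds = "derive",
                         standard_population = NULL, out_dir = NULL) {
  truth <- NULL
  if (is.null(cohort)) {
    sim <- generate_cohort(config, seed = seed)
    cohort <- sim$cohort
    truth <- sim$truth
  }
  th <- resolve_thresholds(thresholds, cohort)
  dx <- classify_cohort(cohort, thresholds = th)
  persons <- dx$persons

  prev <- list(
    crude = crude_prevalence(persons),
    by_age = age_specific_prevalence(persons),
    by_subgroup = do.call(rbind, lapply(
      c("sex", "ethnicity", "literacy", "residence", "visual_status"),
      function(f) subgroup_prevalence(persons, f))))
  standardized <- NULL
  if (!is.null(standard_population)) {
    sp <- if (is.character(standard_population)) {
      read_standard_population(standard_population)
    } else standard_population
    standardized <- direct_standardize(prev$by_age, sp)
  }
  report <- structure(list(
    cohort = cohort, truth = truth, thresholds = th, diagnosis = dx,
    flow_counts = flow_counts(cohort, dx),
    evidence_tab = evidence_tabulation(dx),
    type_tab = type_tabulation(dx),
    prevalence = prev, standardized = standardized,
    agreement = agreement_summaries(cohort, dx),
    blindness = blindness_summary(dx)), class = "glaucsurv_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

resolve_thresholds <- function(thresholds, cohort) {
  if (inherits(thresholds, "diagnostic_thresholds")) return(thresholds)
  if (identical(thresholds, "derive")) return(derive_thresholds(cohort))
  if (identical(thresholds, "published")) return(published_thresholds())
  if (is.character(thresholds) && file.exists(thresholds)) {
    return(read_thresholds(thresholds))
  }
  stop("thresholds must be 'derive', 'published', a file path or a ",
       "diagnostic_thresholds object")
}

#' Diagnostic-flow accounting of a classified cohort
#'
#' Counts mirroring the survey's reporting of its diagnostic algorithm:
#' how many persons triggered the VCDR criteria, how many eyes and persons
#' required and had field analysis, disc-grading completeness, and
#' diagnosed persons per evidence category.
#'
#' @param cohort a [survey_cohort()].
#' @param dx the matching [classify_cohort()] result.
#' @return data.frame with `stage` and `n`.
#' @export
flow_counts <- function(cohort, dx) {
  ee <- dx$eyes
  pp <- dx$persons
  th <- dx$thresholds
  v975 <- unname(th$vcdr_975[ee$vcdr_source])
  vcdr_hi <- !is.na(ee$vcdr) & !is.na(v975) & ee$vcdr >= v975 - 1e-9
  asym_scale <- ifelse(is.na(ee$asym), "none",
                       ifelse(ee$vcdr_source == "image", "image",
                              "clinical"))
  a975 <- unname(th$asym_975[asym_scale])
  asym_hi <- !is.na(ee$asym) & !is.na(a975) & ee$asym >= a975 - 1e-9
  need_vf <- vcdr_hi | asym_hi
  persons_vcdr <- unique(ee$person_id[vcdr_hi])
  persons_need <- unique(ee$person_id[need_vf])
  persons_asym_only <- setdiff(unique(ee$person_id[asym_hi]), persons_vcdr)
  vf_usable_eye <- ee$vf_grade != "not_usable"
  graded <- !is.na(ee$vcdr)
  graded_persons <- unique(ee$person_id[graded])
  no_vcdr_persons <- setdiff(pp$person_id, graded_persons)
  stage <- function(stage, n) data.frame(stage = stage, n = n,
                                         stringsAsFactors = FALSE)
  rbind(
    stage("persons_examined", nrow(pp)),
    stage("eyes_examined", nrow(ee)),
    stage("eyes_with_disc_grade", sum(graded)),
    stage("persons_with_disc_grade", length(graded_persons)),
    stage("persons_no_disc_grade", length(no_vcdr_persons)),
    stage("persons_vcdr_criterion", length(persons_vcdr)),
    stage("persons_asymmetry_only_criterion", length(persons_asym_only)),
    stage("persons_needing_vf", length(persons_need)),
    stage("eyes_needing_vf", sum(need_vf)),
    stage("eyes_needing_vf_with_usable_vf", sum(need_vf & vf_usable_eye)),
    stage("persons_diagnosed", sum(pp$glaucoma)),
    stage("persons_category_1", sum(pp$category == "1")),
    stage("persons_category_2", sum(pp$category == "2")),
    stage("persons_category_2b", sum(pp$category == "2b")),
    stage("persons_category_3", sum(pp$category == "3")))
}

agreement_summaries <- function(cohort, dx) {
  ee <- cohort$eyes
  both <- !is.na(ee$photo_vcdr) & !is.na(ee$clinical_vcdr)
  vcdr_pairs <- list(a = ee$clinical_vcdr[both], b = ee$photo_vcdr[both])
  out <- list()
  if (sum(both) >= 2) {
    out$vcdr_bland_altman <- bland_altman(vcdr_pairs$a, vcdr_pairs$b)
    out$vcdr_kappa_within_0.1 <-
      kappa_within_tolerance(vcdr_pairs$a, vcdr_pairs$b, 0.1)
    out$vcdr_pct_within_0.25 <-
      proportion_within(vcdr_pairs$a, vcdr_pairs$b, 0.25)
  }
  gl_eyes <- dx$eyes$glaucoma
  key <- paste(dx$eyes$person_id, dx$eyes$side)
  ekey <- paste(ee$person_id, ee$side)
  gl <- ekey %in% key[gl_eyes]
  ok <- gl & !is.na(ee$gonioscopy) & !is.na(ee$vh_grade)
  if (sum(ok) >= 10) {
    gon <- factor(ee$gonioscopy[ok] == "closed", levels = c(FALSE, TRUE))
    vh <- factor(vh_angle_group(ee$vh_grade[ok]) == "closure_likely",
                 levels = c(FALSE, TRUE))
    out$vh_gonioscopy_kappa <- cohen_kappa(table(gon, vh))
    out$vh_gonioscopy_agreement_pct <- 100 * mean(gon == vh)
    out$vh_gonioscopy_n_eyes <- sum(ok)
  }
  out
}

#' @export
print.glaucsurv_report <- function(x, ...) {
  cr <- x$prevalence$crude
  cat("Survey analysis report\n")
  cat(sprintf("  examined: %d persons in %d clusters\n", cr$denominator,
              cr$n_clusters))
  cat(sprintf("  glaucoma: %d persons, prevalence %.2f%% (95%% CI %.2f-%.2f)\n",
              cr$numerator, cr$prevalence, cr$ci_low, cr$ci_high))
  cat(sprintf("  design effect %.2f; thresholds source: %s\n",
              cr$design_effect, x$thresholds$source))
  if (!is.null(x$standardized)) {
    cat(sprintf("  age-standardized rate %.2f%%; projected burden %.0f\n",
                x$standardized$adjusted_rate, x$standardized$total_burden))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE, na = "")
  w(report$diagnosis$persons, "diagnosis.csv")
  w(report$diagnosis$eyes, "diagnosis_eyes.csv")
  w(cbind(data.frame(estimate = "crude"), report$prevalence$crude),
    "prevalence.csv")
  w(report$prevalence$by_age, "prevalence_by_age.csv")
  w(report$prevalence$by_subgroup, "subgroups.csv")
  w(report$evidence_tab, "evidence_tabulation.csv")
  w(report$type_tab, "type_tabulation.csv")
  w(report$flow_counts, "flow_counts.csv")
  write_thresholds(report$thresholds, file.path(out_dir, "thresholds.yaml"))
  if (!is.null(report$standardized)) {
    w(report$standardized$by_band, "standardized.csv")
  }
  invisible(out_dir)
}
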