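#' Simulation configuration for a synthetic survey cohort
#'
#' Defaults emulate the statistical structure of the national survey the
#' package's analyses are designed for: 305 clusters of 45 examined persons
#' aged 40+, glaucoma prevalence rising from 1.9% (40-49) to 14.7% (80+),
#' normal-eye IOP ~ N(14, 4) against a trimodal mixture (modes near 12, 28
#' and 50 mmHg) in glaucomatous eyes, photographic disc grading available
#' for 66% of detailed-examination eyes with a 20.5% clinical fallback and
#' 13.5% with no grading, and visual field results available for 60% of
#' eyes.
#'
#' @param n_clusters,persons_per_cluster sampling frame size.
#' @param seed master seed; stage-level substreams are derived from it.
#' @param age_band_weights probabilities of the five age bands
#'   (40-49 ... 80+), summing to 1.
#' @param true_prevalence_by_band latent glaucoma prevalence per band, in
#'   percent.
#' @param iop_normal `c(mean, sd)` of IOP in non-glaucomatous eyes (mmHg),
#'   recorded to the nearest mmHg.
#' @param iop_glaucoma_mixture list with `means`, `sds`, `weights` of the
#'   glaucoma-eye IOP mixture components.
#' @param photo_vcdr_availability,clinical_fallback,no_disc_grade disc
#'   grading availability within detailed-examination eyes (must sum to 1).
#' @param vf_availability_given_needed probability that an eye has a
#'   testable field result.
#' @param awareness_given_glaucoma probability a person with glaucoma knows
#'   their diagnosis.
#' @param secondary_fraction_of_glaucoma fraction of glaucoma that is
#'   secondary.
#' @param cluster_effect_sd SD of the cluster random effect on the logit
#'   scale; the default yields an observed intraclass correlation near
#'   1/44, i.e. a design effect near 2 at 45 persons per cluster. Band
#'   intercepts are solved numerically so that the marginal prevalence
#'   equals `true_prevalence_by_band` despite the logit-scale
#'   heterogeneity.
#' @param bilateral_fraction fraction of glaucoma that is bilateral.
#' @param pacg_fraction_primary fraction of primary glaucoma with closed
#'   angles.
#' @param gonio_missing_fraction fraction of indicated gonioscopies lost
#'   (field conditions damaged gonioscopy lenses).
#' @param iop_availability,vh_availability completeness of tonometry and
#'   Van Herick grading within detailed-examination eyes.
#' @param normal_vcdr list `mean`, `person_sd`, `eye_sd`,
#'   `asym_outlier_p`, `asym_outlier_shift` of the latent normal VCDR
#'   (person + eye effects, plus a rare physiological-asymmetry shift of
#'   one eye; the marginal distribution places the rounded 97.5th/99.5th
#'   percentiles at 0.70/0.75 and the asymmetry percentiles at 0.10/0.20).
#' @param glaucoma_vcdr list `shift`, `scale`, `shape1`, `shape2`: affected
#'   VCDR = shift + scale * Beta(shape1, shape2), rounded to 0.05.
#' @param male_fraction,literacy_fraction,rural_fraction demographics.
#' @param ethnicity_weights named sampling weights of ethnic groups.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 305, persons_per_cluster = 45,
                       seed = 1L,
                       age_band_weights = c(0.360, 0.263, 0.204, 0.122, 0.051),
                       true_prevalence_by_band = c(1.9, 3.6, 6.4, 10.8, 14.7),
                       iop_normal = c(mean = 14, sd = 4),
                       iop_glaucoma_mixture = list(
                         means = c(12, 28, 50), sds = c(3, 5, 6),
                         weights = c(0.50, 0.35, 0.15)),
                       photo_vcdr_availability = 0.66,
                       clinical_fallback = 0.205,
                       no_disc_grade = 0.135,
                       vf_availability_given_needed = 0.60,
                       awareness_given_glaucoma = 0.056,
                       secondary_fraction_of_glaucoma = 0.078,
                       cluster_effect_sd = 1.00,
                       bilateral_fraction = 0.39,
                       pacg_fraction_primary = 0.14,
                       gonio_missing_fraction = 0.58,
                       iop_availability = 0.858,
                       vh_availability = 0.911,
                       normal_vcdr = list(mean = 0.40, person_sd = 0.156,
                                          eye_sd = 0.025,
                                          asym_outlier_p = 0.012,
                                          asym_outlier_shift = 0.20),
                       glaucoma_vcdr = list(shift = 0.35, scale = 0.65,
                                            shape1 = 2.6, shape2 = 2.0),
                       male_fraction = 0.46,
                       literacy_fraction = 0.436,
                       rural_fraction = 0.776,
                       ethnicity_weights = c(
                         Hausa = 0.248, Yoruba = 0.196, Igbo = 0.141,
                         Fulani = 0.062, Kanuri = 0.026, Tiv = 0.025,
                         Ijaw = 0.019, Urhobo = 0.018, Ibibio = 0.016,
                         Nupe = 0.016, Others = 0.233)) {
  cfg <- as.list(environment())
  stopifnot(n_clusters >= 1, persons_per_cluster >= 1)
  if (abs(sum(age_band_weights) - 1) > 1e-6) {
    stop("age_band_weights must sum to 1")
  }
  if (length(true_prevalence_by_band) != 5 ||
      any(true_prevalence_by_band < 0 | true_prevalence_by_band > 100)) {
    stop("true_prevalence_by_band must be 5 percentages")
  }
  if (abs(sum(iop_glaucoma_mixture$weights) - 1) > 1e-6) {
    stop("IOP mixture weights must sum to 1")
  }
  avail <- c(photo_vcdr_availability, clinical_fallback, no_disc_grade,
             vf_availability_given_needed, awareness_given_glaucoma,
             secondary_fraction_of_glaucoma, bilateral_fraction,
             pacg_fraction_primary, gonio_missing_fraction,
             iop_availability, vh_availability)
  if (any(avail < 0 | avail > 1)) {
    stop("availabilities and fractions must lie in [0, 1]")
  }
  if (abs(photo_vcdr_availability + clinical_fallback + no_disc_grade - 1) >
      1e-6) {
    stop("photo/clinical/none disc-grading fractions must sum to 1")
  }
  if (abs(sum(ethnicity_weights) - 1) > 1e-6) {
    stop("ethnicity_weights must sum to 1")
  }
  structure(cfg, class = "sim_config")
}

round05 <- function(x) pmin(1, pmax(0, round(x / 0.05) * 0.05))

# intercept c such that E[plogis(c + sigma * Z)] = p for standard normal Z
logit_intercept <- function(p, sigma) {
  if (p <= 0) return(-Inf)
  if (sigma == 0) return(stats::qlogis(p))
  marg <- function(c) {
    stats::integrate(function(z) stats::plogis(c + sigma * z) *
                       stats::dnorm(z), -8, 8)$value - p
  }
  stats::uniroot(marg, c(stats::qlogis(p) - 3, stats::qlogis(p) + 3))$root
}

stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% 2147483647)
}

.level_code_chr <- c("0", "5", "2", "1", "05")

# defect-level sampling weights as a function of severity in [0, 1]
defect_level_weights <- function(s) {
  shallow <- c(0.55, 0.25, 0.13, 0.07)
  deep <- c(0.08, 0.12, 0.25, 0.55)
  (1 - s) * shallow + s * deep
}

# simulate PDP/TDP level matrices for n eyes; severity 0 = normal eye
sim_defect_maps <- function(severity, diffuse, zones = fdt_c20_zones()) {
  n <- length(severity)
  nz <- nrow(zones)
  pdp <- matrix(0L, n, nz)
  lateral <- which(zones$hemifield != "central")
  central <- which(zones$hemifield == "central")
  hemis <- list(which(zones$hemifield == "superior"),
                which(zones$hemifield == "inferior"))
  p_def <- ifelse(severity > 0, 0.18 + 0.55 * severity, 0.010)
  n_def <- stats::rbinom(n, length(lateral), p_def) +
    (length(central) > 0) * stats::rbinom(n, 1, 0.5 * p_def)
  n_def <- pmin(n_def, nz)
  todo <- which(n_def > 0)
  for (i in todo) {
    s <- severity[i]
    if (s > 0) {
      pref <- hemis[[sample.int(2, 1)]]
      w <- rep(0.2 / (nz - length(pref)), nz)
      w[pref] <- 0.8 / length(pref)
      zs <- sample.int(nz, n_def[i], prob = w)
      lv <- sample.int(4, n_def[i], replace = TRUE,
                       prob = defect_level_weights(s))
    } else {
      zs <- sample.int(nz, n_def[i])
      lv <- sample(c(1L, 2L), n_def[i], replace = TRUE, prob = c(0.97, 0.03))
    }
    pdp[i, zs] <- lv
  }
  tdp <- pdp
  shade <- which(diffuse)
  for (i in shade) {
    zs <- which(stats::runif(nz) < 0.7)
    tdp[i, zs] <- pmax(tdp[i, zs], 1L)
  }
  list(pdp = pdp, tdp = tdp)
}

#' Simulate one visual field test record
#'
#' Glaucomatous eyes draw hemifield-clustered defects whose number and
#' depth increase with VCDR; normal eyes draw sparse isolated shallow
#' defects; reliability indices are drawn so roughly 10\% of tests are
#' unreliable; the record is absent (untestable) with probability
#' `1 - vf_availability_given_needed`.
#'
#' @param true_status logical: does the eye truly have glaucoma?
#' @param vcdr the eye's VCDR, driving defect severity.
#' @param config a [sim_config()].
#' @param diffuse add diffuse (cataract-like) shading to the TDP plot?
#' @param zones zone geometry.
#' @return a [vf_record()], or NULL when the test is absent.
#' @export
generate_vf_record <- function(true_status, vcdr, config = sim_config(),
                               diffuse = FALSE, zones = fdt_c20_zones()) {
  if (stats::runif(1) > config$vf_availability_given_needed) return(NULL)
  sev <- if (isTRUE(true_status)) {
    min(1, max(0.05, (vcdr - 0.5) / 0.45))
  } else 0
  maps <- sim_defect_maps(sev, diffuse, zones)
  vf_record("screening",
            fixation_errors = stats::rpois(1, 0.35),
            false_positives = stats::rpois(1, 0.35),
            pdp = maps$pdp[1, ], tdp = maps$tdp[1, ],
            lid_artefact = stats::runif(1) < 0.01)
}

maps_to_codes <- function(maps, prefix) {
  out <- as.data.frame(matrix(.level_code_chr[maps + 1L], nrow = nrow(maps)))
  names(out) <- sprintf("%s_z%02d", prefix, seq_len(ncol(maps)))
  out
}

#' Generate a synthetic survey cohort with ground truth
#'
#' Builds a fully observed cohort under the configured study conditions —
#' cluster sampling with a logit-normal cluster effect, age-rising latent
#' prevalence, measurement distributions for VCDR (photographic truth plus
#' a noisier clinical grading), IOP, acuity, angle status and visual fields
#' — then applies the configured missingness mechanisms
#' ([apply_missingness()]). Reproducible given the seed.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`.
#' @return list with `cohort` (a [survey_cohort()]) and `truth` (one row
#'   per person: latent status, type, laterality and censoring flags).
#' @export
generate_cohort <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  nc <- cfg$n_clusters; ppc <- cfg$persons_per_cluster
  n <- nc * ppc

  ## stage 1: persons ------------------------------------------------------
  set.seed(stage_seed(seed, 1))
  cluster_id <- rep(sprintf("C%04d", seq_len(nc)), each = ppc)
  person_id <- sprintf("P%06d", seq_len(n))
  band <- sample.int(5, n, replace = TRUE, prob = cfg$age_band_weights)
  lo <- c(40, 50, 60, 70, 80)[band]
  width <- c(10, 10, 10, 10, 13)[band]
  age <- lo + floor(stats::runif(n) * width)
  sex <- ifelse(stats::runif(n) < cfg$male_fraction, "male", "female")
  cluster_rural <- stats::runif(nc) < cfg$rural_fraction
  residence <- ifelse(rep(cluster_rural, each = ppc), "rural", "urban")
  eth_names <- names(cfg$ethnicity_weights)
  home_eth <- sample(eth_names, nc, replace = TRUE,
                     prob = cfg$ethnicity_weights)
  ethnicity <- ifelse(stats::runif(n) < 0.75, rep(home_eth, each = ppc),
                      sample(eth_names, n, replace = TRUE,
                             prob = cfg$ethnicity_weights))
  literate <- stats::runif(n) < cfg$literacy_fraction
  u_cluster <- stats::rnorm(nc, 0, cfg$cluster_effect_sd)
  icpt <- vapply(cfg$true_prevalence_by_band / 100, logit_intercept,
                 numeric(1), sigma = cfg$cluster_effect_sd)
  p_true <- stats::plogis(icpt[band] + rep(u_cluster, each = ppc))
  true_glaucoma <- stats::runif(n) < p_true
  secondary <- true_glaucoma & stats::runif(n) <
    cfg$secondary_fraction_of_glaucoma
  angle_closed <- ifelse(true_glaucoma & !secondary,
                         stats::runif(n) < cfg$pacg_fraction_primary,
                         stats::runif(n) < 0.05)
  true_type <- ifelse(!true_glaucoma, "none",
                      ifelse(secondary, "secondary",
                             ifelse(angle_closed, "PACG", "POAG")))
  bilateral <- true_glaucoma & stats::runif(n) < cfg$bilateral_fraction
  affected_side <- ifelse(stats::runif(n) < 0.5, "R", "L")
  known_glaucoma <- true_glaucoma &
    stats::runif(n) < cfg$awareness_given_glaucoma
  surgery_history <- known_glaucoma & stats::runif(n) < 0.3
  normative <- (seq_len(n) %% 7L) == 0L

  ## stage 2: eyes (fully observed) ----------------------------------------
  set.seed(stage_seed(seed, 2))
  ne <- 2L * n
  pid_e <- rep(person_id, each = 2L)
  side <- rep(c("R", "L"), n)
  idx_p <- rep(seq_len(n), each = 2L)
  affected <- true_glaucoma[idx_p] &
    (bilateral[idx_p] | side == affected_side[idx_p])
  nv <- cfg$normal_vcdr
  # person effect with a compressed upper tail: the normal-disc population
  # thins out faster than a Gaussian beyond ~1.8 SD, which pins the rounded
  # 97.5th/99.5th percentiles at 0.70/0.75
  z_p <- stats::rnorm(n)
  z_p <- ifelse(z_p > 1.9, 1.9 + 0.65 * (z_p - 1.9), z_p)
  person_effect <- nv$mean + nv$person_sd * z_p
  vcdr_raw <- person_effect[idx_p] + stats::rnorm(ne, 0, nv$eye_sd)
  # rare physiological disc asymmetry: one eye offset from its fellow by a
  # whole grid multiple, so the rounded asymmetry is exactly the shift
  outlier_person <- stats::runif(n) < nv$asym_outlier_p
  outlier_eye <- which(outlier_person[idx_p] & !true_glaucoma[idx_p] &
                         side == affected_side[idx_p])
  fellow_idx <- outlier_eye + ifelse(side[outlier_eye] == "R", 1L, -1L)
  shift_sign <- ifelse(vcdr_raw[fellow_idx] > 0.5, -1, 1)
  vcdr_raw[outlier_eye] <- vcdr_raw[fellow_idx] +
    shift_sign * nv$asym_outlier_shift
  ga <- cfg$glaucoma_vcdr
  n_aff <- sum(affected)
  vcdr_raw[affected] <- ga$shift +
    ga$scale * stats::rbeta(n_aff, ga$shape1, ga$shape2)
  vcdr_true <- round05(vcdr_raw)
  # clinical grading under-calls cupping by ~0.1 with extra observer noise
  clinical_vcdr <- round05(vcdr_raw - 0.10 + stats::rnorm(ne, 0, 0.03))

  comp <- sample.int(3, ne, replace = TRUE,
                     prob = cfg$iop_glaucoma_mixture$weights)
  iop_raw <- ifelse(affected,
                    stats::rnorm(ne, cfg$iop_glaucoma_mixture$means[comp],
                                 cfg$iop_glaucoma_mixture$sds[comp]),
                    stats::rnorm(ne, cfg$iop_normal[["mean"]],
                                 cfg$iop_normal[["sd"]]))
  iop <- pmax(0L, as.integer(round(iop_raw)))

  # cataract is largely a person-level process (bilateral, age-related)
  # and the dominant non-glaucoma cause of poor acuity
  cataract_person <- stats::runif(n) < pmin(0.9, 0.08 +
                                              0.006 * (age - 40))
  cataract_sev <- stats::rexp(n, 1.1)
  cataract <- cataract_person[idx_p] & stats::runif(ne) < 0.8
  gla_sev_p <- stats::rnorm(n, 0, 0.60)
  va_logmar <- stats::rnorm(ne, 0.06 + 0.004 * (age[idx_p] - 40), 0.12) +
    ifelse(cataract, cataract_sev[idx_p] * stats::runif(ne, 0.6, 1.4), 0) +
    ifelse(affected, pmax(0, vcdr_true - 0.5) * 4.5 + gla_sev_p[idx_p] +
             stats::rnorm(ne, 0, 0.25), 0)
  va_logmar <- pmax(-0.1, round(va_logmar, 2))

  rapd <- stats::runif(ne) < ifelse(affected & !bilateral[idx_p], 0.25,
                                    ifelse(affected, 0.05, 0.002))
  oedema <- stats::runif(ne) < ifelse(iop >= 40, 0.30, 0.002)
  causes <- c("couching", "trauma", "uveitis", "intracapsular_surgery",
              "other")
  secondary_cause <- rep("none", ne)
  sec_eye <- affected & secondary[idx_p]
  secondary_cause[sec_eye] <- sample(causes, sum(sec_eye), replace = TRUE,
                                     prob = c(0.38, 0.21, 0.19, 0.17, 0.05))
  angle <- ifelse(angle_closed[idx_p], "closed", "open")
  flip <- stats::runif(ne) < 0.03
  gonio_true <- ifelse(flip, ifelse(angle == "closed", "open", "closed"),
                       angle)
  vh_grade <- integer(ne)
  closed_like <- gonio_true == "closed"
  agree_vh <- stats::runif(ne) < ifelse(closed_like, 0.85, 0.90)
  vh_grade[closed_like & agree_vh] <-
    sample(0:2, sum(closed_like & agree_vh), TRUE, prob = c(0.2, 0.4, 0.4))
  vh_grade[closed_like & !agree_vh] <-
    sample(3:4, sum(closed_like & !agree_vh), TRUE)
  vh_grade[!closed_like & agree_vh] <-
    sample(3:4, sum(!closed_like & agree_vh), TRUE, prob = c(0.45, 0.55))
  vh_grade[!closed_like & !agree_vh] <-
    sample(1:2, sum(!closed_like & !agree_vh), TRUE)

  ## stage 3: examination flow ---------------------------------------------
  set.seed(stage_seed(seed, 3))
  by_person <- function(x, f) tapply(x, idx_p, f)[as.character(seq_len(n))]
  va_worst <- by_person(va_logmar, max)
  cvcdr_max <- by_person(clinical_vcdr, max)
  casym <- abs(clinical_vcdr[side == "R"] - clinical_vcdr[side == "L"])
  other_abn <- stats::runif(n) < 0.03
  detailed <- va_worst > log10(2) + 1e-9 | cvcdr_max >= 0.6 - 1e-9 |
    casym >= 0.2 - 1e-9 | normative | other_abn
  exam_level <- ifelse(detailed[idx_p], "detailed", "basic")

  participants <- data.frame(
    person_id = person_id, cluster_id = cluster_id, age_years = age,
    sex = sex, ethnicity = ethnicity, literate = literate,
    residence = residence, known_glaucoma = known_glaucoma,
    glaucoma_surgery_history = surgery_history, normative = normative,
    stringsAsFactors = FALSE)
  eyes <- data.frame(
    person_id = pid_e, side = side,
    photo_vcdr = ifelse(exam_level == "detailed", vcdr_true, NA_real_),
    clinical_vcdr = clinical_vcdr, iop_mmhg = iop, vh_grade = vh_grade,
    gonioscopy = gonio_true, presenting_va = as.character(va_logmar),
    secondary_cause = secondary_cause, rapd = rapd,
    corneal_oedema = oedema, disc_seen = TRUE, exam_level = exam_level,
    stringsAsFactors = FALSE)
  # gonioscopy only where indicated at detailed examination
  indicated <- exam_level == "detailed" &
    needs_gonioscopy(iop, ifelse(is.na(eyes$photo_vcdr), clinical_vcdr,
                                 eyes$photo_vcdr),
                     rep(casym, each = 2), vh_grade)
  eyes$gonioscopy[!indicated] <- NA_character_

  ## stage 4: visual fields (fully observed) -------------------------------
  set.seed(stage_seed(seed, 4))
  severity <- ifelse(affected, pmin(1, pmax(0.05, (vcdr_true - 0.5) / 0.45)),
                     0)
  diffuse <- cataract & stats::runif(ne) < 0.5
  zones <- fdt_c20_zones()
  maps <- sim_defect_maps(severity, diffuse, zones)
  fe <- stats::rpois(ne, 0.35); fp <- stats::rpois(ne, 0.35)
  lid <- stats::runif(ne) < 0.01
  vf_scr <- data.frame(
    person_id = pid_e, side = side, mode = "screening",
    fixation_errors = fe, false_positives = fp, lid_artefact = lid,
    untestable_reason = NA_character_, stringsAsFactors = FALSE)
  vf_scr <- cbind(vf_scr, maps_to_codes(maps$pdp, "pdp"),
                  maps_to_codes(maps$tdp, "tdp"))
  # threshold test when a reliable screening triggers it and logistics allow
  trig <- rowSums(maps$pdp >= 3L) >= 3L | rowSums(maps$pdp >= 4L) >= 2L
  thr_idx <- which(trig & fe <= 1 & fp <= 1 & !lid &
                     stats::runif(ne) < 0.9)
  if (length(thr_idx)) {
    tmaps <- sim_defect_maps(severity[thr_idx], diffuse[thr_idx], zones)
    vf_thr <- data.frame(
      person_id = pid_e[thr_idx], side = side[thr_idx], mode = "threshold",
      fixation_errors = stats::rpois(length(thr_idx), 0.5),
      false_positives = stats::rpois(length(thr_idx), 0.5),
      lid_artefact = stats::runif(length(thr_idx)) < 0.01,
      untestable_reason = NA_character_, stringsAsFactors = FALSE)
    vf_thr <- cbind(vf_thr, maps_to_codes(tmaps$pdp, "pdp"),
                    maps_to_codes(tmaps$tdp, "tdp"))
    vf <- rbind(vf_scr, vf_thr)
  } else {
    vf <- vf_scr
  }

  cohort_full <- survey_cohort(participants, eyes, vf)

  ## stage 5: missingness ---------------------------------------------------
  set.seed(stage_seed(seed, 5))
  cohort <- apply_missingness(cohort_full, cfg)

  ee <- cohort$eyes
  photo_censored <- is.na(ee$photo_vcdr) & eyes$exam_level == "detailed"
  vfm <- cohort$vf
  untest <- !is.na(vfm$untestable_reason) & vfm$mode == "screening"
  truth <- data.frame(
    person_id = person_id, cluster_id = cluster_id,
    age_band = as.character(age_band(age)),
    true_glaucoma = true_glaucoma, true_type = true_type,
    bilateral = bilateral,
    affected_side = ifelse(!true_glaucoma, NA_character_,
                           ifelse(bilateral, "both", affected_side)),
    photo_censored_any = tapply(photo_censored, idx_p,
                                any)[as.character(seq_len(n))],
    vf_untestable_any = person_id %in% vfm$person_id[untest],
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(cohort = cohort, truth = truth)
}

no_photo_reasons <- function(n, diseased) {
  disease_mix <- c(cataract = 0.50, corneal_opacity = 0.30,
                   other_ocular = 0.20)
  tech_mix <- c(faulty_camera = 0.36, no_electricity = 0.12,
                no_reason_stated = 0.23, ungradable_photo = 0.17,
                uncooperative = 0.06, other_participant_factor = 0.06)
  out <- character(n)
  out[diseased] <- sample(names(disease_mix), sum(diseased), TRUE,
                          prob = disease_mix)
  out[!diseased] <- sample(names(tech_mix), sum(!diseased), TRUE,
                           prob = tech_mix)
  out
}

#' Apply the survey's missingness mechanisms to a fully observed cohort
#'
#' Within detailed-examination eyes, photographic VCDR is kept for
#' `photo_vcdr_availability` of eyes; of the remainder, the clinical grade
#' is retained as fallback except for the `no_disc_grade` fraction, which
#' loses both grades (disc not seen) — each removal is labelled with a
#' censoring reason (eye-disease reasons preferentially attach to eyes with
#' worse acuity, technical reasons to the rest). Tonometry and Van Herick
#' grading are thinned to their configured completeness, indicated
#' gonioscopies are lost at the configured rate, and visual field tests are
#' marked untestable with probability `1 - vf_availability_given_needed`.
#' Latent status is never altered.
#'
#' @param cohort a fully observed [survey_cohort()].
#' @param config a [sim_config()].
#' @return the censored [survey_cohort()]; the eyes table gains a
#'   `no_photo_reason` column.
#' @export
apply_missingness <- function(cohort, config = sim_config()) {
  stopifnot(inherits(cohort, "survey_cohort"),
            inherits(config, "sim_config"))
  cfg <- config
  ee <- cohort$eyes
  ne <- nrow(ee)
  detailed <- ee$exam_level == "detailed"
  # the no-grading class is partly person-level (camera faults, no
  # electricity affect both eyes), partly eye-level, so that both-eye
  # censoring is commoner than under independence
  p_person_none <- 0.48 * cfg$no_disc_grade
  p_eye_none <- (cfg$no_disc_grade - p_person_none) / (1 - p_person_none)
  pid_all <- unique(ee$person_id)
  person_none <- pid_all[stats::runif(length(pid_all)) < p_person_none]
  none_eye <- detailed & (ee$person_id %in% person_none |
                            stats::runif(ne) < p_eye_none)
  p_photo_cond <- min(1, cfg$photo_vcdr_availability /
                        max(1e-9, 1 - cfg$no_disc_grade))
  u <- stats::runif(ne)
  keep_photo <- detailed & !none_eye & u < p_photo_cond
  lose_all <- none_eye
  no_photo <- detailed & !keep_photo
  ee$no_photo_reason <- NA_character_
  if (any(no_photo)) {
    va <- va_to_logmar(ee$presenting_va)
    diseased <- !is.na(va[no_photo]) & va[no_photo] > 0.5
    ee$no_photo_reason[no_photo] <- no_photo_reasons(sum(no_photo), diseased)
  }
  ee$photo_vcdr[!keep_photo] <- NA_real_
  ee$clinical_vcdr[lose_all] <- NA_real_
  # basic-examination eyes carry a clinical grade almost always
  basic_lost <- !detailed & stats::runif(ne) < min(0.01, cfg$no_disc_grade)
  ee$clinical_vcdr[basic_lost] <- NA_real_
  ee$photo_vcdr[!detailed] <- NA_real_
  ee$disc_seen <- !(is.na(ee$photo_vcdr) & is.na(ee$clinical_vcdr))
  ee$iop_mmhg[!detailed | stats::runif(ne) > cfg$iop_availability] <-
    NA_integer_
  ee$vh_grade[!detailed | stats::runif(ne) > cfg$vh_availability] <-
    NA_integer_
  had_gonio <- !is.na(ee$gonioscopy)
  ee$gonioscopy[had_gonio &
                  stats::runif(ne) < cfg$gonio_missing_fraction] <-
    NA_character_
  # media too opaque for any disc assessment also precluded gonioscopy
  ee$gonioscopy[!ee$disc_seen] <- NA_character_

  vf <- cohort$vf
  if (nrow(vf)) {
    scr <- vf$mode == "screening"
    untest <- scr & stats::runif(nrow(vf)) >
      cfg$vf_availability_given_needed
    map_cols <- grep("^(pdp|tdp)_z", names(vf), value = TRUE)
    if (any(untest)) {
      vf$untestable_reason[untest] <-
        sample(c("cataract", "did_not_understand", "unable_to_fixate"),
               sum(untest), TRUE, prob = c(0.6, 0.3, 0.1))
      vf[untest, map_cols] <- NA_character_
      # an eye whose screening was untestable has no threshold test either
      key <- paste(vf$person_id, vf$side)
      drop_thr <- vf$mode == "threshold" & key %in% key[untest]
      vf <- vf[!drop_thr, , drop = FALSE]
    }
    rownames(vf) <- NULL
  }
  survey_cohort(cohort$participants, ee, vf)
}
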