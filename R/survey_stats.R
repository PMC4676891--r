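#' Age bands used for reporting
#'
#' @param age_years integer ages (>= 40).
#' @return factor with levels `40-49`, `50-59`, `60-69`, `70-79`, `80+`.
#' @export
age_band <- function(age_years) {
  cut(age_years, breaks = c(40, 50, 60, 70, 80, Inf), right = FALSE,
      labels = c("40-49", "50-59", "60-69", "70-79", "80+"))
}

# ratio-estimator (Taylor linearization) variance with clusters as primary
# sampling units; returns the estimate on the proportion scale
cluster_ratio <- function(case, cluster) {
  keep <- !is.na(case) & !is.na(cluster)
  case <- as.logical(case)[keep]; cluster <- cluster[keep]
  y <- tapply(as.numeric(case), cluster, sum)
  x <- tapply(rep(1, length(case)), cluster, sum)
  m <- length(y)
  if (m < 2) stop("cluster variance undefined with fewer than 2 clusters")
  r <- sum(y) / sum(x)
  z <- y - r * x
  v <- m / (m - 1) * sum(z^2) / sum(x)^2
  list(numerator = sum(y), denominator = sum(x), p = r, var = v,
       n_clusters = m)
}

new_prevalence_estimate <- function(cr, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(cr$var)
  srs_var <- cr$p * (1 - cr$p) / cr$denominator
  deff <- if (srs_var > 0) cr$var / srs_var else NA_real_
  data.frame(
    numerator = cr$numerator, denominator = cr$denominator,
    prevalence = 100 * cr$p,
    ci_low = max(0, 100 * (cr$p - zq * se)),
    ci_high = min(100, 100 * (cr$p + zq * se)),
    design_effect = deff, n_clusters = cr$n_clusters)
}

#' Crude design-based prevalence
#'
#' Point estimate with a 95\% confidence interval accounting for the
#' cluster sampling design: clusters are the primary sampling units, the
#' proportion is a ratio estimator, and its variance comes from the
#' between-cluster variation of cluster totals (Taylor linearization) with
#' a normal-approximation interval truncated to \[0, 100\]. The design
#' effect is the ratio of this variance to the simple-random-sampling
#' binomial variance.
#'
#' @param persons data.frame with one row per examined person.
#' @param case name of the logical outcome column.
#' @param cluster name of the cluster identifier column.
#' @param level confidence level.
#' @return one-row data.frame: `numerator`, `denominator`, `prevalence`
#'   (percent), `ci_low`, `ci_high`, `design_effect`, `n_clusters`.
#' @export
crude_prevalence <- function(persons, case = "glaucoma",
                             cluster = "cluster_id", level = 0.95) {
  new_prevalence_estimate(cluster_ratio(persons[[case]],
                                        persons[[cluster]]), level)
}

#' Age-specific prevalence
#'
#' One design-based estimate per 10-year age band; bands without examined
#' persons are omitted with a warning.
#'
#' @inheritParams crude_prevalence
#' @param age name of the age column (years).
#' @return data.frame with an `age_band` column plus the
#'   [crude_prevalence()] columns.
#' @export
age_specific_prevalence <- function(persons, case = "glaucoma",
                                    cluster = "cluster_id",
                                    age = "age_years") {
  band <- age_band(persons[[age]])
  out <- lapply(levels(band), function(b) {
    sub <- persons[!is.na(band) & band == b, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    cbind(data.frame(age_band = b), crude_prevalence(sub, case, cluster))
  })
  empty <- levels(band)[vapply(out, is.null, logical(1))]
  if (length(empty)) {
    warning("age band(s) with no examined persons omitted: ",
            paste(empty, collapse = ", "))
  }
  do.call(rbind, out)
}

subgroup_variable <- function(persons, factor) {
  switch(factor,
    sex = persons$sex,
    ethnicity = collapse_rare(persons$ethnicity, min_n = 200),
    literacy = ifelse(is.na(persons$literate), NA_character_,
                      ifelse(persons$literate, "literate", "illiterate")),
    residence = persons$residence,
    visual_status = persons$visual_status,
    stop("unknown factor '", factor, "'; use sex, ethnicity, literacy, ",
         "residence or visual_status"))
}

#' Collapse rare factor levels
#'
#' Levels with fewer members than `min_n` are pooled into `"Others"` —
#' the convention used for ethnic groups (analyzed separately only with at
#' least 200 participants).
#'
#' @param x character vector.
#' @param min_n minimum group size.
#' @param other label for the pooled level.
#' @return character vector.
#' @export
collapse_rare <- function(x, min_n = 200, other = "Others") {
  tab <- table(x)
  rare <- names(tab)[tab < min_n]
  ifelse(is.na(x), NA_character_, ifelse(x %in% rare, other, x))
}

#' Subgroup prevalence
#'
#' Design-based prevalence by level of a socio-demographic factor. Missing
#' factor values are excluded and their count reported in the
#' `n_missing_excluded` attribute.
#'
#' @inheritParams crude_prevalence
#' @param factor one of `"sex"`, `"ethnicity"`, `"literacy"`,
#'   `"residence"`, `"visual_status"`.
#' @return data.frame with a `level` column plus the [crude_prevalence()]
#'   columns.
#' @export
subgroup_prevalence <- function(persons, factor, case = "glaucoma",
                                cluster = "cluster_id") {
  v <- subgroup_variable(persons, factor)
  n_missing <- sum(is.na(v))
  levels <- sort(unique(v[!is.na(v)]))
  out <- do.call(rbind, lapply(levels, function(l) {
    sub <- persons[!is.na(v) & v == l, , drop = FALSE]
    cbind(data.frame(factor = factor, level = l),
          crude_prevalence(sub, case, cluster))
  }))
  attr(out, "n_missing_excluded") <- n_missing
  out
}

#' Design-adjusted test of prevalence differences between groups
#'
#' Wald test of equal proportions across factor levels using
#' cluster-robust (linearized) covariance of the level-specific ratio
#' estimators, referred to an F distribution with `L - 1` and
#' `m - L + 1` degrees of freedom (m clusters, L levels) — a
#' Rao-Scott-style correction for the cluster design.
#'
#' @inheritParams subgroup_prevalence
#' @return the p-value.
#' @export
group_difference_test <- function(persons, factor, case = "glaucoma",
                                  cluster = "cluster_id") {
  v <- subgroup_variable(persons, factor)
  keep <- !is.na(v) & !is.na(persons[[case]])
  v <- v[keep]
  y <- as.numeric(persons[[case]][keep])
  cl <- persons[[cluster]][keep]
  levels <- sort(unique(v))
  L <- length(levels)
  if (L < 2) stop("need at least 2 factor levels with data")
  clusters <- sort(unique(cl))
  m <- length(clusters)
  p <- numeric(L); U <- matrix(0, m, L)
  for (j in seq_len(L)) {
    in_l <- v == levels[j]
    yl <- tapply(y * in_l, cl, sum)[as.character(clusters)]
    xl <- tapply(as.numeric(in_l), cl, sum)[as.character(clusters)]
    yl[is.na(yl)] <- 0; xl[is.na(xl)] <- 0
    X <- sum(xl)
    if (X == 0) stop("factor level with empty denominator: ", levels[j])
    p[j] <- sum(yl) / X
    U[, j] <- (yl - p[j] * xl) / X
  }
  V <- m / (m - 1) * crossprod(U)
  C <- cbind(diag(L - 1), -1)
  d <- C %*% p
  if (max(abs(d)) < 1e-12) return(1)
  M <- C %*% V %*% t(C)
  W <- tryCatch(drop(t(d) %*% solve(M, d)),
                error = function(e) stop("degenerate table: ",
                                         conditionMessage(e)))
  df2 <- m - L + 1
  stats::pf(W / (L - 1), L - 1, df2, lower.tail = FALSE)
}

#' Read a standard population file
#'
#' @param path CSV with columns `age_band`, `population`.
#' @return validated data.frame.
#' @export
read_standard_population <- function(path) {
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age_band", "population") %in% names(sp))) {
    stop("standard population file needs columns age_band, population")
  }
  if (any(sp$population <= 0)) stop("standard populations must be positive")
  sp
}

#' Direct age standardization with burden projection
#'
#' The adjusted rate weights the age-specific rates by the standard
#' population's age structure; the projected burden per band is the band
#' rate applied to the band population.
#'
#' @param age_specific_rates data.frame with `age_band` and `prevalence`
#'   (percent), e.g. from [age_specific_prevalence()].
#' @param standard_pop data.frame with `age_band` and `population`.
#' @return list with `adjusted_rate` (percent), `by_band` (rates,
#'   populations and burdens) and `total_burden` (persons).
#' @export
direct_standardize <- function(age_specific_rates, standard_pop) {
  missing_bands <- setdiff(standard_pop$age_band,
                           age_specific_rates$age_band)
  if (length(missing_bands)) {
    stop("no age-specific rate for standard-population band(s): ",
         paste(missing_bands, collapse = ", "))
  }
  m <- match(standard_pop$age_band, age_specific_rates$age_band)
  by_band <- data.frame(
    age_band = standard_pop$age_band,
    prevalence = age_specific_rates$prevalence[m],
    population = standard_pop$population)
  by_band$burden <- by_band$prevalence / 100 * by_band$population
  list(adjusted_rate = sum(by_band$prevalence * by_band$population) /
         sum(by_band$population),
       by_band = by_band,
       total_burden = sum(by_band$burden))
}

#' Blindness summaries among glaucoma cases
#'
#' Three proportions: persons blind (better-eye presenting VA worse than
#' 3/60) among persons with glaucoma; eyes with VA worse than 3/60 among
#' glaucomatous eyes; and glaucoma prevalence among blind persons.
#'
#' @param dx a [classify_cohort()] result.
#' @return list of three lists, each with `numerator`, `denominator`,
#'   `percent`.
#' @export
blindness_summary <- function(dx) {
  stopifnot(inherits(dx, "glaucoma_diagnosis"))
  pers <- dx$persons
  eyes <- dx$eyes
  prop <- function(num, den) {
    list(numerator = num, denominator = den,
         percent = if (den > 0) 100 * num / den else 0)
  }
  g <- pers$glaucoma
  blind <- !is.na(pers$visual_status) & pers$visual_status == "blind"
  ge <- eyes$glaucoma
  eye_blind <- is_blind_va(eyes$va_logmar)
  list(
    persons_blind_among_glaucoma = prop(sum(g & blind), sum(g)),
    eyes_blind_among_glaucoma_eyes = prop(sum(ge & eye_blind), sum(ge)),
    glaucoma_among_blind = prop(sum(g & blind), sum(blind)))
}
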