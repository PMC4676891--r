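make_persons <- function(n_clusters, per_cluster, p, seed = 1,
                         cluster_p = NULL) {
  set.seed(seed)
  cl <- rep(sprintf("C%03d", seq_len(n_clusters)), each = per_cluster)
  pr <- if (is.null(cluster_p)) p else rep(cluster_p, each = per_cluster)
  data.frame(person_id = seq_along(cl), cluster_id = cl,
             glaucoma = runif(length(cl)) < pr,
             age_years = sample(40:90, length(cl), TRUE),
             stringsAsFactors = FALSE)
}

test_that("crude prevalence handles degenerate cohorts", {
  df <- make_persons(10, 20, 1)
  est <- crude_prevalence(df)
  expect_equal(est$prevalence, 100)
  expect_equal(est$ci_low, 100)
  expect_equal(est$ci_high, 100)
  expect_error(crude_prevalence(make_persons(1, 50, 0.5)), "fewer than 2")
})

test_that("prevalence respects numerator/denominator invariants", {
  df <- make_persons(50, 30, 0.08)
  est <- crude_prevalence(df)
  expect_equal(est$numerator, sum(df$glaucoma))
  expect_equal(est$denominator, nrow(df))
  expect_true(est$ci_low <= est$prevalence &&
                est$prevalence <= est$ci_high)
  expect_gte(est$design_effect, 0)
  expect_equal(est$n_clusters, 50)
})

test_that("age-specific estimates sum to the crude counts", {
  df <- make_persons(40, 40, 0.06)
  by_age <- age_specific_prevalence(df)
  crude <- crude_prevalence(df)
  expect_equal(sum(by_age$numerator), crude$numerator)
  expect_equal(sum(by_age$denominator), crude$denominator)
  single <- df[age_band(df$age_years) == "50-59", ]
  one <- suppressWarnings(age_specific_prevalence(single))
  expect_equal(nrow(one), 1)
  expect_equal(one$prevalence, crude_prevalence(single)$prevalence)
})

test_that("empty age bands are omitted with a warning", {
  df <- make_persons(10, 30, 0.1)
  df$age_years <- sample(40:59, nrow(df), TRUE)
  expect_warning(res <- age_specific_prevalence(df), "omitted")
  expect_equal(res$age_band, c("40-49", "50-59"))
})

test_that("subgroup prevalence collapses rare groups and counts missing", {
  df <- make_persons(30, 30, 0.05)
  df$ethnicity <- sample(c(rep("Hausa", 5), rep("Igbo", 4), "Tiny"),
                         nrow(df), TRUE)
  df$ethnicity[1:7] <- NA
  res <- subgroup_prevalence(df, "ethnicity")
  expect_true("Others" %in% res$level)
  expect_false("Tiny" %in% res$level)
  expect_equal(attr(res, "n_missing_excluded"), 7)
  expect_equal(sum(res$denominator), nrow(df) - 7)
  # a single-level factor reproduces the crude estimate
  df$sex <- "female"
  one <- subgroup_prevalence(df, "sex")
  expect_equal(one$prevalence, crude_prevalence(df)$prevalence)
  expect_error(subgroup_prevalence(df, "shoe"), "unknown factor")
})

test_that("the design-adjusted group test behaves at the null and under effects", {
  # exactly equal level proportions in every cluster -> p = 1
  df <- data.frame(
    cluster_id = rep(sprintf("C%02d", 1:30), each = 20),
    glaucoma = rep(c(TRUE, rep(FALSE, 9)), 60),
    sex = rep(c("male", "female"), each = 10, times = 30),
    stringsAsFactors = FALSE)
  expect_equal(group_difference_test(df, "sex"), 1)
  expect_error(group_difference_test(df[df$sex == "male", ], "sex"),
               "at least 2")
  # strong simulated effect is detected in nearly all replicates
  set.seed(31)
  hits <- replicate(20, {
    n <- 100 * 30
    d <- data.frame(
      cluster_id = rep(sprintf("C%03d", 1:100), each = 30),
      sex = sample(c("male", "female"), n, TRUE),
      stringsAsFactors = FALSE)
    d$glaucoma <- runif(n) < ifelse(d$sex == "male", 0.10, 0.02)
    group_difference_test(d, "sex") < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("direct standardization matches hand arithmetic", {
  rates <- data.frame(age_band = c("a", "b"), prevalence = c(10, 20))
  pops <- data.frame(age_band = c("a", "b"), population = c(100, 300))
  res <- direct_standardize(rates, pops)
  expect_equal(res$adjusted_rate, 17.5)
  expect_equal(res$by_band$burden, c(10, 60))
  expect_equal(res$total_burden, 70)
  zero <- direct_standardize(
    data.frame(age_band = c("a", "b"), prevalence = c(0, 0)), pops)
  expect_equal(zero$adjusted_rate, 0)
  expect_equal(zero$total_burden, 0)
  expect_error(direct_standardize(rates[1, ], pops), "band")
})

test_that("identity standardization reproduces the crude rate", {
  df <- make_persons(40, 40, 0.06, seed = 5)
  by_age <- age_specific_prevalence(df)
  std <- direct_standardize(
    by_age, data.frame(age_band = by_age$age_band,
                       population = by_age$denominator))
  expect_equal(std$adjusted_rate, crude_prevalence(df)$prevalence,
               tolerance = 1e-10)
})

test_that("the design effect is near 1 when clusters are uninformative", {
  set.seed(61)
  cluster_p <- plogis(qlogis(0.08) + rnorm(60, 0, 0.8))
  df <- make_persons(60, 50, NA, seed = 61, cluster_p = cluster_p)
  est <- crude_prevalence(df)
  expect_gt(est$design_effect, 1.3)
  perm <- df
  perm$cluster_id <- sample(perm$cluster_id)
  est_perm <- crude_prevalence(perm)
  expect_lt(abs(est_perm$design_effect - 1), 0.35)
})

test_that("confidence intervals shrink like one over root clusters", {
  width <- function(m, seed) {
    df <- make_persons(m, 40, 0.05, seed = seed)
    est <- crude_prevalence(df)
    est$ci_high - est$ci_low
  }
  set.seed(71)
  w50 <- mean(vapply(1:30, function(i) width(50, i), numeric(1)))
  w200 <- mean(vapply(1:30, function(i) width(200, 100 + i), numeric(1)))
  expect_lt(abs(w50 / w200 - 2), 0.45)
})

test_that("blindness summaries handle cohorts with no blindness", {
  sim <- generate_cohort(sim_config(n_clusters = 10), seed = 3)
  dx <- classify_cohort(sim$cohort, published_thresholds())
  dx$persons$visual_status <- "not_blind"
  dx$eyes$va_logmar <- 0
  bl <- blindness_summary(dx)
  expect_equal(bl$persons_blind_among_glaucoma$percent, 0)
  expect_equal(bl$eyes_blind_among_glaucoma_eyes$percent, 0)
  expect_equal(bl$glaucoma_among_blind$percent, 0)
})
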