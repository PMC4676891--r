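#' Published summary counts of the national survey
#'
#' The person-level data of the national blindness survey are not publicly
#' deposited, but its published report tabulates the counts behind every
#' prevalence and proportion it prints. These tables ship with the package
#' as plain CSV inputs so that the bookkeeping operations can be exercised
#' against them:
#'
#' * `margins`: examined persons and glaucoma cases by subgroup (total, age
#'   band, sex, ethnic group, literacy, residence, visual status);
#' * `evidence`: diagnosed persons and eyes by level of evidence and basis;
#' * `types`: diagnosed persons by glaucoma type;
#' * `scalars`: named scalar counts (examined persons, diagnosed eyes,
#'   awareness, blindness, gonioscopy flow, ...).
#'
#' @return list of data.frames `margins`, `evidence`, `types` and `scalars`
#'   (the latter also usable via [survey_count()]).
#' @export
survey_published_counts <- function() {
  path <- function(f) system.file("extdata", f, package = "glaucsurv",
                                  mustWork = TRUE)
  list(
    margins = utils::read.csv(path("survey_margins.csv"),
                              stringsAsFactors = FALSE),
    evidence = utils::read.csv(path("evidence_counts.csv"),
                               stringsAsFactors = FALSE,
                               colClasses = c(category = "character")),
    types = utils::read.csv(path("type_counts.csv"),
                            stringsAsFactors = FALSE),
    scalars = utils::read.csv(path("results_counts.csv"),
                              stringsAsFactors = FALSE))
}

#' Look up one published scalar count
#'
#' @param name row name in the published scalar-count table.
#' @param counts optionally a pre-loaded [survey_published_counts()] list.
#' @return the count as a number.
#' @export
survey_count <- function(name, counts = survey_published_counts()) {
  sc <- counts$scalars
  m <- match(name, sc$name)
  if (any(is.na(m))) stop("unknown count name: ",
                          paste(name[is.na(m)], collapse = ", "))
  sc$value[m]
}

#' Synthetic standard population
#'
#' A stand-in for the 2012 national census age structure (which users must
#' supply themselves for real analyses), reconstructed so that direct
#' standardization of the survey's published age-specific rates reproduces
#' its published adjusted rate and burden. Clearly synthetic: use only for
#' examples and tests.
#'
#' @return data.frame with `age_band` and `population`.
#' @export
standard_population_synthetic <- function() {
  read_standard_population(
    system.file("extdata", "standard_population_synthetic.csv",
                package = "glaucsurv", mustWork = TRUE))
}
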