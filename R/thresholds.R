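#' Nearest-rank percentile
#'
#' The value at rank `ceiling(p/100 * n)` of the sorted sample. No
#' interpolation is performed: with VCDR recorded on a 0.05 grid,
#' interpolated percentiles would fabricate unobservable values.
#'
#' @param values numeric vector (NAs dropped).
#' @param p percent, strictly between 0 and 100.
#' @return the nearest-rank percentile.
#' @examples
#' percentile_nearest_rank(1:100, 97.5)  # 98
#' @export
percentile_nearest_rank <- function(values, p) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("cannot take a percentile of an empty sample")
  if (p <= 0 || p >= 100) stop("p must be strictly between 0 and 100")
  sort(values)[ceiling(p / 100 * length(values))]
}

#' Diagnostic threshold set
#'
#' Percentile cutoffs used by the ISGEO classifier: 97.5th and 99.5th
#' percentiles of VCDR and of VCDR asymmetry, separately for image-based
#' (fundus photograph) and clinical (ophthalmoscopy) measurements, plus the
#' 99.5th percentile of IOP.
#'
#' @param vcdr_975,vcdr_995,asym_975,asym_995 named numeric vectors with
#'   elements `image` and `clinical`, values in \[0, 1\].
#' @param iop_995 mmHg.
#' @param source `"derived"` (from a normative subsample) or `"published"`
#'   (the survey's published cutoffs).
#' @param n_eyes optional named counts of contributing eyes.
#' @return object of class `diagnostic_thresholds`.
#' @export
diagnostic_thresholds <- function(vcdr_975, vcdr_995, asym_975, asym_995,
                                  iop_995, source = "derived",
                                  n_eyes = NULL) {
  for (nm in c("vcdr_975", "vcdr_995", "asym_975", "asym_995")) {
    v <- get(nm)
    if (!all(c("image", "clinical") %in% names(v))) {
      stop(nm, " must have elements 'image' and 'clinical'")
    }
    if (any(v < 0 | v > 1)) stop(nm, " outside [0, 1]")
  }
  if (any(vcdr_975 > vcdr_995) || any(asym_975 > asym_995)) {
    stop("97.5th percentile cutoffs must not exceed 99.5th cutoffs")
  }
  if (iop_995 <= 0) stop("iop_995 must be positive")
  structure(list(vcdr_975 = vcdr_975[c("image", "clinical")],
                 vcdr_995 = vcdr_995[c("image", "clinical")],
                 asym_975 = asym_975[c("image", "clinical")],
                 asym_995 = asym_995[c("image", "clinical")],
                 iop_995 = iop_995, source = source, n_eyes = n_eyes),
            class = "diagnostic_thresholds")
}

#' @export
print.diagnostic_thresholds <- function(x, ...) {
  cat("Diagnostic thresholds (", x$source, ")\n", sep = "")
  cat(sprintf("  VCDR      97.5th: image %.2f / clinical %.2f\n",
              x$vcdr_975[["image"]], x$vcdr_975[["clinical"]]))
  cat(sprintf("  VCDR      99.5th: image %.2f / clinical %.2f\n",
              x$vcdr_995[["image"]], x$vcdr_995[["clinical"]]))
  cat(sprintf("  asymmetry 97.5th: image %.2f / clinical %.2f\n",
              x$asym_975[["image"]], x$asym_975[["clinical"]]))
  cat(sprintf("  asymmetry 99.5th: image %.2f / clinical %.2f\n",
              x$asym_995[["image"]], x$asym_995[["clinical"]]))
  cat(sprintf("  IOP       99.5th: %g mmHg\n", x$iop_995))
  invisible(x)
}

#' Published percentile cutoffs
#'
#' The cutoff set published by the Nigeria national survey, derived from its
#' normative subsample (n = 1759): image-scale VCDR 0.70/0.75 and asymmetry
#' 0.10/0.20 at the 97.5th/99.5th percentiles, clinical-scale VCDR 0.60/0.70
#' and asymmetry 0.20/0.30, and IOP 28 mmHg at the 99.5th percentile.
#'
#' @return a [diagnostic_thresholds()] object with `source = "published"`.
#' @export
published_thresholds <- function() {
  diagnostic_thresholds(
    vcdr_975 = c(image = 0.70, clinical = 0.60),
    vcdr_995 = c(image = 0.75, clinical = 0.70),
    asym_975 = c(image = 0.10, clinical = 0.20),
    asym_995 = c(image = 0.20, clinical = 0.30),
    iop_995 = 28, source = "published")
}

#' Derive percentile cutoffs from a normative subsample
#'
#' Computes the nearest-rank 97.5th/99.5th percentiles of VCDR and VCDR
#' asymmetry (separately on the image and clinical scales) and the 99.5th
#' percentile of IOP from the eyes of participants flagged as the 1-in-7
#' systematic normative subsample.
#'
#' Glaucomatous eyes are removed before taking percentiles, in a single
#' pass using the published cutoffs as the provisional rule. The removal
#' must not circularly truncate the very tails whose percentiles are being
#' estimated, so it is deliberately asymmetric:
#' * eyes with functionally corroborated disease (Category 1) and eyes with
#'   an absolute VCDR at the provisional 99.5th cutoff without usable
#'   fields (Category 2, VCDR basis) are excluded everywhere — these would
#'   otherwise pull the VCDR and IOP percentiles far into the glaucomatous
#'   range;
#' * asymmetry percentiles are instead computed from structurally normal
#'   fellow-eye pairs (both eyes below the provisional 97.5th VCDR cutoff
#'   of their scale and neither eye Category 1): an eye flagged only by the
#'   asymmetry criterion carries no independent evidence of disease, and
#'   excluding such pairs would empty the asymmetry tail by construction.
#'
#' @param cohort a [survey_cohort()].
#' @param normative_col logical column of `cohort$participants` flagging the
#'   normative subsample.
#' @param exclude_glaucoma drop eyes as described above before taking
#'   percentiles?
#' @return a [diagnostic_thresholds()] object with `source = "derived"` and
#'   contributing-eye counts in `n_eyes`.
#' @export
derive_thresholds <- function(cohort, normative_col = "normative",
                              exclude_glaucoma = TRUE) {
  stopifnot(inherits(cohort, "survey_cohort"))
  pp <- cohort$participants
  if (!normative_col %in% names(pp)) {
    stop("participants table has no '", normative_col, "' column")
  }
  ids <- pp$person_id[isTRUE_vec(pp[[normative_col]])]
  if (!length(ids)) stop("normative subsample is empty")
  eyes <- cohort$eyes[cohort$eyes$person_id %in% ids, , drop = FALSE]
  pub <- published_thresholds()
  cat1_key <- character(0)
  if (exclude_glaucoma) {
    dx <- classify_cohort(cohort, thresholds = pub)
    key <- paste(dx$eyes$person_id, dx$eyes$side)
    cat1_key <- key[dx$eyes$category == "1"]
    drop <- key[dx$eyes$category == "1" |
                  (dx$eyes$category == "2" &
                     dx$eyes$evidence_basis == "vcdr")]
    eyes <- eyes[!paste(eyes$person_id, eyes$side) %in% drop, , drop = FALSE]
  }
  full_eyes <- cohort$eyes[cohort$eyes$person_id %in% ids, , drop = FALSE]
  full_eyes <- full_eyes[!paste(full_eyes$person_id, full_eyes$side) %in%
                           cat1_key, , drop = FALSE]
  wide <- merge(full_eyes[full_eyes$side == "R",
                          c("person_id", "photo_vcdr", "clinical_vcdr")],
                full_eyes[full_eyes$side == "L",
                          c("person_id", "photo_vcdr", "clinical_vcdr")],
                by = "person_id", suffixes = c("_r", "_l"))
  img_ok <- !is.na(wide$photo_vcdr_r) & !is.na(wide$photo_vcdr_l) &
    wide$photo_vcdr_r < pub$vcdr_975[["image"]] &
    wide$photo_vcdr_l < pub$vcdr_975[["image"]]
  cli_ok <- !is.na(wide$clinical_vcdr_r) & !is.na(wide$clinical_vcdr_l) &
    wide$clinical_vcdr_r < pub$vcdr_975[["clinical"]] &
    wide$clinical_vcdr_l < pub$vcdr_975[["clinical"]]
  vals <- list(
    image = eyes$photo_vcdr,
    clinical = eyes$clinical_vcdr,
    asym_image = abs(wide$photo_vcdr_r - wide$photo_vcdr_l)[img_ok],
    asym_clinical = abs(wide$clinical_vcdr_r -
                          wide$clinical_vcdr_l)[cli_ok],
    iop = eyes$iop_mmhg)
  n_eyes <- vapply(vals, function(v) sum(!is.na(v)), integer(1))
  empty <- names(vals)[n_eyes == 0]
  if (length(empty)) {
    stop("normative subsample has no observations for: ",
         paste(empty, collapse = ", "))
  }
  pct <- function(v, p) percentile_nearest_rank(v, p)
  diagnostic_thresholds(
    vcdr_975 = c(image = pct(vals$image, 97.5),
                 clinical = pct(vals$clinical, 97.5)),
    vcdr_995 = c(image = pct(vals$image, 99.5),
                 clinical = pct(vals$clinical, 99.5)),
    asym_975 = c(image = pct(vals$asym_image, 97.5),
                 clinical = pct(vals$asym_clinical, 97.5)),
    asym_995 = c(image = pct(vals$asym_image, 99.5),
                 clinical = pct(vals$asym_clinical, 99.5)),
    iop_995 = pct(vals$iop, 99.5),
    source = "derived", n_eyes = n_eyes)
}

#' Write / read a threshold set as YAML
#'
#' @param thresholds a [diagnostic_thresholds()] object.
#' @param path file path.
#' @return `read_thresholds()` returns a [diagnostic_thresholds()] object.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "diagnostic_thresholds"))
  x <- unclass(thresholds)
  x[c("vcdr_975", "vcdr_995", "asym_975", "asym_995")] <-
    lapply(x[c("vcdr_975", "vcdr_995", "asym_975", "asym_995")], as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- yaml::read_yaml(path)
  diagnostic_thresholds(
    vcdr_975 = unlist(x$vcdr_975), vcdr_995 = unlist(x$vcdr_995),
    asym_975 = unlist(x$asym_975), asym_995 = unlist(x$asym_995),
    iop_995 = x$iop_995, source = x$source,
    n_eyes = if (!is.null(x$n_eyes)) unlist(x$n_eyes))
}

isTRUE_vec <- function(x) !is.na(x) & x
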