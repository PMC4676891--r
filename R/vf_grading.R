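#' @name vf_grading
#' @title FDT visual field grading
#'
#' @description
#' Interpretation of FDT C-20 suprathreshold screening (C20-1/C20-5) and
#' threshold tests for epidemiological glaucoma classification. Defects are
#' recorded per zone at four probability levels; a zone's level is the worst
#' probability at which it is flagged, with the levels totally ordered
#' none < p<5\% < p<2\% < p<1\% < p<0.5\%. Internally levels are integers
#' 0..4; the file interface uses the printout codes `0`, `5`, `2`, `1`,
#' `05`.
#'
#' Grading uses the pattern deviation probability (PDP) plot compared with
#' the total deviation probability (TDP) plot, so that the two screening
#' modes are equalized; diffuse loss (heavily shaded TDP with a clean PDP,
#' typical of cataract), fields where the TDP is strictly better than the
#' PDP, and defect patterns aligned on the vertical meridian are graded
#' `unlikely` rather than glaucomatous.
NULL

#' Probability-level codes used in defect-map files
#'
#' @return named integer vector mapping file codes to internal levels.
#' @export
vf_level_codes <- function() {
  c(`0` = 0L, `5` = 1L, `2` = 2L, `1` = 3L, `05` = 4L)
}

.vf_grades <- c("normal", "definite", "probable", "possible", "unlikely",
                "not_usable")

#' Severity rank of a visual field grade
#'
#' `definite` > `probable` > `possible` > everything else (0).
#' @param grade character vector of grades.
#' @return integer severity ranks.
#' @export
vf_grade_rank <- function(grade) {
  r <- c(definite = 3L, probable = 2L, possible = 1L)
  out <- unname(r[grade])
  out[is.na(out)] <- 0L
  out
}

check_counts <- function(...) {
  for (x in list(...)) {
    if (any(is.na(x)) || any(x < 0)) stop("reliability counts must be >= 0")
  }
  invisible(TRUE)
}

#' Reliability of an FDT screening test
#'
#' A screening test is reliable with at most one fixation error and at most
#' one false positive; failing either index makes the test unreliable
#' (tests were restarted in the field at two or more fixation errors or two
#' to three false positives).
#'
#' @param fixation_errors,false_positives non-negative counts.
#' @return logical vector.
#' @export
screening_reliable <- function(fixation_errors, false_positives) {
  check_counts(fixation_errors, false_positives)
  fixation_errors <= 1 & false_positives <= 1
}

#' Reliability of an FDT threshold test
#'
#' At most two fixation errors and at most two false positives.
#' @inheritParams screening_reliable
#' @return logical vector.
#' @export
threshold_reliable <- function(fixation_errors, false_positives) {
  check_counts(fixation_errors, false_positives)
  fixation_errors <= 2 & false_positives <= 2
}

map_levels <- function(map, zones) {
  map <- as.integer(map)
  if (length(map) != nrow(zones)) {
    stop("defect map length ", length(map), " does not match the ",
         nrow(zones), "-zone geometry")
  }
  if (any(is.na(map)) || any(map < 0L | map > 4L)) {
    stop("defect-map levels must be integers in 0..4")
  }
  map
}

#' Does a screening result trigger a threshold test?
#'
#' Threshold testing follows a reliable screening test with three or more
#' defects at p<1\% or two or more at p<0.5\% (levels counted cumulatively:
#' a p<0.5\% defect also counts at p<1\%).
#'
#' @param screening_map integer vector of zone levels (0..4) from the
#'   screening PDP plot.
#' @param zones zone geometry, see [zone_grid()].
#' @return logical scalar.
#' @export
needs_threshold_test <- function(screening_map, zones = fdt_c20_zones()) {
  m <- map_levels(screening_map, zones)
  sum(m >= 3L) >= 3L || sum(m >= 4L) >= 2L
}

#' Is a reliable screening test normal?
#'
#' Normal means no defects, or at most two defects at p<1\% and at most one
#' at p<0.5\% — exactly the complement of [needs_threshold_test()], so a map
#' that triggers a threshold test is never normal.
#'
#' @inheritParams needs_threshold_test
#' @param map integer vector of zone levels.
#' @return logical scalar.
#' @export
screening_normal <- function(map, zones = fdt_c20_zones()) {
  m <- map_levels(map, zones)
  sum(m >= 3L) <= 2L && sum(m >= 4L) <= 1L
}

#' Is a reliable threshold test normal?
#'
#' Two rule variants are exposed because the field protocol stated threshold
#' normality in two non-equivalent ways: `"strict"` (the default) requires
#' no defects at p<1\% or p<0.5\%; `"lenient"` additionally accepts a single
#' defect at p<2\% or up to two non-adjacent defects at p<0.5\%.
#'
#' @inheritParams screening_normal
#' @param rule `"strict"` or `"lenient"`.
#' @return logical scalar.
#' @export
threshold_normal <- function(map, rule = c("strict", "lenient"),
                             zones = fdt_c20_zones()) {
  rule <- match.arg(rule)
  m <- map_levels(map, zones)
  strict <- sum(m >= 3L) == 0L
  if (rule == "strict") return(strict)
  deep <- which(m >= 4L)
  non_adj_deep <- length(deep) <= 2L && !any_adjacent(m >= 4L, zones)
  strict || sum(m >= 2L) <= 1L || (sum(m >= 4L) <= 2L && non_adj_deep)
}

any_adjacent <- function(flags, zones) {
  pairs <- zone_adjacent_pairs(zones)
  if (!nrow(pairs)) return(FALSE)
  any(flags[pairs$i] & flags[pairs$j])
}

# defect pattern hugging the vertical meridian: at least two defective
# zones, all in the same meridian-adjacent column, present in both
# hemifields (a hemianopia-like respect of the vertical midline, which
# glaucoma does not produce)
vertical_meridian_pattern <- function(pdp, zones) {
  n_cols <- max(zones$col, na.rm = TRUE)
  mer <- c(n_cols / 2, n_cols / 2 + 1)
  out <- rep(FALSE, nrow(pdp))
  n_def <- rowSums(pdp >= 1L)
  sup <- zones$hemifield == "superior"
  inf <- zones$hemifield == "inferior"
  for (cc in mer) {
    off_col <- is.na(zones$col) | zones$col != cc
    in_col_only <- rowSums(pdp[, off_col, drop = FALSE] >= 1L) == 0L
    both_hemi <- rowSums(pdp[, sup, drop = FALSE] >= 1L) > 0L &
      rowSums(pdp[, inf, drop = FALSE] >= 1L) > 0L
    out <- out | (n_def >= 2L & in_col_only & both_hemi)
  }
  out
}

#' Grade a batch of defect maps
#'
#' Vectorized core of [grade_defect_map()]: `pdp` and `tdp` are integer
#' matrices with one row per test and one column per zone.
#'
#' @param pdp,tdp level matrices (0..4).
#' @param zones zone geometry.
#' @param diffuse_min_fraction fraction of zones that must be shaded on the
#'   TDP plot, with a PDP matching no glaucomatous pattern, for the test to
#'   be graded `unlikely` as diffuse loss.
#' @return character vector of grades.
#' @export
grade_defect_maps <- function(pdp, tdp, zones = fdt_c20_zones(),
                              diffuse_min_fraction = 0.5) {
  pdp <- as.matrix(pdp); tdp <- as.matrix(tdp)
  if (!all(dim(pdp) == dim(tdp))) stop("PDP and TDP maps differ in shape")
  if (ncol(pdp) != nrow(zones)) {
    stop("maps have ", ncol(pdp), " zones but the geometry has ", nrow(zones))
  }
  if (any(is.na(pdp)) || any(is.na(tdp)) ||
      any(pdp < 0L | pdp > 4L) || any(tdp < 0L | tdp > 4L)) {
    stop("defect-map levels must be integers in 0..4")
  }
  n <- nrow(pdp)
  n1 <- rowSums(pdp >= 1L); n2 <- rowSums(pdp >= 2L)
  n3 <- rowSums(pdp >= 3L); n4 <- rowSums(pdp >= 4L)
  # most severe satisfied row, counts read as minimum thresholds
  definite <- n1 >= 4L | n2 >= 3L | n3 >= 2L | n4 >= 1L
  probable <- possible <- rep(FALSE, n)
  for (h in c("superior", "inferior")) {
    in_h <- zones$hemifield == h
    sub <- pdp[, in_h, drop = FALSE]
    nh1 <- rowSums(sub >= 1L); nh2 <- rowSums(sub >= 2L)
    ne <- in_h & !zones$edge
    nh3_ne <- rowSums(pdp[, ne, drop = FALSE] >= 3L)
    nh4_ne <- rowSums(pdp[, ne, drop = FALSE] >= 4L)
    probable <- probable | nh1 >= 3L | nh2 >= 2L | nh3_ne >= 1L | nh4_ne >= 1L
    adj <- zone_adjacent_pairs(zones, h)
    adj_hit <- rep(FALSE, n)
    if (nrow(adj)) {
      for (k in seq_len(nrow(adj))) {
        adj_hit <- adj_hit | (pdp[, adj$i[k]] >= 1L & pdp[, adj$j[k]] >= 1L)
      }
    }
    possible <- possible | adj_hit | nh2 >= 1L
  }
  row_grade <- rep("none", n)
  row_grade[possible] <- "possible"
  row_grade[probable] <- "probable"
  row_grade[definite] <- "definite"

  tdp_better <- rowSums(tdp) < rowSums(pdp)
  diffuse <- row_grade == "none" &
    rowSums(tdp >= 1L) >= ceiling(diffuse_min_fraction * nrow(zones))
  vertical <- vertical_meridian_pattern(pdp, zones)

  grade <- rep("normal", n)
  has_def <- n1 > 0L
  grade[!has_def & diffuse] <- "unlikely"
  grade[has_def & (tdp_better | vertical)] <- "unlikely"
  keep <- has_def & !(tdp_better | vertical)
  grade[keep & row_grade != "none"] <- row_grade[keep & row_grade != "none"]
  grade[keep & row_grade == "none" & diffuse] <- "unlikely"
  grade
}

#' Grade one PDP/TDP defect-map pair
#'
#' Applies the defect-grading table for level 1 evidence on the PDP plot,
#' taking the most severe satisfied row:
#' * `definite`: >=4 defects at p<5\%, >=3 at p<2\%, >=2 at p<1\% or >=1 at
#'   p<0.5\%, at any location in any hemifield;
#' * `probable`: within one hemifield, >=3 at p<5\%, >=2 at p<2\%, or one
#'   non-edge defect at p<1\% (or p<0.5\%, subsumed by `definite`);
#' * `possible`: within one hemifield, two adjacent defects at p<5\% or one
#'   at p<2\%;
#' * `unlikely`: the TDP plot is strictly better (lower total severity) than
#'   the PDP plot, the defect pattern hugs the vertical meridian, or the TDP
#'   is heavily shaded while the PDP matches no row (diffuse loss);
#' * otherwise `normal`.
#'
#' Counts are cumulative over levels (a p<0.5\% defect counts at every
#' shallower level).
#'
#' @param pdp,tdp integer vectors of zone levels (0..4).
#' @inheritParams grade_defect_maps
#' @return one of `"normal"`, `"definite"`, `"probable"`, `"possible"`,
#'   `"unlikely"`.
#' @examples
#' z <- fdt_c20_zones()
#' m <- integer(17); m[c(1, 5, 9, 13)] <- 1L
#' grade_defect_map(m, m)   # 4 defects at p<5% anywhere -> definite
#' @export
grade_defect_map <- function(pdp, tdp = pdp, zones = fdt_c20_zones(),
                             diffuse_min_fraction = 0.5) {
  pdp <- map_levels(pdp, zones); tdp <- map_levels(tdp, zones)
  grade_defect_maps(matrix(pdp, nrow = 1), matrix(tdp, nrow = 1),
                    zones = zones,
                    diffuse_min_fraction = diffuse_min_fraction)
}

#' Construct a visual field test record
#'
#' @param mode `"screening"` or `"threshold"`.
#' @param fixation_errors,false_positives reliability indices.
#' @param pdp,tdp zone level vectors (0..4), or NULL when untestable.
#' @param lid_artefact uniformly dense artefact along the upper or lower
#'   edge of the chart (makes the test unusable).
#' @param untestable_reason code such as `"cataract"` or
#'   `"did_not_understand"`, or NA.
#' @return list of class `vf_test_record`.
#' @export
vf_record <- function(mode = c("screening", "threshold"),
                      fixation_errors = 0, false_positives = 0,
                      pdp = NULL, tdp = NULL, lid_artefact = FALSE,
                      untestable_reason = NA_character_) {
  mode <- match.arg(mode)
  check_counts(fixation_errors, false_positives)
  if (!is.na(untestable_reason) && (!is.null(pdp) || !is.null(tdp))) {
    stop("an untestable record cannot carry defect maps")
  }
  structure(list(mode = mode, fixation_errors = fixation_errors,
                 false_positives = false_positives, pdp = pdp,
                 tdp = if (is.null(tdp)) pdp else tdp,
                 lid_artefact = isTRUE(lid_artefact),
                 untestable_reason = untestable_reason),
            class = "vf_test_record")
}

vf_usable <- function(rec) {
  if (is.null(rec)) return(FALSE)
  if (!is.na(rec$untestable_reason)) return(FALSE)
  if (rec$lid_artefact) return(FALSE)
  if (is.null(rec$pdp)) return(FALSE)
  ok <- if (rec$mode == "threshold") {
    threshold_reliable(rec$fixation_errors, rec$false_positives)
  } else {
    screening_reliable(rec$fixation_errors, rec$false_positives)
  }
  isTRUE(ok)
}

#' Final visual field grade for one eye
#'
#' Threshold results take precedence over screening results when both are
#' usable; a test is unusable when unreliable, untestable or spoiled by a
#' lid artefact. When both tests are usable the result notes repeatability
#' (a defect at the same location on both PDP plots) as attribute
#' `repeatable`.
#'
#' @param screening,threshold [vf_record()] objects or NULL.
#' @param zones zone geometry.
#' @return grade string (see [grade_defect_map()]), `"not_usable"` when no
#'   usable test exists.
#' @export
interpret_vf <- function(screening = NULL, threshold = NULL,
                         zones = fdt_c20_zones()) {
  use_thr <- vf_usable(threshold)
  use_scr <- vf_usable(screening)
  if (!use_thr && !use_scr) return("not_usable")
  rec <- if (use_thr) threshold else screening
  g <- grade_defect_map(rec$pdp, rec$tdp, zones = zones)
  if (use_thr && use_scr) {
    rep_ok <- any(map_levels(threshold$pdp, zones) >= 1L &
                    map_levels(screening$pdp, zones) >= 1L)
    attr(g, "repeatable") <- rep_ok
  }
  g
}
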