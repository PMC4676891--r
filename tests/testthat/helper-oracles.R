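# Independent brute-force oracles; deliberately written as literal,
# loop-based enumerations of the documented rules, separate from the
# vectorized implementation paths they check.

# reduced 8-zone geometry (one row per hemifield, outer columns are edge)
reduced_zones <- function() {
  zone_grid(2, 4, central = FALSE, edge_rule = "lateral")
}

# literal enumeration of the defect-grading table for one PDP/TDP pair
oracle_grade <- function(pdp, tdp, zones) {
  stopifnot(length(pdp) == nrow(zones))
  adjacent <- function(a, b) {
    if (zones$hemifield[a] != zones$hemifield[b]) return(FALSE)
    if (is.na(zones$row[a]) || is.na(zones$row[b])) return(FALSE)
    dr <- abs(zones$row[a] - zones$row[b])
    dc <- abs(zones$col[a] - zones$col[b])
    (dr == 1 && dc == 0) || (dr == 0 && dc == 1)
  }
  definite <- sum(pdp >= 1) >= 4 || sum(pdp >= 2) >= 3 ||
    sum(pdp >= 3) >= 2 || sum(pdp >= 4) >= 1
  probable <- FALSE
  possible <- FALSE
  for (h in c("superior", "inferior")) {
    hz <- which(zones$hemifield == h)
    lv <- pdp[hz]
    if (sum(lv >= 1) >= 3 || sum(lv >= 2) >= 2) probable <- TRUE
    nez <- which(zones$hemifield == h & !zones$edge)
    if (sum(pdp[nez] >= 3) >= 1 || sum(pdp[nez] >= 4) >= 1) probable <- TRUE
    if (sum(lv >= 2) >= 1) possible <- TRUE
    for (a in hz) {
      for (b in hz) {
        if (a < b && adjacent(a, b) && pdp[a] >= 1 && pdp[b] >= 1) {
          possible <- TRUE
        }
      }
    }
  }
  row_grade <- if (definite) "definite" else if (probable) "probable" else
    if (possible) "possible" else "none"
  # TDP relation and non-glaucomatous patterns
  n_cols <- max(zones$col, na.rm = TRUE)
  vertical <- FALSE
  for (cc in c(n_cols / 2, n_cols / 2 + 1)) {
    defs <- which(pdp >= 1)
    if (length(defs) >= 2 &&
        all(!is.na(zones$col[defs]) & zones$col[defs] == cc) &&
        any(zones$hemifield[defs] == "superior") &&
        any(zones$hemifield[defs] == "inferior")) {
      vertical <- TRUE
    }
  }
  tdp_better <- sum(tdp) < sum(pdp)
  diffuse <- row_grade == "none" &&
    sum(tdp >= 1) >= ceiling(0.5 * nrow(zones))
  if (sum(pdp >= 1) == 0) {
    return(if (diffuse) "unlikely" else "normal")
  }
  if (tdp_better || vertical) return("unlikely")
  if (row_grade != "none") return(row_grade)
  if (diffuse) "unlikely" else "normal"
}

# literal truth-table implementation of the four-category case definition
oracle_classify_eye <- function(vcdr, vcdr_source, asym, asym_scale, iop,
                                rapd, oedema, disc_seen, va_logmar,
                                vf_grade, surgery, known, th) {
  at_least <- function(x, cut) {
    !is.na(x) && !is.na(cut) && x >= cut - 1e-9
  }
  v975 <- if (vcdr_source == "none") NA else th$vcdr_975[[vcdr_source]]
  v995 <- if (vcdr_source == "none") NA else th$vcdr_995[[vcdr_source]]
  a975 <- if (asym_scale == "none") NA else th$asym_975[[asym_scale]]
  a995 <- if (asym_scale == "none") NA else th$asym_995[[asym_scale]]
  typical <- vf_grade %in% c("definite", "probable", "possible")
  unusable <- vf_grade == "not_usable"
  iop_hi <- !is.na(iop) && iop >= th$iop_995 - 1e-9
  blind <- !is.na(va_logmar) && va_logmar > log10(20) + 1e-7
  if ((at_least(vcdr, v975) || at_least(asym, a975)) && typical) {
    return("1")
  }
  if ((at_least(vcdr, v995) || at_least(asym, a995)) && unusable) {
    return("2")
  }
  if (disc_seen && !is.na(vcdr) && !is.na(v975) && vcdr < v975 - 1e-9 &&
      iop_hi && (rapd || oedema) && vf_grade != "normal") {
    return("2b")
  }
  if (!disc_seen && is.na(vcdr) && unusable &&
      ((blind && iop_hi) || surgery || known)) {
    return("3")
  }
  "none"
}

# sort-and-index nearest-rank percentile
oracle_percentile <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p / 100 * length(s)))]
}
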