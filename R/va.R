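#' Convert a visual acuity code to logMAR
#'
#' Accepts Snellen fractions written as `"numerator/denominator"` (metre or
#' foot notation, e.g. `"6/12"`, `"3/60"`, `"20/400"`) and plain numeric
#' logMAR values (numeric or numeric string). Snellen fractions are converted
#' as `log10(denominator/numerator)`, which reproduces the conventional
#' chart values (6/12 = 0.30, 6/18 = 0.48, 6/60 = 1.00, 3/60 = 1.30) and
#' makes 20/400 equivalent to 3/60.
#'
#' @param va character or numeric vector of acuity codes.
#' @return numeric vector of logMAR values; unparseable entries raise an
#'   error naming the offending values.
#' @examples
#' va_to_logmar(c("6/6", "6/12", "2/60", "0.3"))
#' @export
va_to_logmar <- function(va) {
  if (is.numeric(va)) return(as.numeric(va))
  va <- trimws(as.character(va))
  out <- rep(NA_real_, length(va))
  out[is.na(va) | va == ""] <- NA_real_
  frac <- grepl("^[0-9]+(\\.[0-9]+)?/[0-9]+(\\.[0-9]+)?$", va)
  if (any(frac, na.rm = TRUE)) {
    parts <- strsplit(va[which(frac)], "/", fixed = TRUE)
    num <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    den <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    if (any(num <= 0)) stop("Snellen numerator must be positive")
    out[which(frac)] <- log10(den / num)
  }
  plain <- !frac & !is.na(va) & va != ""
  if (any(plain)) {
    parsed <- suppressWarnings(as.numeric(va[plain]))
    bad <- is.na(parsed)
    if (any(bad)) {
      stop("unparseable visual acuity code(s): ",
           paste(unique(va[plain][bad]), collapse = ", "))
    }
    out[plain] <- parsed
  }
  out
}

# category boundaries on the logMAR scale; "worse than X" is strictly
# greater, so equality at a boundary stays in the better category
.va_eps <- 1e-7
.va_bounds <- c(mild = log10(2), moderate = log10(3),
                severe = 1, blind = log10(20))

#' Categorize presenting visual acuity in the better eye
#'
#' WHO visual impairment categories with an added mild category
#' (worse than 6/12 up to 6/18). Blindness is presenting acuity worse than
#' 3/60 in the better eye. Boundaries are half-open on the worse side:
#' an acuity exactly at 6/12 is `normal`, exactly at 3/60 is `severe_vi`.
#'
#' @param va acuity in the better-seeing eye (logMAR or Snellen code,
#'   see [va_to_logmar()]).
#' @return factor with levels `normal`, `mild_vi`, `moderate_vi`,
#'   `severe_vi`, `blind`.
#' @examples
#' va_category(c("6/6", "6/15", "6/24", "2/60"))
#' @export
va_category <- function(va) {
  lm <- va_to_logmar(va)
  lev <- c("normal", "mild_vi", "moderate_vi", "severe_vi", "blind")
  idx <- findInterval(lm, .va_bounds + .va_eps) + 1L
  factor(lev[idx], levels = lev)
}

#' Is acuity worse than 3/60 (blind)?
#' @param logmar numeric logMAR values.
#' @return logical vector.
#' @keywords internal
is_blind_va <- function(logmar) {
  !is.na(logmar) & logmar > .va_bounds[["blind"]] + .va_eps
}
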