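#' ECSC-1993 prediction equations
#'
#' The 1993 European Coal and Steel Community adult reference equations:
#' linear in standing height (metres in the original publication) and age,
#' one equation per sex and outcome. Following the source's convention for
#' young adults, ages between 18 and 25 are clamped to 25 before
#' evaluation, so predictions are constant over 18–25.
#'
#' The ratio equations carry a zero height slope: FEV1/FVC is predicted
#' from age alone.
#'
#' @return `ecsc_coefficients()` returns the packaged coefficient table
#'   (height slopes per metre, age slopes per year, intercepts, provenance
#'   label).
#' @examples
#' ecsc_coefficients()
#' ecsc_predict("male", age = 46.92, height = 175.8)
#' @export
ecsc_coefficients <- function() {
  if (is.null(.spiroref_cache$ecsc)) {
    .spiroref_cache$ecsc <- read.delim(
      spiroref_extdata("ecsc_coefficients.tsv"), stringsAsFactors = FALSE)
  }
  .spiroref_cache$ecsc
}

#' @rdname ecsc_coefficients
#' @param sex `"male"` or `"female"` (vectorized, recycled).
#' @param age age in years, at least 18; ages below 25 are clamped to 25.
#' @param height standing height in centimetres (converted to metres at the
#'   call site, since the package stores height in cm everywhere).
#' @return `ecsc_predict()` returns a data frame with `fev1_pred`,
#'   `fvc_pred` (litres) and `ratio_pred` (percent).
#' @export
ecsc_predict <- function(sex, age, height) {
  sex <- check_sex(sex)
  check_range(age, 18, 95, "age", "years")
  check_range(height, 120, 220, "height", "cm")
  n <- max(length(sex), length(age), length(height))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  height <- rep_len(height, n)
  age_eff <- pmax(age, 25)
  h_m <- height / 100
  tab <- ecsc_coefficients()
  one <- function(outcome) {
    out <- numeric(n)
    for (s in c("male", "female")) {
      row <- tab[tab$sex == s & tab$outcome == outcome, ]
      if (nrow(row) != 1L) {
        stop("ECSC coefficient table lacks (", s, ", ", outcome, ")",
             call. = FALSE)
      }
      pick <- sex == s
      out[pick] <- row$height_slope_per_m * h_m[pick] +
        row$age_slope_per_yr * age_eff[pick] + row$intercept
    }
    out
  }
  data.frame(fev1_pred = one("fev1"), fvc_pred = one("fvc"),
             ratio_pred = one("ratio"))
}
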