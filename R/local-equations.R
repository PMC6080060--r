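#' Locally derived (Greek study) prediction equations
#'
#' Sex-specific reference equations for FEV1 (litres), ln(FVC) (FVC in
#' litres, modelled on the natural-log scale) and the FEV1/FVC ratio
#' (percent), derived from 500 healthy never-smoking Greek adults aged
#' 18–89. Age enters the volume models as a piecewise-linear term with a
#' knot at 25 years — lung function rises (or is flat) up to about age 25
#' and declines linearly thereafter — each branch printed with its own
#' intercept. The ratio models use age only (linearly for men, with a
#' quadratic term for women); height, weight and BMI were not significant
#' ratio predictors.
#'
#' Two coefficient-table variants ship with the package:
#' \describe{
#'   \item{`"corrected"` (default)}{identical to the published table except
#'     that the young-branch height-squared coefficient of the male ln(FVC)
#'     model is taken as −0.00041 rather than the published +0.00041. The
#'     positive sign puts ln(FVC) near 26 (an FVC of e^26 litres), which is
#'     physically impossible and inconsistent with the negative quadratic in
#'     the old branch and in the female model, so it is read as a sign typo.}
#'   \item{`"as_printed"`}{the published coefficients verbatim, kept for
#'     audit.}
#' }
#' The male ln(FVC) model is discontinuous at the knot as published (young
#' branch reaches −13.028 at age 25 against an old-branch intercept of
#' −13.094, a 0.066 ln-scale gap); both intercepts are retained without
#' smoothing in both variants.
#'
#' @param variant `"corrected"` (default) or `"as_printed"`; see Details.
#' @return `local_coefficients()` returns the coefficient table as a data
#'   frame with columns `sex`, `outcome`, `branch`, `term`, `coefficient`.
#' @examples
#' head(local_coefficients())
#' predict_fev1_local("male", age = 40, height = 175)
#' @export
local_coefficients <- function(variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  tab <- local_equation_cache()
  tab[tab$variant == variant,
      c("sex", "outcome", "branch", "term", "coefficient")]
}

.spiroref_cache <- new.env(parent = emptyenv())

local_equation_cache <- function() {
  if (is.null(.spiroref_cache$local)) {
    .spiroref_cache$local <- read.delim(
      spiroref_extdata("local_equations.tsv"),
      stringsAsFactors = FALSE)
  }
  .spiroref_cache$local
}

#' Age knot (years) of the piecewise-linear age basis
#' @keywords internal
AGE_KNOT <- 25

check_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  sex
}

check_range <- function(x, lo, hi, what, unit) {
  if (any(!is.finite(x) | x < lo | x > hi)) {
    stop(sprintf("%s must be finite and in [%g, %g] %s", what, lo, hi, unit),
         call. = FALSE)
  }
  x
}

# Evaluate one local equation, vectorized over subjects. Age < 25 uses the
# young branch (slope on A); age >= 25 uses the old branch (slope on A-25).
eval_local <- function(sex, outcome, age, height = 0, weight = 0,
                       variant = "corrected") {
  n <- max(length(sex), length(age), length(height), length(weight))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  height <- rep_len(height, n); weight <- rep_len(weight, n)
  tab <- local_equation_cache()
  tab <- tab[tab$variant == variant & tab$outcome == outcome, ]
  branch <- if (outcome == "ratio") rep("all", n) else
    ifelse(age < AGE_KNOT, "young", "old")
  out <- numeric(n)
  for (s in unique(sex)) {
    for (b in unique(branch[sex == s])) {
      pick <- sex == s & branch == b
      cf <- setNames(tab$coefficient[tab$sex == s & tab$branch == b],
                     tab$term[tab$sex == s & tab$branch == b])
      term <- function(name) if (is.na(cf[name])) 0 else cf[[name]]
      out[pick] <- term("intercept") +
        term("age") * age[pick] +
        term("age_minus_knot") * (age[pick] - AGE_KNOT) +
        term("age2") * age[pick]^2 +
        term("height") * height[pick] +
        term("height2") * height[pick]^2 +
        term("weight") * weight[pick]
    }
  }
  out
}

#' Predict spirometric indices from the study equations
#'
#' @param sex `"male"` or `"female"` (vectorized, recycled).
#' @param age age in years, 18–95.
#' @param height standing height in centimetres, 120–220.
#' @param weight body weight in kilograms (ln(FVC) models only).
#' @param variant coefficient-table variant, see [local_coefficients()].
#' @return Predicted FEV1 or FVC in litres, or FEV1/FVC in percent.
#' @examples
#' predict_fev1_local("male", 40, 175)        # 3.929 L
#' predict_fvc_local("female", 40, 163, 70)   # about 3.28 L
#' predict_ratio_local("male", 46.92)         # 82.75 %
#' @export
predict_fev1_local <- function(sex, age, height,
                               variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  sex <- check_sex(sex)
  check_range(age, 18, 95, "age", "years")
  check_range(height, 120, 220, "height", "cm")
  eval_local(sex, "fev1", age, height, variant = variant)
}

#' @rdname predict_fev1_local
#' @export
predict_fvc_local <- function(sex, age, height, weight,
                              variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  if (missing(weight) || anyNA(weight)) {
    stop("weight (kg) is required by the ln(FVC) models", call. = FALSE)
  }
  sex <- check_sex(sex)
  check_range(age, 18, 95, "age", "years")
  check_range(height, 120, 220, "height", "cm")
  check_range(weight, 30, 200, "weight", "kg")
  exp(eval_local(sex, "ln_fvc", age, height, weight, variant = variant))
}

#' @rdname predict_fev1_local
#' @export
predict_ratio_local <- function(sex, age,
                                variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  sex <- check_sex(sex)
  check_range(age, 18, 95, "age", "years")
  eval_local(sex, "ratio", age, variant = variant)
}

#' Published fit statistics of the study equations
#'
#' R-squared and residual standard deviation of each study regression
#' model on its fitting scale (litres for FEV1, ln-litres for ln(FVC),
#' percentage points for the ratio). The residual SDs double as the default
#' noise levels of the synthetic healthy-cohort generator.
#'
#' @return A data frame with columns `sex`, `outcome`, `r_squared`,
#'   `residual_sd`.
#' @export
local_equation_stats <- function() {
  data.frame(
    sex = rep(c("male", "female"), 3),
    outcome = rep(c("fev1", "ln_fvc", "ratio"), each = 2),
    r_squared = c(0.73, 0.80, 0.69, 0.74, 0.03, 0.08),
    residual_sd = c(0.38, 0.28, 0.12, 0.13, 6.82, 8.45),
    stringsAsFactors = FALSE
  )
}

#' Moments of the predicted FEV1/FVC ratio over an age distribution
#'
#' Because the male ratio equation is linear in age, the cohort mean of its
#' predictions equals the equation evaluated at the cohort's mean age, and
#' their standard deviation equals the absolute age slope times the age SD —
#' no individual-level data are needed. For the female quadratic the mean
#' uses E\[A^2\] = mean^2 + SD^2 (exact for any age distribution); the SD
#' additionally assumes normally distributed age,
#' Var(c1 A + c2 A^2) = sigma^2 (c1 + 2 c2 mu)^2 + 2 c2^2 sigma^4.
#'
#' @inheritParams predict_fev1_local
#' @param age_mean,age_sd mean and standard deviation of age in years.
#' @return A list with `mean` and `sd` of the predicted ratio (percent).
#' @examples
#' ratio_prediction_moments("male", 46.92, 16.16)
#' @export
ratio_prediction_moments <- function(sex, age_mean, age_sd,
                                     variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  sex <- check_sex(sex)
  stopifnot(length(sex) == 1L, age_sd >= 0)
  tab <- local_equation_cache()
  tab <- tab[tab$variant == variant & tab$outcome == "ratio" &
               tab$sex == sex, ]
  cf <- setNames(tab$coefficient, tab$term)
  c0 <- cf[["intercept"]]
  c1 <- cf[["age"]]
  c2 <- if ("age2" %in% names(cf)) cf[["age2"]] else 0
  m <- c0 + c1 * age_mean + c2 * (age_mean^2 + age_sd^2)
  v <- age_sd^2 * (c1 + 2 * c2 * age_mean)^2 + 2 * c2^2 * age_sd^4
  list(mean = m, sd = sqrt(v))
}

#' Predictions from all three sources for a cohort
#'
#' Evaluates one prediction source for every subject of a cohort table and
#' returns a prediction set: predicted FEV1 and FVC (litres) and FEV1/FVC
#' (percent), plus — for the GLI source only — the lower limit of normal
#' and z-score of the measured FEV1.
#'
#' @param x a [cohort()] table.
#' @param source `"local"`, `"ecsc"` or `"gli"`.
#' @param variant coefficient variant for the local source.
#' @return A data frame with columns `id`, `source`, `fev1_pred`,
#'   `fvc_pred`, `ratio_pred` and (GLI only) `lln_fev1`, `zscore_fev1`.
#' @examples
#' ch <- cohort("s1", "male", 40, 175, 80, 3.7, 4.6)
#' predict_cohort(ch, "local")
#' @export
predict_cohort <- function(x, source = c("local", "ecsc", "gli"),
                           variant = c("corrected", "as_printed")) {
  source <- match.arg(source)
  variant <- match.arg(variant)
  stopifnot(inherits(x, "spiro_cohort"))
  out <- switch(source,
    local = data.frame(
      id = x$id, source = "local",
      fev1_pred = predict_fev1_local(x$sex, x$age, x$height, variant),
      fvc_pred = predict_fvc_local(x$sex, x$age, x$height, x$weight, variant),
      ratio_pred = predict_ratio_local(x$sex, x$age, variant),
      stringsAsFactors = FALSE),
    ecsc = {
      p <- ecsc_predict(x$sex, x$age, x$height)
      data.frame(id = x$id, source = "ecsc", p, stringsAsFactors = FALSE)
    },
    gli = {
      p <- gli_predict(x$sex, x$age, x$height)
      p$zscore_fev1 <- gli_zscore(x$fev1, x$sex, x$age, x$height, "fev1")
      data.frame(id = x$id, source = "gli", p, stringsAsFactors = FALSE)
    })
  stopifnot(all(out$fev1_pred > 0), all(out$fvc_pred > 0),
            all(out$ratio_pred > 0), all(out$ratio_pred <= 120))
  out
}
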