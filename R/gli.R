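#' GLI-2012-style LMS predictions with an age-indexed lookup
#'
#' Implements the Global Lung function Initiative (GLI-2012) reference-model
#' structure: for each sex and outcome the predicted median is
#' \deqn{M = \exp(a_0 + a_1 \ln H + a_2 \ln A + M_{spline}(A)),}
#' the coefficient of variation is
#' \deqn{S = \exp(p_0 + p_1 \ln A + S_{spline}(A)),}
#' and L is the Box-Cox skewness power, with the age-varying spline
#' contributions tabulated on an age grid and linearly interpolated between
#' grid rows (no extrapolation beyond the grid). The z-score of a measured
#' value y is \eqn{z = ((y/M)^L - 1)/(L S)} and the lower limit of normal
#' (5th centile) is \eqn{LLN = M (1 + L S z_{0.05})^{1/L}} with
#' \eqn{z_{0.05} = -1.645}.
#'
#' The packaged lookup table (`gli_lookup_synthetic.tsv`) is a *synthetic*
#' coefficient set: it has the genuine GLI model structure and covers ages
#' 18–95, but its median trajectories were calibrated, once, to the adult
#' Caucasian trajectories implied by the study equations scaled by the mean
#' offsets between GLI and study predictions observed in the healthy Greek
#' cohort. It exercises every code path faithfully but is not the published
#' GLI-2012 coefficient set and must not be used clinically. The FEV1/FVC
#' outcome is tabulated directly on the percent scale with a zero height
#' exponent (GLI predicts the ratio from its own model, not as a quotient
#' of predicted volumes).
#'
#' @param lookup a lookup table as returned by `gli_lookup()`; supply your
#'   own (e.g. transcribed from the published GLI coefficient tables) to
#'   replace the synthetic fixture.
#' @return `gli_lookup()` returns the packaged lookup as a data frame with
#'   columns `sex`, `outcome`, `age`, `a0`, `a1`, `a2`, `Mspline`,
#'   `Sspline`, `L`, `p0`, `p1`, `version`.
#' @examples
#' gli_predict("male", age = 40, height = 175)
#' gli_zscore(3.2, "male", age = 40, height = 175, outcome = "fev1")
#' @export
gli_lookup <- function() {
  if (is.null(.spiroref_cache$gli)) {
    tab <- read.delim(spiroref_extdata("gli_lookup_synthetic.tsv"),
                      stringsAsFactors = FALSE)
    num <- c("age", "a0", "a1", "a2", "Mspline", "Sspline", "L", "p0", "p1")
    if (!all(vapply(tab[num], function(x) all(is.finite(x)), logical(1)))) {
      stop("GLI lookup contains non-finite values", call. = FALSE)
    }
    .spiroref_cache$gli <- tab
  }
  .spiroref_cache$gli
}

#' @rdname gli_lookup
#' @export
gli_lookup_version <- function(lookup = gli_lookup()) {
  unique(lookup$version)
}

# Interpolated M, S, L at requested ages for one (sex, outcome).
gli_msl <- function(sex, age, height, outcome, lookup) {
  n <- max(length(sex), length(age), length(height))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  height <- rep_len(height, n)
  M <- S <- L <- numeric(n)
  for (s in unique(sex)) {
    grid <- lookup[lookup$sex == s & lookup$outcome == outcome, ]
    grid <- grid[order(grid$age), ]
    if (!nrow(grid)) {
      stop("GLI lookup lacks (", s, ", ", outcome, ")", call. = FALSE)
    }
    pick <- sex == s
    a <- age[pick]
    if (any(a < min(grid$age) | a > max(grid$age))) {
      stop(sprintf("age outside the GLI lookup grid [%g, %g]",
                   min(grid$age), max(grid$age)), call. = FALSE)
    }
    msp <- stats::approx(grid$age, grid$Mspline, xout = a)$y
    ssp <- stats::approx(grid$age, grid$Sspline, xout = a)$y
    Lv <- stats::approx(grid$age, grid$L, xout = a)$y
    M[pick] <- exp(grid$a0[1] + grid$a1[1] * log(height[pick]) +
                     grid$a2[1] * log(a) + msp)
    S[pick] <- exp(grid$p0[1] + grid$p1[1] * log(a) + ssp)
    L[pick] <- Lv
  }
  list(M = M, S = S, L = L)
}

GLI_Z_LLN <- -1.645  # z at the 5th centile

#' @rdname gli_lookup
#' @param sex `"male"` or `"female"` (vectorized, recycled).
#' @param age age in years; must lie inside the lookup's age grid.
#' @param height standing height in centimetres.
#' @return `gli_predict()` returns a data frame with `fev1_pred`,
#'   `fvc_pred` (litres, the LMS medians), `ratio_pred` (percent) and
#'   `lln_fev1` (litres, 5th-centile lower limit of normal).
#' @export
gli_predict <- function(sex, age, height, lookup = gli_lookup()) {
  sex <- check_sex(sex)
  check_range(height, 120, 220, "height", "cm")
  fev1 <- gli_msl(sex, age, height, "fev1", lookup)
  fvc <- gli_msl(sex, age, height, "fvc", lookup)
  ratio <- gli_msl(sex, age, height, "ratio", lookup)
  data.frame(
    fev1_pred = fev1$M,
    fvc_pred = fvc$M,
    ratio_pred = ratio$M,
    lln_fev1 = fev1$M * (1 + fev1$L * fev1$S * GLI_Z_LLN)^(1 / fev1$L)
  )
}

#' @rdname gli_lookup
#' @param y measured value (litres, or percent for the ratio outcome).
#' @param outcome `"fev1"`, `"fvc"` or `"ratio"`.
#' @return `gli_zscore()` returns the LMS z-score of `y`; `gli_lln()` the
#'   5th-centile lower limit of normal.
#' @export
gli_zscore <- function(y, sex, age, height, outcome = c("fev1", "fvc", "ratio"),
                       lookup = gli_lookup()) {
  outcome <- match.arg(outcome)
  sex <- check_sex(sex)
  m <- gli_msl(sex, age, height, outcome, lookup)
  ((y / m$M)^m$L - 1) / (m$L * m$S)
}

#' @rdname gli_lookup
#' @export
gli_lln <- function(sex, age, height, outcome = c("fev1", "fvc", "ratio"),
                    lookup = gli_lookup()) {
  outcome <- match.arg(outcome)
  sex <- check_sex(sex)
  m <- gli_msl(sex, age, height, outcome, lookup)
  m$M * (1 + m$L * m$S * GLI_Z_LLN)^(1 / m$L)
}
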