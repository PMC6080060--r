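GOLD_LEVELS <- c("mild", "moderate", "severe", "very_severe")

#' GOLD spirometric severity staging
#'
#' Stages airflow limitation from percent-predicted FEV1 using the GOLD
#' half-open bands: stage 1 (mild) at >= 80% predicted, stage 2 (moderate)
#' in \[50, 80), stage 3 (severe) in \[30, 50), stage 4 (very severe)
#' below 30%. Percent predicted is never rounded before thresholding.
#'
#' With `require_obstruction = TRUE` the fixed-ratio COPD gate is applied
#' first: subjects whose *measured* FEV1/FVC ratio is at least 70% get the
#' outcome `"none"` (no airflow limitation) regardless of percent
#' predicted. The gate defaults off because cohorts being cross-staged are
#' typically already diagnosed COPD patients.
#'
#' @param measured_fev1 measured FEV1 in litres.
#' @param predicted_fev1 predicted FEV1 in litres (must be positive).
#' @param measured_ratio measured FEV1/FVC in percent; required when
#'   `require_obstruction` is `TRUE`.
#' @param require_obstruction apply the measured-ratio < 70% gate first.
#' @return A factor with ordered levels `mild < moderate < severe <
#'   very_severe` (plus `none` when the gate is on), one element per
#'   subject; `percent_predicted` is attached as an attribute.
#' @examples
#' gold_stage(c(3.2, 1.9), c(4.0, 4.0))
#' @export
gold_stage <- function(measured_fev1, predicted_fev1, measured_ratio = NULL,
                       require_obstruction = FALSE) {
  if (any(predicted_fev1 <= 0)) {
    stop("predicted FEV1 must be positive", call. = FALSE)
  }
  n <- max(length(measured_fev1), length(predicted_fev1))
  measured_fev1 <- rep_len(measured_fev1, n)
  predicted_fev1 <- rep_len(predicted_fev1, n)
  pct <- 100 * measured_fev1 / predicted_fev1
  idx <- 4L - findInterval(pct, c(30, 50, 80))  # 1=mild .. 4=very severe
  stage <- GOLD_LEVELS[idx]
  levels <- GOLD_LEVELS
  if (require_obstruction) {
    if (is.null(measured_ratio)) {
      stop("measured_ratio is required when require_obstruction = TRUE",
           call. = FALSE)
    }
    stage[rep_len(measured_ratio, n) >= 70] <- "none"
    levels <- c("none", GOLD_LEVELS)
  }
  structure(factor(stage, levels = levels, ordered = TRUE),
            percent_predicted = pct)
}

#' Stage a cohort under one prediction source
#'
#' @param x a [cohort()] table.
#' @inheritParams predict_cohort
#' @inheritParams gold_stage
#' @return A data frame with `id`, `source`, `percent_predicted` and
#'   `stage`.
#' @examples
#' ch <- cohort("s1", "male", 64, 172, 79, 1.6, 3.1)
#' stage_cohort(ch, "local")
#' @export
stage_cohort <- function(x, source = c("local", "ecsc", "gli"),
                         variant = c("corrected", "as_printed"),
                         require_obstruction = FALSE) {
  source <- match.arg(source)
  variant <- match.arg(variant)
  stopifnot(inherits(x, "spiro_cohort"))
  pred <- predict_cohort(x, source, variant)
  st <- gold_stage(x$fev1, pred$fev1_pred, x$ratio, require_obstruction)
  data.frame(id = x$id, source = source,
             percent_predicted = attr(st, "percent_predicted"),
             stage = as.character(st), stringsAsFactors = FALSE)
}

#' Cross-tabulate two stage assignments
#'
#' Builds the 4x4 contingency table of GOLD stages assigned to the same
#' subjects by two prediction sources; `counts[i, j]` is the number of
#' subjects staged `i` by the row source and `j` by the column source.
#'
#' @param stages_a,stages_b stage vectors (characters or factors over the
#'   four GOLD levels), aligned by subject.
#' @param row_source,col_source labels for the two sources.
#' @return A `spiro_crosstab`: an integer matrix with stage dimnames and
#'   `row_source`/`col_source` attributes.
#' @examples
#' a <- c("mild", "moderate", "moderate")
#' b <- c("mild", "moderate", "severe")
#' cross_tabulate(a, b, "local", "ecsc")
#' @export
cross_tabulate <- function(stages_a, stages_b, row_source = "a",
                           col_source = "b") {
  if (length(stages_a) != length(stages_b)) {
    stop("stage vectors must have equal length", call. = FALSE)
  }
  to_factor <- function(x, which) {
    x <- as.character(x)
    if (!all(x %in% GOLD_LEVELS)) {
      stop("non-stage values in ", which,
           " (filter out 'none' outcomes before cross-tabulating)",
           call. = FALSE)
    }
    factor(x, levels = GOLD_LEVELS)
  }
  counts <- table(to_factor(stages_a, "stages_a"),
                  to_factor(stages_b, "stages_b"))
  m <- matrix(as.integer(counts), 4, 4, dimnames = dimnames(counts))
  names(dimnames(m)) <- c(row_source, col_source)
  new_crosstab(m, row_source, col_source)
}

new_crosstab <- function(m, row_source, col_source) {
  structure(m, class = c("spiro_crosstab", class(m)),
            row_source = row_source, col_source = col_source)
}

#' @export
print.spiro_crosstab <- function(x, ...) {
  cat(sprintf("<spiro_crosstab> %s (rows) vs %s (columns), n = %d\n",
              attr(x, "row_source"), attr(x, "col_source"), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Read a labelled 4x4 stage count table
#'
#' Reads a tab-delimited count table with a `stage` label column and one
#' column per GOLD stage, as shipped in the package fixtures.
#'
#' @param path file path.
#' @inheritParams cross_tabulate
#' @return A `spiro_crosstab`.
#' @export
read_crosstab <- function(path, row_source = "a", col_source = "b") {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(tab)[1], "stage")) {
    stop("first column of a count table must be 'stage'", call. = FALSE)
  }
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$stage
  if (!identical(rownames(m), GOLD_LEVELS) ||
      !identical(colnames(m), GOLD_LEVELS)) {
    stop("count table must be labelled with the four GOLD stages",
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  if (any(m < 0) || sum(m) == 0) {
    stop("counts must be nonnegative with a positive total", call. = FALSE)
  }
  new_crosstab(m, row_source, col_source)
}

#' COPD validation-cohort staging tables
#'
#' The three pairwise GOLD staging cross-tabulations of the 124-patient
#' COPD validation cohort, staged under the study, ECSC and GLI equation
#' sets; shipped as packaged fixtures.
#'
#' @return A named list of three `spiro_crosstab` tables:
#'   `local_vs_ecsc`, `local_vs_gli`, `ecsc_vs_gli`.
#' @examples
#' sapply(copd_staging_tables(), sum)  # each sums to 124
#' @export
copd_staging_tables <- function() {
  list(
    local_vs_ecsc = read_crosstab(
      spiroref_extdata("copd_staging_local_vs_ecsc.tsv"), "local", "ecsc"),
    local_vs_gli = read_crosstab(
      spiroref_extdata("copd_staging_local_vs_gli.tsv"), "local", "gli"),
    ecsc_vs_gli = read_crosstab(
      spiroref_extdata("copd_staging_ecsc_vs_gli.tsv"), "ecsc", "gli")
  )
}

#' Percent agreement of a stage cross-tabulation
#'
#' @param tab a `spiro_crosstab` (or any square count matrix).
#' @return A list with `diagonal` (count of agreeing subjects), `n` and
#'   `percent` (100 * diagonal / n).
#' @examples
#' percent_agreement(copd_staging_tables()$local_vs_ecsc)
#' @export
percent_agreement <- function(tab) {
  m <- as_count_matrix(tab)
  n <- sum(m)
  if (n <= 0) stop("empty table", call. = FALSE)
  d <- sum(diag(m))
  list(diagonal = d, n = n, percent = 100 * d / n)
}

as_count_matrix <- function(tab) {
  m <- unclass(tab)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("count table must be square", call. = FALSE)
  if (any(m < 0)) stop("counts must be nonnegative", call. = FALSE)
  m
}

#' Cohen's kappa for ordinal stage tables
#'
#' Chance-corrected agreement for a k x k contingency table. With weights
#' \eqn{w_{ij} = 1 - |i-j|/(k-1)} (linear), \eqn{1 - (i-j)^2/(k-1)^2}
#' (quadratic) or the identity matrix (unweighted),
#' \deqn{\kappa = \frac{\sum w_{ij} p_{ij} - \sum w_{ij} e_{ij}}
#'                     {1 - \sum w_{ij} e_{ij}},}
#' where \eqn{p_{ij}} are observed proportions and \eqn{e_{ij}} the
#' products of the marginals. Linear weighting is the default: it credits
#' near-miss disagreements in proportion to their ordinal distance, the
#' convention under which the shipped COPD staging tables reproduce their
#' published agreement coefficients.
#'
#' @param tab a `spiro_crosstab` or square count matrix.
#' @param weighting `"linear"` (default), `"none"` or `"quadratic"`.
#' @return The kappa coefficient, or `NA` (with a warning) when the table
#'   is degenerate (all mass in one row and column category).
#' @examples
#' cohen_kappa(copd_staging_tables()$local_vs_ecsc)           # 0.936
#' cohen_kappa(copd_staging_tables()$local_vs_ecsc, "none")
#' @export
cohen_kappa <- function(tab, weighting = c("linear", "none", "quadratic")) {
  weighting <- match.arg(weighting)
  m <- as_count_matrix(tab)
  n <- sum(m)
  if (n <= 0) stop("empty table", call. = FALSE)
  k <- nrow(m)
  p <- m / n
  pr <- rowSums(p); pc <- colSums(p)
  if (sum(pr > 0) < 2 && sum(pc > 0) < 2) {
    warning("kappa undefined: a single category holds all mass",
            call. = FALSE)
    return(NA_real_)
  }
  i <- row(m); j <- col(m)
  w <- switch(weighting,
    none = (i == j) * 1,
    linear = 1 - abs(i - j) / (k - 1),
    quadratic = 1 - (i - j)^2 / (k - 1)^2)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("kappa undefined: expected agreement is 1", call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Agreement battery for a stage cross-tabulation
#'
#' @inheritParams cohen_kappa
#' @return A list with `percent_agreement`, `diagonal`, `n`,
#'   `kappa_unweighted`, `kappa_linear`, `kappa_quadratic`.
#' @examples
#' agreement_report(copd_staging_tables()$ecsc_vs_gli)
#' @export
agreement_report <- function(tab) {
  pa <- percent_agreement(tab)
  list(percent_agreement = pa$percent, diagonal = pa$diagonal, n = pa$n,
       kappa_unweighted = cohen_kappa(tab, "none"),
       kappa_linear = cohen_kappa(tab, "linear"),
       kappa_quadratic = cohen_kappa(tab, "quadratic"))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two continuous measurements of the same quantity:
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x,y)}
#'                     {\mathrm{var}(x) + \mathrm{var}(y) +
#'                      (\bar x - \bar y)^2},}
#' using 1/n (population) moment estimators as in the original definition;
#' set `estimator = "sample"` for 1/(n-1) moments. Unlike Pearson's r,
#' \eqn{\rho_c} penalizes location and scale shifts, so
#' \eqn{|\rho_c| \le |r|} always.
#'
#' @param x,y numeric vectors of equal length (at least 3), e.g. predicted
#'   and measured FEV1. The reported `average_difference` is `mean(x - y)`,
#'   so pass the prediction as `x` for the predicted-minus-measured
#'   convention.
#' @param estimator `"population"` (1/n, default) or `"sample"` (1/(n-1)).
#' @return A list with `lins_ccc`, `pearson_r`, `r_squared`,
#'   `average_difference` and `n`.
#' @examples
#' lins_ccc(c(1, 2, 3), c(1, 2, 4))
#' @export
lins_ccc <- function(x, y, estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations",
                          call. = FALSE)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  denom_n <- if (estimator == "population") n else n - 1L
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / denom_n
  vy <- sum((y - my)^2) / denom_n
  cxy <- sum((x - mx) * (y - my)) / denom_n
  if (vx == 0 || vy == 0) {
    warning("concordance undefined: zero variance", call. = FALSE)
    return(list(lins_ccc = NA_real_, pearson_r = NA_real_,
                r_squared = NA_real_, average_difference = mx - my, n = n))
  }
  r <- cxy / sqrt(vx * vy)
  ccc <- 2 * cxy / (vx + vy + (mx - my)^2)
  list(lins_ccc = ccc, pearson_r = r, r_squared = r^2,
       average_difference = mx - my, n = n)
}
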