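#' Model specification for re-deriving the study equations
#'
#' A model spec names the outcome, the sex stratum and an ordered set of
#' basis terms drawn from:
#' \describe{
#'   \item{`age_young`}{`min(A, 25)` — slope of the rising limb;}
#'   \item{`age_old`}{`max(A - 25, 0)` — slope of the declining limb;}
#'   \item{`knot_jump`}{indicator `A >= 25` — a level offset at the knot,
#'     letting the fit represent the published two-intercept branch form
#'     exactly;}
#'   \item{`H`, `H2`}{height (cm) and its square;}
#'   \item{`W`}{weight (kg);}
#'   \item{`A`, `A2`}{plain age and its square (ratio models).}
#' }
#' `age_young` + `age_old` give a continuous piecewise-linear age effect
#' with the knot at 25 years; adding `knot_jump` permits the small
#' branch-intercept offsets the published equations carry.
#'
#' @param outcome `"fev1"`, `"ln_fvc"` (FVC fitted on the natural-log
#'   scale) or `"ratio"`.
#' @param terms character vector of basis labels (see Details), unique.
#' @param sex `"male"` or `"female"`.
#' @return An object of class `spiro_model_spec`.
#' @examples
#' model_spec("fev1", c("age_young", "age_old", "H", "H2"), "male")
#' @export
model_spec <- function(outcome = c("fev1", "ln_fvc", "ratio"), terms, sex) {
  outcome <- match.arg(outcome)
  sex <- check_sex(sex)
  allowed <- c("age_young", "age_old", "knot_jump", "H", "H2", "W", "A", "A2")
  if (!length(terms) || anyDuplicated(terms) ||
      !all(terms %in% allowed)) {
    stop("terms must be unique labels from: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  structure(list(outcome = outcome, terms = terms, sex = sex),
            class = "spiro_model_spec")
}

#' Build the regression design for a model spec
#'
#' Selects the spec's sex stratum from a cohort and materializes the design
#' matrix (leading intercept column, then the spec's terms in order) and
#' the response on the fitting scale (`log(fvc)` for `ln_fvc`).
#'
#' @param x a [cohort()] table.
#' @param spec a [model_spec()].
#' @return A list with `X` (design matrix), `y` (response) and `spec`.
#' @examples
#' ch <- generate_healthy(cohort_spec(n = 100, seed = 1))
#' d <- build_design(ch, model_spec("fev1", c("age_young", "age_old", "H"),
#'                                  "male"))
#' dim(d$X)
#' @export
build_design <- function(x, spec) {
  stopifnot(inherits(x, "spiro_cohort"), inherits(spec, "spiro_model_spec"))
  rows <- x[x$sex == spec$sex, , drop = FALSE]
  if (!nrow(rows)) {
    stop("cohort has no ", spec$sex, " subjects", call. = FALSE)
  }
  if ("W" %in% spec$terms && anyNA(rows$weight)) {
    stop("weight is required by the spec but missing for some subjects",
         call. = FALSE)
  }
  A <- rows$age
  basis <- list(
    age_young = pmin(A, AGE_KNOT),
    age_old = pmax(A - AGE_KNOT, 0),
    knot_jump = as.numeric(A >= AGE_KNOT),
    H = rows$height,
    H2 = rows$height^2,
    W = rows$weight,
    A = A,
    A2 = A^2
  )
  X <- cbind(`(Intercept)` = 1,
             do.call(cbind, setNames(basis[spec$terms], spec$terms)))
  y <- switch(spec$outcome,
    fev1 = rows$fev1,
    ln_fvc = log(rows$fvc),
    ratio = rows$ratio)
  list(X = X, y = y, spec = spec)
}

#' Ordinary least-squares fit with fit statistics
#'
#' Fits the design by QR-based least squares and reports the statistics the
#' study equations are annotated with: R-squared on the fitting scale and
#' the residual standard deviation `sqrt(RSS / (n - p))`, `p` counting the
#' intercept.
#'
#' @param design a list as returned by [build_design()] (or any list with
#'   `X`, `y` and optionally `spec`).
#' @return An object of class `spiro_fit` with `coefficients`, `se`,
#'   `r_squared`, `residual_sd`, `n`, `df_residual` and `spec`.
#' @examples
#' d <- list(X = cbind(1, x = 1:10), y = 2 + 3 * (1:10))
#' coef(fit_ols(d))
#' @export
fit_ols <- function(design) {
  X <- as.matrix(design$X)
  y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more rows than columns", call. = FALSE)
  # column-equilibrate so rank detection is scale-free (H^2 sits four
  # orders of magnitude above the 0/1 knot indicator)
  norms <- sqrt(colSums(X^2))
  if (any(norms == 0)) {
    stop("design is rank-deficient; collinear column(s): ",
         paste(colnames(X)[norms == 0], collapse = ", "), call. = FALSE)
  }
  Xs <- sweep(X, 2, norms, "/")
  qr_x <- qr(Xs, tol = 1e-9)
  if (qr_x$rank < p) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_x, y) / norms
  names(beta) <- colnames(X)
  res <- y - X %*% beta
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p)
  r_s <- qr.R(qr_x)
  xtx_inv_s <- chol2inv(r_s)[order(qr_x$pivot), order(qr_x$pivot)]
  se <- sqrt(diag(xtx_inv_s) * sigma2) / norms
  names(se) <- names(beta)
  structure(list(
    coefficients = beta,
    se = se,
    r_squared = if (tss > 0) 1 - rss / tss else 0,
    residual_sd = sqrt(sigma2),
    n = n,
    df_residual = n - p,
    spec = design$spec
  ), class = "spiro_fit")
}

#' @export
coef.spiro_fit <- function(object, ...) object$coefficients

#' @export
print.spiro_fit <- function(x, ...) {
  if (!is.null(x$spec)) {
    cat(sprintf("<spiro_fit> %s, %s (n = %d)\n",
                x$spec$outcome, x$spec$sex, x$n))
  }
  print(round(x$coefficients, 6))
  cat(sprintf("R^2 = %.3f, residual SD = %.4f\n", x$r_squared, x$residual_sd))
  invisible(x)
}

# The published term sets, per (sex, outcome). Every piecewise model carries
# knot_jump so the published branch-specific intercepts are exactly
# representable (the male ln(FVC) equations in particular differ by 0.066 at
# the knot).
study_model_terms <- function() {
  list(
    male.fev1 = c("age_young", "age_old", "knot_jump", "H", "H2"),
    female.fev1 = c("age_young", "age_old", "knot_jump", "H"),
    male.ln_fvc = c("age_young", "age_old", "knot_jump", "H", "H2", "W"),
    female.ln_fvc = c("age_young", "age_old", "knot_jump", "H", "H2", "W"),
    male.ratio = "A",
    female.ratio = c("A", "A2")
  )
}

#' Re-derive the six study equations from a cohort
#'
#' Fits the six published model structures (per sex: FEV1, ln(FVC), ratio)
#' to a cohort with the piecewise-linear age basis. The canonical variant
#' fixes the published term sets; the exploratory variant instead starts
#' from the full candidate pool and drops terms by partial-F tests at the
#' 0.05 level — it is labelled non-canonical and exists for sensitivity
#' checks only, since the original covariate-selection path is not
#' reproducible.
#'
#' @param x a [cohort()] table with at least 50 subjects per sex
#'   (fewer triggers a warning; an absent sex is an error).
#' @param variant `"canonical"` (default) or `"exploratory"`.
#' @return A named list of six [fit_ols()] results
#'   (`male.fev1`, `female.fev1`, ..., `female.ratio`).
#' @examples
#' ch <- generate_healthy(cohort_spec(n = 200, seed = 42))
#' fits <- refit_study_models(ch)
#' fits$male.ratio
#' @export
refit_study_models <- function(x, variant = c("canonical", "exploratory")) {
  variant <- match.arg(variant)
  stopifnot(inherits(x, "spiro_cohort"))
  for (s in c("male", "female")) {
    n_s <- sum(x$sex == s)
    if (n_s == 0L) stop("cohort has no ", s, " subjects", call. = FALSE)
    if (n_s < 50L) warning("only ", n_s, " ", s,
                           " subjects; fits may be unstable", call. = FALSE)
  }
  sets <- study_model_terms()
  # the knot offset (and, in the extreme, the young-age slope) is only
  # estimable with under-knot subjects in the stratum; degrade gracefully
  # rather than fail on sparse young support
  distinct_young <- vapply(c("male", "female"), function(s) {
    length(unique(round(x$age[x$sex == s & x$age < AGE_KNOT], 6)))
  }, integer(1))
  out <- lapply(names(sets), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    terms <- sets[[key]]
    if (variant == "exploratory") {
      pool <- if (parts[2] == "ratio") c("A", "A2") else
        c("age_young", "age_old", "knot_jump", "H", "H2", "W")
      return(fit_backward(x, parts[2], pool, parts[1]))
    }
    ny <- distinct_young[[parts[1]]]
    if (ny < 2 && "knot_jump" %in% terms) {
      message("dropping knot_jump for ", key,
              ": fewer than two distinct ages below the knot")
      terms <- setdiff(terms, "knot_jump")
    }
    if (ny < 1 && "age_young" %in% terms) {
      message("dropping age_young for ", key,
              ": no subjects below the knot")
      terms <- setdiff(terms, "age_young")
    }
    fit_ols(build_design(x, model_spec(parts[2], terms, parts[1])))
  })
  setNames(out, names(sets))
}

# Backward elimination by partial F (equivalently t) tests at alpha.
fit_backward <- function(x, outcome, pool, sex, alpha = 0.05) {
  terms <- pool
  repeat {
    fit <- fit_ols(build_design(x, model_spec(outcome, terms, sex)))
    tval <- fit$coefficients[-1] / fit$se[-1]
    pval <- 2 * stats::pt(abs(tval), fit$df_residual, lower.tail = FALSE)
    if (!length(pval) || min(length(terms), 1) == 0 || max(pval) <= alpha ||
        length(terms) == 1L) {
      fit$selection <- "exploratory (backward partial-F, alpha = 0.05)"
      return(fit)
    }
    terms <- terms[-which.max(pval)]
  }
}

#' Display a piecewise fit in two-branch form
#'
#' Converts a fitted piecewise model (basis `age_young`, `age_old`,
#' optional `knot_jump`) to the two-branch display convention of the
#' published equations: an intercept plus slope on A for age < 25, and an
#' intercept plus slope on (A - 25) for age >= 25, shared covariate terms
#' unchanged.
#'
#' @param fit a [fit_ols()] result whose terms include `age_young` and
#'   `age_old`.
#' @return A list with `young` and `old` coefficient vectors.
#' @export
as_branch_form <- function(fit) {
  b <- fit$coefficients
  need <- c("age_young", "age_old")
  if (!all(need %in% names(b))) {
    stop("fit does not use the piecewise age basis", call. = FALSE)
  }
  jump <- if ("knot_jump" %in% names(b)) b[["knot_jump"]] else 0
  shared <- b[setdiff(names(b),
                      c("(Intercept)", "age_young", "age_old", "knot_jump"))]
  list(
    young = c(intercept = unname(b[["(Intercept)"]]),
              age = unname(b[["age_young"]]), shared),
    old = c(intercept = unname(b[["(Intercept)"]] +
                                 AGE_KNOT * b[["age_young"]] + jump),
            age_minus_knot = unname(b[["age_old"]]), shared)
  )
}
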