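test_that("build_design materializes the piecewise age basis", {
  ch <- cohort(id = c("a", "b", "c"), sex = "male",
               age = c(25, 40, 18), height = 175, weight = 80,
               fev1 = c(3, 3, 3), fvc = c(4, 4, 4))
  d <- build_design(ch, model_spec("fev1", c("age_young", "age_old"), "male"))
  expect_equal(unname(d$X[, "age_young"]), c(25, 25, 18))
  expect_equal(unname(d$X[, "age_old"]), c(0, 15, 0))
  expect_equal(colnames(d$X)[1], "(Intercept)")
  # ln_fvc outcome logs the response
  d2 <- build_design(ch, model_spec("ln_fvc", c("age_young", "age_old", "W"),
                                    "male"))
  expect_equal(d2$y, log(ch$fvc))
  # missing covariate errors
  ch_na <- cohort("a", "male", 40, 175, NA, 3.7, 4.6)
  expect_error(build_design(ch_na, model_spec("fev1", "W", "male")),
               "weight is required")
  expect_error(build_design(ch, model_spec("fev1", "H", "female")),
               "no female subjects")
})

test_that("fit_ols recovers noiseless linear models exactly", {
  set.seed(11)
  X <- cbind(`(Intercept)` = 1, a = rnorm(30), b = runif(30, 10, 20))
  beta <- c(2, -1.5, 0.25)
  fit <- fit_ols(list(X = X, y = drop(X %*% beta)))
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-8)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-8)

  # constant response: slopes 0, r_squared 0
  fit0 <- fit_ols(list(X = X, y = rep(4, 30)))
  expect_equal(unname(coef(fit0)), c(4, 0, 0), tolerance = 1e-8)
  expect_equal(fit0$r_squared, 0)
})

test_that("fit_ols names collinear columns on rank deficiency", {
  X <- cbind(`(Intercept)` = 1, a = 1:20, dup = 2 * (1:20))
  expect_error(fit_ols(list(X = X, y = rnorm(20))),
               "rank-deficient.*dup")
  expect_error(fit_ols(list(X = cbind(1, diag(3)), y = 1:3)),
               "more rows than columns")
})

test_that("fit_ols agrees with the normal-equations oracle", {
  # brute-force solve of X'X beta = X'y on random 20x4 systems
  for (s in 1:8) {
    set.seed(100 + s)
    X <- cbind(1, matrix(rnorm(60), 20, 3))
    colnames(X) <- c("(Intercept)", "x1", "x2", "x3")
    y <- rnorm(20)
    fit <- fit_ols(list(X = X, y = y))
    beta_ne <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(unname(coef(fit)), unname(drop(beta_ne)), tolerance = 1e-8)
    res <- y - X %*% beta_ne
    expect_equal(fit$residual_sd, sqrt(sum(res^2) / (20 - 4)),
                 tolerance = 1e-8)
    expect_equal(fit$r_squared,
                 1 - sum(res^2) / sum((y - mean(y))^2), tolerance = 1e-8)
  }
})

test_that("r_squared is invariant under affine covariate rescaling", {
  set.seed(5)
  X <- cbind(`(Intercept)` = 1, a = rnorm(40), b = runif(40))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(40, 0, 0.5)
  f1 <- fit_ols(list(X = X, y = y))
  X2 <- X
  X2[, "a"] <- 100 * X[, "a"] - 3
  X2[, "b"] <- 0.01 * X[, "b"] + 7
  f2 <- fit_ols(list(X = X2, y = y))
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
  expect_equal(f1$residual_sd, f2$residual_sd, tolerance = 1e-10)
})

test_that("noiseless synthetic cohorts return the printed coefficients", {
  ch <- generate_healthy(noiseless_spec(n = 400, seed = 3),
                         enforce_validity = FALSE)
  fits <- refit_study_models(ch)
  for (nm in c("male.fev1", "female.fev1", "male.ln_fvc", "female.ln_fvc")) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tgt <- printed_basis_coefs(parts[1], parts[2])
    got <- coef(fits[[nm]])
    expect_equal(got[names(tgt)], tgt, tolerance = 1e-6, info = nm)
  }
  # ratio models: simulate the ratio response from its own equation
  for (s in c("male", "female")) {
    terms <- if (s == "male") "A" else c("A", "A2")
    d <- build_design(ch, model_spec("ratio", terms, s))
    fit <- fit_ols(list(X = d$X, y = predict_ratio_local(s, d$X[, "A"]),
                        spec = d$spec))
    tgt <- printed_basis_coefs(s, "ratio")
    expect_equal(coef(fit)[names(tgt)], tgt, tolerance = 1e-6, info = s)
  }
})

test_that("piecewise predictions are continuous at the knot without the jump term", {
  ch <- generate_healthy(cohort_spec(n = 300, seed = 9))
  d <- build_design(ch, model_spec("fev1", c("age_young", "age_old", "H"),
                                   "male"))
  fit <- fit_ols(d)
  b <- coef(fit)
  pred_at <- function(a, h) {
    b[["(Intercept)"]] + b[["age_young"]] * min(a, 25) +
      b[["age_old"]] * max(a - 25, 0) + b[["H"]] * h
  }
  expect_equal(pred_at(25 - 1e-9, 175), pred_at(25, 175), tolerance = 1e-7)
})

test_that("refit errors when a sex stratum is absent", {
  males <- tiny_cohort()[tiny_cohort()$sex == "male", ]
  ch <- cohort(males$id, males$sex, males$age, males$height, males$weight,
               males$fev1, males$fvc)
  expect_error(suppressWarnings(refit_study_models(ch)),
               "no female subjects")
})

test_that("as_branch_form reproduces the published display convention", {
  ch <- generate_healthy(noiseless_spec(n = 400, seed = 4),
                         enforce_validity = FALSE)
  fit <- refit_study_models(ch)$male.ln_fvc
  bf <- as_branch_form(fit)
  expect_equal(bf$young[["intercept"]], -13.518, tolerance = 1e-5)
  expect_equal(bf$young[["age"]], 0.0196, tolerance = 1e-6)
  expect_equal(bf$old[["intercept"]], -13.094, tolerance = 1e-5)
  expect_equal(bf$old[["age_minus_knot"]], -0.0070, tolerance = 1e-6)
  expect_equal(bf$old[["W"]], -0.00138, tolerance = 1e-7)
})

test_that("exploratory selection keeps strong terms and labels itself", {
  ch <- generate_healthy(cohort_spec(n = 400, seed = 13))
  fit <- refit_study_models(ch, variant = "exploratory")$male.fev1
  expect_match(fit$selection, "exploratory")
  # height enters in some form (H and H2 are nearly collinear, so either
  # may carry the effect) and the age decline survives selection
  expect_true(any(c("H", "H2") %in% names(coef(fit))))
  expect_true("age_old" %in% names(coef(fit)))
})
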