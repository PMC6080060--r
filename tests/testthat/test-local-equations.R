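test_that("local FEV1 equations evaluate the printed branches", {
  # direct arithmetic: -25.144 + 0.296*175 - 0.000728*175^2 - 0.0288*15
  expect_equal(predict_fev1_local("male", 40, 175), 3.929, tolerance = 1e-6)
  # young branch at fixed height
  expect_equal(predict_fev1_local("male", 20, 175),
               -25.857 + 0.296 * 175 - 0.000728 * 175^2 + 0.0285 * 20,
               tolerance = 1e-9)
  # female old-age slope: 0.0232 L/yr
  for (a in c(30, 45, 60)) {
    expect_equal(predict_fev1_local("female", a, 163) -
                   predict_fev1_local("female", a + 10, 163),
                 0.232, tolerance = 1e-9)
  }
})

test_that("local ln(FVC) equations evaluate and exponentiate correctly", {
  # female, 40y, 163cm, 70kg: ln(FVC) = 1.18845
  expect_equal(predict_fvc_local("female", 40, 163, 70), exp(1.18845),
               tolerance = 1e-9)
  expect_error(predict_fvc_local("female", 40, 163), "weight")
  # negative weight coefficients: monotone decreasing in weight
  for (s in c("male", "female")) {
    w <- seq(55, 95, by = 10)
    p <- predict_fvc_local(s, 45, 170, w)
    expect_true(all(diff(p) < 0), info = s)
  }
})

test_that("branches are near-continuous at the knot except male ln(FVC)", {
  eps <- 1e-9
  h <- 170
  expect_lt(abs(predict_fev1_local("male", 25 - eps, h) -
                  predict_fev1_local("male", 25, h)), 0.001)
  expect_lt(abs(predict_fev1_local("female", 25 - eps, h) -
                  predict_fev1_local("female", 25, h)), 0.002)
  expect_lt(abs(log(predict_fvc_local("female", 25 - eps, h, 65)) -
                  log(predict_fvc_local("female", 25, h, 65))), 0.002)
  # the published male ln(FVC) branch intercepts genuinely differ by 0.066
  gap <- log(predict_fvc_local("male", 25 - eps, h, 80)) -
    log(predict_fvc_local("male", 25, h, 80))
  expect_equal(gap, 0.066, tolerance = 1e-6)
})

test_that("as_printed variant preserves the published H^2 sign typo", {
  # +0.00041*H^2 in the young male branch puts ln(FVC) near 26
  absurd <- predict_fvc_local("male", 22, 175, 80, variant = "as_printed")
  expect_gt(log(absurd), 20)
  # corrected variant is physiologic
  expect_lt(predict_fvc_local("male", 22, 175, 80), 8)
  # the two variants agree wherever the typo is not involved
  expect_equal(predict_fvc_local("male", 40, 175, 80, variant = "as_printed"),
               predict_fvc_local("male", 40, 175, 80))
  expect_equal(predict_fev1_local("female", 30, 160, variant = "as_printed"),
               predict_fev1_local("female", 30, 160))
})

test_that("ratio equations are linear (men) / quadratic (women) in age only", {
  expect_equal(predict_ratio_local("male", 46.92), 82.75, tolerance = 5e-3)
  expect_equal(predict_ratio_local("male", 62.65), 81.64, tolerance = 5e-3)
  for (a in c(20, 35, 50, 70)) {
    expect_equal(predict_ratio_local("male", a) -
                   predict_ratio_local("male", a + 10),
                 0.707, tolerance = 1e-9)
  }
  # male ratio strictly decreasing; female decreasing then flattening with
  # vertex near 56.9 years
  ages <- seq(18, 95, by = 0.5)
  expect_true(all(diff(predict_ratio_local("male", ages)) < 0))
  fr <- predict_ratio_local("female", ages)
  vertex <- 0.7852 / (2 * 0.0069)
  expect_equal(ages[which.min(fr)], vertex, tolerance = 0.5)
  expect_true(all(diff(fr[ages < vertex - 0.5]) < 0))
})

test_that("predictions are positive over the realistic input box", {
  grid <- expand.grid(sex = c("male", "female"),
                      age = c(18, 25, 40, 60, 80, 95),
                      height = c(140, 155, 170, 185, 205),
                      weight = c(40, 70, 100, 160),
                      stringsAsFactors = FALSE)
  expect_true(all(predict_fev1_local(grid$sex, grid$age, grid$height) > 0))
  expect_true(all(predict_fvc_local(grid$sex, grid$age, grid$height,
                                    grid$weight) > 0))
  r <- predict_ratio_local(grid$sex, grid$age)
  expect_true(all(r > 0 & r <= 120))
})

test_that("range violations raise errors", {
  expect_error(predict_fev1_local("male", 16, 175), "age")
  expect_error(predict_fev1_local("male", 40, 230), "height")
  expect_error(predict_ratio_local("male", 97), "age")
  expect_error(predict_fev1_local("other", 40, 175), "sex")
})

test_that("ratio moments follow from the equation's linearity/quadratic form", {
  m <- ratio_prediction_moments("male", 46.92, 16.16)
  expect_equal(m$mean, predict_ratio_local("male", 46.92))
  expect_equal(m$sd, 0.0707 * 16.16, tolerance = 1e-12)
  # female mean uses E[A^2] = mu^2 + sd^2; cross-check by discretized
  # normal-expectation quadrature
  f <- ratio_prediction_moments("female", 48.20, 17.19)
  a <- seq(-6, 6, length.out = 20001) * 17.19 + 48.20
  wdens <- dnorm(a, 48.20, 17.19); wdens <- wdens / sum(wdens)
  vals <- 105.38 - 0.7852 * a + 0.0069 * a^2
  expect_equal(f$mean, sum(wdens * vals), tolerance = 1e-6)
  expect_equal(f$sd, sqrt(sum(wdens * (vals - sum(wdens * vals))^2)),
               tolerance = 1e-4)
})
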