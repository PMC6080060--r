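test_that("gold_stage applies the half-open GOLD bands", {
  pred <- rep(4, 6)
  meas <- c(80, 79.999, 50, 49.999, 30, 29.999) / 100 * 4
  st <- gold_stage(meas, pred)
  expect_equal(as.character(st),
               c("mild", "moderate", "moderate", "severe", "severe",
                 "very_severe"))
  expect_equal(attr(st, "percent_predicted"),
               c(80, 79.999, 50, 49.999, 30, 29.999))
  expect_error(gold_stage(3, 0), "predicted FEV1 must be positive")
})

test_that("the obstruction gate overrides staging when the ratio is >= 70", {
  st <- gold_stage(c(2.2, 2.2), c(4, 4), measured_ratio = c(72, 65),
                   require_obstruction = TRUE)
  expect_equal(as.character(st), c("none", "moderate"))
  expect_error(gold_stage(1.9, 4, require_obstruction = TRUE),
               "measured_ratio is required")
})

test_that("cross_tabulate counts aligned pairs and transposes on swap", {
  a <- c("mild", "mild", "moderate", "severe", "very_severe")
  b <- c("mild", "moderate", "moderate", "severe", "very_severe")
  tab <- cross_tabulate(a, b, "x", "y")
  expect_equal(sum(tab), 5)
  expect_equal(tab["mild", "mild"], 1L)
  expect_equal(tab["mild", "moderate"], 1L)
  expect_equal(unclass(cross_tabulate(b, a)), t(unclass(tab)),
               ignore_attr = TRUE)
  # identical vectors give a purely diagonal table
  d <- cross_tabulate(a, a)
  expect_equal(sum(diag(d)), 5)
  expect_equal(sum(d) - sum(diag(d)), 0)
  expect_error(cross_tabulate(a, b[-1]), "equal length")
  expect_error(cross_tabulate(c(a, "none"), c(b, "none")), "non-stage")
})

test_that("percent agreement matches the shipped COPD staging tables", {
  tabs <- copd_staging_tables()
  pa <- percent_agreement(tabs$local_vs_ecsc)
  expect_equal(pa$diagonal, 116L)
  expect_equal(pa$n, 124L)
  expect_equal(round(pa$percent, 1), 93.5)  # 116/124
  expect_equal(round(percent_agreement(tabs$ecsc_vs_gli)$percent, 1), 86.3)
  expect_equal(percent_agreement(tabs$ecsc_vs_gli)$diagonal, 107L)
  # all-diagonal table is 100%
  expect_equal(percent_agreement(diag(c(3, 1, 2, 5)))$percent, 100)
})

test_that("cohen_kappa matches hand-derived small cases", {
  expect_equal(cohen_kappa(diag(c(5, 3, 2, 4)), "none"), 1)
  expect_equal(cohen_kappa(diag(c(5, 3, 2, 4)), "linear"), 1)
  expect_equal(cohen_kappa(diag(c(5, 3, 2, 4)), "quadratic"), 1)
  # 2x2 [[2,1],[1,2]]: p_o = 2/3, p_e = 1/2 under any weighting -> 1/3
  expect_equal(cohen_kappa(matrix(c(2, 1, 1, 2), 2), "linear"), 1 / 3,
               tolerance = 1e-12)
  expect_warning(k <- cohen_kappa(matrix(c(7, 0, 0, 0), 2)), "undefined")
  expect_true(is.na(k))
})

test_that("cohen_kappa agrees with a brute-force definitional oracle", {
  brute_kappa <- function(m, weighting) {
    k <- nrow(m); n <- sum(m)
    w <- matrix(0, k, k)
    for (i in 1:k) for (j in 1:k) {
      w[i, j] <- switch(weighting,
        none = as.numeric(i == j),
        linear = 1 - abs(i - j) / (k - 1),
        quadratic = 1 - (i - j)^2 / (k - 1)^2)
    }
    po <- pe <- 0
    for (i in 1:k) for (j in 1:k) {
      po <- po + w[i, j] * m[i, j] / n
      pe <- pe + w[i, j] * (sum(m[i, ]) / n) * (sum(m[, j]) / n)
    }
    (po - pe) / (1 - pe)
  }
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(8:50, 1)
    m <- matrix(0L, 4, 4)
    idx <- sample(16, n, replace = TRUE,
                  prob = (diag(4) * 3 + 1)[seq_len(16)])
    for (i in idx) m[i] <- m[i] + 1L
    if (sum(rowSums(m) > 0) < 2 || sum(colSums(m) > 0) < 2) next
    for (wt in c("none", "linear", "quadratic")) {
      expect_equal(cohen_kappa(m, wt), brute_kappa(m, wt), tolerance = 1e-8)
    }
  }
})

test_that("ordinal weights are order-sensitive; identity weights are not", {
  tabs <- copd_staging_tables()
  m <- unclass(tabs$local_vs_gli)
  perm <- c(3, 1, 4, 2)
  mp <- m[perm, perm]
  expect_equal(cohen_kappa(mp, "none"), cohen_kappa(m, "none"),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cohen_kappa(mp, "linear"),
                                cohen_kappa(m, "linear"))))
})

test_that("lins_ccc matches its definition and penalizes shifts", {
  r <- lins_ccc(c(1, 2, 3), c(1, 2, 4))
  # hand arithmetic with 1/n moments: cov = 1, var_x = 2/3, var_y = 14/9,
  # dmean = -1/3 -> ccc = 2 / (2/3 + 14/9 + 1/9) = 6/7
  expect_equal(r$lins_ccc, 6 / 7, tolerance = 1e-12)
  expect_equal(r$average_difference, -1 / 3, tolerance = 1e-12)

  x <- c(2.3, 3.1, 4.7, 5.2, 6.8)
  same <- lins_ccc(x, x)
  expect_equal(same$lins_ccc, 1)
  expect_equal(same$average_difference, 0)
  shifted <- lins_ccc(x, x + 2)
  expect_lt(shifted$lins_ccc, 1)
  expect_equal(shifted$pearson_r, 1)

  expect_error(lins_ccc(1:5, 1:4), "equal length")
  expect_error(lins_ccc(1:2, 1:2), "at least 3")
  expect_warning(z <- lins_ccc(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(z$lins_ccc))
})

test_that("lins_ccc agrees with a brute-force oracle and |ccc| <= |r|", {
  brute_ccc <- function(x, y) {
    n <- length(x)
    mx <- sum(x) / n; my <- sum(y) / n
    vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
    sxy <- sum((x - mx) * (y - my)) / n
    2 * sxy / (vx + vy + (mx - my)^2)
  }
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(3:40, 1)
    x <- rnorm(n, 3, 2)
    y <- 0.5 * x + rnorm(n, sample(-2:2, 1), 1.5)
    r <- lins_ccc(x, y)
    expect_equal(r$lins_ccc, brute_ccc(x, y), tolerance = 1e-8)
    expect_lte(abs(r$lins_ccc), abs(r$pearson_r) + 1e-12)
  }
  # sample estimator matches the population one up to (n-1)/n factors
  x <- rnorm(20); y <- rnorm(20)
  rp <- lins_ccc(x, y)
  rs <- lins_ccc(x, y, estimator = "sample")
  expect_equal(rp$pearson_r, rs$pearson_r, tolerance = 1e-12)
})

test_that("read_crosstab validates labelling", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("stage\tmild\tmoderate\tsevere\tvery_severe",
               "mild\t1\t0\t0\t0", "moderate\t0\t1\t0\t0",
               "severe\t0\t0\t1\t0", "very_severe\t0\t0\t0\t1"), p)
  tab <- read_crosstab(p, "a", "b")
  expect_equal(sum(diag(tab)), 4L)
  writeLines(c("stage\tmild\tmoderate", "mild\t1\t0", "moderate\t0\t1"),
             p)
  expect_error(read_crosstab(p), "four GOLD stages")
})
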