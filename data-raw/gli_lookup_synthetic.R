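# Builds inst/extdata/gli_lookup_synthetic.tsv.
#
# The genuine GLI-2012 coefficient/spline tables are not redistributed here;
# this synthetic lookup keeps the exact LMS model structure (a0, a1, a2,
# age-indexed Mspline/Sspline, age-varying L, p0/p1 scatter model) and
# calibrates the median trajectory at a per-sex reference height to the
# adult trajectory implied by the study equations, scaled by the mean
# GLI/study prediction offsets observed in the healthy cohort (FEV1 ~ +4%,
# FVC ~ +8/+10%, ratio ~ -3/-5%). Height dependence is a power law with a
# fixed exponent per sex/outcome; the ratio outcome is height-free and
# tabulated on the percent scale. Run from the package root:
#   Rscript data-raw/gli_lookup_synthetic.R

source("R/spiroref-package.R")
source("R/local-equations.R")
spiroref_extdata <- function(file) file.path("inst", "extdata", file)

ages <- 18:95
href <- c(male = 175.80, female = 162.69)
wref <- c(male = 84.90, female = 69.70)

# mean GLI / mean study prediction in the healthy cohort, per sex
scale_k <- list(
  fev1  = c(male = 3.90 / 3.75, female = 2.80 / 2.70),
  fvc   = c(male = 4.88 / 4.52, female = 3.44 / 3.14),
  ratio = c(male = 80.01 / 82.75, female = 81.61 / 85.63)
)

# fixed (height exponent, ln-age slope, scatter model, Box-Cox L model)
shape <- list(
  fev1 = list(
    male   = list(a1 = 2.2196, a2 = 0.0574, p0 = -2.3268, p1 = 0.0798,
                  q0 = 0.8866, q1 = 0.0850),
    female = list(a1 = 2.2500, a2 = 0.0500, p0 = -2.3000, p1 = 0.0700,
                  q0 = 0.9000, q1 = 0.0800)),
  fvc = list(
    male   = list(a1 = 2.4135, a2 = 0.0865, p0 = -2.2940, p1 = 0.0181,
                  q0 = 0.9346, q1 = 0.0892),
    female = list(a1 = 2.4000, a2 = 0.0800, p0 = -2.2700, p1 = 0.0200,
                  q0 = 0.9500, q1 = 0.0850)),
  ratio = list(
    male   = list(a1 = 0, a2 = 0, p0 = -2.9000, p1 = 0.0200,
                  q0 = 1.5000, q1 = 0),
    female = list(a1 = 0, a2 = 0, p0 = -2.9000, p1 = 0.0200,
                  q0 = 1.5000, q1 = 0))
)

target_median <- function(sex, outcome, age) {
  k <- scale_k[[outcome]][[sex]]
  k * switch(outcome,
    fev1  = eval_local(sex, "fev1", age, href[[sex]]),
    fvc   = exp(eval_local(sex, "ln_fvc", age, href[[sex]], wref[[sex]])),
    ratio = eval_local(sex, "ratio", age))
}

rows <- list()
for (outcome in names(shape)) {
  for (sex in c("male", "female")) {
    sh <- shape[[outcome]][[sex]]
    tm <- target_median(sex, outcome, ages)
    # anchor a0 at age 40 so the spline is ~0 mid-adulthood
    a0 <- round(log(target_median(sex, outcome, 40)) -
                  sh$a1 * log(href[[sex]]) - sh$a2 * log(40), 4)
    mspline <- log(tm) - (a0 + sh$a1 * log(href[[sex]]) + sh$a2 * log(ages))
    rows[[length(rows) + 1L]] <- data.frame(
      sex = sex, outcome = outcome, age = ages,
      a0 = a0, a1 = sh$a1, a2 = sh$a2,
      Mspline = round(mspline, 6), Sspline = 0,
      L = round(sh$q0 + sh$q1 * log(ages), 4),
      p0 = sh$p0, p1 = sh$p1,
      version = "synthetic-1.0")
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "inst/extdata/gli_lookup_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", nrow(tab), "rows\n")
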