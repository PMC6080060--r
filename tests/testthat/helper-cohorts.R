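# Small programmatic fixtures shared across test files.

# A hand-written six-subject cohort covering both sexes and both sides of
# the age knot.
tiny_cohort <- function() {
  cohort(
    id = sprintf("s%d", 1:6),
    sex = c("male", "male", "male", "female", "female", "female"),
    age = c(22, 40, 67, 24, 48, 71),
    height = c(178, 175, 170, 165, 162, 158),
    weight = c(75, 85, 80, 60, 70, 65),
    fev1 = c(4.1, 3.7, 2.6, 3.0, 2.5, 1.8),
    fvc = c(4.9, 4.6, 3.5, 3.6, 3.1, 2.4),
    provenance = "test fixture"
  )
}

# Write a cohort CSV by hand (not via write_cohort) so reader tests do not
# depend on the writer.
write_cohort_text <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("id,sex,age_years,height_cm,weight_kg,fev1_l,fvc_l", lines),
             path)
  path
}

# Printed study coefficients rearranged on the fitting basis used by
# refit_study_models (intercept = young intercept; knot_jump = old intercept
# minus the young branch evaluated at the knot).
printed_basis_coefs <- function(sex, outcome) {
  tab <- local_coefficients()
  tab <- tab[tab$sex == sex & tab$outcome == outcome, ]
  cf <- function(branch, term) {
    v <- tab$coefficient[tab$branch == branch & tab$term == term]
    if (length(v)) v else 0
  }
  if (outcome == "ratio") {
    out <- c(`(Intercept)` = cf("all", "intercept"), A = cf("all", "age"))
    if (sex == "female") out <- c(out, A2 = cf("all", "age2"))
    return(out)
  }
  out <- c(`(Intercept)` = cf("young", "intercept"),
           age_young = cf("young", "age"),
           age_old = cf("old", "age_minus_knot"),
           knot_jump = cf("old", "intercept") - cf("young", "intercept") -
             25 * cf("young", "age"),
           H = cf("young", "height"))
  if (cf("young", "height2") != 0) out <- c(out, H2 = cf("young", "height2"))
  if (cf("young", "weight") != 0) out <- c(out, W = cf("young", "weight"))
  out
}

# Zero-noise spec for exact-recovery tests (pure generative model).
noiseless_spec <- function(n = 400, seed = 1) {
  cohort_spec(n = n, seed = seed,
              noise = list(fev1 = c(male = 0, female = 0),
                           ln_fvc = c(male = 0, female = 0),
                           residual_cor = 0))
}
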