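#' Synthetic healthy-cohort specification
#'
#' Defaults reproduce the healthy reference cohort the study equations were
#' derived from: 500 subjects (239 men, 261 women) with sex-stratified
#' normal age, height and weight (truncated to the validated input box) and
#' measurement noise equal to the published residual SDs of the FEV1 and
#' ln(FVC) models. Measured FEV1 is the study FEV1 equation plus
#' N(0, sd) noise; measured FVC is the exponentiated study ln(FVC) equation
#' plus ln-scale noise; the measured ratio is derived from the pair. The
#' FEV1 and ln(FVC) noises share a residual correlation (default 0.7),
#' reflecting the within-subject coupling of effort and size that real
#' spirograms show; 0.7 puts the spread of the derived measured ratio near
#' the healthy cohort's observed ratio SDs (about 7 points in men, 9 in
#' women). Marginal noise SDs are unaffected by the correlation, so
#' coefficient recovery by [refit_study_models()] stays unbiased.
#'
#' @param n number of subjects.
#' @param male_fraction proportion of men; male count is `round(n * male_fraction)`.
#' @param age,height,weight per-sex `mean` and `sd` lists (years, cm, kg).
#' @param age_bounds,height_bounds,weight_bounds truncation bounds keeping
#'   demographics inside the equations' validated box.
#' @param noise per-model residual SDs: `fev1` and `ln_fvc`, each
#'   `c(male =, female =)`, plus `residual_cor` between the two noises.
#' @param seed integer seed making generation fully reproducible; `NULL`
#'   uses (and advances) the session RNG.
#' @return An object of class `spiro_cohort_spec`.
#' @examples
#' cohort_spec(n = 100, seed = 1)
#' @export
cohort_spec <- function(
    n = 500,
    male_fraction = 239 / 500,
    age = list(male = c(mean = 46.92, sd = 16.16),
               female = c(mean = 48.20, sd = 17.19)),
    height = list(male = c(mean = 175.80, sd = 7.25),
                  female = c(mean = 162.69, sd = 7.18)),
    weight = list(male = c(mean = 84.90, sd = 4.90),
                  female = c(mean = 69.70, sd = 15.92)),
    age_bounds = c(18, 89),
    height_bounds = c(140, 205),
    weight_bounds = c(40, 160),
    noise = list(fev1 = c(male = 0.38, female = 0.28),
                 ln_fvc = c(male = 0.12, female = 0.13),
                 residual_cor = 0.7),
    seed = NULL) {
  spec <- list(n = n, male_fraction = male_fraction, age = age,
               height = height, weight = weight, age_bounds = age_bounds,
               height_bounds = height_bounds, weight_bounds = weight_bounds,
               noise = noise, seed = seed)
  validate_cohort_spec(spec)
  structure(spec, class = "spiro_cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n >= 1, spec$male_fraction >= 0, spec$male_fraction <= 1)
  demo_sds <- c(vapply(spec$age, `[[`, 0, "sd"),
                vapply(spec$height, `[[`, 0, "sd"),
                vapply(spec$weight, `[[`, 0, "sd"))
  if (any(demo_sds <= 0)) stop("demographic SDs must be > 0", call. = FALSE)
  if (any(c(spec$noise$fev1, spec$noise$ln_fvc) < 0)) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  stopifnot(abs(spec$noise$residual_cor) < 1)
  for (b in list(spec$age_bounds, spec$height_bounds, spec$weight_bounds)) {
    if (b[1] >= b[2]) stop("infeasible truncation bounds", call. = FALSE)
  }
  invisible(spec)
}

# Demographics whose equation-implied FEV1/FVC exceeds this are redrawn.
RATIO_CAP <- 98

# Truncated-normal draws by rejection; fails loudly if the bounds leave
# essentially no mass.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  for (attempt in 1:1000) {
    draw <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("truncation bounds reject nearly all draws", call. = FALSE)
}

draw_demographics <- function(n_male, n_female, spec) {
  one_sex <- function(sex, n) {
    data.frame(
      sex = rep(sex, n),
      age = rnorm_trunc(n, spec$age[[sex]][["mean"]], spec$age[[sex]][["sd"]],
                        spec$age_bounds[1], spec$age_bounds[2]),
      height = rnorm_trunc(n, spec$height[[sex]][["mean"]],
                           spec$height[[sex]][["sd"]],
                           spec$height_bounds[1], spec$height_bounds[2]),
      weight = rnorm_trunc(n, spec$weight[[sex]][["mean"]],
                           spec$weight[[sex]][["sd"]],
                           spec$weight_bounds[1], spec$weight_bounds[2]),
      stringsAsFactors = FALSE)
  }
  rbind(one_sex("male", n_male), one_sex("female", n_female))
}

#' Generate a synthetic healthy cohort
#'
#' @param spec a [cohort_spec()].
#' @param enforce_validity apply the two physiologic rejection rules below
#'   (default). With `FALSE` the cohort is the *exact* generative model —
#'   demographics drawn from the truncated normals and each volume equal
#'   to its equation plus noise, nothing rejected — which is the right
#'   input for estimator-calibration and coefficient-recovery studies, at
#'   the price that a few spirograms may fail row validation (FEV1 above
#'   FVC) where the printed equations are mutually inconsistent.
#' @return A [cohort()] table of `spec$n` subjects with provenance
#'   `"synthetic healthy"`.
#' @details Two rejection rules keep spirograms physiologic. First,
#'   demographics whose *equation-implied* ratio (predicted FEV1 over
#'   predicted FVC) exceeds 98% are redrawn: the published young-age
#'   branches make the two volume equations mutually inconsistent for a
#'   small corner of the demographic space (notably women under about 21,
#'   where the implied ratio passes 100%), and no noise draw can repair a
#'   deterministic inconsistency. Because this rejection depends only on
#'   covariates, it leaves coefficient recovery by [refit_study_models()]
#'   unbiased. Second, noise pairs producing a spirogram that would fail
#'   row validation (non-positive volume, or FEV1 above FVC by more than
#'   the 2% tolerance) are redrawn for the affected subject, mirroring
#'   session-level quality control. This second rule truncates the noise
#'   distribution slightly — in development runs it shifted the male
#'   ln(FVC) old-age slope by about half a standard error at n = 500 —
#'   because the printed male equations imply FEV1/FVC ratios near 94%
#'   over much of the age range, leaving little headroom before the
#'   validity bound. With zero noise SDs every spirogram equals its
#'   equation prediction exactly and only the first rule acts.
#' @examples
#' ch <- generate_healthy(cohort_spec(n = 50, seed = 7))
#' nrow(ch)
#' @export
generate_healthy <- function(spec = cohort_spec(), enforce_validity = TRUE) {
  stopifnot(inherits(spec, "spiro_cohort_spec"))
  with_seed(spec$seed, {
    n_male <- round(spec$n * spec$male_fraction)
    demo <- draw_demographics(n_male, spec$n - n_male, spec)
    if (enforce_validity) {
      # redraw demographics where the equations are mutually inconsistent
      # (implied ratio above RATIO_CAP); covariate-only rejection
      for (attempt in 1:1000) {
        implied <- 100 * predict_fev1_local(demo$sex, demo$age, demo$height) /
          predict_fvc_local(demo$sex, demo$age, demo$height, demo$weight)
        bad <- implied > RATIO_CAP
        if (!any(bad)) break
        redraw <- draw_demographics(sum(bad & demo$sex == "male"),
                                    sum(bad & demo$sex == "female"), spec)
        demo[bad & demo$sex == "male", ] <-
          redraw[redraw$sex == "male", , drop = FALSE]
        demo[bad & demo$sex == "female", ] <-
          redraw[redraw$sex == "female", , drop = FALSE]
      }
      if (any(bad)) {
        stop("could not draw demographics with consistent volume equations",
             call. = FALSE)
      }
    }
    mu_fev1 <- predict_fev1_local(demo$sex, demo$age, demo$height)
    mu_lnfvc <- log(predict_fvc_local(demo$sex, demo$age, demo$height,
                                      demo$weight))
    sd1 <- spec$noise$fev1[demo$sex]
    sd2 <- spec$noise$ln_fvc[demo$sex]
    rho <- spec$noise$residual_cor
    n <- spec$n
    fev1 <- fvc <- rep(NA_real_, n)
    todo <- rep(TRUE, n)
    for (attempt in 1:1000) {
      k <- sum(todo)
      if (!k) break
      z1 <- rnorm(k)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(k)
      f1 <- mu_fev1[todo] + sd1[todo] * z1
      f2 <- exp(mu_lnfvc[todo] + sd2[todo] * z2)
      # accept exactly what row validation accepts: FEV1 may exceed FVC by
      # at most the 2% measurement-noise tolerance
      ok <- if (enforce_validity) f1 > 0 & f1 <= 1.02 * f2 else rep(TRUE, k)
      idx <- which(todo)[ok]
      fev1[idx] <- f1[ok]
      fvc[idx] <- f2[ok]
      todo[idx] <- FALSE
    }
    if (any(todo)) stop("could not draw physiologic spirograms", call. = FALSE)
    df <- data.frame(id = sprintf("H%04d", seq_len(n)), sex = demo$sex,
                     age = demo$age, height = demo$height,
                     weight = demo$weight, fev1 = fev1, fvc = fvc,
                     stringsAsFactors = FALSE)
    new_cohort(df, "synthetic healthy")
  })
}

#' Synthetic COPD-cohort specification
#'
#' Defaults reproduce the COPD validation cohort: 124 patients (84 men,
#' 40 women) aged 24–91 with the cohort's demographic means and SDs, and a
#' GOLD stage mix of 17:44:42:21 over stages 1–4 (the staging marginals
#' under the study equations).
#'
#' @inheritParams cohort_spec
#' @param stage_mix proportions over GOLD stages 1–4; must sum to 1.
#' @param stage_bands percent-predicted FEV1 bands subjects are drawn
#'   uniformly within, per stage (stage 1 capped at 95% so synthetic
#'   patients stay clearly abnormal; stage 4 floored at 15%).
#' @param ratio_band measured FEV1/FVC is drawn uniformly in this percent
#'   band; the default (40, 69) brackets the cohort's measured ratio of
#'   about 58 (SD 11) while guaranteeing the fixed-ratio <70% diagnosis
#'   gate.
#' @return An object of class `spiro_copd_spec`.
#' @examples
#' copd_spec(n = 124, seed = 3)
#' @export
copd_spec <- function(
    n = 124,
    male_fraction = 84 / 124,
    age = list(male = c(mean = 62.65, sd = 12.82),
               female = c(mean = 63.18, sd = 14.00)),
    height = list(male = c(mean = 172.17, sd = 6.54),
                  female = c(mean = 159.03, sd = 6.56)),
    weight = list(male = c(mean = 79.20, sd = 15.73),
                  female = c(mean = 64.78, sd = 12.00)),
    age_bounds = c(24, 91),
    height_bounds = c(140, 205),
    weight_bounds = c(40, 160),
    stage_mix = c(17, 44, 42, 21) / 124,
    stage_bands = list(mild = c(80, 95), moderate = c(50, 80),
                       severe = c(30, 50), very_severe = c(15, 30)),
    ratio_band = c(40, 69),
    seed = NULL) {
  if (abs(sum(stage_mix) - 1) > 1e-9) {
    stop("stage_mix must sum to 1", call. = FALSE)
  }
  stopifnot(n >= 4, length(stage_mix) == 4, all(stage_mix >= 0),
            ratio_band[1] > 0, ratio_band[2] < 70)
  spec <- list(n = n, male_fraction = male_fraction, age = age,
               height = height, weight = weight, age_bounds = age_bounds,
               height_bounds = height_bounds, weight_bounds = weight_bounds,
               stage_mix = stage_mix, stage_bands = stage_bands,
               ratio_band = ratio_band, seed = seed)
  for (b in list(spec$age_bounds, spec$height_bounds, spec$weight_bounds)) {
    if (b[1] >= b[2]) stop("infeasible truncation bounds", call. = FALSE)
  }
  structure(spec, class = "spiro_copd_spec")
}

#' Generate a synthetic COPD cohort
#'
#' Each patient draws a target GOLD stage from `stage_mix`, then a
#' percent-predicted FEV1 uniformly within that stage's band; measured
#' FEV1 is that fraction of the study-equation predicted FEV1, and
#' measured FVC is chosen so the measured ratio is uniform in
#' `ratio_band` — which guarantees the <70% obstruction gate and makes
#' staging under the study equations invert the construction exactly.
#'
#' @param spec a [copd_spec()].
#' @return A [cohort()] table with provenance `"synthetic COPD"` and the
#'   drawn stages attached as attribute `target_stage`.
#' @examples
#' ch <- generate_copd(copd_spec(n = 40, seed = 11))
#' table(attr(ch, "target_stage"))
#' @export
generate_copd <- function(spec = copd_spec()) {
  stopifnot(inherits(spec, "spiro_copd_spec"))
  with_seed(spec$seed, {
    n_male <- round(spec$n * spec$male_fraction)
    demo <- draw_demographics(n_male, spec$n - n_male, spec)
    stage <- sample(GOLD_LEVELS, spec$n, replace = TRUE,
                    prob = spec$stage_mix)
    band <- do.call(rbind, spec$stage_bands)[stage, , drop = FALSE]
    pct <- runif(spec$n, band[, 1], band[, 2])
    pred_fev1 <- predict_fev1_local(demo$sex, demo$age, demo$height)
    fev1 <- pct / 100 * pred_fev1
    ratio <- runif(spec$n, spec$ratio_band[1], spec$ratio_band[2])
    fvc <- 100 * fev1 / ratio
    df <- data.frame(id = sprintf("C%04d", seq_len(spec$n)), sex = demo$sex,
                     age = demo$age, height = demo$height,
                     weight = demo$weight, fev1 = fev1, fvc = fvc,
                     stringsAsFactors = FALSE)
    structure(new_cohort(df, "synthetic COPD"),
              target_stage = factor(stage, levels = GOLD_LEVELS,
                                    ordered = TRUE))
  })
}
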