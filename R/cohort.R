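#' Cohort tables
#'
#' A cohort table is a data frame with one row per subject pairing
#' demographics (sex, age, height, weight) with the best-test spirogram
#' (measured FEV1 and FVC in litres). The measured FEV1/FVC ratio (percent)
#' and BMI (kg/m^2) are always derived, never stored, so they can never
#' disagree with the fields they are computed from.
#'
#' Units are fixed package-wide: age in years, height in centimetres, weight
#' in kilograms, volumes in litres, ratios in percent.
#'
#' @param id character vector of unique subject identifiers.
#' @param sex character vector, `"male"` or `"female"` (file I/O accepts
#'   case-insensitive M/F codes).
#' @param age,height,weight numeric demographics; `weight` may be `NA` for
#'   equations that omit it.
#' @param fev1,fvc measured volumes in litres.
#' @param provenance free-text label recording where the rows came from.
#'
#' @return A `data.frame` of class `spiro_cohort` with columns `id`, `sex`,
#'   `age`, `height`, `weight`, `fev1`, `fvc` and derived columns `ratio`
#'   and `bmi`, plus a `provenance` attribute.
#'
#' @details Validation ranges: age 18–95 years, height 120–220 cm, weight
#'   30–200 kg (when present), both volumes positive, derived ratio in
#'   (0, 120]. A measured FEV1 exceeding FVC by at most 2% is tolerated with
#'   a warning (measurement noise); a larger excess rejects the row.
#'
#' @examples
#' cohort(id = c("a", "b"), sex = c("male", "female"),
#'        age = c(40, 55), height = c(175, 162), weight = c(80, 65),
#'        fev1 = c(3.7, 2.4), fvc = c(4.6, 3.1))
#' @export
cohort <- function(id, sex, age, height, weight = NA_real_, fev1, fvc,
                   provenance = "constructed") {
  df <- data.frame(
    id = as.character(id),
    sex = tolower(as.character(sex)),
    age = as.numeric(age),
    height = as.numeric(height),
    weight = as.numeric(weight),
    fev1 = as.numeric(fev1),
    fvc = as.numeric(fvc),
    stringsAsFactors = FALSE
  )
  problems <- validate_cohort_rows(df)
  if (nrow(problems)) {
    stop(format_row_problems(problems), call. = FALSE)
  }
  warn_fev1_over_fvc(df)
  new_cohort(df, provenance)
}

# Internal constructor: assumes rows already validated.
new_cohort <- function(df, provenance) {
  df$ratio <- 100 * df$fev1 / df$fvc
  df$bmi <- df$weight / (df$height / 100)^2
  rownames(df) <- NULL
  structure(df, class = c("spiro_cohort", "data.frame"),
            provenance = provenance)
}

#' @export
print.spiro_cohort <- function(x, ...) {
  cat(sprintf("<spiro_cohort> %d subjects (%d male, %d female) — %s\n",
              nrow(x), sum(x$sex == "male"), sum(x$sex == "female"),
              attr(x, "provenance") %||% "unlabelled"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One diagnostic row per (row, field) violation; empty when all rows pass.
validate_cohort_rows <- function(df) {
  bad <- function(row, field, message) {
    data.frame(row = row, field = field, message = message,
               stringsAsFactors = FALSE)
  }
  out <- list()
  flag <- function(cond, field, message) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) out[[length(out) + 1L]] <<- bad(which(cond), field, message)
  }
  flag(!df$sex %in% c("male", "female"), "sex",
       "must be one of 'male'/'female' (M/F accepted in files)")
  flag(df$age < 18 | df$age > 95, "age", "must be in [18, 95] years")
  flag(df$height < 120 | df$height > 220, "height", "must be in [120, 220] cm")
  weight_bad <- !is.na(df$weight) & (df$weight < 30 | df$weight > 200)
  if (any(weight_bad)) {
    out[[length(out) + 1L]] <-
      bad(which(weight_bad), "weight", "must be in [30, 200] kg when present")
  }
  flag(df$fev1 <= 0, "fev1", "must be > 0 litres")
  flag(df$fvc <= 0, "fvc", "must be > 0 litres")
  ok_vol <- !is.na(df$fev1) & !is.na(df$fvc) & df$fev1 > 0 & df$fvc > 0
  excess <- ok_vol & df$fev1 > 1.02 * df$fvc
  if (any(excess)) {
    out[[length(out) + 1L]] <-
      bad(which(excess), "fev1", "exceeds FVC by more than 2%")
  }
  ratio <- 100 * df$fev1 / df$fvc
  ratio_bad <- ok_vol & !excess & (ratio <= 0 | ratio > 120)
  if (any(ratio_bad)) {
    out[[length(out) + 1L]] <-
      bad(which(ratio_bad), "ratio", "derived FEV1/FVC must be in (0, 120]%")
  }
  if (anyDuplicated(df$id)) {
    dup <- which(duplicated(df$id) | duplicated(df$id, fromLast = TRUE))
    out[[length(out) + 1L]] <- bad(dup, "id", "duplicated subject id")
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(row = integer(), field = character(), message = character())
}

format_row_problems <- function(problems) {
  lines <- sprintf("  row %d, field %s: %s",
                   problems$row, problems$field, problems$message)
  paste0("cohort validation failed:\n", paste(lines, collapse = "\n"))
}

warn_fev1_over_fvc <- function(df) {
  over <- !is.na(df$fev1) & !is.na(df$fvc) &
    df$fev1 > df$fvc & df$fev1 <= 1.02 * df$fvc
  if (any(over)) {
    warning(sprintf(
      "FEV1 exceeds FVC by <=2%% on row(s) %s; kept (measurement noise)",
      paste(which(over), collapse = ", ")), call. = FALSE)
  }
}

#' Read and write cohort files
#'
#' Cohort files are comma-delimited UTF-8 text with the header
#' `id,sex,age_years,height_cm,weight_kg,fev1_l,fvc_l`, decimal points and
#' no thousands separators. Sex is coded `M`/`F` (case-insensitive;
#' `male`/`female` also accepted). `weight_kg` may be empty.
#'
#' @param path file path.
#' @param strict if `TRUE` (default) any invalid row aborts the read with
#'   row-indexed diagnostics; if `FALSE` invalid rows are dropped with a
#'   warning listing them.
#' @return `read_cohort()` returns a [cohort()] table; `write_cohort()`
#'   returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' ch <- cohort("s1", "male", 40, 175, 80, 3.7, 4.6)
#' write_cohort(ch, tf)
#' read_cohort(tf)
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  required <- c("id", "sex", "age_years", "height_cm", "weight_kg",
                "fev1_l", "fvc_l")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("cohort file is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  df <- data.frame(
    id = raw$id,
    sex = decode_sex(raw$sex),
    age = num(raw$age_years),
    height = num(raw$height_cm),
    weight = num(raw$weight_kg),
    fev1 = num(raw$fev1_l),
    fvc = num(raw$fvc_l),
    stringsAsFactors = FALSE
  )
  # unparsable numerics become NA and fall out of range checks
  problems <- validate_cohort_rows(df)
  if (nrow(problems)) {
    if (strict) stop(format_row_problems(problems), call. = FALSE)
    drop <- unique(problems$row)
    warning(sprintf("dropped %d invalid row(s): %s", length(drop),
                    paste(sort(drop), collapse = ", ")), call. = FALSE)
    df <- df[-drop, , drop = FALSE]
  }
  warn_fev1_over_fvc(df)
  new_cohort(df, provenance = path)
}

decode_sex <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male")] <- "male"
  out[x %in% c("f", "female")] <- "female"
  out[is.na(out)] <- x[is.na(out)]  # left invalid for the validator to name
  out
}

#' @param x a [cohort()] table.
#' @rdname read_cohort
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "spiro_cohort"))
  out <- data.frame(
    id = x$id,
    sex = ifelse(x$sex == "male", "M", "F"),
    age_years = x$age,
    height_cm = x$height,
    weight_kg = x$weight,
    fev1_l = x$fev1,
    fvc_l = x$fvc
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8",
            na = "")
  invisible(path)
}

#' Best-maneuver selection
#'
#' From repeated forced-expiration maneuvers for one subject, selects the
#' largest FEV1 and the largest FVC independently (they may come from
#' different maneuvers, the convention of ATS/ERS test sessions) and
#' recomputes the ratio from the selected pair.
#'
#' @param maneuvers a data frame (or matrix) with columns `fev1` and `fvc`,
#'   one row per maneuver, volumes in litres. Sessions normally hold at most
#'   eight maneuvers; more triggers a warning, not an error.
#' @return A list with `fev1`, `fvc` (litres) and `ratio` (percent).
#' @examples
#' select_best(data.frame(fev1 = c(2.0, 2.2), fvc = c(3.0, 2.9)))
#' @export
select_best <- function(maneuvers) {
  maneuvers <- as.data.frame(maneuvers)
  if (!all(c("fev1", "fvc") %in% names(maneuvers))) {
    stop("maneuvers must have columns 'fev1' and 'fvc'", call. = FALSE)
  }
  if (nrow(maneuvers) == 0L) {
    stop("no maneuvers supplied", call. = FALSE)
  }
  if (nrow(maneuvers) > 8L) {
    warning("more than eight maneuvers supplied; using all of them",
            call. = FALSE)
  }
  if (any(maneuvers$fev1 <= 0) || any(maneuvers$fvc <= 0)) {
    stop("maneuver volumes must be positive", call. = FALSE)
  }
  fev1 <- max(maneuvers$fev1)
  fvc <- max(maneuvers$fvc)
  list(fev1 = fev1, fvc = fvc, ratio = 100 * fev1 / fvc)
}
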