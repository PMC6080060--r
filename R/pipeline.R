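#' Configuration for a full comparison run
#'
#' @param cohort a [cohort()] table or a path to a cohort CSV file.
#' @param sources two or three distinct prediction sources from
#'   `"local"`, `"ecsc"`, `"gli"`; every ordered pair is cross-tabulated.
#' @param weighting kappa weighting for the agreement reports.
#' @param variant local coefficient-table variant.
#' @param require_obstruction apply the measured-ratio <70% gate before
#'   staging (off by default: cohorts being cross-staged are normally
#'   already diagnosed COPD patients).
#' @param outdir optional output directory for the report bundle (created
#'   if needed); `NULL` keeps everything in memory.
#' @param seed optional integer recorded in the summary; the comparison
#'   itself is deterministic.
#' @return An object of class `spiro_run_config`.
#' @examples
#' run_config(generate_copd(copd_spec(n = 40, seed = 1)),
#'            sources = c("local", "ecsc"))
#' @export
run_config <- function(cohort, sources = c("local", "ecsc", "gli"),
                       weighting = c("linear", "none", "quadratic"),
                       variant = c("corrected", "as_printed"),
                       require_obstruction = FALSE,
                       outdir = NULL, seed = NULL) {
  weighting <- match.arg(weighting)
  variant <- match.arg(variant)
  sources <- match.arg(sources, c("local", "ecsc", "gli"),
                       several.ok = TRUE)
  if (anyDuplicated(sources)) {
    stop("prediction sources must be distinct", call. = FALSE)
  }
  if (length(sources) < 2) {
    stop("need at least two prediction sources to compare", call. = FALSE)
  }
  structure(list(cohort = cohort, sources = sources, weighting = weighting,
                 variant = variant,
                 require_obstruction = require_obstruction,
                 outdir = outdir, seed = seed),
            class = "spiro_run_config")
}

#' Run the full prediction/staging/agreement comparison
#'
#' For every configured source: predicts FEV1, FVC and the ratio for each
#' subject, stages airflow limitation by GOLD percent-predicted criteria,
#' then cross-tabulates every source pair and computes the agreement
#' battery (percent agreement, unweighted/linear/quadratic kappa) and
#' concordance reports (Lin's rho_c, Pearson r, r-squared, average
#' difference) both against the measured values (predicted minus measured)
#' and between source pairs. The run is deterministic given its inputs;
#' when `outdir` is set the bundle is written as CSV files plus one JSON
#' summary, and partial outputs are removed if any stage fails.
#'
#' @param config a [run_config()].
#' @return (Invisibly when writing to disk) a list with elements
#'   `n`, `predictions`, `stages`, `crosstabs`, `agreement`,
#'   `concordance_vs_measured`, `concordance_between_sources`, `meta`.
#' @examples
#' res <- run_comparison(run_config(generate_copd(copd_spec(n = 60, seed = 2)),
#'                                  sources = c("local", "ecsc")))
#' res$agreement$local_vs_ecsc$kappa_linear
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "spiro_run_config"))
  ch <- config$cohort
  if (is.character(ch)) ch <- read_cohort(ch)
  stopifnot(inherits(ch, "spiro_cohort"))
  message(sprintf(
    "spiroref run: n = %d, sources = %s, variant = %s, GLI lookup %s",
    nrow(ch), paste(config$sources, collapse = "+"), config$variant,
    if ("gli" %in% config$sources) gli_lookup_version() else "(unused)"))

  preds <- lapply(config$sources, function(s) {
    predict_cohort(ch, s, config$variant)
  })
  names(preds) <- config$sources
  stages <- lapply(config$sources, function(s) {
    st <- gold_stage(ch$fev1, preds[[s]]$fev1_pred, ch$ratio,
                     config$require_obstruction)
    data.frame(id = ch$id, source = s,
               percent_predicted = attr(st, "percent_predicted"),
               stage = as.character(st), stringsAsFactors = FALSE)
  })
  names(stages) <- config$sources

  pairs <- utils::combn(config$sources, 2, simplify = FALSE)
  crosstabs <- agreement <- conc_pairs <- list()
  for (p in pairs) {
    key <- paste0(p[1], "_vs_", p[2])
    staged <- stages[[p[1]]]$stage != "none" & stages[[p[2]]]$stage != "none"
    tab <- cross_tabulate(stages[[p[1]]]$stage[staged],
                          stages[[p[2]]]$stage[staged], p[1], p[2])
    crosstabs[[key]] <- tab
    agreement[[key]] <- if (sum(tab) > 0) agreement_report(tab) else
      list(percent_agreement = NA_real_, diagonal = 0L, n = 0L,
           kappa_unweighted = NA_real_, kappa_linear = NA_real_,
           kappa_quadratic = NA_real_)
    conc_pairs[[key]] <- lapply(
      c(fev1 = "fev1_pred", fvc = "fvc_pred", ratio = "ratio_pred"),
      function(col) lins_ccc(preds[[p[1]]][[col]], preds[[p[2]]][[col]]))
  }
  conc_measured <- lapply(preds, function(p) {
    list(fev1 = lins_ccc(p$fev1_pred, ch$fev1),
         fvc = lins_ccc(p$fvc_pred, ch$fvc),
         ratio = lins_ccc(p$ratio_pred, ch$ratio))
  })

  result <- list(
    n = nrow(ch),
    predictions = do.call(rbind, lapply(preds, function(p) {
      p[setdiff(names(p), c("lln_fev1", "zscore_fev1"))]
    })),
    stages = do.call(rbind, stages),
    crosstabs = crosstabs,
    agreement = agreement,
    concordance_vs_measured = conc_measured,
    concordance_between_sources = conc_pairs,
    meta = list(sources = config$sources, weighting = config$weighting,
                variant = config$variant,
                gli_lookup_version = if ("gli" %in% config$sources)
                  gli_lookup_version() else NA,
                require_obstruction = config$require_obstruction,
                seed = config$seed)
  )
  rownames(result$predictions) <- rownames(result$stages) <- NULL

  if (!is.null(config$outdir)) {
    write_report_bundle(result, config$outdir)
    return(invisible(result))
  }
  result
}

# CSV + JSON report bundle; removes everything it wrote if any write fails.
write_report_bundle <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(file, writer) {
    path <- file.path(outdir, file)
    writer(path)
    written <<- c(written, path)
  }
  tryCatch({
    emit("predictions.csv", function(p) {
      write.csv(result$predictions, p, row.names = FALSE, quote = FALSE)
    })
    emit("stages.csv", function(p) {
      write.csv(result$stages, p, row.names = FALSE, quote = FALSE)
    })
    for (key in names(result$crosstabs)) {
      emit(paste0("crosstab_", key, ".csv"), function(p) {
        tab <- result$crosstabs[[key]]
        write.csv(data.frame(stage = rownames(tab), unclass(tab),
                             check.names = FALSE),
                  p, row.names = FALSE, quote = FALSE)
      })
    }
    emit("summary.json", function(p) {
      jsonlite::write_json(
        list(n = result$n, agreement = result$agreement,
             concordance_vs_measured = result$concordance_vs_measured,
             concordance_between_sources = result$concordance_between_sources,
             meta = result$meta),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    })
  }, error = function(e) {
    unlink(written)
    stop("report bundle failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(outdir)
}
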