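# Curve and config file round-tripping and the end-to-end ROI pipeline.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    dce_stop(sprintf("[%s] %s", stage, conditionMessage(e)), "dce_pipeline_error")
  })
}

#' Read a curve file
#'
#' Two-column delimited text with header `time_s,signal` (signal curve),
#' `time_s,conc_mM` (concentration curve) or `time_s,value` (treated as a
#' concentration curve). Rows are sorted by time; duplicated timestamps and
#' non-numeric rows are errors.
#'
#' @param path File path.
#' @param baseline Optional pre-contrast baseline signal attached to a
#'   signal curve.
#' @return A [signal_curve()] or [conc_curve()] according to the header.
#' @export
read_curve <- function(path, baseline = NA_real_) {
  if (!file.exists(path)) {
    dce_stop(sprintf("curve file not found: %s", path), "dce_file_not_found")
  }
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (length(header) != 2L || header[1] != "time_s" ||
      !header[2] %in% c("signal", "conc_mM", "value")) {
    dce_stop(sprintf(
      "expected header 'time_s,signal', 'time_s,conc_mM' or 'time_s,value' in %s",
      path), "dce_parse_error")
  }
  df <- utils::read.csv(path, header = TRUE, colClasses = "character")
  t <- suppressWarnings(as.numeric(df[[1]]))
  v <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(t) | is.na(v))
  if (length(bad)) {
    dce_stop(sprintf("malformed row at line %d of %s", bad[1] + 1L, path),
             "dce_parse_error")
  }
  ord <- order(t)
  t <- t[ord]; v <- v[ord]
  if (anyDuplicated(t)) {
    dce_stop(sprintf("duplicated timestamp %.12g s in %s", t[which(duplicated(t))[1]], path),
             "dce_validation_error")
  }
  if (header[2] == "signal") signal_curve(t, v, baseline) else conc_curve(t, v)
}

#' Write a curve file
#'
#' Inverse of [read_curve()]; values are written with 15 significant digits
#' so a write/read round-trip is lossless well beyond 12 digits.
#'
#' @param curve A [signal_curve()] or [conc_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  col <- if (inherits(curve, "signal_curve")) "signal" else if
    (inherits(curve, "conc_curve")) "conc_mM" else
    dce_stop("curve must be a signal_curve or conc_curve", "dce_invalid_parameter")
  lines <- c(paste0("time_s,", col),
             sprintf("%.15g,%.15g", curve$times, curve$values))
  writeLines(lines, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param acq [acq_params()].
#' @param fit [fit_config()].
#' @param hct Haematocrit fraction for blood-to-plasma conversion.
#' @param models Non-empty subset of `c("steady_state", "patlak", "mtofts")`.
#' @param T10_tissue Pre-contrast tissue T1 (s); alternatively supply
#'   `vfa_signals` to estimate it.
#' @param t10_blood Pre-contrast blood T1 (s) used to convert the VIF signal
#'   to concentration.
#' @param vfa_signals Optional list with elements `S_a`, `S_b` (pre-contrast
#'   signals at the low/high flip angle); used to estimate `T10_tissue` when
#'   that is `NULL`.
#' @param tissue_baseline,vif_baseline Pre-contrast baseline signals S0 for
#'   the two curves.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(acq = acq_params(), fit = fit_config(),
                            hct = 0.45,
                            models = c("steady_state", "patlak", "mtofts"),
                            T10_tissue = NULL, t10_blood = 1.4,
                            vfa_signals = NULL,
                            tissue_baseline = NA_real_,
                            vif_baseline = NA_real_) {
  models <- match.arg(models, c("steady_state", "patlak", "mtofts"),
                      several.ok = TRUE)
  if (!length(models)) dce_stop("models must be non-empty", "dce_invalid_parameter")
  if (is.null(T10_tissue) && is.null(vfa_signals)) {
    dce_stop("supply T10_tissue or vfa_signals", "dce_invalid_parameter")
  }
  structure(list(acq = acq, fit = fit, hct = hct, models = models,
                 T10_tissue = T10_tissue, t10_blood = t10_blood,
                 vfa_signals = vfa_signals,
                 tissue_baseline = tissue_baseline,
                 vif_baseline = vif_baseline),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Keys mirror the [pipeline_config()] arguments; `acq` and `fit` are nested
#' objects whose keys mirror [acq_params()] and [fit_config()].
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    dce_stop(sprintf("config file not found: %s", path), "dce_file_not_found")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw
  args$acq <- if (is.null(raw$acq)) acq_params() else do.call(acq_params, as.list(raw$acq))
  args$fit <- if (is.null(raw$fit)) fit_config() else do.call(fit_config, as.list(raw$fit))
  do.call(pipeline_config, args[names(args) %in% names(formals(pipeline_config))])
}

#' Run the full ROI analysis pipeline
#'
#' Raw signal curves to report: enhancement, T1 estimation (given or VFA),
#' signal-to-concentration conversion for tissue and VIF, blood-to-plasma
#' correction, multi-start fits of the requested nested models, AICc model
#' comparison, CNR estimate and semi-quantitative metrics.
#'
#' @param cfg A [pipeline_config()].
#' @param tissue_path,vif_path Paths to signal curve files (header
#'   `time_s,signal`).
#' @param out Optional path for a JSON report.
#' @return The report as a list (invisibly written to `out` if given).
#' @export
run_pipeline <- function(cfg, tissue_path, vif_path, out = NULL) {
  tissue <- with_stage("read_tissue",
                       read_curve(tissue_path, baseline = cfg$tissue_baseline))
  vifc <- with_stage("read_vif", read_curve(vif_path, baseline = cfg$vif_baseline))
  if (!inherits(tissue, "signal_curve") || !inherits(vifc, "signal_curve")) {
    dce_stop("pipeline inputs must be signal curves (header time_s,signal)",
             "dce_invalid_parameter")
  }
  T10 <- with_stage("t1_estimation", {
    if (!is.null(cfg$T10_tissue)) cfg$T10_tissue
    else vfa_t1(cfg$vfa_signals$S_a, cfg$vfa_signals$S_b, cfg$acq)
  })
  E_tissue <- with_stage("enhancement", enhancement(tissue))
  E_vif <- with_stage("enhancement", enhancement(vifc))
  Ct <- with_stage("concentration",
                   signal_to_concentration(tissue, T10, cfg$acq))
  Cp <- with_stage("concentration", {
    Cb <- signal_to_concentration(vifc, cfg$t10_blood, cfg$acq)
    conc_curve(Cb$times, blood_to_plasma(Cb$values, cfg$hct))
  })
  fits <- with_stage("fitting", fit_nested_models(Ct, Cp, cfg$models, cfg$fit))
  comparison <- if (length(fits) > 1L) {
    with_stage("model_selection", compare_models(fits))
  } else NULL
  cnr <- if ("patlak" %in% names(fits)) {
    with_stage("cnr", estimate_cnr(Ct, fits$patlak))
  } else NA_real_
  semi <- with_stage("semiquant", list(
    auc_norm = auc_norm(E_tissue, E_vif, tissue$times, cfg$fit$exclude_first),
    late_slope = late_slope(E_tissue, tissue$times, cfg$fit$exclude_first)))
  report <- list(
    T10_tissue = T10,
    seed = cfg$fit$seed,
    enhancement = list(tissue = E_tissue, vif = E_vif),
    concentration = list(tissue = as.data.frame(Ct), vif_plasma = as.data.frame(Cp)),
    fits = lapply(fits, function(f) {
      list(model = f$model, params = f$params, ss = f$ss,
           n_included = f$n_included, converged = f$converged)
    }),
    comparison = if (!is.null(comparison)) {
      list(models = comparison$models, aicc = comparison$aicc,
           delta = comparison$delta, weights = comparison$weights,
           best_model = comparison$best_model)
    },
    cnr = cnr,
    semiquant = semi)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  report
}
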