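# Pixel-level evaluation inside the pathologically confirmed area: TP/FN/
# FP/TN bookkeeping, specificity/sensitivity/accuracy, region-stratified
# sensitivity, cohort summaries, difference spectra, thickness analysis.

#' Confusion counts for one specimen
#'
#' Counts are restricted to valid pixels inside the evaluated area. Tumor
#' (exposed and unexposed pooled) is the positive class. For the
#' `"exposed"` / `"unexposed"` strata only tumor pixels of that region are
#' tallied (TP/FN; FP and TN are structurally 0).
#'
#' @param pred A `prediction_map`.
#' @param annotation The matching [annotation_map].
#' @param mask The matching [validity_mask].
#' @param stratum `"all"`, `"exposed"` or `"unexposed"`.
#' @return An object of class `confusion_counts`: `tp`, `fn`, `fp`, `tn`,
#'   `specimen_id`, `stratum`.
#' @export
confusion_counts <- function(pred, annotation, mask, stratum = "all") {
  stratum <- match.arg(stratum, c("all", "exposed", "unexposed"))
  lab <- annotation$labels
  p <- pred$class
  stopifnot(identical(dim(lab), dim(p)), identical(dim(lab), dim(mask$valid)))
  v <- mask$valid & !is.na(p)
  pos_lab <- switch(stratum,
    all = tumor_label_matrix(lab),
    exposed = lab == LABELS[["exposed_tumor"]],
    unexposed = lab == LABELS[["unexposed_tumor"]])
  neg_lab <- if (stratum == "all") lab == LABELS[["normal"]]
             else matrix(FALSE, nrow(lab), ncol(lab))
  structure(list(
    tp = sum(v & pos_lab & p == 1L),
    fn = sum(v & pos_lab & p == 0L),
    fp = sum(v & neg_lab & p == 1L),
    tn = sum(v & neg_lab & p == 0L),
    specimen_id = pred$specimen_id, stratum = stratum),
    class = "confusion_counts")
}

#' Build confusion counts from known tallies
#'
#' For re-computing metrics from published per-specimen pixel counts.
#'
#' @param tp,fn,fp,tn Non-negative integer pixel counts.
#' @param specimen_id,stratum Provenance tags.
#' @return A `confusion_counts`.
#' @export
as_confusion_counts <- function(tp, fn, fp = 0L, tn = 0L,
                                specimen_id = NA_character_,
                                stratum = "all") {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 specimen_id = specimen_id, stratum = stratum),
            class = "confusion_counts")
}

#' Specificity, sensitivity and accuracy from confusion counts
#'
#' `specificity = TN/(FP+TN) * 100`, `sensitivity = TP/(TP+FN) * 100`,
#' `accuracy = (TP+TN)/(TP+TN+FP+FN) * 100`, in percent. A metric whose
#' denominator is zero is `NA` (undefined), never 0 — e.g. specificity and
#' accuracy for the exposed/unexposed strata, which contain no negatives.
#'
#' @param counts A `confusion_counts`.
#' @return A one-row `data.frame` (class `metrics_row`): `specimen_id`,
#'   `stratum`, `tp`, `fn`, `fp`, `tn`, `specificity`, `sensitivity`,
#'   `accuracy`.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- data.frame(
    specimen_id = counts$specimen_id, stratum = counts$stratum,
    tp = counts$tp, fn = counts$fn, fp = counts$fp, tn = counts$tn,
    specificity = rate(counts$tn, counts$fp + counts$tn),
    sensitivity = rate(counts$tp, counts$tp + counts$fn),
    accuracy = rate(counts$tp + counts$tn,
                    counts$tp + counts$tn + counts$fp + counts$fn),
    stringsAsFactors = FALSE)
  class(out) <- c("metrics_row", class(out))
  out
}

#' Region-stratified sensitivity
#'
#' Sensitivity (percent) computed separately for the exposed and unexposed
#' tumor regions of one specimen. A region with no tumor pixels yields `NA`
#' and is excluded from cohort means.
#'
#' @param counts_exposed,counts_unexposed `confusion_counts` for the two
#'   strata.
#' @return Named numeric vector `c(exposed = ..., unexposed = ...)`.
#' @export
region_sensitivity <- function(counts_exposed, counts_unexposed) {
  sens <- function(cc) {
    den <- cc$tp + cc$fn
    if (den > 0) 100 * cc$tp / den else NA_real_
  }
  c(exposed = sens(counts_exposed), unexposed = sens(counts_unexposed))
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Cohort summary of per-specimen metrics
#'
#' Unweighted mean +/- population standard deviation of each metric across
#' the specimens where it is defined (undefined values are excluded, not
#' zero-filled). Pooled-count metrics — the same formulas applied to the
#' summed confusion counts — are reported as a secondary field; note they
#' generally differ from the per-specimen means.
#'
#' @param rows A list of `metrics_row` (or a row-bound data.frame of them).
#' @return A list of class `cohort_summary`: `per_metric` (data.frame with
#'   `metric`, `mean`, `sd`, `n`), `pooled` (a `metrics_row` on summed
#'   counts), `n_specimens`.
#' @export
summarize_cohort <- function(rows) {
  df <- if (is.data.frame(rows)) rows else do.call(rbind, rows)
  per <- do.call(rbind, lapply(
    c("specificity", "sensitivity", "accuracy"), function(m) {
      v <- df[[m]][!is.na(df[[m]])]
      data.frame(metric = m,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v)) sd_pop(v) else NA_real_,
                 n = length(v))
    }))
  pooled <- metrics(as_confusion_counts(sum(df$tp), sum(df$fn),
                                        sum(df$fp), sum(df$tn),
                                        specimen_id = "pooled",
                                        stratum = df$stratum[1L]))
  structure(list(per_metric = per, pooled = pooled, n_specimens = nrow(df)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d specimens\n", x$n_specimens))
  with(x$per_metric,
       cat(sprintf("  %-12s %5.1f +/- %4.1f  (n=%d)\n", metric, mean, sd, n),
           sep = ""))
  invisible(x)
}

#' Difference spectrum between a tumor region and the normal training mean
#'
#' `delta(lambda)` = mean SNV spectrum over the valid pixels of the chosen
#' tumor region of the test specimen, minus the mean SNV spectrum of the
#' normal training pixels of that specimen's fold. Visualizes which bands
#' drive the classification.
#'
#' @param test_snv The test specimen's SNV [hsi_cube] (trimmed window).
#' @param annotation,mask The specimen's annotation and validity mask.
#' @param region `"exposed"` or `"unexposed"`.
#' @param normal_training_mean Numeric vector: the fold's mean normal
#'   training spectrum (see [run_loocv()]).
#' @return A list of class `difference_spectrum`: `wavelengths`, `delta`,
#'   `region`, `n_pixels`; or `NULL`-delta (`n_pixels = 0`) when the region
#'   is absent.
#' @export
difference_spectrum <- function(test_snv, annotation, mask, region,
                                normal_training_mean) {
  region <- match.arg(region, c("exposed", "unexposed"))
  lab_code <- LABELS[[paste0(region, "_tumor")]]
  idx <- which(mask$valid & annotation$labels == lab_code)
  d <- dim(test_snv$data)
  delta <- if (length(idx)) {
    x <- matrix(test_snv$data, d[1L] * d[2L], d[3L])[idx, , drop = FALSE]
    colMeans(x) - normal_training_mean
  } else NULL
  structure(list(wavelengths = test_snv$wavelengths, delta = delta,
                 region = region, n_pixels = length(idx)),
            class = "difference_spectrum")
}

#' Tumor-thickness analysis of identified and unidentified areas
#'
#' Identified pixels are the true positives, unidentified the false
#' negatives; each set's (min, max) tumor thickness in mm is reported.
#' The 80%-sensitivity rule decides which ranges a slide-based measurement
#' protocol would use: above 80% sensitivity only the identified range
#' (`rule = "identified_only"`), otherwise both (`rule = "both"`). Both
#' ranges are always computed here since synthetic truth is complete.
#'
#' @param pred A `prediction_map`.
#' @param annotation The matching [annotation_map] (with a thickness
#'   raster).
#' @param mask The matching [validity_mask].
#' @param row The specimen's `metrics_row` (supplies the sensitivity).
#' @return A list of class `thickness_report`: `identified_range_mm`,
#'   `unidentified_range_mm` (each `c(min, max)` or `NULL` if the set is
#'   empty), `sensitivity`, `rule`.
#' @export
thickness_analysis <- function(pred, annotation, mask, row) {
  v <- mask$valid & !is.na(pred$class)
  tumor <- tumor_label_matrix(annotation$labels)
  th <- annotation$thickness_mm
  rng <- function(sel) if (any(sel)) range(th[sel]) else NULL
  identified <- rng(v & tumor & pred$class == 1L)
  unidentified <- rng(v & tumor & pred$class == 0L)
  sens <- row$sensitivity
  structure(list(identified_range_mm = identified,
                 unidentified_range_mm = unidentified,
                 sensitivity = sens,
                 rule = if (!is.na(sens) && sens > 80) "identified_only"
                        else "both"),
            class = "thickness_report")
}

#' Detection transition thickness of a trained classifier
#'
#' Sweeps noise-free single-pixel probes of increasing tumor thickness
#' through the generator's forward model (fixed covering-mucosa thickness),
#' preprocesses each probe exactly as the pipeline would (window trim +
#' SNV), and returns the smallest thickness from which the classifier calls
#' tumor for every thicker probe — the generator-configured detection
#' limit.
#'
#' @param model A `pixel_classifier` trained on the trimmed SNV window.
#' @param config The [specimen_config] whose forward model to probe (its
#'   nominal endmembers, i.e. `jitter = 0`).
#' @param params The [preprocess_params] used in the pipeline.
#' @param t_grid Tumor thicknesses (mm) to probe.
#' @param t_cover Covering-mucosa thickness (mm) of the probes.
#' @return Transition thickness in mm (`Inf` if no probe is called tumor).
#' @export
detection_transition <- function(model, config,
                                 params = preprocess_params(),
                                 t_grid = seq(0.1, 10, by = 0.05),
                                 t_cover = 0) {
  em <- config$endmembers %||% make_endmembers(config$wavelengths,
                                               jitter_sd = 0)
  keep <- config$wavelengths >= params$keep_window[1] &
    config$wavelengths <= params$keep_window[2]
  w <- tumor_weight(t_grid, t_cover, config$k_t, config$attenuation_k)
  a <- outer(w, em$tumor - em$normal) +
    rep(em$normal, each = length(w))
  a <- a[, keep, drop = FALSE]
  z <- t(apply(a, 1L, function(x) (x - mean(x)) / stats::sd(x)))
  called <- decision_values(model, z) > 0
  if (!any(called)) return(Inf)
  last_miss <- if (all(called)) 0L else max(which(!called))
  if (last_miss == length(t_grid)) return(Inf)
  t_grid[last_miss + 1L]
}

#' Reference per-specimen confusion counts
#'
#' Bundled worked example: per-specimen TP/FN/FP/TN pixel counts (overall
#' and stratified by exposed/unexposed tumor region) as reported for a
#' published 10-specimen gastric-cancer NIR-HSI study, for validating the
#' metric formulas and cohort summaries against printed results. Specimens
#' g-j have no unexposed region (`NA` counts). The exposed/unexposed counts
#' partition the overall tumor counts exactly.
#'
#' @return A `data.frame` with columns `specimen_id`, `tp`, `fn`, `fp`,
#'   `tn`, `tp_exposed`, `fn_exposed`, `tp_unexposed`, `fn_unexposed`.
#' @export
reference_confusion_counts <- function() {
  data.frame(
    specimen_id = letters[1:10],
    tp = c(4070L, 1520L, 30443L, 10952L, 10095L, 31940L, 1153L, 17642L,
           13460L, 39418L),
    fn = c(2041L, 379L, 5506L, 1804L, 1387L, 10354L, 3326L, 3438L, 485L,
           6797L),
    fp = c(1310L, 777L, 7007L, 1075L, 15712L, 6487L, 7624L, 2143L, 6760L,
           6672L),
    tn = c(7607L, 3891L, 19267L, 17886L, 11450L, 49284L, 64705L, 10518L,
           19821L, 3482L),
    tp_exposed = c(2096L, 901L, 24236L, 7816L, 1387L, 30436L, 1153L,
                   17642L, 13460L, 39418L),
    fn_exposed = c(300L, 121L, 4855L, 414L, 535L, 7701L, 3326L, 3438L,
                   485L, 6797L),
    tp_unexposed = c(1974L, 619L, 6207L, 3136L, 8708L, 1504L, NA, NA, NA,
                     NA),
    fn_unexposed = c(1741L, 258L, 651L, 1390L, 852L, 2653L, NA, NA, NA,
                     NA),
    stringsAsFactors = FALSE)
}

#' Evaluate a cross-validated cohort
#'
#' Convenience wrapper: per-specimen overall metrics, region-stratified
#' sensitivities, cohort summaries, difference spectra and thickness
#' reports for a [run_loocv()] result.
#'
#' @param cv A `loocv_result`.
#' @param prep The matching list of `preprocessed_specimen`.
#' @return A list of class `cohort_evaluation`: `per_specimen`
#'   (data.frame), `summary_all` (a `cohort_summary`), `region`
#'   (data.frame of exposed/unexposed sensitivities), `region_means`,
#'   `difference_spectra`, `thickness`.
#' @export
evaluate_cohort <- function(cv, prep) {
  n <- length(prep)
  rows <- vector("list", n)
  region <- vector("list", n)
  dspec <- vector("list", n)
  thick <- vector("list", n)
  for (i in seq_len(n)) {
    p <- prep[[i]]; pr <- cv$predictions[[i]]
    cc_all <- confusion_counts(pr, p$annotation, p$mask, "all")
    cc_e <- confusion_counts(pr, p$annotation, p$mask, "exposed")
    cc_u <- confusion_counts(pr, p$annotation, p$mask, "unexposed")
    rows[[i]] <- metrics(cc_all)
    rs <- region_sensitivity(cc_e, cc_u)
    region[[i]] <- data.frame(
      specimen_id = p$id,
      tp_exposed = cc_e$tp, fn_exposed = cc_e$fn,
      sens_exposed = rs[["exposed"]],
      tp_unexposed = cc_u$tp, fn_unexposed = cc_u$fn,
      sens_unexposed = rs[["unexposed"]])
    nm <- cv$folds[[i]]$normal_training_mean
    dspec[[i]] <- list(
      exposed = difference_spectrum(p$snv, p$annotation, p$mask,
                                    "exposed", nm),
      unexposed = difference_spectrum(p$snv, p$annotation, p$mask,
                                      "unexposed", nm))
    thick[[i]] <- thickness_analysis(pr, p$annotation, p$mask, rows[[i]])
  }
  per_specimen <- do.call(rbind, rows)
  region_df <- do.call(rbind, region)
  mean_na <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE)
                         else NA_real_
  structure(list(
    per_specimen = per_specimen,
    summary_all = summarize_cohort(per_specimen),
    region = region_df,
    region_means = c(exposed = mean_na(region_df$sens_exposed),
                     unexposed = mean_na(region_df$sens_unexposed)),
    difference_spectra = stats::setNames(dspec, per_specimen$specimen_id),
    thickness = stats::setNames(thick, per_specimen$specimen_id)),
    class = "cohort_evaluation")
}
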