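# toy prediction/annotation pair used by several blocks
toy_eval <- function() {
  labels <- matrix(LABELS[["normal"]], 4, 4)
  labels[1, 1:2] <- LABELS[["exposed_tumor"]]
  labels[2, 1:2] <- LABELS[["unexposed_tumor"]]
  labels[4, 4] <- LABELS[["outside_evaluated"]]
  th <- matrix(0, 4, 4); th[labels %in% 2:3] <- c(1, 3, 5, 2)
  ann <- annotation_map(labels, thickness_mm = th)
  pred <- matrix(0L, 4, 4)
  pred[1, 1] <- 1L; pred[2, 1] <- 1L  # one exposed TP, one unexposed TP
  pred[3, 3] <- 1L                    # one FP
  pred[4, 4] <- NA
  valid <- matrix(TRUE, 4, 4); valid[4, 4] <- FALSE
  reason <- matrix(NA_character_, 4, 4); reason[4, 4] <- "outside_evaluated"
  list(pred = structure(list(class = pred, specimen_id = "t", sigma2 = 1),
                        class = "prediction_map"),
       ann = ann, mask = validity_mask(valid, reason))
}

test_that("confusion counts match an exhaustive per-pixel tally", {
  e <- toy_eval()
  cc <- confusion_counts(e$pred, e$ann, e$mask, "all")
  # brute-force tally oracle
  tp <- fn <- fp <- tn <- 0
  for (r in 1:4) for (c_ in 1:4) {
    if (!e$mask$valid[r, c_]) next
    truth <- e$ann$labels[r, c_]
    if (truth %in% 2:3) {
      if (e$pred$class[r, c_] == 1) tp <- tp + 1 else fn <- fn + 1
    } else if (truth == 1) {
      if (e$pred$class[r, c_] == 1) fp <- fp + 1 else tn <- tn + 1
    }
  }
  expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")]),
               c(tp = tp, fn = fn, fp = fp, tn = tn))
  # accounting identity: counts cover every valid evaluated pixel
  expect_equal(cc$tp + cc$fn + cc$fp + cc$tn, sum(e$mask$valid))
  # strata tally only their own tumor pixels, and TP split adds up
  cc_e <- confusion_counts(e$pred, e$ann, e$mask, "exposed")
  cc_u <- confusion_counts(e$pred, e$ann, e$mask, "unexposed")
  expect_equal(c(cc_e$tp, cc_e$fn, cc_e$fp, cc_e$tn), c(1, 1, 0, 0))
  expect_equal(c(cc_u$tp, cc_u$fn), c(1, 1))
  expect_equal(cc_e$tp + cc_u$tp, cc$tp)
  expect_equal(cc_e$fn + cc_u$fn, cc$fn)
})

test_that("a specimen without a region yields zero counts and NA sensitivity", {
  labels <- matrix(LABELS[["normal"]], 3, 3)
  labels[2, 2] <- LABELS[["exposed_tumor"]]
  th <- matrix(0, 3, 3); th[2, 2] <- 4
  ann <- annotation_map(labels, thickness_mm = th)
  mask <- validity_mask(matrix(TRUE, 3, 3), matrix(NA_character_, 3, 3))
  pred <- structure(list(class = matrix(1L, 3, 3), specimen_id = "x",
                         sigma2 = 1), class = "prediction_map")
  cc_u <- confusion_counts(pred, ann, mask, "unexposed")
  expect_equal(c(cc_u$tp, cc_u$fn, cc_u$fp, cc_u$tn), rep(0, 4))
  rs <- region_sensitivity(confusion_counts(pred, ann, mask, "exposed"), cc_u)
  expect_equal(rs[["exposed"]], 100)
  expect_true(is.na(rs[["unexposed"]]))
})

test_that("metric formulas reproduce published per-specimen values", {
  # row (d) of the bundled reference counts
  m <- metrics(as_confusion_counts(10952, 1804, 1075, 17886))
  expect_equal(round(m$specificity, 1), 94.3)
  expect_equal(round(m$sensitivity, 1), 85.9)
  expect_equal(round(m$accuracy, 1), 90.9)
  # row (g): low sensitivity case
  expect_equal(round(metrics(as_confusion_counts(1153, 3326, 7624,
                                                 64705))$sensitivity, 1),
               25.7)
  # zero denominators are undefined, never zero
  m0 <- metrics(as_confusion_counts(0, 0, 0, 5))
  expect_equal(m0$specificity, 100)
  expect_true(is.na(m0$sensitivity))
  m1 <- metrics(as_confusion_counts(0, 0, 0, 0))
  expect_true(is.na(m1$accuracy))
})

test_that("region sensitivities reproduce published stratified values", {
  expect_equal(round(region_sensitivity(
    as_confusion_counts(2096, 300, stratum = "exposed"),
    as_confusion_counts(0, 0, stratum = "unexposed"))[["exposed"]], 1), 87.5)
  expect_equal(round(region_sensitivity(
    as_confusion_counts(0, 0, stratum = "exposed"),
    as_confusion_counts(1504, 2653, stratum = "unexposed"))[["unexposed"]],
    1), 36.2)
})

test_that("cohort summaries use per-specimen means with population SD", {
  ref <- reference_confusion_counts()
  rows <- lapply(seq_len(nrow(ref)), function(i)
    metrics(as_confusion_counts(ref$tp[i], ref$fn[i], ref$fp[i], ref$tn[i],
                                specimen_id = ref$specimen_id[i])))
  s <- summarize_cohort(rows)
  pm <- s$per_metric
  expect_equal(round(pm$mean[pm$metric == "specificity"], 1), 74.8)
  expect_equal(round(pm$sd[pm$metric == "specificity"], 1), 19.3)
  expect_equal(round(pm$mean[pm$metric == "sensitivity"], 1), 77.2)
  expect_equal(round(pm$sd[pm$metric == "sensitivity"], 1), 18.7)
  expect_equal(round(pm$mean[pm$metric == "accuracy"], 1), 79.7)
  expect_equal(round(pm$sd[pm$metric == "accuracy"], 1), 8.9)
  # pooled-count metrics are a different (secondary) quantity
  expect_false(round(s$pooled$specificity, 1) ==
                 round(pm$mean[pm$metric == "specificity"], 1))
  # single row: SD 0; undefined metrics are excluded from means
  s1 <- summarize_cohort(rows[1])
  expect_equal(s1$per_metric$sd, rep(0, 3))
  rows_na <- c(rows, list(metrics(as_confusion_counts(0, 0, 0, 5))))
  sna <- summarize_cohort(rows_na)
  expect_equal(sna$per_metric$n[sna$per_metric$metric == "sensitivity"], 10L)
})

test_that("difference spectra recover a known SNV-domain offset", {
  p <- cached("prep_diff", preprocess_specimen(
    simulate_specimen(small_config(seed = 51, noise_sd = 0,
                                   artifact_counts = list(highlight = 0L,
                                                          shadow = 0L,
                                                          necrosis = 0L)),
                      id = "d")))
  em <- make_endmembers(small_config()$wavelengths, seed = 51L)
  # identical means -> zero difference
  nm <- rep(0, n_bands(p$snv))
  ds0 <- difference_spectrum(p$snv, p$annotation, p$mask, "exposed", nm)
  expect_gt(ds0$n_pixels, 0)
  # oracle: noiseless exposed pixels' SNV mean from the generator's weights
  lab <- p$annotation$labels
  idx <- which(p$mask$valid & lab == LABELS[["exposed_tumor"]])
  d <- dim(p$snv$data)
  x <- matrix(p$snv$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
  expect_equal(ds0$delta, colMeans(x), tolerance = 1e-12)
  # against the normal-pixel SNV mean the sign pattern appears
  nm_true <- local({
    keep <- p$snv$wavelengths
    a <- em$normal[match(keep, small_config()$wavelengths)]
    (a - mean(a)) / stats::sd(a)
  })
  ds <- difference_spectrum(p$snv, p$annotation, p$mask, "exposed", nm_true)
  wlk <- ds$wavelengths
  expect_lt(ds$delta[band_nearest(wlk, 1075)], 0)
  expect_gt(ds$delta[band_nearest(wlk, 1300)], 0)
  # absent region -> not-applicable result
  ds_none <- difference_spectrum(p$snv, p$annotation, p$mask, "unexposed",
                                 nm_true)
  if (ds_none$n_pixels == 0) expect_null(ds_none$delta)
})

test_that("thickness analysis separates identified and unidentified sets", {
  labels <- matrix(LABELS[["normal"]], 3, 3)
  labels[1, 1:3] <- LABELS[["exposed_tumor"]]
  th <- matrix(0, 3, 3); th[1, ] <- c(1, 3, 5)
  ann <- annotation_map(labels, thickness_mm = th)
  mask <- validity_mask(matrix(TRUE, 3, 3), matrix(NA_character_, 3, 3))
  pred <- matrix(0L, 3, 3); pred[1, 1] <- 1L; pred[1, 3] <- 1L  # middle FN
  pm <- structure(list(class = pred, specimen_id = "t", sigma2 = 1),
                  class = "prediction_map")
  row <- metrics(confusion_counts(pm, ann, mask))
  rep_ <- thickness_analysis(pm, ann, mask, row)
  expect_equal(rep_$identified_range_mm, c(1, 5))
  expect_equal(rep_$unidentified_range_mm, c(3, 3))
  expect_equal(rep_$rule, "both")  # sensitivity 66.7% < 80%
  # perfect sensitivity: empty unidentified set, identified-only rule
  pred2 <- matrix(0L, 3, 3); pred2[1, ] <- 1L
  pm2 <- structure(list(class = pred2, specimen_id = "t", sigma2 = 1),
                   class = "prediction_map")
  row2 <- metrics(confusion_counts(pm2, ann, mask))
  rep2 <- thickness_analysis(pm2, ann, mask, row2)
  expect_null(rep2$unidentified_range_mm)
  expect_equal(rep2$rule, "identified_only")
})
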