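# Two-class kernel SVM over per-pixel SNV spectra, with the protocol used
# throughout: 200 training pixels per class per specimen, C = 1, RBF kernel
# with the median-heuristic bandwidth, leave-one-specimen-out folds.

#' Sample a balanced training set from one specimen
#'
#' Draws `n_per_class` valid pixels uniformly without replacement from each
#' class — normal versus tumor (exposed and unexposed pooled) — restricted
#' to the evaluated area and the validity mask. Sampling is deterministic
#' under the seed.
#'
#' @param snv An [hsi_cube] with `value_kind = "snv"`.
#' @param annotation The specimen's [annotation_map].
#' @param mask The specimen's [validity_mask].
#' @param n_per_class Pixels drawn per class (default 200).
#' @param seed Integer seed.
#' @param specimen_id Identifier recorded in the provenance.
#' @return An object of class `training_set`: `spectra` (rows = pixels),
#'   `labels` (`"normal"`/`"tumor"`), `provenance` (specimen, row, col),
#'   `seed`.
#' @export
sample_training_pixels <- function(snv, annotation, mask,
                                   n_per_class = 200L, seed = 1L,
                                   specimen_id = NA_character_) {
  stopifnot(inherits(snv, "hsi_cube"), inherits(annotation, "annotation_map"),
            inherits(mask, "validity_mask"))
  lab <- annotation$labels
  pools <- list(normal = which(mask$valid & lab == LABELS[["normal"]]),
                tumor = which(mask$valid & tumor_label_matrix(lab)))
  for (cls in names(pools))
    if (length(pools[[cls]]) < n_per_class)
      stop(sprintf(
        "specimen %s: only %d valid '%s' pixels, need %d per class",
        specimen_id, length(pools[[cls]]), cls, n_per_class), call. = FALSE)
  idx <- local_seed(seed, lapply(pools, function(p)
    p[sample.int(length(p), n_per_class)]))
  all_idx <- c(idx$normal, idx$tumor)
  d <- dim(snv$data)
  x <- matrix(snv$data, d[1L] * d[2L], d[3L])[all_idx, , drop = FALSE]
  structure(
    list(spectra = x,
         labels = rep(c("normal", "tumor"), each = n_per_class),
         provenance = data.frame(
           specimen = specimen_id,
           row = row(lab)[all_idx], col = col(lab)[all_idx]),
         wavelengths = snv$wavelengths,
         seed = seed),
    class = "training_set")
}

rbind_training_sets <- function(sets) {
  structure(
    list(spectra = do.call(rbind, lapply(sets, `[[`, "spectra")),
         labels = unlist(lapply(sets, `[[`, "labels"), use.names = FALSE),
         provenance = do.call(rbind, lapply(sets, `[[`, "provenance")),
         wavelengths = sets[[1L]]$wavelengths,
         seed = NA_integer_),
    class = "training_set")
}

#' Median-heuristic RBF bandwidth
#'
#' `sigma2 = median of the squared Euclidean distances over all unordered
#' row pairs (i < j)`. The median is exact: with an even pair count it is
#' the mean of the two central order statistics.
#'
#' @param spectra Numeric matrix, one observation per row.
#' @return The bandwidth `sigma2` (> 0).
#' @export
median_heuristic_sigma2 <- function(spectra) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2L)
    stop("need at least 2 rows for pairwise distances", call. = FALSE)
  d2 <- as.vector(stats::dist(spectra))^2
  s2 <- stats::median(d2)
  if (s2 <= 0)
    stop("degenerate bandwidth: median pairwise distance is 0 ",
         "(all rows identical?)", call. = FALSE)
  s2
}

#' RBF kernel value
#'
#' `K(xi, xj) = exp(-||xi - xj||^2 / sigma2)`; symmetric, in `(0, 1]`.
#'
#' @param xi,xj Numeric vectors of equal length.
#' @param sigma2 Bandwidth (> 0).
#' @return Kernel value.
#' @export
rbf_kernel <- function(xi, xj, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  exp(-sum((xi - xj)^2) / sigma2)
}

#' Train the pixel classifier
#'
#' Fits a soft-margin binary SVM (cost `C`, RBF kernel) on a balanced
#' training set, with the bandwidth set by [median_heuristic_sigma2()] on
#' the training spectra. Tumor is the positive class: decision values are
#' oriented so that positive means tumor, and an exact tie (decision value
#' 0) is assigned normal, favoring specificity.
#'
#' @param ts A `training_set` (see [sample_training_pixels()]).
#' @param C Soft-margin cost (default 1).
#' @return An object of class `pixel_classifier` with fields `svm` (the
#'   fitted model), `sigma2`, `C`, `n_bands`, `classes`.
#' @export
train_classifier <- function(ts, C = 1) {
  stopifnot(inherits(ts, "training_set"))
  classes <- unique(ts$labels)
  if (length(classes) < 2L)
    stop("training set contains a single class: ", classes, call. = FALSE)
  sigma2 <- median_heuristic_sigma2(ts$spectra)
  y <- factor(ts$labels, levels = c("tumor", "normal"))
  fit <- e1071::svm(ts$spectra, y, scale = FALSE, type = "C-classification",
                    kernel = "radial", gamma = 1 / sigma2, cost = C)
  # libsvm orients decision values toward whichever class it saw first;
  # record the orientation so decision > 0 always means tumor
  dv <- attr(stats::predict(fit, ts$spectra[1:2, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- if (identical(colnames(dv), "normal/tumor")) -1 else 1
  structure(list(svm = fit, sigma2 = sigma2, C = C,
                 n_bands = ncol(ts$spectra), flip = flip,
                 classes = c(negative = "normal", positive = "tumor")),
            class = "pixel_classifier")
}

#' Decision values of a pixel classifier
#'
#' @param model A `pixel_classifier`.
#' @param x Numeric matrix of spectra (rows) matching the training band
#'   count.
#' @return Numeric vector; positive means tumor.
#' @export
decision_values <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_bands)
    stop("spectra have ", ncol(x), " bands; model was trained on ",
         model$n_bands, call. = FALSE)
  dv <- attr(stats::predict(model$svm, x, decision.values = TRUE),
             "decision.values")
  model$flip * as.vector(dv)
}

#' Predict a per-pixel class map
#'
#' Classifies every valid pixel of an SNV cube as tumor or normal; invalid
#' pixels are `not_evaluated`.
#'
#' @param model A `pixel_classifier`.
#' @param snv An [hsi_cube] with `value_kind = "snv"`.
#' @param mask A [validity_mask] of matching spatial shape.
#' @param specimen_id Identifier recorded on the map.
#' @return An object of class `prediction_map`: `class` (integer matrix,
#'   0 = normal, 1 = tumor, `NA` = not evaluated), `specimen_id`, `sigma2`.
#' @export
predict_map <- function(model, snv, mask, specimen_id = NA_character_) {
  stopifnot(inherits(model, "pixel_classifier"), inherits(snv, "hsi_cube"),
            inherits(mask, "validity_mask"))
  d <- dim(snv$data)
  if (d[3L] != model$n_bands)
    stop("cube has ", d[3L], " bands; model was trained on ", model$n_bands,
         call. = FALSE)
  cls <- matrix(NA_integer_, d[1L], d[2L])
  idx <- which(mask$valid)
  if (length(idx)) {
    x <- matrix(snv$data, d[1L] * d[2L], d[3L])[idx, , drop = FALSE]
    dv <- decision_values(model, x)
    cls[idx] <- as.integer(dv > 0)  # tie (exactly 0) -> normal
  }
  structure(list(class = cls, specimen_id = specimen_id,
                 sigma2 = model$sigma2),
            class = "prediction_map")
}

#' Leave-one-specimen-out cross-validation
#'
#' For each specimen, a classifier is trained on the pooled balanced samples
#' (`n_per_class` per class) of all *other* specimens and applied to it, so
#' no pixel of a specimen ever appears in its own fold's training data.
#' With 10 specimens at the default 200 px/class, each fold trains on
#' 9 x 400 = 3600 spectra. Each specimen's sample is drawn once (seed
#' derived as `seed + index`) and reused across the folds it serves.
#'
#' @param prep List of `preprocessed_specimen` (see
#'   [preprocess_specimen()]).
#' @param n_per_class Training pixels per class per specimen.
#' @param C Soft-margin cost.
#' @param seed Master seed for the per-specimen sampling.
#' @return An object of class `loocv_result`: `predictions` (list of
#'   `prediction_map`), `folds` (per fold: `sigma2`, `n_train`,
#'   `normal_training_mean` — the mean normal training spectrum, used for
#'   difference spectra), `samples` (the per-specimen training sets).
#' @export
run_loocv <- function(prep, n_per_class = 200L, C = 1, seed = 1L) {
  n <- length(prep)
  if (n < 2L) stop("leave-one-out needs at least 2 specimens", call. = FALSE)
  samples <- lapply(seq_len(n), function(i) {
    p <- prep[[i]]
    sample_training_pixels(p$snv, p$annotation, p$mask,
                           n_per_class = n_per_class,
                           seed = seed + i, specimen_id = p$id)
  })
  folds <- vector("list", n)
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    ts <- rbind_training_sets(samples[-i])
    model <- train_classifier(ts, C = C)
    preds[[i]] <- predict_map(model, prep[[i]]$snv, prep[[i]]$mask,
                              specimen_id = prep[[i]]$id)
    folds[[i]] <- list(
      held_out = prep[[i]]$id,
      sigma2 = model$sigma2,
      n_train = nrow(ts$spectra),
      provenance = ts$provenance,
      normal_training_mean = colMeans(ts$spectra[ts$labels == "normal", ,
                                                 drop = FALSE]),
      model = model)
  }
  names(preds) <- names(folds) <- vapply(prep, `[[`, "", "id")
  structure(list(predictions = preds, folds = folds, samples = samples,
                 n_per_class = n_per_class, C = C, seed = seed),
            class = "loocv_result")
}
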