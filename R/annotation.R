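#' Tissue label vocabulary
#'
#' Integer codes for the per-pixel annotation raster. `outside_evaluated`
#' marks pixels outside the pathologically confirmed area; only pixels inside
#' it carry ground truth and enter any metric.
#'
#' @format Named integer vector.
#' @export
LABELS <- c(outside_evaluated = 0L, normal = 1L, exposed_tumor = 2L,
            unexposed_tumor = 3L, necrosis = 4L)

#' Exclusion-reason vocabulary for validity masks
#' @format Character vector, in decreasing precedence order.
#' @export
EXCLUSION_REASONS <- c("outside_evaluated", "necrosis", "highlight",
                       "shadow", "boundary_margin")

tumor_label_matrix <- function(labels)
  labels == LABELS[["exposed_tumor"]] | labels == LABELS[["unexposed_tumor"]]

#' Per-specimen annotation map
#'
#' Holds the pathologist-style ground truth for one specimen: a label raster,
#' the tumor-extent boundary polyline (the "white line"), the exposed /
#' unexposed borderline (the "yellow line"), and a per-pixel tumor thickness
#' raster in mm.
#'
#' @param labels Integer matrix of codes from [LABELS].
#' @param tumor_boundary,exposure_boundary Two-column integer matrices of
#'   (row, col) pixel coordinates tracing each boundary line; may have zero
#'   rows (e.g. no unexposed area means no yellow line).
#' @param thickness_mm Numeric matrix, tumor thickness in mm; must be > 0
#'   exactly on tumor-labelled pixels and 0 elsewhere.
#' @return An object of class `annotation_map`.
#' @export
annotation_map <- function(labels, tumor_boundary = NULL,
                           exposure_boundary = NULL, thickness_mm = NULL) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(LABELS))
  if (length(bad))
    stop("unknown label code(s): ", paste(bad, collapse = ", "),
         " (vocabulary: ", paste(LABELS, names(LABELS), sep = "=",
                                 collapse = ", "), ")", call. = FALSE)
  as_coords <- function(x) {
    if (is.null(x)) return(matrix(integer(), 0L, 2L,
                                  dimnames = list(NULL, c("row", "col"))))
    x <- as.matrix(x)
    storage.mode(x) <- "integer"
    if (ncol(x) != 2L) stop("boundary coordinates must have 2 columns",
                            call. = FALSE)
    colnames(x) <- c("row", "col")
    x
  }
  if (is.null(thickness_mm))
    thickness_mm <- matrix(0, nrow(labels), ncol(labels))
  if (!identical(dim(thickness_mm), dim(labels)))
    stop("`thickness_mm` must match the label raster's shape", call. = FALSE)
  tumor <- tumor_label_matrix(labels)
  if (any(tumor & labels == LABELS[["outside_evaluated"]]))
    stop("tumor pixels must lie inside the evaluated area", call. = FALSE)
  if (any(thickness_mm[tumor] <= 0) || any(thickness_mm[!tumor] != 0))
    stop("thickness_mm must be > 0 exactly on tumor-labelled pixels",
         call. = FALSE)
  structure(
    list(labels = labels,
         tumor_boundary = as_coords(tumor_boundary),
         exposure_boundary = as_coords(exposure_boundary),
         thickness_mm = thickness_mm),
    class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  tab <- table(factor(names(LABELS)[match(x$labels, LABELS)],
                      levels = names(LABELS)))
  cat(sprintf("<annotation_map> %d x %d px\n", nrow(x$labels), ncol(x$labels)))
  print(tab)
  invisible(x)
}

#' Per-pixel validity mask
#'
#' Marks which pixels enter training and evaluation. Every excluded pixel
#' records one reason from [EXCLUSION_REASONS]; valid pixels record none.
#'
#' @param valid Logical matrix.
#' @param exclusion_reason Character matrix, `NA` on valid pixels and a
#'   reason from [EXCLUSION_REASONS] on every excluded pixel.
#' @return An object of class `validity_mask`.
#' @export
validity_mask <- function(valid, exclusion_reason) {
  stopifnot(is.matrix(valid), is.logical(valid),
            identical(dim(valid), dim(exclusion_reason)))
  if (any(valid & !is.na(exclusion_reason)))
    stop("valid pixels must not carry an exclusion reason", call. = FALSE)
  if (any(!valid & is.na(exclusion_reason)))
    stop("every excluded pixel must record a reason", call. = FALSE)
  reasons <- unique(exclusion_reason[!is.na(exclusion_reason)])
  bad <- setdiff(reasons, EXCLUSION_REASONS)
  if (length(bad)) stop("unknown exclusion reason(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(valid = valid, exclusion_reason = exclusion_reason),
            class = "validity_mask")
}

#' @export
print.validity_mask <- function(x, ...) {
  cat(sprintf("<validity_mask> %d / %d px valid\n",
              sum(x$valid), length(x$valid)))
  if (any(!x$valid))
    print(table(x$exclusion_reason[!x$valid]))
  invisible(x)
}
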