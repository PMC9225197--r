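#' Horizontal extent of a set of classes in a label mask
#'
#' Column indices (1-based) of the leftmost and rightmost pixels belonging to
#' any class in `class_ids`.  By default stray mispredicted islands are
#' suppressed first: connected components (8-connectivity) of the class
#' union smaller than `min_fraction` of the largest component are dropped.
#' A fraction rather than "keep only the largest" is used because the lung
#' class legitimately consists of two components of similar size.
#'
#' @param mask integer label matrix.
#' @param class_ids integer vector of class ids forming the structure.
#' @param suppress_islands drop small connected components first.
#' @param min_fraction smallest component area kept, as a fraction of the
#'   largest component's area.
#' @return integer vector `c(min_col, max_col)`.
#' @export
horizontal_extent <- function(mask, class_ids, suppress_islands = TRUE,
                              min_fraction = 0.1) {
  bin <- matrix(mask %in% class_ids, nrow(mask), ncol(mask))
  if (!any(bin)) {
    stop(sprintf("class(es) %s absent from the mask; extent undefined",
                 paste(class_ids, collapse = ", ")))
  }
  if (suppress_islands) {
    lab <- EBImage::bwlabel(bin)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_fraction * max(sizes))
    bin <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  cols <- which(colSums(bin) > 0)
  c(min_col = min(cols), max_col = max(cols))
}

#' Cardiomegaly decision from a cardiothoracic ratio
#'
#' The normal range is 0.42 to 0.50; a ratio above 0.50 indicates
#' cardiomegaly, below 0.42 a smaller-than-normal cardiac silhouette.
#'
#' @param ctr numeric ratio.
#' @return one of `"cardiomegaly"`, `"normal"`, `"below_normal"`.
#' @export
ctr_decision <- function(ctr) {
  if (ctr > 0.50) "cardiomegaly" else if (ctr < 0.42) "below_normal" else "normal"
}

ctr_measurement <- function(cardiac, thoracic, midline_col = NA_integer_,
                            d_left = NA_integer_, d_right = NA_integer_) {
  if (thoracic <= 0) stop("thoracic diameter must be positive")
  ctr <- cardiac / thoracic
  structure(list(
    cardiac_diameter = as.integer(cardiac),
    thoracic_diameter = as.integer(thoracic),
    ctr = ctr,
    decision = ctr_decision(ctr),
    midline_col = midline_col, d_left = d_left, d_right = d_right
  ), class = "ctr_measurement")
}

#' Cardiothoracic ratio from diameters
#'
#' CTR = (D_L + D_R) / M: the maximum horizontal cardiac diameter (the sum of
#' the leftward and rightward extents of the heart about the midline) over
#' the maximum horizontal thoracic diameter.  Because
#' (mid - min) + (max - mid) = max - min, the reported cardiac diameter never
#' depends on where the midline is placed.
#'
#' @param cardiac_diameter D_L + D_R in pixels.
#' @param thoracic_diameter M in pixels.
#' @return a `ctr_measurement` with the ratio and screening decision.
#' @examples
#' ctr_ratio(126, 304)   # ratio 0.4145, not cardiomegaly
#' @export
ctr_ratio <- function(cardiac_diameter, thoracic_diameter) {
  ctr_measurement(cardiac_diameter, thoracic_diameter)
}

#' Compute the cardiothoracic ratio from a segmentation mask
#'
#' The cardiac diameter D_L + D_R is the horizontal extent of the heart
#' class; the thoracic diameter M is the horizontal extent of the combined
#' lung fields.  Both use the index-difference convention
#' `max_col - min_col`, applied identically to numerator and denominator so
#' the ratio is insensitive to the convention to within 1/M.  The midline
#' (for the separate D_L / D_R report) is the midpoint of the thoracic
#' extent.
#'
#' @param mask integer label matrix containing lung and heart classes.
#' @param lung_class,heart_class class ids (defaults: 1 and 2).
#' @param suppress_islands,min_fraction see [horizontal_extent()].
#' @return a `ctr_measurement`: cardiac and thoracic diameters (pixels), the
#'   ratio, the screening decision, and the midline decomposition.
#' @export
compute_ctr <- function(mask, lung_class = 1L, heart_class = 2L,
                        suppress_islands = TRUE, min_fraction = 0.1) {
  lungs <- horizontal_extent(mask, lung_class, suppress_islands, min_fraction)
  heart <- horizontal_extent(mask, heart_class, suppress_islands, min_fraction)
  thoracic <- lungs[["max_col"]] - lungs[["min_col"]]
  cardiac <- heart[["max_col"]] - heart[["min_col"]]
  mid <- as.integer(round((lungs[["min_col"]] + lungs[["max_col"]]) / 2))
  ctr_measurement(cardiac, thoracic,
                  midline_col = mid,
                  d_left = mid - heart[["min_col"]],
                  d_right = heart[["max_col"]] - mid)
}

#' @export
print.ctr_measurement <- function(x, ...) {
  cat(sprintf("CTR = %d / %d = %.4f  [%s]\n", x$cardiac_diameter,
              x$thoracic_diameter, x$ctr, x$decision))
  if (!is.na(x$midline_col)) {
    cat(sprintf("  midline col %d: D_L = %d, D_R = %d\n", x$midline_col,
                x$d_left, x$d_right))
  }
  invisible(x)
}

#' CTR report as JSON
#'
#' @param x a `ctr_measurement`.
#' @param path optional file to write to.
#' @return JSON string (invisibly if written to file).
#' @export
ctr_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "ctr_measurement"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for JSON reports")
  }
  js <- jsonlite::toJSON(list(
    cardiac_diameter = x$cardiac_diameter,
    thoracic_diameter = x$thoracic_diameter,
    ctr = round(x$ctr, 4), decision = x$decision
  ), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
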