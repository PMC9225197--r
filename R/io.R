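#' Mask color palettes
#'
#' The multi-class palette maps background to black, lungs to blue, heart to
#' green and clavicles to red; the binary lung palette (`"mc"`) maps lungs
#' to white on black.  Palettes are data frames and can be edited or
#' replaced wholesale wherever a `palette` argument is accepted.
#'
#' @param name `"jsrt"` (4-class) or `"mc"` (binary lung).
#' @return data frame with columns `class`, `name`, `r`, `g`, `b` (0-255).
#' @export
cardionet_palette <- function(name = c("jsrt", "mc")) {
  name <- match.arg(name)
  if (name == "jsrt") {
    data.frame(
      class = 0:3,
      name = c("background", "lung", "heart", "clavicle"),
      r = c(0L, 0L, 0L, 255L), g = c(0L, 0L, 255L, 0L),
      b = c(0L, 255L, 0L, 0L)
    )
  } else {
    data.frame(class = 0:1, name = c("background", "lung"),
               r = c(0L, 255L), g = c(0L, 255L), b = c(0L, 255L))
  }
}

resolve_palette <- function(palette) {
  if (is.character(palette)) cardionet_palette(palette) else palette
}

#' Read / write a label mask as a palette PNG
#'
#' `write_mask` encodes class labels as palette colors; `read_mask` inverts
#' the mapping and errors on any color not in the palette, listing the
#' offending RGB triple.  The round trip `read_mask(write_mask(m))` is
#' lossless.  Grayscale PNGs are accepted on read (treated as r = g = b),
#' which covers binary lung masks stored as white-on-black.
#'
#' @param path PNG file path.
#' @param palette palette name or data frame, see [cardionet_palette()].
#' @param mask integer label matrix.
#' @return `read_mask`: integer label matrix; `write_mask`: the path,
#'   invisibly.
#' @export
read_mask <- function(path, palette = "jsrt") {
  pal <- resolve_palette(palette)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) {
    rgb <- array(a, dim = c(dim(a), 3L))
  } else {
    rgb <- a[, , 1:3, drop = FALSE]
  }
  key <- round(rgb[, , 1] * 255) * 65536 + round(rgb[, , 2] * 255) * 256 +
    round(rgb[, , 3] * 255)
  palkey <- pal$r * 65536 + pal$g * 256 + pal$b
  idx <- match(as.vector(key), palkey)
  if (anyNA(idx)) {
    bad <- as.vector(key)[which(is.na(idx))[1]]
    stop(sprintf("unknown mask color RGB(%d, %d, %d)", bad %/% 65536,
                 (bad %/% 256) %% 256, bad %% 256))
  }
  matrix(pal$class[idx], nrow(key), ncol(key))
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path, palette = "jsrt") {
  pal <- resolve_palette(palette)
  idx <- match(as.vector(mask), pal$class)
  if (anyNA(idx)) {
    stop(sprintf("mask contains label(s) outside the palette: %s",
                 paste(unique(as.vector(mask)[is.na(idx)]), collapse = ", ")))
  }
  h <- nrow(mask); w <- ncol(mask)
  a <- array(0, dim = c(h, w, 3))
  a[, , 1] <- matrix(pal$r[idx], h, w) / 255
  a[, , 2] <- matrix(pal$g[idx], h, w) / 255
  a[, , 3] <- matrix(pal$b[idx], h, w) / 255
  png::writePNG(a, path)
  invisible(path)
}

#' Read / write a grayscale radiograph PNG
#'
#' Color PNGs are converted to luminance on read; values are in `[0, 1]`.
#'
#' @param path PNG file path.
#' @param image numeric matrix in `[0, 1]`.
#' @return `read_radiograph`: numeric matrix; `write_radiograph`: the path,
#'   invisibly.
#' @export
read_radiograph <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  a
}

#' @rdname read_radiograph
#' @export
write_radiograph <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Render a prediction/ground-truth agreement overlay
#'
#' Per-pixel color coding of segmentation quality: true positives take their
#' class color (lung blue, heart green, clavicle red), false negatives
#' (ground-truth foreground predicted as background) are yellow, false
#' positives (predicted foreground on background ground truth, or a
#' foreground pixel predicted as the wrong foreground class) are black, and
#' correctly predicted background is white.
#'
#' @param pred,truth integer label matrices of identical shape.
#' @param palette palette name or data frame for the TP class colors.
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
render_overlay <- function(pred, truth, palette = "jsrt") {
  if (!all(dim(pred) == dim(truth))) stop("pred and truth shapes differ")
  pal <- resolve_palette(palette)
  h <- nrow(pred); w <- ncol(pred)
  r <- g <- b <- matrix(1, h, w)                  # TN: white
  tp <- pred == truth & truth != 0L
  idx <- match(truth[tp], pal$class)
  r[tp] <- pal$r[idx] / 255; g[tp] <- pal$g[idx] / 255
  b[tp] <- pal$b[idx] / 255
  fn <- truth != 0L & pred == 0L                  # missed foreground: yellow
  r[fn] <- 1; g[fn] <- 1; b[fn] <- 0
  fp <- pred != 0L & pred != truth                # spurious/wrong class: black
  r[fp] <- 0; g[fp] <- 0; b[fp] <- 0
  out <- array(0, dim = c(h, w, 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
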