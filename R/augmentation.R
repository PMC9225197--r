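#' Horizontal flip of an image/mask pair
#'
#' Reverses the column order of both arrays; labels are untouched, so the
#' per-class pixel histogram is preserved exactly and the operation is an
#' involution.
#'
#' @param image numeric H x W matrix.
#' @param mask integer H x W label matrix of the same shape.
#' @return list with flipped `image` and `mask`.
#' @export
hflip <- function(image, mask) {
  if (!all(dim(image) == dim(mask))) stop("image and mask shapes differ")
  rev_cols <- rev(seq_len(ncol(image)))
  list(image = image[, rev_cols, drop = FALSE],
       mask = mask[, rev_cols, drop = FALSE])
}

## shift a matrix by (dx columns rightward, dy rows downward); vacated
## borders are filled by edge replication (images) or a constant (masks).
shift_matrix <- function(m, dx, dy, fill = c("replicate", "constant"),
                         value = 0L) {
  fill <- match.arg(fill)
  H <- nrow(m); W <- ncol(m)
  rows <- seq_len(H) - dy
  cols <- seq_len(W) - dx
  if (fill == "replicate") {
    m[pmin(pmax(rows, 1L), H), pmin(pmax(cols, 1L), W), drop = FALSE]
  } else {
    out <- matrix(value, H, W)
    ok_r <- rows >= 1L & rows <= H
    ok_c <- cols >= 1L & cols <= W
    out[ok_r, ok_c] <- m[rows[ok_r], cols[ok_c], drop = FALSE]
    out
  }
}

#' Translate an image/mask pair
#'
#' Axis convention: `dx` moves content along columns (positive rightward),
#' `dy` along rows (positive downward).  Vacated image borders are filled by
#' edge replication (a zero fill would fabricate dark bands at lung borders);
#' vacated mask borders become background (class 0).  Masks move with
#' nearest-neighbour semantics -- labels are never blended.
#'
#' @param image numeric H x W matrix.
#' @param mask integer H x W label matrix.
#' @param dx,dy integer pixel shifts, `|dx|, |dy|` smaller than the image
#'   side.
#' @return list with shifted `image` and `mask`.
#' @export
translate <- function(image, mask, dx, dy) {
  if (!all(dim(image) == dim(mask))) stop("image and mask shapes differ")
  dx <- as.integer(dx); dy <- as.integer(dy)
  if (abs(dx) >= ncol(image) || abs(dy) >= nrow(image)) {
    stop("shift exceeds the image size")
  }
  list(image = shift_matrix(image, dx, dy, "replicate"),
       mask = shift_matrix(mask, dx, dy, "constant", 0L))
}

#' Expand a training fold with the staged flip/translate cascade
#'
#' The fully deterministic four-stage cascade: (1) originals plus their
#' horizontal flips (n to 2n); (2) plus a translation of (X = 4, Y = -4) of
#' stage 1 (to 4n); (3) plus horizontal flips of stage 2 (to 8n); (4) two
#' branches applied to the whole stage-3 set, one translating by (X = 8,
#' Y = 8) and one by (X = -12, Y = -12), each branch keeping the translated
#' images together with their horizontal flips (16n per branch).  The
#' returned training set is the union of the two stage-4 branches (32n);
#' with `include_earlier_stages = TRUE` the stage-3 set is kept as well
#' (40n).  For a 124-image fold the stage sizes are 248, 496, 992 and the
#' final set 3968 (1984 + 1984).
#'
#' @param images,masks non-empty lists of paired matrices.
#' @param include_earlier_stages also keep the stage-3 images in the output.
#' @return list with `images`, `masks` and `stage_sizes`, a named integer
#'   vector of the cascade cardinalities (stage1, stage2, stage3, final).
#' @export
expand_fold <- function(images, masks, include_earlier_stages = FALSE) {
  n <- length(images)
  if (n == 0L || length(masks) != n) {
    stop("images and masks must be non-empty lists of equal length")
  }
  pairs <- Map(function(i, m) list(image = i, mask = m), images, masks)
  flip_all <- function(ps) lapply(ps, function(p) hflip(p$image, p$mask))
  shift_all <- function(ps, dx, dy) {
    lapply(ps, function(p) translate(p$image, p$mask, dx, dy))
  }
  s1 <- c(pairs, flip_all(pairs))
  s2 <- c(s1, shift_all(s1, 4L, -4L))
  s3 <- c(s2, flip_all(s2))
  t4a <- shift_all(s3, 8L, 8L)
  t4b <- shift_all(s3, -12L, -12L)
  final <- c(t4a, flip_all(t4a), t4b, flip_all(t4b))
  out <- if (include_earlier_stages) c(s3, final) else final
  list(
    images = lapply(out, `[[`, "image"),
    masks = lapply(out, `[[`, "mask"),
    stage_sizes = c(stage1 = length(s1), stage2 = length(s2),
                    stage3 = length(s3), final = length(final))
  )
}

#' Resize an image/mask pair to a square working resolution
#'
#' The image is resampled with bilinear interpolation, the mask with
#' nearest-neighbour so labels are never interpolated: a resized mask can
#' only contain label values already present in the input.
#'
#' @param image numeric H x W matrix.
#' @param mask integer H x W label matrix.
#' @param side target side in pixels (>= 16).
#' @return list with resized `image` and `mask` (`side` x `side`).
#' @export
resize_pair <- function(image, mask, side) {
  side <- as.integer(side)
  if (side < 16L) stop("side must be >= 16")
  img <- EBImage::resize(image, w = side, h = side, filter = "bilinear")
  msk <- EBImage::resize(mask, w = side, h = side, filter = "none")
  list(image = matrix(as.numeric(img), side, side),
       mask = matrix(as.integer(round(as.numeric(msk))), side, side))
}

#' Crop a centered square window (utility)
#'
#' Cropping belongs to the augmentation vocabulary but not to the cascade of
#' [expand_fold()]; it is provided as a standalone utility.
#'
#' @param image,mask paired matrices.
#' @param side window side, at most `min(dim(image))`.
#' @return list with cropped `image` and `mask`.
#' @export
crop_center <- function(image, mask, side) {
  if (!all(dim(image) == dim(mask))) stop("image and mask shapes differ")
  side <- as.integer(side)
  if (side > min(dim(image))) stop("crop window exceeds the image")
  r0 <- (nrow(image) - side) %/% 2L
  c0 <- (ncol(image) - side) %/% 2L
  rr <- r0 + seq_len(side); cc <- c0 + seq_len(side)
  list(image = image[rr, cc, drop = FALSE], mask = mask[rr, cc, drop = FALSE])
}
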