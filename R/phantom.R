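## Synthetic chest-radiograph phantoms.
##
## A phantom emulates the geometry a posterior-anterior radiograph presents
## to the segmenter: two elliptical lung fields, a cardiac ellipse straddling
## the midline and overlapping the medial-inferior lung borders (so the
## heart/lung boundary is low-contrast, as on real films), two thin tilted
## clavicle bars, a smooth illumination gradient and additive Gaussian
## noise.  Geometry is snapped to a half-pixel grid -- integer centers,
## half-integer semi-axes -- so the rasterized horizontal extents realize the
## analytic ones exactly and the closed-form CTR is recovered by
## compute_ctr() to within the index-difference convention.

#' Specify a synthetic chest phantom
#'
#' All geometry is given in pixels of the `side` x `side` frame.  Centers
#' are rounded to integers and semi-axes to half-integers (k + 0.5).  The
#' analytic CTR, `(a_left + a_right) / lung_span`, is computable from the
#' spec before rasterization.
#'
#' @param side frame side in pixels.
#' @param lung_left,lung_right lists `list(cx, cy, a, b)` (center and
#'   semi-axes) for the two lung ellipses; defaults scale with `side`.
#' @param heart list `list(cx, cy, a_left, a_right, b)`: the cardiac ellipse
#'   has separate left/right horizontal semi-axes about a center on or near
#'   the midline.
#' @param clavicles `NULL` for none, else list with `half_thickness` and
#'   segments `left`/`right` = `c(x0, y0, x1, y1)`.
#' @param intensity list of absolute attenuation levels (`background`,
#'   `lung`, `heart`, `clavicle`; later structures override earlier ones,
#'   so bone stays bright over lung), plus `noise_sd` (additive Gaussian)
#'   and `gradient` (peak-to-peak smooth illumination drift).  Air is dark
#'   and bone bright, as on a radiograph; the heart level is deliberately
#'   close to the background so the mediastinal boundary is low-contrast.
#' @param seed integer seed for the noise.
#' @return a list of class `phantom_spec` with an `expected_ctr` field.
#' @export
phantom_spec <- function(side = 96L,
                         lung_left = NULL, lung_right = NULL, heart = NULL,
                         clavicles = NULL, intensity = NULL, seed = 1L) {
  side <- as.integer(side)
  if (side < 32L) stop("side must be >= 32")
  snap_c <- function(x) as.integer(round(x))
  snap_a <- function(x) floor(x) + 0.5
  deflung <- function(fx) {
    list(cx = snap_c(fx * side), cy = snap_c(0.48 * side),
         a = snap_a(0.155 * side), b = snap_a(0.30 * side))
  }
  if (is.null(lung_left)) lung_left <- deflung(0.32)
  if (is.null(lung_right)) lung_right <- deflung(0.68)
  for (nm in c("cx", "cy")) {
    lung_left[[nm]] <- snap_c(lung_left[[nm]])
    lung_right[[nm]] <- snap_c(lung_right[[nm]])
  }
  for (nm in c("a", "b")) {
    lung_left[[nm]] <- snap_a(lung_left[[nm]])
    lung_right[[nm]] <- snap_a(lung_right[[nm]])
  }
  if (is.null(heart)) {
    heart <- list(cx = snap_c(0.50 * side), cy = snap_c(0.62 * side),
                  a_left = snap_a(0.15 * side), a_right = snap_a(0.15 * side),
                  b = snap_a(0.18 * side))
  }
  heart$cx <- snap_c(heart$cx); heart$cy <- snap_c(heart$cy)
  heart$a_left <- snap_a(heart$a_left)
  heart$a_right <- snap_a(heart$a_right)
  heart$b <- snap_a(heart$b)
  if (is.null(clavicles)) {
    t <- max(1.5, 0.025 * side)
    clavicles <- list(
      half_thickness = t,
      left = c(0.17, 0.27, 0.45, 0.20) * side,
      right = c(0.55, 0.20, 0.83, 0.27) * side
    )
  }
  if (is.null(intensity)) {
    intensity <- list(background = 0.55, lung = 0.25, heart = 0.66,
                      clavicle = 0.88, noise_sd = 0.03, gradient = 0.08)
  }
  span <- (lung_right$cx + lung_right$a) - (lung_left$cx - lung_left$a)
  spec <- list(
    side = side, lung_left = lung_left, lung_right = lung_right,
    heart = heart, clavicles = clavicles, intensity = intensity,
    seed = as.integer(seed),
    lung_span = span,
    expected_ctr = (heart$a_left + heart$a_right) / span
  )
  ## frame check
  lo <- min(lung_left$cx - lung_left$a, heart$cx - heart$a_left)
  hi <- max(lung_right$cx + lung_right$a, heart$cx + heart$a_right)
  vlo <- min(lung_left$cy - lung_left$b, lung_right$cy - lung_right$b)
  vhi <- max(lung_left$cy + lung_left$b, lung_right$cy + lung_right$b,
             heart$cy + heart$b)
  if (lo < 1 || vlo < 1 || hi > side || vhi > side) {
    stop("phantom geometry does not fit in the frame")
  }
  class(spec) <- "phantom_spec"
  spec
}

ellipse_mask <- function(R, C, cx, cy, a, b) {
  ((C - cx) / a)^2 + ((R - cy) / b)^2 <= 1
}

half_ellipse_mask <- function(R, C, cx, cy, a_left, a_right, b) {
  a <- ifelse(C < cx, a_left, a_right)
  ((C - cx) / a)^2 + ((R - cy) / b)^2 <= 1
}

bar_mask <- function(R, C, seg, t) {
  x0 <- seg[1]; y0 <- seg[2]; x1 <- seg[3]; y1 <- seg[4]
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  u <- pmin(pmax(((C - x0) * vx + (R - y0) * vy) / len2, 0), 1)
  (C - (x0 + u * vx))^2 + (R - (y0 + u * vy))^2 <= t^2
}

#' Rasterize a phantom
#'
#' Produces the image, the pixel-exact ground-truth mask (0 = background,
#' 1 = lung, 2 = heart, 3 = clavicle; the heart takes precedence where it
#' overlaps a lung, the clavicles where they cross one, so each pixel holds
#' exactly one label) and the analytic CTR of the spec.  With the same seed
#' the output is bitwise reproducible.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `cardionet_phantom`: `image` (side x side, in
#'   `[0, 1]`), `mask`, `expected_ctr`, `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$side
  R <- matrix(seq_len(s), s, s)        # row index
  C <- matrix(seq_len(s), s, s, byrow = TRUE)  # column index
  ll <- spec$lung_left; lr <- spec$lung_right; h <- spec$heart
  lung <- ellipse_mask(R, C, ll$cx, ll$cy, ll$a, ll$b) |
    ellipse_mask(R, C, lr$cx, lr$cy, lr$a, lr$b)
  heart <- half_ellipse_mask(R, C, h$cx, h$cy, h$a_left, h$a_right, h$b)
  mask <- matrix(0L, s, s)
  mask[lung] <- 1L
  mask[heart] <- 2L
  clav <- NULL
  if (!is.null(spec$clavicles)) {
    cl <- spec$clavicles
    clav <- bar_mask(R, C, cl$left, cl$half_thickness) |
      bar_mask(R, C, cl$right, cl$half_thickness)
    mask[clav] <- 3L
  }
  ## absolute attenuation levels with override semantics (bone is bright
  ## regardless of what it overlies); the heart level sits close to the
  ## mediastinal background so that boundary is low-contrast, while the
  ## heart/lung boundary is carried by the dark air-filled lung
  iy <- spec$intensity
  lev <- matrix(iy$background, s, s)
  lev[lung] <- iy$lung
  lev[heart] <- iy$heart
  if (!is.null(clav)) lev[clav] <- iy$clavicle
  img <- lev + iy$gradient * ((R + C) / (2 * s) - 0.5)
  if (iy$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
    img <- img + matrix(stats::rnorm(s * s, sd = iy$noise_sd), s, s)
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, mask = mask,
                 expected_ctr = spec$expected_ctr, spec = spec),
            class = "cardionet_phantom")
}

#' Generate a dataset of randomized phantoms
#'
#' Geometry is jittered per phantom under one master seed, and the analytic
#' CTR is placed on a controllable side of the 0.50 cardiomegaly threshold:
#' with probability `p_cardiomegaly` the target CTR is drawn uniformly from
#' `(0.51, 0.60)`, otherwise from `(0.40, 0.50)`, so a screening classifier
#' sees both outcomes.  `two_class = TRUE` collapses heart and clavicles
#' into the background, emulating lung-only binary masks.
#'
#' @param n number of phantoms (>= 1).
#' @param side frame side in pixels.
#' @param seed master seed; the dataset is a pure function of the arguments.
#' @param two_class produce lung-only masks (classes 0/1).
#' @param p_cardiomegaly fraction of phantoms with analytic CTR above 0.50.
#' @param noise_sd intensity noise level.
#' @param clavicles include clavicle bars.
#' @return a list of class `cardionet_phantom_set` of `n`
#'   [make_phantom()] results; see [phantom_images()], [phantom_masks()],
#'   [phantom_ctrs()].
#' @export
make_phantom_dataset <- function(n, side = 96L, seed = 1L, two_class = FALSE,
                                 p_cardiomegaly = 0.5, noise_sd = 0.03,
                                 clavicles = TRUE) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  side <- as.integer(side)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    u <- function(lo, hi) stats::runif(1, lo, hi)
    lungL <- list(cx = u(0.30, 0.34) * side, cy = u(0.46, 0.50) * side,
                  a = u(0.14, 0.17) * side, b = u(0.26, 0.31) * side)
    lungR <- list(cx = u(0.66, 0.70) * side, cy = u(0.46, 0.50) * side,
                  a = u(0.14, 0.17) * side, b = u(0.26, 0.31) * side)
    big <- stats::runif(1) < p_cardiomegaly
    target <- if (big) u(0.51, 0.60) else u(0.40, 0.50)
    ## span of the snapped lungs, then split the cardiac width about a
    ## near-midline center
    snap_c <- function(x) as.integer(round(x))
    snap_a <- function(x) floor(x) + 0.5
    span <- (snap_c(lungR$cx) + snap_a(lungR$a)) -
      (snap_c(lungL$cx) - snap_a(lungL$a))
    cw <- target * span
    frac <- u(0.45, 0.55)
    heart <- list(cx = snap_c(u(0.49, 0.51) * side),
                  cy = snap_c(u(0.58, 0.63) * side),
                  a_left = cw * frac, a_right = cw * (1 - frac),
                  b = u(0.16, 0.20) * side)
    clv <- if (clavicles) {
      t <- max(1.5, u(0.02, 0.03) * side)
      list(half_thickness = t,
           left = c(u(0.15, 0.19), u(0.25, 0.29), u(0.43, 0.47),
                    u(0.18, 0.22)) * side,
           right = c(u(0.53, 0.57), u(0.18, 0.22), u(0.81, 0.85),
                     u(0.25, 0.29)) * side)
    } else NULL
    spec <- phantom_spec(
      side = side, lung_left = lungL, lung_right = lungR, heart = heart,
      clavicles = clv,
      intensity = list(background = 0.55, lung = 0.25, heart = 0.66,
                       clavicle = 0.88, noise_sd = noise_sd,
                       gradient = 0.08),
      seed = sample.int(.Machine$integer.max, 1L)
    )
    ph <- make_phantom(spec)
    if (two_class) ph$mask[ph$mask > 1L] <- 0L
    out[[i]] <- ph
  }
  class(out) <- "cardionet_phantom_set"
  out
}

#' Accessors for phantom datasets
#'
#' @param ds a `cardionet_phantom_set`.
#' @return list of images / list of masks / numeric vector of analytic CTRs.
#' @export
phantom_images <- function(ds) lapply(ds, `[[`, "image")

#' @rdname phantom_images
#' @export
phantom_masks <- function(ds) lapply(ds, `[[`, "mask")

#' @rdname phantom_images
#' @export
phantom_ctrs <- function(ds) vapply(ds, `[[`, numeric(1), "expected_ctr")

#' Write a phantom dataset to disk
#'
#' Writes paired grayscale image PNGs and palette mask PNGs plus a CSV of
#' the analytic CTRs.
#'
#' @param ds a `cardionet_phantom_set`.
#' @param dir output directory (created if missing).
#' @param palette mask palette name, see [cardionet_palette()].
#' @return the CSV path, invisibly.
#' @export
write_phantom_dataset <- function(ds, dir, palette = "jsrt") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pal <- cardionet_palette(palette)
  rows <- lapply(seq_along(ds), function(i) {
    img_path <- file.path(dir, sprintf("phantom_%03d.png", i))
    msk_path <- file.path(dir, sprintf("phantom_%03d_mask.png", i))
    write_radiograph(ds[[i]]$image, img_path)
    write_mask(ds[[i]]$mask, msk_path, pal)
    data.frame(id = i, image = basename(img_path), mask = basename(msk_path),
               expected_ctr = ds[[i]]$expected_ctr)
  })
  csv <- file.path(dir, "expected_ctr.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}
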