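#' Training control parameters
#'
#' Defaults follow the reference training protocol: Adam with learning rate
#' 0.001, batch size 4, 30 epochs, global L2 gradient clipping (epsilon
#' 1e-6), and median-frequency class-balanced cross-entropy (weights are
#' computed from the training masks unless supplied to [cardionet()]).
#'
#' @param learning_rate Adam step size.
#' @param batch_size images per gradient step.
#' @param epochs passes over the training set.
#' @param beta1,beta2,adam_epsilon Adam moment decays and stabilizer.
#' @param gradient_threshold global L2 norm above which gradients are
#'   rescaled; `Inf` disables clipping.
#' @param gradient_epsilon epsilon of the L2 normalization.
#' @param bn_momentum running-statistics update rate for batch norm.
#' @param seed seed for weight initialization and batch shuffling.
#' @param normalize rescale each image linearly to `[0, 1]` before use.
#' @param verbose print per-epoch progress.
#' @return a list of class `cardionet_control`.
#' @export
cardionet_control <- function(learning_rate = 0.001, batch_size = 4L,
                              epochs = 30L, beta1 = 0.9, beta2 = 0.999,
                              adam_epsilon = 1e-8, gradient_threshold = 2,
                              gradient_epsilon = 1e-6, bn_momentum = 0.1,
                              seed = 1L, normalize = TRUE, verbose = FALSE) {
  ctl <- list(
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
    adam_epsilon = adam_epsilon, gradient_threshold = gradient_threshold,
    gradient_epsilon = gradient_epsilon, bn_momentum = bn_momentum,
    seed = as.integer(seed), normalize = normalize, verbose = verbose
  )
  stopifnot(
    ctl$learning_rate >= 0, ctl$batch_size >= 1L, ctl$epochs >= 0L,
    ctl$gradient_threshold > 0, ctl$bn_momentum > 0, ctl$bn_momentum <= 1
  )
  class(ctl) <- "cardionet_control"
  ctl
}

#' Median-frequency class weights
#'
#' For class c, `freq_c` is the number of pixels of class c divided by the
#' total pixel count of the images that contain class c; the weight is the
#' median of all class frequencies divided by `freq_c`.  Rare classes (such
#' as clavicles) therefore receive weights above 1 and dominant classes below
#' 1, balancing the pixel-wise cross-entropy.
#'
#' @param masks list of label matrices with values in `0:(num_classes-1)`.
#' @param num_classes number of classes including background.
#' @return numeric vector of length `num_classes` (class 0 first).
#' @export
median_frequency_weights <- function(masks, num_classes) {
  if (length(masks) == 0L) stop("no masks supplied")
  num_classes <- as.integer(num_classes)
  pix <- numeric(num_classes)
  denom <- numeric(num_classes)
  for (m in masks) {
    cnt <- tabulate(as.integer(m) + 1L, nbins = num_classes)
    pix <- pix + cnt
    denom <- denom + ifelse(cnt > 0L, length(m), 0)
  }
  if (any(pix == 0)) {
    stop(sprintf("class(es) %s never present in the masks; weights undefined",
                 paste(which(pix == 0) - 1L, collapse = ", ")))
  }
  freq <- pix / denom
  stats::median(freq) / freq
}

#' Fit a CardioNet segmentation model
#'
#' Trains the dense-concatenation encoder--decoder on image/mask pairs by
#' minimizing median-frequency-weighted pixel-wise cross-entropy with Adam
#' and global L2 gradient clipping.  Training is deterministic for a fixed
#' `control$seed` on CPU.
#'
#' @param images list of numeric H x W matrices (grayscale radiographs); H
#'   and W must equal `input_side`.
#' @param masks list of integer H x W label matrices with classes
#'   `0:(num_classes-1)` (0 = background).
#' @param variant `"B"` (with the full-resolution feature-boost block) or
#'   `"X"` (the ablation without it).
#' @param num_classes number of classes; default is inferred from the masks.
#' @param input_side image side in pixels; default is taken from the first
#'   image.
#' @param class_weights per-class loss weights; default
#'   [median_frequency_weights()] of the training masks.
#' @param control a [cardionet_control()].
#' @return an object of class `cardionet` with components `schedule`,
#'   `variant`, `num_classes`, `input_side`, `class_weights`, `control`,
#'   `history` (per-step loss and pixel accuracy with epoch labels) and the
#'   network state; supports `print`, `summary`, `coef`, `predict`, `plot`.
#' @examples
#' \donttest{
#' ds <- make_phantom_dataset(8, side = 32, seed = 1)
#' fit <- cardionet(phantom_images(ds), phantom_masks(ds),
#'                  control = cardionet_control(epochs = 1, seed = 1))
#' pred <- predict(fit, phantom_images(ds)[[1]])
#' table(pred$label)
#' }
#' @export
cardionet <- function(images, masks, variant = c("B", "X"),
                      num_classes = NULL, input_side = NULL,
                      class_weights = NULL,
                      control = cardionet_control()) {
  variant <- match.arg(variant)
  stopifnot(inherits(control, "cardionet_control"))
  if (length(images) == 0L || length(images) != length(masks)) {
    stop("images and masks must be non-empty lists of equal length")
  }
  if (is.null(input_side)) input_side <- nrow(images[[1]])
  for (i in seq_along(images)) {
    if (!all(dim(images[[i]]) == c(input_side, input_side)) ||
        !all(dim(masks[[i]]) == c(input_side, input_side))) {
      stop(sprintf("image/mask %d does not match input_side %d", i,
                   input_side))
    }
  }
  if (is.null(num_classes)) {
    num_classes <- max(2L, max(vapply(masks, max, numeric(1))) + 1L)
  }
  if (is.null(class_weights)) {
    class_weights <- median_frequency_weights(masks, num_classes)
  }
  stopifnot(length(class_weights) == num_classes, all(is.finite(class_weights)),
            all(class_weights > 0))

  schedule <- build_cardionet_schedule(num_classes, input_side,
                                       with_fbb = variant == "B")
  net <- cardionet_init(schedule, seed = control$seed)

  if (control$normalize) images <- lapply(images, normalize_image)
  labels <- lapply(masks, function(m) {
    if (min(m) < 0 || max(m) > num_classes - 1L) {
      stop("mask labels outside 0:(num_classes-1)")
    }
    matrix(as.integer(m) + 1L, nrow(m), ncol(m))
  })

  n <- length(images)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(control$seed + 1L)
  exec <- make_executor(net, maxN = control$batch_size)
  hist_rows <- list()
  step <- 0L
  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = control$batch_size)
    for (b in starts) {
      take <- ord[b:min(b + control$batch_size - 1L, n)]
      x <- stack_batch(images[take])
      y <- array(unlist(labels[take], use.names = FALSE),
                 dim = c(input_side, input_side, length(take)))
      sm <- cn_model_train_step(
        exec, x, y, class_weights, control$learning_rate, control$beta1,
        control$beta2, control$adam_epsilon, control$gradient_threshold,
        control$gradient_epsilon, control$bn_momentum, 1e-5
      )
      if (!is.finite(sm$loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d, step %d",
                     ep, step + 1L))
      }
      step <- step + 1L
      hist_rows[[step]] <- c(step, ep, sm$loss, sm$pixel_accuracy)
    }
    if (control$verbose) {
      h <- do.call(rbind, hist_rows)
      message(sprintf("epoch %d/%d  loss %.4f  pixel acc %.4f", ep,
                      control$epochs, mean(h[h[, 2] == ep, 3]),
                      mean(h[h[, 2] == ep, 4])))
    }
  }
  ## pull the trained weights back into the double-precision network state
  ## used by predict()
  trained <- cn_model_get_params(exec)
  for (nm in names(trained)) {
    for (f in names(trained[[nm]])) {
      v <- trained[[nm]][[f]]
      if (f %in% c("b", "gamma", "beta", "rmean", "rvar")) v <- as.numeric(v)
      net$par[[nm]][[f]] <- v
    }
  }
  net$t <- step

  history <- as.data.frame(do.call(rbind, hist_rows))
  if (nrow(history) > 0) {
    names(history) <- c("step", "epoch", "loss", "pixel_accuracy")
  } else {
    history <- data.frame(step = integer(), epoch = integer(),
                          loss = numeric(), pixel_accuracy = numeric())
  }

  structure(list(
    net = net, schedule = schedule, variant = variant,
    num_classes = num_classes, input_side = input_side,
    class_weights = class_weights, control = control, history = history,
    n_train = n, call = match.call()
  ), class = "cardionet")
}

#' Segment images with a fitted CardioNet
#'
#' Runs the network in inference mode (batch-norm running statistics, ties in
#' the per-pixel argmax broken toward the lower class index).
#'
#' @param object a fitted `cardionet`.
#' @param newdata a numeric H x W matrix or a list of them; H and W must
#'   equal the model's `input_side`.
#' @param type `"segmentation"` returns label map plus class probabilities;
#'   `"label"` just the label matrix.
#' @param ... unused.
#' @return for a single image, a `cardionet_segmentation`: list with `label`
#'   (H x W integer matrix, classes `0:(K-1)`), `prob` (H x W x K, softmax,
#'   each pixel summing to 1) and `score` (raw class scores).  For a list
#'   input, a list of those.
#' @export
predict.cardionet <- function(object, newdata,
                              type = c("segmentation", "label"), ...) {
  type <- match.arg(type)
  single <- is.matrix(newdata)
  imgs <- if (single) list(newdata) else newdata
  side <- object$input_side
  for (img in imgs) {
    if (!all(dim(img) == c(side, side))) {
      stop(sprintf("image is %dx%d but the model expects %dx%d",
                   nrow(img), ncol(img), side, side))
    }
  }
  if (object$control$normalize) imgs <- lapply(imgs, normalize_image)
  maxN <- min(length(imgs), 8L)
  exec <- make_executor(object$net, maxN)
  out <- vector("list", length(imgs))
  for (b in seq(1L, length(imgs), by = maxN)) {
    take <- b:min(b + maxN - 1L, length(imgs))
    x <- stack_batch(imgs[take])
    sc <- cn_model_forward(exec, x, FALSE, 0.1, 1e-5)$scores
    if (any(!is.finite(range(sc)))) stop("non-finite class scores")
    pr <- cn_softmax(sc)
    lb <- cn_argmax(sc)
    for (j in seq_along(take)) {
      lab <- matrix(as.integer(lb[, , j]) - 1L, side, side)
      out[[take[j]]] <- if (type == "label") lab else {
        structure(list(
          label = lab,
          prob = array(pr[, , , j], dim = dim(pr)[1:3]),
          score = array(sc[, , , j], dim = dim(sc)[1:3])
        ), class = "cardionet_segmentation")
      }
    }
  }
  if (single) out[[1]] else out
}

#' @export
print.cardionet <- function(x, ...) {
  cat(sprintf("CardioNet-%s: %d-class segmentation at %dx%d\n", x$variant,
              x$num_classes, x$input_side, x$input_side))
  cat(sprintf("  trained on %d images, %d epochs, %d gradient steps\n",
              x$n_train, x$control$epochs, nrow(x$history)))
  if (nrow(x$history) > 0) {
    last <- x$history[x$history$epoch == max(x$history$epoch), ]
    cat(sprintf("  final epoch: loss %.4f, training pixel accuracy %.4f\n",
                mean(last$loss), mean(last$pixel_accuracy)))
  }
  cat(sprintf("  class weights: %s\n",
              paste(sprintf("%.3f", x$class_weights), collapse = ", ")))
  invisible(x)
}

#' @export
summary.cardionet <- function(object, ...) {
  out <- list(fit = object, audit = audit_schedule(object$schedule))
  class(out) <- "summary.cardionet"
  out
}

#' @export
print.summary.cardionet <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$audit)
  invisible(x)
}

#' Extract network weights
#'
#' @param object a fitted `cardionet`.
#' @param ... unused.
#' @return named list of per-layer parameter lists.
#' @export
coef.cardionet <- function(object, ...) object$net$par

#' Plot training curves
#'
#' Loss and training pixel accuracy against epoch, mirroring the usual
#' convergence diagnostics for this architecture family.
#'
#' @param x a fitted `cardionet`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cardionet <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) stop("no training history to plot")
  ep <- sort(unique(h$epoch))
  loss <- vapply(ep, function(e) mean(h$loss[h$epoch == e]), numeric(1))
  acc <- vapply(ep, function(e) mean(h$pixel_accuracy[h$epoch == e]),
                numeric(1))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(ep, loss, type = "b", xlab = "epoch", ylab = "loss",
                 main = "training loss", ...)
  graphics::plot(ep, acc, type = "b", xlab = "epoch",
                 ylab = "pixel accuracy", main = "training accuracy", ...)
  invisible(x)
}

#' Evaluate a fitted model on a labelled test set
#'
#' Predicts every image and scores the result per class with
#' accuracy/Jaccard/Dice.
#'
#' @param object a fitted `cardionet`.
#' @param images,masks test images and ground-truth label matrices.
#' @param aggregate `"micro"` (confusion counts summed over images before
#'   scoring, the default) or `"macro"` (per-image scores averaged).
#' @return a `cardionet_metrics` data frame (see [class_metrics()]).
#' @export
evaluate_cardionet <- function(object, images, masks,
                               aggregate = c("micro", "macro")) {
  aggregate <- match.arg(aggregate)
  preds <- predict(object, images, type = "label")
  if (is.matrix(preds)) preds <- list(preds)
  class_metrics(preds, masks, classes = 0:(object$num_classes - 1L),
                aggregate = aggregate)
}

#' Two-fold cross-evaluation protocol
#'
#' Splits the data into odd-numbered and even-numbered folds, trains on one
#' fold (optionally expanded by the deterministic augmentation cascade of
#' [expand_fold()]), tests on the other, swaps, and averages the two per-class
#' metric tables.  Augmentation is applied only to the training fold, never
#' to the test fold.
#'
#' @param images,masks the full labelled dataset.
#' @param variant,num_classes,control as in [cardionet()].
#' @param augment expand each training fold with the flip/translate cascade.
#' @return list with `fold1`, `fold2` (each: fitted model and metrics on the
#'   held-out fold) and `average` (the [two_fold_average()] of the metrics).
#' @export
two_fold_protocol <- function(images, masks, variant = "B",
                              num_classes = NULL,
                              control = cardionet_control(),
                              augment = TRUE) {
  n <- length(images)
  if (n < 2L) stop("need at least two items for a two-fold split")
  odd <- seq(1L, n, by = 2L)
  even <- seq(2L, n, by = 2L)
  if (is.null(num_classes)) {
    num_classes <- max(2L, max(vapply(masks, max, numeric(1))) + 1L)
  }
  run <- function(tr, te) {
    timg <- images[tr]; tmsk <- masks[tr]
    if (augment) {
      aug <- expand_fold(timg, tmsk)
      timg <- aug$images; tmsk <- aug$masks
    }
    fit <- cardionet(timg, tmsk, variant = variant,
                     num_classes = num_classes, control = control)
    list(fit = fit,
         metrics = evaluate_cardionet(fit, images[te], masks[te]))
  }
  f1 <- run(odd, even)
  f2 <- run(even, odd)
  list(fold1 = f1, fold2 = f2,
       average = two_fold_average(f1$metrics, f2$metrics))
}

#' Save / load a fitted CardioNet
#'
#' The checkpoint stores the weights together with the layer schedule; on
#' load the schedule is compared against the stored one so weights can never
#' be attached to a mismatched topology.
#'
#' @param object a fitted `cardionet`.
#' @param path file path.
#' @return `save_cardionet` the path invisibly; `load_cardionet` the
#'   restored `cardionet` object.
#' @export
save_cardionet <- function(object, path) {
  stopifnot(inherits(object, "cardionet"))
  state <- list(
    par = object$net$par, t = object$net$t,
    schedule = object$schedule, variant = object$variant,
    num_classes = object$num_classes, input_side = object$input_side,
    class_weights = object$class_weights, control = object$control,
    history = object$history, n_train = object$n_train
  )
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_cardionet
#' @export
load_cardionet <- function(path) {
  state <- readRDS(path)
  rebuilt <- build_cardionet_schedule(
    state$num_classes, state$input_side,
    with_fbb = state$variant == "B"
  )
  if (!identical(as.data.frame(rebuilt), as.data.frame(state$schedule))) {
    stop("checkpoint schedule does not match the current topology definition")
  }
  net <- cardionet_init(state$schedule, seed = 1L)
  net$par <- state$par
  net$t <- state$t
  structure(list(
    net = net, schedule = state$schedule, variant = state$variant,
    num_classes = state$num_classes, input_side = state$input_side,
    class_weights = state$class_weights, control = state$control,
    history = state$history, n_train = state$n_train,
    call = quote(load_cardionet())
  ), class = "cardionet")
}
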