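## Executable computation graph driven by a cardionet_schedule.
##
## The network state lives in an environment: `par` holds one parameter list
## per layer (W/b for convolutions, Wd/Wp for depth-wise separable pairs,
## gamma/beta/rmean/rvar for batch norm), `adam` the optimizer moments.
## Forward and backward walk the schedule rows, which are stored in
## topological order; all heavy lifting happens in the compiled primitives.

layer_has_params <- function(kind) {
  kind %in% c("conv3x3", "bottleneck1x1", "dw_sep_conv3x3")
}

#' Initialize network weights for a schedule
#'
#' He-normal initialization: 3x3 convolution weights are drawn with standard
#' deviation sqrt(2 / (9 * in_channels)), point-wise maps with
#' sqrt(2 / in_channels).  Batch-norm scale starts at 1, shift at 0, running
#' statistics at (0, 1).  Convolutions followed by batch norm carry no bias.
#'
#' @param schedule a `cardionet_schedule`.
#' @param seed integer seed for the draws.
#' @return an environment holding `schedule`, the layer table, the shape
#'   trace and the parameter list.
#' @keywords internal
cardionet_init <- function(schedule, seed = 1L) {
  validate_schedule(schedule)
  s <- as.data.frame(schedule)
  net <- new.env(parent = emptyenv())
  net$schedule <- schedule
  net$layers <- s
  net$shapes <- propagate_shapes(schedule)
  net$t <- 0L
  par <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (i in seq_len(nrow(s))) {
    kind <- s$kind[i]
    if (!layer_has_params(kind)) next
    inc <- s$in_channels[i]; outc <- s$out_channels[i]
    p <- list()
    if (kind == "dw_sep_conv3x3") {
      p$Wd <- matrix(stats::rnorm(9L * inc, sd = sqrt(2 / 9)), 9L, inc)
      p$Wp <- matrix(stats::rnorm(inc * outc, sd = sqrt(2 / inc)), inc, outc)
    } else {
      k <- s$kernel[i]
      fan <- k * k * inc
      p$W <- matrix(stats::rnorm(fan * outc, sd = sqrt(2 / fan)), fan, outc)
    }
    if (s$followed_by_bn_relu[i]) {
      p$gamma <- rep(1, outc); p$beta <- rep(0, outc)
      p$rmean <- rep(0, outc); p$rvar <- rep(1, outc)
    } else {
      p$b <- rep(0, outc)
    }
    par[[s$name[i]]] <- p
  }
  net$par <- par
  net
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

## Forward pass.  x is an H x W x C x N array already normalized.  Returns
## activations, per-layer caches needed for the backward pass, and the raw
## class scores (output of the final bottleneck).
cn_forward <- function(net, x, training = FALSE, bn_momentum = 0.1,
                       bn_eps = 1e-5, check_finite = !training) {
  s <- net$layers
  acts <- list(input = x)
  caches <- list()
  for (i in seq_len(nrow(s))) {
    kind <- s$kind[i]
    nm <- s$name[i]
    if (kind %in% c("softmax", "pixel_classification")) {
      if (training) next
      src <- acts[[s$input[i]]]
      acts[[nm]] <- if (kind == "softmax") cn_softmax(src) else cn_argmax(src)
      next
    }
    if (kind == "concat") {
      src <- strsplit(s$concat_sources[i], ",")[[1]]
      acts[[nm]] <- cn_concat(lapply(src, function(z) acts[[z]]))
      next
    }
    xin <- acts[[s$input[i]]]
    p <- net$par[[nm]]
    if (kind == "pool2x2") {
      pf <- cn_maxpool_fwd(xin)
      acts[[nm]] <- pf$y
      caches[[nm]] <- list(idx = pf$idx, in_dim = dim(xin))
    } else if (kind == "unpool2x2") {
      pc <- caches[[s$pool_pair[i]]]
      acts[[nm]] <- cn_pool_scatter(xin, pc$idx, pc$in_dim[1], pc$in_dim[2])
      caches[[nm]] <- list(idx = pc$idx)
    } else if (kind == "dw_sep_conv3x3") {
      mid <- cn_dwconv_fwd(xin, p$Wd)
      z <- cn_conv_fwd(mid, p$Wp, if (is.null(p$b)) numeric(0) else p$b, 1L)
      caches[[nm]] <- list(mid = mid)
      acts[[nm]] <- cn_finish_unit(net, nm, z, caches, training, bn_momentum,
                                   bn_eps)
      caches[[nm]]$z <- z
      caches[[nm]]$bn <- net$.last_bn
    } else {  # conv3x3 / bottleneck1x1
      z <- cn_conv_fwd(xin, p$W, if (is.null(p$b)) numeric(0) else p$b,
                       s$kernel[i])
      acts[[nm]] <- cn_finish_unit(net, nm, z, caches, training, bn_momentum,
                                   bn_eps)
      caches[[nm]] <- list(z = z, bn = net$.last_bn)
    }
    if (check_finite && kind != "pool2x2") {
      r <- range(acts[[nm]])
      if (any(!is.finite(r))) {
        stop(sprintf("non-finite activations at layer %s", nm))
      }
    }
  }
  list(acts = acts, caches = caches,
       scores = acts[["Bottleneck-C-8"]],
       probs = acts[["Softmax"]],
       labels = acts[["Pixel-Classification"]])
}

## BN + ReLU tail shared by the convolutional units; stores the batch
## statistics in net$.last_bn for the caller to cache.
cn_finish_unit <- function(net, nm, z, caches, training, bn_momentum, bn_eps) {
  p <- net$par[[nm]]
  if (is.null(p$gamma)) {
    net$.last_bn <- NULL
    return(z)
  }
  bf <- cn_bn_fwd(z, p$gamma, p$beta, p$rmean, p$rvar, bn_momentum, bn_eps,
                  training)
  if (training) {
    net$par[[nm]]$rmean <- bf$rmean
    net$par[[nm]]$rvar <- bf$rvar
  }
  net$.last_bn <- list(mean = bf$mean, invstd = bf$invstd)
  cn_relu_fwd(bf$y)
}

## Backward pass from the gradient of the class scores.  Returns a list of
## per-layer parameter gradients keyed by layer name.
cn_backward <- function(net, fw, dscores) {
  s <- net$layers
  gact <- list()
  gact[["Bottleneck-C-8"]] <- dscores
  grads <- list()
  acc <- function(nm, g) {
    if (nm == "input") return()
    cur <- gact[[nm]]
    gact[[nm]] <<- if (is.null(cur)) g else cur + g
  }
  for (i in rev(seq_len(nrow(s)))) {
    kind <- s$kind[i]
    if (kind %in% c("softmax", "pixel_classification")) next
    nm <- s$name[i]
    g <- gact[[nm]]
    if (is.null(g)) next
    gact[[nm]] <- NULL  # free
    if (kind == "concat") {
      src <- strsplit(s$concat_sources[i], ",")[[1]]
      sizes <- vapply(src, function(z) {
        dim(fw$acts[[z]])[3]
      }, integer(1))
      parts <- cn_split(g, sizes)
      for (j in seq_along(src)) acc(src[j], parts[[j]])
      next
    }
    inp <- s$input[i]
    if (kind == "pool2x2") {
      pc <- fw$caches[[nm]]
      acc(inp, cn_pool_scatter(g, pc$idx, pc$in_dim[1], pc$in_dim[2]))
      next
    }
    if (kind == "unpool2x2") {
      acc(inp, cn_pool_gather(g, fw$caches[[nm]]$idx))
      next
    }
    p <- net$par[[nm]]
    cache <- fw$caches[[nm]]
    glay <- list()
    if (!is.null(p$gamma)) {
      g <- cn_relu_bwd(fw$acts[[nm]], g)
      bb <- cn_bn_bwd(cache$z, g, p$gamma, cache$bn$mean, cache$bn$invstd)
      g <- bb$dx
      glay$gamma <- bb$dgamma
      glay$beta <- bb$dbeta
    }
    need_dx <- inp != "input"
    if (kind == "dw_sep_conv3x3") {
      pw <- cn_conv_bwd(cache$mid, p$Wp, g, 1L, TRUE, !is.null(p$b))
      glay$Wp <- pw$dw
      if (!is.null(p$b)) glay$b <- pw$db
      dwb <- cn_dwconv_bwd(fw$acts[[inp]], p$Wd, pw$dx, need_dx)
      glay$Wd <- dwb$dw
      if (need_dx) acc(inp, dwb$dx)
    } else {
      cb <- cn_conv_bwd(fw$acts[[inp]], p$W, g, s$kernel[i], need_dx,
                        !is.null(p$b))
      glay$W <- cb$dw
      if (!is.null(p$b)) glay$b <- cb$db
      if (need_dx) acc(inp, cb$dx)
    }
    grads[[nm]] <- glay
  }
  grads
}

## Global-L2 gradient clipping followed by one Adam step over all tensors.
cn_adam_step <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, clip_threshold = Inf,
                         clip_eps = 1e-6) {
  sq <- 0
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) sq <- sq + sum(grads[[nm]][[f]]^2)
  }
  gnorm <- sqrt(sq)
  scale <- if (is.finite(clip_threshold) && gnorm > clip_threshold) {
    clip_threshold / (gnorm + clip_eps)
  } else 1
  net$t <- net$t + 1L
  t <- net$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  if (is.null(net$adam)) net$adam <- list()
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]] * scale
      key <- paste0(nm, ".", f)
      st <- net$adam[[key]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      net$adam[[key]] <- st
      net$par[[nm]][[f]] <- net$par[[nm]][[f]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  gnorm
}

## Build the single-precision training executor for a network.  The
## executor mirrors the schedule (minus the parameter-free softmax /
## pixel-classification tail) with 0-based layer indices; its float
## arithmetic is validated against the double-precision primitives in the
## test suite.
make_executor <- function(net, maxN) {
  s <- net$layers
  tr <- net$shapes
  keep <- !(s$kind %in% c("softmax", "pixel_classification"))
  s2 <- s[keep, , drop = FALSE]
  tr2 <- tr[keep, , drop = FALSE]
  side <- attr(net$schedule, "input_side")
  inch <- attr(net$schedule, "input_channels")
  kindcode <- c(conv3x3 = 0L, bottleneck1x1 = 0L, dw_sep_conv3x3 = 1L,
                pool2x2 = 2L, unpool2x2 = 3L, concat = 4L)
  idx_of <- function(nm) match(nm, s2$name) - 1L
  shape_of <- function(nm) {
    if (nm == "input") return(c(side, side, inch))
    j <- match(nm, tr2$name)
    c(tr2$height[j], tr2$width[j], tr2$channels[j])
  }
  descr <- lapply(seq_len(nrow(s2)), function(i) {
    kind <- kindcode[[s2$kind[i]]]
    inp <- if (kind == 4L) {
      strsplit(s2$concat_sources[i], ",")[[1]][1]
    } else s2$input[i]
    ish <- shape_of(if (kind == 4L) inp else s2$input[i])
    osh <- shape_of(s2$name[i])
    list(
      name = s2$name[i], kind = kind,
      k = if (is.na(s2$kernel[i])) 1L else s2$kernel[i],
      cin = as.integer(ish[3]), cout = as.integer(osh[3]),
      in_h = as.integer(ish[1]), in_w = as.integer(ish[2]),
      h = as.integer(osh[1]), w = as.integer(osh[2]),
      input = if (kind == 4L || s2$input[i] == "input") -1L
              else idx_of(s2$input[i]),
      pair = if (is.na(s2$pool_pair[i])) -1L else idx_of(s2$pool_pair[i]),
      bn = s2$followed_by_bn_relu[i],
      sources = if (kind == 4L) {
        vapply(strsplit(s2$concat_sources[i], ",")[[1]], idx_of, integer(1))
      } else integer(0)
    )
  })
  ## concat keeps input = -1 but cin of first source for bookkeeping
  ptr <- cn_model_build(descr, side, side, inch, as.integer(maxN))
  cn_model_set_params(ptr, net$par)
  ptr
}

#' Rescale an image linearly onto [0, 1]
#'
#' Per-image min-max normalization used before inference and training; a
#' constant image maps to all zeros.
#'
#' @param img numeric matrix.
#' @return matrix with values in `[0, 1]`.
#' @export
normalize_image <- function(img) {
  r <- range(img)
  if (!all(is.finite(r))) stop("image contains non-finite values")
  if (r[2] > r[1]) (img - r[1]) / (r[2] - r[1]) else img * 0
}

## Stack a list of H x W matrices into an H x W x C x N tensor.
stack_batch <- function(images, channels = 1L) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  array(unlist(images, use.names = FALSE), dim = c(H, W, channels,
                                                   length(images)))
}
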