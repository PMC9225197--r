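test_that("unpooling is the exact inverse placement of its paired pooling", {
  set.seed(5)
  for (rep in 1:5) {
    x <- array(rnorm(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
    pf <- cardionet:::cn_maxpool_fwd(x)
    up <- cardionet:::cn_pool_scatter(pf$y, pf$idx, 8L, 8L)
    # maxima restored in place, everything else zero
    for (n in 1:2) for (c in 1:3) {
      sl <- x[, , c, n]
      ups <- up[, , c, n]
      nz <- which(ups != 0)
      expect_true(all(ups[nz] == sl[nz]))
      expect_equal(sum(ups != 0), 16)  # one survivor per 2x2 window
      # every survivor is its window's maximum
      for (wi in 0:3) for (hi in 0:3) {
        win <- sl[hi * 2 + 1:2, wi * 2 + 1:2]
        expect_equal(max(win), pf$y[hi + 1, wi + 1, c, n])
      }
    }
  }
})

test_that("forward pass is deterministic with well-formed per-pixel scores", {
  sch <- build_cardionet_schedule(3, 32, TRUE)
  net <- cardionet:::cardionet_init(sch, seed = 2)
  x <- array(rnorm(32 * 32), dim = c(32, 32, 1, 1))
  f1 <- cardionet:::cn_forward(net, x, training = FALSE)
  f2 <- cardionet:::cn_forward(net, x, training = FALSE)
  expect_identical(f1$scores, f2$scores)
  expect_true(all(is.finite(f1$scores)))
  # softmax normalizes each pixel
  sums <- apply(f1$probs, c(1, 2, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  # channel count entering the classifier head
  expect_equal(dim(f1$acts[["Concatenation-8"]])[3], 160)
  xnet <- cardionet:::cardionet_init(
    build_cardionet_schedule(3, 32, FALSE), seed = 2
  )
  fx <- cardionet:::cn_forward(xnet, x, training = FALSE)
  expect_equal(dim(fx$acts[["Concatenation-8"]])[3], 128)
})

test_that("constant-zero input yields finite scores and a defined labeling", {
  sch <- build_cardionet_schedule(4, 32, TRUE)
  net <- cardionet:::cardionet_init(sch, seed = 3)
  x <- array(0, dim = c(32, 32, 1, 1))
  fw <- cardionet:::cn_forward(net, x, training = FALSE)
  expect_true(all(is.finite(fw$scores)))
  expect_true(all(fw$labels %in% 1:4))
})

test_that("analytic gradients match finite differences through every unit type", {
  sch <- build_cardionet_schedule(3, 32, TRUE)
  net <- cardionet:::cardionet_init(sch, seed = 7)
  set.seed(11)
  x <- array(rnorm(32 * 32), dim = c(32, 32, 1, 1))
  y <- array(sample(1:3, 32 * 32, TRUE), dim = c(32, 32, 1))
  w <- c(1, 1.4, 0.7)
  lossfn <- function() {
    f <- cardionet:::cn_forward(net, x, training = TRUE)
    cardionet:::cn_softmax_ce(f$scores, y, w, FALSE)$loss
  }
  fwt <- cardionet:::cn_forward(net, x, training = TRUE)
  sm <- cardionet:::cn_softmax_ce(fwt$scores, y, w, TRUE)
  gr <- cardionet:::cn_backward(net, fwt, sm$dscores)
  eps <- 1e-6
  cases <- list(
    c("Conv-1-1", "W", 3),            # standard conv with BN
    c("U-DW-Sep-Conv-3-2", "Wd", 5),  # depth-wise kernel
    c("U-DW-Sep-Conv-3-2", "Wp", 10), # point-wise map
    c("Bottleneck-C-6", "gamma", 3),  # BN scale after a 640-wide concat
    c("Boost-Conv-2-1", "W", 17),     # boost-block conv
    c("Bottleneck-C-8", "beta", 1)    # classifier-head BN shift
  )
  for (cs in cases) {
    layer <- cs[1]; field <- cs[2]; i <- as.integer(cs[3])
    p0 <- net$par[[layer]][[field]][i]
    net$par[[layer]][[field]][i] <- p0 + eps
    lp <- lossfn()
    net$par[[layer]][[field]][i] <- p0 - eps
    lm <- lossfn()
    net$par[[layer]][[field]][i] <- p0
    num <- (lp - lm) / (2 * eps)
    ana <- gr[[layer]][[field]][i]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-3)
  }
})

test_that("the float executor agrees with the reference primitives", {
  sch <- build_cardionet_schedule(3, 32, TRUE)
  net <- cardionet:::cardionet_init(sch, seed = 4)
  set.seed(8)
  x <- array(rnorm(32 * 32 * 2), dim = c(32, 32, 1, 2))
  fw <- cardionet:::cn_forward(net, x, training = FALSE)
  ex <- cardionet:::make_executor(net, 2)
  fe <- cardionet:::cn_model_forward(ex, x, FALSE, 0.1, 1e-5)
  expect_lt(max(abs(fw$scores - fe$scores)), 1e-4)

  # one full training step: loss, clipped-gradient norm and updated weights
  y <- array(sample(1:3, 32 * 32 * 2, TRUE), dim = c(32, 32, 2))
  w <- c(1, 1.3, 0.8)
  st <- cardionet:::cn_model_train_step(ex, x, y, w, 1e-3, 0.9, 0.999, 1e-8,
                                        2, 1e-6, 0.1, 1e-5)
  fwt <- cardionet:::cn_forward(net, x, training = TRUE)
  sm <- cardionet:::cn_softmax_ce(fwt$scores, y, w, TRUE)
  gr <- cardionet:::cn_backward(net, fwt, sm$dscores)
  gn <- cardionet:::cn_adam_step(net, gr, 1e-3, clip_threshold = 2)
  expect_lt(abs(st$loss - sm$loss), 1e-5)
  expect_lt(abs(st$gnorm - gn) / gn, 1e-4)
  pe <- cardionet:::cn_model_get_params(ex)
  for (nm in c("Conv-1-1", "DW-Sep-Conv-4-1", "Bottleneck-C-8")) {
    for (f in names(pe[[nm]])) {
      expect_lt(max(abs(pe[[nm]][[f]] - net$par[[nm]][[f]])), 1e-4)
    }
  }
})

test_that("checkpoints round-trip and refuse mismatched topologies", {
  ds <- make_phantom_dataset(2, side = 32, seed = 9)
  fit <- cardionet(phantom_images(ds), phantom_masks(ds),
                   control = cardionet_control(epochs = 1, seed = 1))
  path <- tempfile(fileext = ".rds")
  save_cardionet(fit, path)
  back <- load_cardionet(path)
  img <- phantom_images(ds)[[1]]
  expect_identical(predict(fit, img, type = "label"),
                   predict(back, img, type = "label"))
  # corrupt the stored variant: the rebuilt schedule no longer matches
  state <- readRDS(path)
  state$variant <- "X"
  saveRDS(state, path)
  expect_error(load_cardionet(path), "topology")
  unlink(path)
})

test_that("images with the wrong spatial size are rejected", {
  ds <- make_phantom_dataset(2, side = 32, seed = 10)
  fit <- cardionet(phantom_images(ds), phantom_masks(ds),
                   control = cardionet_control(epochs = 0, seed = 1))
  expect_error(predict(fit, matrix(0, 48, 48)), "48x48")
})
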