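test_that("median-frequency weighting balances the cross-entropy", {
  # perfectly balanced classes: all weights 1
  m <- matrix(rep(0:3, each = 16), 8, 8)
  expect_equal(median_frequency_weights(list(m), 4), rep(1, 4))
  # rare classes weigh more than dominant ones
  m2 <- matrix(0L, 10, 10); m2[1, 1:2] <- 1L; m2[5:10, ] <- 2L
  w <- median_frequency_weights(list(m2), 3)
  expect_gt(w[2], 1)           # 2 pixels of class 1
  expect_lt(w[3], w[2])
  expect_true(which.max(w) == 2)
  # hand tally on a two-image set: class 1 present only in the first image
  a <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  b <- matrix(c(0L, 0L, 0L, 2L), 2, 2)
  w2 <- median_frequency_weights(list(a, b), 3)
  freq <- c(5 / 8, 2 / 4, 1 / 4)   # pixels / pixels-of-images-containing
  expect_equal(w2, median(freq) / freq)
  expect_error(median_frequency_weights(list(a), 3), "never present")
})

test_that("a zero learning rate leaves the weights untouched", {
  ds <- make_phantom_dataset(2, side = 32, seed = 3)
  ctl0 <- cardionet_control(epochs = 1, learning_rate = 0, seed = 5)
  fit <- cardionet(phantom_images(ds), phantom_masks(ds), control = ctl0)
  sch <- build_cardionet_schedule(4, 32, TRUE)
  fresh <- cardionet:::cardionet_init(sch, seed = 5)
  expect_equal(coef(fit)[["Conv-1-1"]]$W, fresh$par[["Conv-1-1"]]$W,
               tolerance = 1e-6)
  expect_equal(coef(fit)[["U-Conv-1-1"]]$b, fresh$par[["U-Conv-1-1"]]$b,
               tolerance = 1e-6)
})

test_that("training is reproducible and its history is recorded", {
  ds <- make_phantom_dataset(4, side = 32, seed = 7)
  ctl <- cardionet_control(epochs = 2, seed = 21)
  f1 <- cardionet(phantom_images(ds), phantom_masks(ds), control = ctl)
  f2 <- cardionet(phantom_images(ds), phantom_masks(ds), control = ctl)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_equal(nrow(f1$history), 2 * 1)   # 4 images / batch 4, 2 epochs
  expect_true(all(c("step", "epoch", "loss", "pixel_accuracy") %in%
                    names(f1$history)))
  expect_output(print(f1), "CardioNet-B")
  expect_s3_class(summary(f1), "summary.cardionet")
  grDevices::pdf(NULL)
  expect_silent(plot(f1))
  grDevices::dev.off()
})

test_that("the network can overfit a single phantom", {
  ds <- make_phantom_dataset(1, side = 48, seed = 9)
  ctl <- cardionet_control(epochs = 150, batch_size = 1, seed = 2)
  fit <- cardionet(phantom_images(ds), phantom_masks(ds), control = ctl)
  h <- fit$history
  expect_gt(h$loss[1], tail(h$loss, 1))    # loss decreased
  expect_gte(tail(h$pixel_accuracy, 1), 0.99)
  pred <- predict(fit, phantom_images(ds)[[1]], type = "label")
  expect_gt(mean(pred == phantom_masks(ds)[[1]]), 0.98)
})

test_that("the two-fold protocol trains on one fold and scores the other", {
  ds <- make_phantom_dataset(4, side = 32, seed = 15)
  res <- two_fold_protocol(phantom_images(ds), phantom_masks(ds),
                           control = cardionet_control(epochs = 1, seed = 3),
                           augment = TRUE)
  expect_named(res, c("fold1", "fold2", "average"))
  # augmentation expanded each 2-image training fold 32-fold
  expect_equal(res$fold1$fit$n_train, 64)
  expect_equal(res$average$class, 0:3)
  expect_true(all(res$average$jaccard >=
                    pmin(res$fold1$metrics$jaccard, res$fold2$metrics$jaccard)))
  expect_true(all(res$average$jaccard <=
                    pmax(res$fold1$metrics$jaccard, res$fold2$metrics$jaccard)))
})

test_that("degenerate training inputs are rejected", {
  ds <- make_phantom_dataset(2, side = 32, seed = 1)
  expect_error(cardionet(list(), list()), "non-empty")
  bad <- phantom_masks(ds)
  bad[[1]][1, 1] <- 9L
  expect_error(cardionet(phantom_images(ds), bad, num_classes = 4), "labels")
})
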