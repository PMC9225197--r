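test_that("horizontal flip is an involution that preserves class histograms", {
  p <- tiny_pair(16, 1)
  f <- hflip(p$image, p$mask)
  ff <- hflip(f$image, f$mask)
  expect_identical(ff$image, p$image)
  expect_identical(ff$mask, p$mask)
  expect_equal(tabulate(f$mask + 1L, 4), tabulate(p$mask + 1L, 4))
  # an asymmetric structure swaps sides
  m <- matrix(0L, 8, 8); m[, 1:2] <- 1L
  fl <- hflip(matrix(0, 8, 8), m)
  expect_true(all(fl$mask[, 7:8] == 1L) && all(fl$mask[, 1:6] == 0L))
  expect_error(hflip(matrix(0, 4, 4), matrix(0L, 5, 5)), "shape")
})

test_that("translation follows the stated axis convention", {
  expect_identical(translate(diag(4), diag(4) * 1L, 0, 0)$mask, diag(4) * 1L)
  # single foreground pixel at (r, c), shift (dx = 4, dy = -4):
  # moves 4 columns right and 4 rows up
  m <- matrix(0L, 16, 16); m[10, 5] <- 1L
  tr <- translate(matrix(0, 16, 16), m, 4, -4)
  expect_equal(which(tr$mask == 1L, arr.ind = TRUE)[1, ], c(row = 6, col = 9))
  # class histogram changes only by the border-clipped pixels
  p <- tiny_pair(16, 2)
  dx <- 5; dy <- -3
  tr2 <- translate(p$image, p$mask, dx, dy)
  kept <- p$mask[(1 - dy):16, 1:(16 - dx)]   # region surviving the shift
  expect_equal(tabulate(tr2$mask + 1L, 4) - c(16^2 - length(kept), 0, 0, 0),
               tabulate(kept + 1L, 4))
  expect_error(translate(p$image, p$mask, 16, 0), "shift")
})

test_that("the four-stage cascade multiplies a fold by exactly 32", {
  for (n in c(1, 3)) {
    imgs <- replicate(n, matrix(runif(256), 16, 16), simplify = FALSE)
    msks <- replicate(n, matrix(sample(0:3, 256, TRUE), 16, 16),
                      simplify = FALSE)
    aug <- expand_fold(imgs, msks)
    expect_equal(unname(aug$stage_sizes),
                 c(2L * n, 4L * n, 8L * n, 32L * n))
    expect_length(aug$images, 32L * n)
    expect_length(aug$masks, 32L * n)
    expect_true(all(unlist(aug$masks) %in% 0:3))
  }
  aug40 <- expand_fold(list(matrix(0, 16, 16)), list(matrix(0L, 16, 16)),
                       include_earlier_stages = TRUE)
  expect_length(aug40$images, 40)
  expect_error(expand_fold(list(), list()), "non-empty")
})

test_that("resizing interpolates images but never invents mask labels", {
  p <- tiny_pair(32, 3)
  same <- resize_pair(p$image, p$mask, 32)
  expect_equal(same$mask, p$mask)
  down <- resize_pair(p$image, p$mask, 16)
  expect_equal(dim(down$image), c(16L, 16L))
  expect_true(all(down$mask %in% unique(as.vector(p$mask))))
  flat <- resize_pair(matrix(0.42, 32, 32), p$mask, 20)
  expect_true(all(abs(flat$image - 0.42) < 1e-8))
  expect_error(resize_pair(p$image, p$mask, 8), ">= 16")
})
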