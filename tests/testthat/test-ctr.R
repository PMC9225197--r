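test_that("horizontal extents match an exhaustive column scan", {
  m <- matrix(0L, 12, 12)
  m[, 7] <- 1L
  expect_equal(unname(horizontal_extent(m, 1)), c(7, 7))
  m2 <- matrix(0L, 5, 9); m2[3, ] <- 1L
  expect_equal(unname(horizontal_extent(m2, 1)), c(1, 9))
  set.seed(21)
  for (rep in 1:10) {
    blob <- matrix(rbinom(400, 1, 0.3), 20, 20)
    if (!any(blob == 1)) next
    ext <- horizontal_extent(blob, 1, suppress_islands = FALSE)
    cols <- which(apply(blob == 1, 2, any))
    expect_equal(unname(ext), c(min(cols), max(cols)))
  }
  expect_error(horizontal_extent(matrix(0L, 4, 4), 1), "absent")
})

test_that("island suppression ignores stray pixels but keeps both lungs", {
  m <- matrix(0L, 40, 40)
  m[10:30, 5:12] <- 1L    # left lung
  m[10:30, 28:35] <- 1L   # right lung
  m[2, 39] <- 1L          # stray misprediction
  expect_equal(unname(horizontal_extent(m, 1)), c(5, 35))
  expect_equal(unname(horizontal_extent(m, 1, suppress_islands = FALSE)),
               c(5, 39))
})

test_that("the printed worked example reproduces ratio and screening call", {
  meas <- ctr_ratio(126, 304)
  expect_equal(round(meas$ctr, 4), 0.4145)
  expect_false(meas$decision == "cardiomegaly")
  expect_equal(meas$decision, "below_normal")
  # threshold semantics
  expect_equal(ctr_decision(0.55), "cardiomegaly")
  expect_equal(ctr_decision(0.46), "normal")
  expect_equal(ctr_decision(0.50), "normal")
  expect_equal(ctr_decision(0.41), "below_normal")
})

test_that("a mask with known extents yields the same measurement", {
  m <- matrix(0L, 60, 350)
  m[20:50, 11:80] <- 1L            # left lung
  m[20:50, 245:315] <- 1L          # right lung: thoracic span 315-11 = 304
  m[30:55, 100:226] <- 2L          # heart: cardiac span 226-100 = 126
  meas <- compute_ctr(m)
  expect_equal(meas$cardiac_diameter, 126L)
  expect_equal(meas$thoracic_diameter, 304L)
  expect_equal(round(meas$ctr, 4), 0.4145)
  # midline decomposition always recombines to the cardiac diameter
  expect_equal(meas$d_left + meas$d_right, meas$cardiac_diameter)
  # degenerate case: heart as wide as the thorax
  m2 <- m
  m2[33:52, 11:315] <- 2L
  full <- compute_ctr(m2)
  expect_equal(full$ctr, 1)
  expect_equal(full$decision, "cardiomegaly")
})

test_that("the ratio is invariant under horizontal flip and rescaling", {
  ds <- make_phantom_dataset(5, side = 96, seed = 31)
  for (ph in ds) {
    a <- compute_ctr(ph$mask)
    flip <- hflip(ph$image, ph$mask)
    b <- compute_ctr(flip$mask)
    expect_equal(a$ctr, b$ctr)
    # upscale the mask 2x with nearest-neighbour labels
    up <- resize_pair(ph$image, ph$mask, 192)
    c2 <- compute_ctr(up$mask)
    expect_lt(abs(c2$ctr - a$ctr), 2 / a$thoracic_diameter)
  }
})

test_that("unusable masks are signalled as measurement errors", {
  m <- matrix(0L, 20, 20)
  m[5:15, 3:17] <- 1L
  expect_error(compute_ctr(m), "absent")   # no heart class anywhere
  expect_error(ctr_ratio(120, 0), "thoracic")
})

test_that("CTR JSON report carries the four reporting fields", {
  js <- ctr_report_json(ctr_ratio(126, 304))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$ctr, 0.4145)
  expect_equal(parsed$decision, "below_normal")
  expect_equal(parsed$cardiac_diameter, 126)
  expect_equal(parsed$thoracic_diameter, 304)
})
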