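test_that("phantoms are a pure function of their spec", {
  a <- make_phantom(phantom_spec(side = 64, seed = 5))
  b <- make_phantom(phantom_spec(side = 64, seed = 5))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  d <- make_phantom(phantom_spec(side = 64, seed = 6))
  expect_false(identical(a$image, d$image))   # noise differs
  expect_identical(a$mask, d$mask)            # geometry does not
  # datasets too
  d1 <- make_phantom_dataset(4, side = 64, seed = 9)
  d2 <- make_phantom_dataset(4, side = 64, seed = 9)
  expect_identical(phantom_images(d1), phantom_images(d2))
  expect_identical(phantom_ctrs(d1), phantom_ctrs(d2))
})

test_that("every requested class is present with legal labels", {
  ds <- make_phantom_dataset(6, side = 64, seed = 13)
  for (ph in ds) {
    h <- tabulate(ph$mask + 1L, 4)
    expect_true(all(h > 0))
    expect_true(all(ph$mask %in% 0:3))
    expect_equal(dim(ph$image), c(64L, 64L))
    expect_true(all(ph$image >= 0 & ph$image <= 1))
  }
  ds2 <- make_phantom_dataset(3, side = 64, seed = 13, two_class = TRUE)
  for (ph in ds2) expect_true(all(ph$mask %in% 0:1))
})

test_that("a noise-free phantom rasterizes its analytic ellipse boundaries", {
  spec <- phantom_spec(side = 64, seed = 1,
                       intensity = list(background = 0.55, lung = 0.25,
                                        heart = 0.66, clavicle = 0.88,
                                        noise_sd = 0, gradient = 0))
  ph <- make_phantom(spec)
  ll <- spec$lung_left
  inside <- ((col(ph$mask) - ll$cx) / ll$a)^2 +
    ((row(ph$mask) - ll$cy) / ll$b)^2 <= 1
  # lung pixels exactly where the ellipse says, unless overwritten by
  # heart/clavicle precedence
  expect_true(all(ph$mask[inside] %in% c(1L, 2L, 3L)))
  left_half <- inside & col(ph$mask) < spec$heart$cx - spec$heart$a_left
  expect_true(all(ph$mask[left_half & row(ph$mask) > 30] == 1L))
})

test_that("the measured CTR recovers the analytic one", {
  ds <- make_phantom_dataset(20, side = 96, seed = 17)
  for (ph in ds) {
    meas <- compute_ctr(ph$mask)
    expect_lt(abs(meas$ctr - ph$expected_ctr), 2 / meas$thoracic_diameter)
  }
})

test_that("the cardiomegaly mix is controlled by p_cardiomegaly", {
  all_big <- phantom_ctrs(make_phantom_dataset(12, 64, seed = 19,
                                               p_cardiomegaly = 1))
  expect_true(all(all_big > 0.5))
  none_big <- phantom_ctrs(make_phantom_dataset(12, 64, seed = 19,
                                                p_cardiomegaly = 0))
  expect_true(all(none_big <= 0.5))
})

test_that("degenerate requests are rejected", {
  expect_error(make_phantom_dataset(0, 64, 1), "n must be")
  expect_error(phantom_spec(side = 16), "side")
  # geometry escaping the frame
  expect_error(phantom_spec(side = 64,
                            heart = list(cx = 32, cy = 60, a_left = 10,
                                         a_right = 10, b = 10)),
               "frame")
})

test_that("phantom datasets write paired PNGs plus a CTR table", {
  dir <- tempfile("phantoms")
  ds <- make_phantom_dataset(3, side = 48, seed = 23)
  csv <- write_phantom_dataset(ds, dir)
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$expected_ctr, phantom_ctrs(ds))
  m <- read_mask(file.path(dir, tab$mask[1]), "jsrt")
  expect_identical(m, ds[[1]]$mask)
  img <- read_radiograph(file.path(dir, tab$image[1]))
  expect_lt(max(abs(img - ds[[1]]$image)), 1 / 255)
  unlink(dir, recursive = TRUE)
})
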