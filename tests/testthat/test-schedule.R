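test_that("shape trace reproduces the printed encoder/decoder geometry", {
  sch <- build_cardionet_schedule(4, 350, with_fbb = TRUE)
  tr <- propagate_shapes(sch)
  get <- function(nm) unlist(tr[tr$name == nm, c("height", "width", "channels")],
                             use.names = FALSE)
  expect_equal(get("Pool-4"), c(21, 21, 256))
  expect_equal(get("UnPool-4"), c(43, 43, 256))
  expect_equal(get("Concatenation-6"), c(87, 87, 640))
  expect_equal(get("Concatenation-7"), c(175, 175, 320))
  expect_equal(get("Concatenation-8"), c(350, 350, 160))
  # smallest encoder map
  dsb <- as.data.frame(sch)$name[as.data.frame(sch)$block == "DSB"]
  expect_equal(min(tr$height[tr$name %in% dsb]), 21)
})

test_that("concatenation widths match the dense-skip topology", {
  sch <- build_cardionet_schedule(4, 350, with_fbb = TRUE)
  tr <- propagate_shapes(sch)
  cc <- paste0("Concatenation-", 1:8)
  expect_equal(tr$channels[match(cc, tr$name)],
               c(128, 256, 512, 512, 512, 640, 320, 160))
  # the ablation only narrows the final concatenation
  trx <- propagate_shapes(build_cardionet_schedule(4, 350, with_fbb = FALSE))
  expect_equal(trx$channels[match(cc, trx$name)],
               c(128, 256, 512, 512, 512, 640, 320, 128))
  common <- intersect(tr$name, trx$name)
  common <- setdiff(common, "Concatenation-8")
  expect_equal(tr[match(common, tr$name), ], trx[match(common, trx$name), ],
               ignore_attr = TRUE)
})

test_that("layer counts separate standard and depth-wise convolutions", {
  b <- build_cardionet_schedule(4, 350, TRUE)
  x <- build_cardionet_schedule(4, 350, FALSE)
  expect_equal(count_layers(b, "conv3x3"), 16)
  expect_equal(count_layers(b, "dw_sep_conv3x3"), 6)
  expect_equal(count_layers(x, "conv3x3"), 10)
  expect_equal(count_layers(x, "dw_sep_conv3x3"), 6)
  # the difference is exactly the boost-block convolutions
  expect_equal(count_layers(b, "conv3x3") - count_layers(x, "conv3x3"), 6)
  expect_equal(count_layers(b, "pool2x2"), 4)
})

test_that("two-class lung-only configuration builds without the boost block", {
  sch <- build_cardionet_schedule(2, 96, with_fbb = FALSE)
  s <- as.data.frame(sch)
  expect_false(any(s$block == "FBB"))
  expect_equal(s$out_channels[s$name == "Bottleneck-C-8"], 2L)
  expect_silent(validate_schedule(sch))
})

test_that("degenerate input sides are rejected naming the pool stage", {
  expect_error(build_cardionet_schedule(4, 8), "pooling stage")
  expect_error(build_cardionet_schedule(1, 350), "num_classes")
})

test_that("shape propagation is deterministic and idempotent", {
  sch <- build_cardionet_schedule(4, 96, TRUE)
  expect_identical(propagate_shapes(sch), propagate_shapes(sch))
})

test_that("parameter count is audited per layer and monotone", {
  sch <- build_cardionet_schedule(4, 350, TRUE)
  tot <- count_parameters(sch)
  br <- attr(tot, "breakdown")
  expect_equal(sum(br$total), as.integer(tot))
  expect_equal(sum(br$weights + br$bias + br$batch_norm), as.integer(tot))
  # empty schedule counts zero
  empty <- sch[0, ]
  expect_equal(as.integer(count_parameters(empty)), 0L)
  # B has strictly more parameters than X under any one convention
  x <- build_cardionet_schedule(4, 350, FALSE)
  for (conv in list(param_convention(), param_convention(grouped_bottlenecks = TRUE),
                    param_convention(bias_without_bn = FALSE, bn_learnable = FALSE))) {
    expect_gt(count_parameters(sch, conv), count_parameters(x, conv))
  }
  # monotone in num_classes and input channels
  p4 <- count_parameters(build_cardionet_schedule(4, 350, TRUE))
  p2 <- count_parameters(build_cardionet_schedule(2, 350, TRUE))
  expect_gte(as.integer(p4), as.integer(p2))
  pc3 <- count_parameters(build_cardionet_schedule(4, 350, TRUE, input_channels = 3))
  expect_gte(as.integer(pc3), as.integer(p4))
})

test_that("schedules serialize to a diffable plain-text table", {
  sch <- build_cardionet_schedule(4, 350, TRUE)
  path <- tempfile(fileext = ".tsv")
  write_schedule(sch, path)
  rec <- utils::read.delim(path, check.names = FALSE)
  expect_equal(nrow(rec), nrow(as.data.frame(sch)))
  expect_true(all(c("Layer Name", "Filters/Groups", "Output") %in% names(rec)))
  expect_equal(rec$Output[rec$`Layer Name` == "Concatenation-6"], "87 x 87 x 640")
  unlink(path)
})

test_that("schedule audit reports both counting conventions", {
  aud <- audit_schedule(build_cardionet_schedule(4, 350, TRUE))
  expect_s3_class(aud, "cardionet_audit")
  expect_gt(as.integer(aud$params_ungrouped), as.integer(aud$params_grouped))
  expect_output(print(aud), "grouped")
})
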