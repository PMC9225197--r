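#' Build the CardioNet layer schedule
#'
#' Constructs the declarative, layer-by-layer description of the CardioNet
#' encoder--decoder from which the executable graph, the shape trace and the
#' parameter audit all derive.  The architecture has three principal parts: a
#' downsample block (DSB) of five 3x3 convolutions and three depth-wise
#' separable convolutions with four 2x2 max-poolings, an upsample block (USB)
#' mirroring it with max-unpooling driven by the recorded pooling indices, and
#' (for the "B" variant) a feature-boost block (FBB) that runs at full input
#' resolution with no pooling and whose 32-channel output joins the final
#' full-resolution concatenation.  Within every encoder/decoder stage the two
#' convolution outputs are depth-wise concatenated and compressed by a 1x1
#' bottleneck with batch normalization and ReLU; decoder stages additionally
#' receive the first-convolution feature of the corresponding encoder stage
#' as a dense skip, so the concatenation widths are 128/256/512/512 going
#' down and 512/640/320/160 coming up.
#'
#' @param num_classes number of segmentation classes including background
#'   (>= 2); 4 for lungs/heart/clavicle masks, 2 for lung-only masks.
#' @param input_side input image side in pixels (>= 16); odd sides are
#'   floored by each 2x2 pooling and restored exactly by the paired
#'   unpooling, so 350 traces 175/87/43/21 through the encoder.
#' @param with_fbb logical; `TRUE` builds the CardioNet-B variant (with the
#'   feature-boost block), `FALSE` the CardioNet-X ablation.
#' @param input_channels number of image channels (1 for grayscale
#'   radiographs).
#' @return an object of class `cardionet_schedule`: a data frame with one row
#'   per layer (name, printed label, block, kind, channel counts, kernel,
#'   stride, batch-norm flag, concatenation sources, pooling pair) plus
#'   attributes `num_classes`, `input_side`, `input_channels`, `variant`.
#' @seealso [propagate_shapes()], [count_layers()], [count_parameters()],
#'   [audit_schedule()]
#' @export
build_cardionet_schedule <- function(num_classes = 4L, input_side = 350L,
                                     with_fbb = TRUE, input_channels = 1L) {
  num_classes <- as.integer(num_classes)
  input_side <- as.integer(input_side)
  input_channels <- as.integer(input_channels)
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (input_channels < 1L) stop("input_channels must be >= 1")
  ## 2x2 pooling floors odd sides (350 -> 175 -> 87 -> 43 -> 21) and
  ## unpooling restores them through the recorded indices, so the only
  ## dimensional requirement is that the map stays at least 2x2 entering
  ## every pooling stage.
  side <- input_side
  for (stage in 1:4) {
    if (side < 2L) {
      stop(sprintf(
        "input_side %d collapses before pooling stage %d (side %d < 2)",
        input_side, stage, side
      ))
    }
    side <- side %/% 2L
  }

  rows <- list()
  add <- function(name, block, kind, input = NA_character_, inch = NA_integer_,
                  outch = NA_integer_, kernel = NA_integer_, stride = 1L,
                  bn = FALSE, sources = "", pair = NA_character_,
                  label = name) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, label = label, block = block, kind = kind, input = input,
      in_channels = as.integer(inch), out_channels = as.integer(outch),
      kernel = as.integer(kernel), stride = as.integer(stride),
      followed_by_bn_relu = bn, concat_sources = sources,
      pool_pair = pair, stringsAsFactors = FALSE
    )
  }

  ## ---- downsample block -------------------------------------------------
  ## stage widths and per-stage layer kinds follow the printed table: stages
  ## 1-2 use two standard convolutions, stage 3 a standard + depth-wise
  ## separable pair, stage 4 two depth-wise separable convolutions.
  widths <- c(64L, 128L, 256L, 256L)
  kinds_a <- c("conv3x3", "conv3x3", "conv3x3", "dw_sep_conv3x3")
  kinds_b <- c("conv3x3", "conv3x3", "dw_sep_conv3x3", "dw_sep_conv3x3")
  dsb_names_a <- c("Conv-1-1", "Conv-2-1", "Conv-3-1", "DW-Sep-Conv-4-1")
  dsb_names_b <- c("Conv-1-2", "Conv-2-2", "DW-Sep-Conv-3-2", "DW-Sep-Conv-4-2")
  prev <- "input"
  prev_ch <- input_channels
  for (i in 1:4) {
    w <- widths[i]
    a <- dsb_names_a[i]; b <- dsb_names_b[i]
    add(a, "DSB", kinds_a[i], prev, prev_ch, w, 3L, bn = TRUE)
    add(b, "DSB", kinds_b[i], a, w, w, 3L, bn = FALSE)
    cc <- sprintf("Concatenation-%d", i)
    add(cc, "DSB", "concat", sources = paste(a, b, sep = ","),
        inch = 2L * w, outch = 2L * w)
    bk <- sprintf("Bottleneck-C-%d", i)
    add(bk, "DSB", "bottleneck1x1", cc, 2L * w, w, 1L, bn = TRUE)
    pl <- sprintf("Pool-%d", i)
    add(pl, "DSB", "pool2x2", bk, w, w, 2L, stride = 2L)
    prev <- pl
    prev_ch <- w
  }

  ## ---- upsample block ---------------------------------------------------
  ## decoder stage i mirrors encoder stage i; the first conv keeps the stage
  ## width, the second reduces toward the next (shallower) stage width.  The
  ## deepest decoder stage has no encoder skip; stages 3 and 2 receive the
  ## encoder first-conv feature; stage 1 receives the FBB output instead
  ## (or nothing, for CardioNet-X).
  usb_a <- c("DW-Sep-Conv-4-2", "DW-Sep-Conv-3-2", "Conv-2-2", "Conv-1-2")
  usb_b <- c("DW-Sep-Conv-4-1", "Conv-3-1", "Conv-2-1", "Conv-1-1")
  usb_kind_a <- c("dw_sep_conv3x3", "dw_sep_conv3x3", "conv3x3", "conv3x3")
  usb_kind_b <- c("dw_sep_conv3x3", "conv3x3", "conv3x3", "conv3x3")
  usb_wa <- c(256L, 256L, 128L, 64L)   # width of first decoder conv
  usb_wb <- c(256L, 128L, 64L, 64L)    # width of second decoder conv
  skips <- c(NA, "Conv-3-1", "Conv-2-1", if (with_fbb) "Boost-Conv-3-2" else NA)
  bott_out <- c(256L, 128L, 64L, num_classes)
  for (j in 1:4) {
    enc <- 5L - j                     # encoder stage this decoder stage mirrors
    up <- sprintf("UnPool-%d", enc)
    add(up, "USB", "unpool2x2", prev, prev_ch, prev_ch, 2L, stride = 2L,
        pair = sprintf("Pool-%d", enc))
    a <- paste0("U-", usb_a[j]); b <- paste0("U-", usb_b[j])
    add(a, "USB", usb_kind_a[j], up, prev_ch, usb_wa[j], 3L, bn = TRUE,
        label = usb_a[j])
    add(b, "USB", usb_kind_b[j], a, usb_wa[j], usb_wb[j], 3L, bn = FALSE,
        label = usb_b[j])
    src <- c(a, b, skips[j])
    src <- src[!is.na(src)]
    cc <- sprintf("Concatenation-%d", 4L + j)
    add(cc, "USB", "concat", sources = paste(src, collapse = ","))
    bk <- sprintf("Bottleneck-C-%d", 4L + j)
    add(bk, "USB", "bottleneck1x1", cc, NA, bott_out[j], 1L, bn = TRUE)
    prev <- bk
    prev_ch <- bott_out[j]
  }

  df <- do.call(rbind, rows)

  ## ---- feature-boost block ---------------------------------------------
  ## full-resolution branch fed from the input through a 1x1 stem; all its
  ## layers carry batch norm + ReLU.
  if (with_fbb) {
    rows <- list()
    add("FBB-Bottleneck-C", "FBB", "bottleneck1x1", "input", input_channels,
        8L, 1L, bn = TRUE, label = "Bottleneck-C")
    fbb_in <- c(8L, 8L, 8L, 16L, 16L, 32L)
    fbb_out <- c(8L, 8L, 16L, 16L, 32L, 32L)
    fbb_names <- c("Boost-Conv-1-1", "Boost-Conv-1-2", "Boost-Conv-2-1",
                   "Boost-Conv-2-2", "Boost-Conv-3-1", "Boost-Conv-3-2")
    fprev <- "FBB-Bottleneck-C"
    for (i in seq_along(fbb_names)) {
      add(fbb_names[i], "FBB", "conv3x3", fprev, fbb_in[i], fbb_out[i], 3L,
          bn = TRUE)
      fprev <- fbb_names[i]
    }
    fbb <- do.call(rbind, rows)
    ## insert the FBB just before the final concatenation so row order is a
    ## valid topological order
    at <- which(df$name == "Concatenation-8")
    df <- rbind(df[seq_len(at - 1L), ], fbb, df[at:nrow(df), ])
  }

  rows <- list()
  add("Softmax", "USB", "softmax", "Bottleneck-C-8", num_classes, num_classes)
  add("Pixel-Classification", "USB", "pixel_classification", "Softmax",
      num_classes, num_classes)
  df <- rbind(df, do.call(rbind, rows))
  rownames(df) <- NULL

  ## fill concat in/out channel counts from sources
  for (i in which(df$kind == "concat")) {
    src <- strsplit(df$concat_sources[i], ",")[[1]]
    tot <- sum(df$out_channels[match(src, df$name)])
    df$in_channels[i] <- tot
    df$out_channels[i] <- tot
  }
  for (i in which(df$kind == "bottleneck1x1" & is.na(df$in_channels))) {
    df$in_channels[i] <- df$out_channels[match(df$input[i], df$name)]
  }

  structure(df,
    class = c("cardionet_schedule", "data.frame"),
    num_classes = num_classes, input_side = input_side,
    input_channels = input_channels,
    variant = if (with_fbb) "B" else "X"
  )
}

#' Validate schedule invariants
#'
#' Checks that pooling layers have stride 2 and preserve channels, that every
#' concatenation's channel count equals the sum of its sources', and that
#' bottleneck layers use 1x1 kernels.
#'
#' @param schedule a `cardionet_schedule`.
#' @return the schedule, invisibly; errors on violation.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "cardionet_schedule"))
  s <- as.data.frame(schedule)
  pool <- s[s$kind %in% c("pool2x2", "unpool2x2"), ]
  if (any(pool$stride != 2L)) stop("pool/unpool layers must have stride 2")
  if (any(pool$in_channels != pool$out_channels)) {
    stop("pool/unpool layers must preserve channel count")
  }
  if (any(s$kernel[s$kind == "bottleneck1x1"] != 1L)) {
    stop("bottleneck layers must use a 1x1 kernel")
  }
  for (i in which(s$kind == "concat")) {
    src <- strsplit(s$concat_sources[i], ",")[[1]]
    m <- match(src, s$name)
    if (anyNA(m)) {
      stop(sprintf("concat %s references unknown source(s): %s", s$name[i],
                   paste(src[is.na(m)], collapse = ", ")))
    }
    tot <- sum(s$out_channels[m])
    if (tot != s$out_channels[i]) {
      stop(sprintf(
        "concat %s: recorded %d channels but sources sum to %d",
        s$name[i], s$out_channels[i], tot
      ))
    }
  }
  invisible(schedule)
}

#' Propagate feature-map shapes through a schedule
#'
#' Deterministically assigns every layer an output (height, width, channels)
#' triple: convolutions are padded so they preserve the spatial size, 2x2
#' pooling halves it (floor), and unpooling restores the spatial size of the
#' paired pooling layer's input (so odd sizes such as 87 round-trip exactly).
#'
#' @param schedule a `cardionet_schedule`.
#' @return a data frame of class `cardionet_shapes` with columns `name`,
#'   `height`, `width`, `channels`.
#' @export
propagate_shapes <- function(schedule) {
  validate_schedule(schedule)
  s <- as.data.frame(schedule)
  side <- attr(schedule, "input_side")
  shp <- list(input = c(side, side, attr(schedule, "input_channels")))
  for (i in seq_len(nrow(s))) {
    kind <- s$kind[i]
    if (kind == "concat") {
      src <- strsplit(s$concat_sources[i], ",")[[1]]
      hs <- vapply(src, function(nm) shp[[nm]][1], numeric(1))
      ws <- vapply(src, function(nm) shp[[nm]][2], numeric(1))
      if (length(unique(hs)) > 1L || length(unique(ws)) > 1L) {
        stop(sprintf("concat %s: sources disagree spatially", s$name[i]))
      }
      out <- c(hs[1], ws[1], sum(vapply(src, function(nm) shp[[nm]][3],
                                        numeric(1))))
    } else {
      inshp <- shp[[s$input[i]]]
      if (is.null(inshp)) stop(sprintf("layer %s: unknown input", s$name[i]))
      out <- switch(kind,
        pool2x2 = c(inshp[1] %/% 2L, inshp[2] %/% 2L, inshp[3]),
        unpool2x2 = {
          pr <- s$pool_pair[i]
          pshp <- shp[[s$input[match(pr, s$name)]]]  # paired pool's input
          c(pshp[1], pshp[2], inshp[3])
        },
        c(inshp[1], inshp[2], s$out_channels[i])
      )
    }
    shp[[s$name[i]]] <- out
  }
  tr <- data.frame(
    name = s$name,
    height = vapply(s$name, function(nm) shp[[nm]][1], numeric(1)),
    width = vapply(s$name, function(nm) shp[[nm]][2], numeric(1)),
    channels = vapply(s$name, function(nm) shp[[nm]][3], numeric(1)),
    row.names = NULL
  )
  class(tr) <- c("cardionet_shapes", "data.frame")
  tr
}

#' Count layers of a given kind
#'
#' Standard 3x3 convolutions and depth-wise separable convolutions are
#' distinct kinds and counted separately.
#'
#' @param schedule a `cardionet_schedule`.
#' @param kind one of `"conv3x3"`, `"dw_sep_conv3x3"`, `"bottleneck1x1"`,
#'   `"pool2x2"`, `"unpool2x2"`, `"concat"`, `"softmax"`,
#'   `"pixel_classification"`.
#' @return integer count.
#' @export
count_layers <- function(schedule, kind) {
  kind <- match.arg(kind, c(
    "conv3x3", "dw_sep_conv3x3", "bottleneck1x1", "pool2x2", "unpool2x2",
    "concat", "softmax", "pixel_classification"
  ))
  sum(as.data.frame(schedule)$kind == kind)
}

#' Parameter-counting convention
#'
#' The printed architecture tables admit more than one way of counting
#' trainable parameters; the convention object makes each choice explicit so
#' the audit can be compared against any external total.
#'
#' @param bias_without_bn count a bias term on convolutions NOT followed by
#'   batch normalization (standard practice omits biases under BN).
#' @param bn_learnable count the batch-norm scale and shift as trainable.
#' @param grouped_bottlenecks treat 1x1 bottlenecks as grouped convolutions
#'   with as many groups as filters (dividing their weight count by the
#'   group count); `FALSE` counts them as ordinary dense 1x1 convolutions.
#' @return a list of class `cardionet_convention`.
#' @export
param_convention <- function(bias_without_bn = TRUE, bn_learnable = TRUE,
                             grouped_bottlenecks = FALSE) {
  structure(list(
    bias_without_bn = bias_without_bn,
    bn_learnable = bn_learnable,
    grouped_bottlenecks = grouped_bottlenecks
  ), class = "cardionet_convention")
}

#' Count trainable parameters under an explicit convention
#'
#' Returns the deterministic total with a per-layer breakdown (as attribute
#' `breakdown`) so the counting convention can be audited.  A depth-wise
#' separable convolution counts 9 weights per input channel plus a dense
#' point-wise 1x1 map.
#'
#' @param schedule a `cardionet_schedule` (any subset of rows is accepted;
#'   an empty schedule counts 0).
#' @param convention a [param_convention()].
#' @return integer total with attribute `breakdown`, a data frame of
#'   per-layer weight/bias/bn counts.
#' @export
count_parameters <- function(schedule, convention = param_convention()) {
  s <- as.data.frame(schedule)
  n <- nrow(s)
  wts <- bias <- bn <- integer(if (is.null(n)) 0L else n)
  if (!is.null(n) && n > 0L) {
    for (i in seq_len(n)) {
      kind <- s$kind[i]
      inc <- s$in_channels[i]; outc <- s$out_channels[i]
      if (kind == "conv3x3") {
        wts[i] <- 9L * inc * outc
      } else if (kind == "dw_sep_conv3x3") {
        wts[i] <- 9L * inc + inc * outc
      } else if (kind == "bottleneck1x1") {
        wts[i] <- if (convention$grouped_bottlenecks) {
          g <- outc  # groups = printed filter count
          as.integer(round(inc * outc / g))
        } else {
          inc * outc
        }
      } else {
        next
      }
      if (s$followed_by_bn_relu[i]) {
        if (convention$bn_learnable) bn[i] <- 2L * outc
      } else if (convention$bias_without_bn) {
        bias[i] <- outc
      }
    }
  }
  breakdown <- data.frame(
    name = if (is.null(n) || n == 0L) character(0) else s$name,
    kind = if (is.null(n) || n == 0L) character(0) else s$kind,
    weights = wts, bias = bias, batch_norm = bn,
    total = wts + bias + bn
  )
  structure(sum(breakdown$total), breakdown = breakdown)
}

#' Audit a schedule against its printed description
#'
#' Collates the layer counts, the concatenation channel sums, the shape trace
#' and the parameter totals under both bottleneck conventions into a single
#' report.  The grouped and ungrouped totals are reported side by side
#' precisely because externally printed totals for this architecture family
#' cannot be reconciled from the layer tables without fixing that ambiguity.
#'
#' @param schedule a `cardionet_schedule`.
#' @return a list of class `cardionet_audit`.
#' @export
audit_schedule <- function(schedule) {
  validate_schedule(schedule)
  s <- as.data.frame(schedule)
  tr <- propagate_shapes(schedule)
  concats <- s$name[s$kind == "concat"]
  out <- list(
    variant = attr(schedule, "variant"),
    num_classes = attr(schedule, "num_classes"),
    input_side = attr(schedule, "input_side"),
    n_conv3x3 = count_layers(schedule, "conv3x3"),
    n_dw_sep = count_layers(schedule, "dw_sep_conv3x3"),
    n_bottleneck = count_layers(schedule, "bottleneck1x1"),
    n_pool = count_layers(schedule, "pool2x2"),
    concat_channels = stats::setNames(
      tr$channels[match(concats, tr$name)], concats
    ),
    min_encoder_side = min(tr$height[match(s$name[s$block == "DSB"], tr$name)]),
    params_ungrouped = count_parameters(
      schedule, param_convention(grouped_bottlenecks = FALSE)
    ),
    params_grouped = count_parameters(
      schedule, param_convention(grouped_bottlenecks = TRUE)
    ),
    shapes = tr,
    notes = c(
      "Bottleneck-C-3 printed with 128 filters but a 256-channel output; the output column is taken as authoritative (256 filters).",
      "Boost-Conv-2-1 printed with a 3x3x16 kernel; its input has 8 channels, so in_channels = 8 is used.",
      "Externally printed totals (1.72M / 1.57M) are not reproduced by either convention; both are reported for audit rather than forced."
    )
  )
  class(out) <- "cardionet_audit"
  out
}

#' @export
print.cardionet_audit <- function(x, ...) {
  cat(sprintf("CardioNet-%s schedule audit (input %dx%d, %d classes)\n",
              x$variant, x$input_side, x$input_side, x$num_classes))
  cat(sprintf("  3x3 convolutions:            %d\n", x$n_conv3x3))
  cat(sprintf("  depth-wise separable convs:  %d\n", x$n_dw_sep))
  cat(sprintf("  1x1 bottlenecks:             %d\n", x$n_bottleneck))
  cat(sprintf("  pooling stages:              %d (smallest encoder map %dx%d)\n",
              x$n_pool, x$min_encoder_side, x$min_encoder_side))
  cat("  concatenation widths:        ",
      paste(x$concat_channels, collapse = ", "), "\n")
  cat(sprintf("  parameters (ungrouped 1x1 bottlenecks): %s\n",
              format(as.integer(x$params_ungrouped), big.mark = ",")))
  cat(sprintf("  parameters (grouped 1x1 bottlenecks):   %s\n",
              format(as.integer(x$params_grouped), big.mark = ",")))
  cat("  notes:\n")
  for (nt in x$notes) cat("   -", nt, "\n")
  invisible(x)
}

#' Serialize a schedule to a plain-text table
#'
#' Writes one record per layer with the field names used by the printed
#' architecture tables (layer name, kernel, stride, filters, output shape) so
#' the audit can be diffed line by line against an external description.
#'
#' @param schedule a `cardionet_schedule`.
#' @param path output file path (TSV).
#' @return the path, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  s <- as.data.frame(schedule)
  tr <- propagate_shapes(schedule)
  rec <- data.frame(
    Block = s$block,
    `Layer Name` = ifelse(s$followed_by_bn_relu, paste(s$label, "**"), s$label),
    Kind = s$kind,
    `Layer Size` = ifelse(is.na(s$kernel), "",
                          sprintf("%d x %d (S = %d)", s$kernel, s$kernel,
                                  s$stride)),
    `Filters/Groups` = ifelse(is.na(s$out_channels), "",
                              as.character(s$out_channels)),
    Output = sprintf("%d x %d x %d", tr$height, tr$width, tr$channels),
    check.names = FALSE
  )
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
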