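# CNN slice-encoder backbones.
#
# Two backbones share one interface: the 18-layer residual network
# (stem 7x7/2 + maxpool + four stages of two basic blocks; 224 -> 7x7x512)
# and a small residual "tiny" backbone for CPU-scale work
# (stem 3x3/2 + three strided residual blocks; 64 -> 4x4x64).

init_kaiming_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

init_xavier_uniform <- function(fin, fout, dims = c(fin, fout)) {
  lim <- sqrt(6 / (fin + fout))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

add_conv_bn <- function(ps, name, kh, kw, cin, cout) {
  ps_add(ps, paste0(name, ".conv.w"), init_kaiming_conv(kh, kw, cin, cout))
  ps_add(ps, paste0(name, ".bn.g"), rep(1, cout))
  ps_add(ps, paste0(name, ".bn.b"), numeric(cout))
  ps$state[[paste0(name, ".bn")]] <- new.env(parent = emptyenv())
  invisible(ps)
}

# convolution (bias-free, as usual before normalization) + fused bn(+relu)
conv_bn_fw <- function(tape, ps, name, x, stride, pad, training,
                       act = FALSE) {
  w <- pnode(tape, ps, paste0(name, ".conv.w"))
  need_gx <- !is.null(x$backward) || !is.null(x$param_name)
  y <- op_conv2d(tape, x, w, NULL, stride, pad, need_gx = need_gx)
  g <- pnode(tape, ps, paste0(name, ".bn.g"))
  be <- pnode(tape, ps, paste0(name, ".bn.b"))
  op_bn_act(tape, y, g, be, ps$state[[paste0(name, ".bn")]], training,
            relu = act)
}

backbone_spec <- function(backbone) {
  switch(backbone,
    tiny = list(
      stages = c("stem", "b1", "b2", "b3"),
      out_channels = 64L,
      out_hw = function(input_size) as.integer(input_size / 16)),
    resnet18 = list(
      stages = c("stem", "l1", "l2", "l3", "l4"),
      out_channels = 512L,
      out_hw = function(input_size) as.integer(input_size / 32)),
    stop("unknown backbone: ", backbone))
}

build_encoder <- function(ps, backbone, in_channels = 2L, prefix = "enc") {
  p <- function(...) paste0(prefix, ".", ...)
  if (backbone == "tiny") {
    add_conv_bn(ps, p("stem"), 3, 3, in_channels, 16)
    chans <- c(16, 32, 48, 64)
    for (i in 1:3) {
      add_conv_bn(ps, p("b", i, ".main"), 3, 3, chans[i], chans[i + 1])
      add_conv_bn(ps, p("b", i, ".skip"), 1, 1, chans[i], chans[i + 1])
    }
  } else if (backbone == "resnet18") {
    add_conv_bn(ps, p("stem"), 7, 7, in_channels, 64)
    chans <- c(64, 64, 128, 256, 512)
    for (st in 1:4) {
      cin <- chans[st]; cout <- chans[st + 1]
      stride1 <- if (st == 1) 1 else 2
      for (blk in 1:2) {
        bcin <- if (blk == 1) cin else cout
        nm <- p("l", st, ".blk", blk)
        add_conv_bn(ps, paste0(nm, ".c1"), 3, 3, bcin, cout)
        add_conv_bn(ps, paste0(nm, ".c2"), 3, 3, cout, cout)
        if (blk == 1 && (stride1 != 1 || cin != cout))
          add_conv_bn(ps, paste0(nm, ".skip"), 1, 1, bcin, cout)
      }
    }
  } else stop("unknown backbone: ", backbone)
  invisible(ps)
}

encoder_forward <- function(tape, ps, backbone, x, training, prefix = "enc") {
  p <- function(...) paste0(prefix, ".", ...)
  if (backbone == "tiny") {
    h <- conv_bn_fw(tape, ps, p("stem"), x, 2, 1, training, act = TRUE)
    for (i in 1:3) {
      main <- conv_bn_fw(tape, ps, p("b", i, ".main"), h, 2, 1, training)
      skip <- conv_bn_fw(tape, ps, p("b", i, ".skip"), h, 2, 0, training)
      h <- op_add_relu(tape, main, skip)
    }
    return(h)
  }
  # resnet18
  h <- conv_bn_fw(tape, ps, p("stem"), x, 2, 3, training, act = TRUE)
  h <- op_maxpool(tape, h, 3, 2, 1)
  for (st in 1:4) {
    stride1 <- if (st == 1) 1 else 2
    for (blk in 1:2) {
      nm <- p("l", st, ".blk", blk)
      s <- if (blk == 1) stride1 else 1
      y <- conv_bn_fw(tape, ps, paste0(nm, ".c1"), h, s, 1, training,
                      act = TRUE)
      y <- conv_bn_fw(tape, ps, paste0(nm, ".c2"), y, 1, 1, training)
      skip <- if (!is.null(ps$params[[paste0(nm, ".skip.conv.w")]]))
        conv_bn_fw(tape, ps, paste0(nm, ".skip"), h, s, 0, training)
      else h
      h <- op_add_relu(tape, y, skip)
    }
  }
  h
}

#' Adapt a pretrained RGB first-layer convolution to dual-channel input
#'
#' For transfer from an RGB-pretrained backbone to the dual-channel
#' (T2WI-FS, DWI) input: per output filter, the three RGB kernels are
#' averaged and the average duplicated into both new input channels; the
#' bias is unchanged. Feeding the same image into both channels then
#' yields exactly 2/3 of the original layer's pre-bias response to the
#' RGB-replicated image.
#'
#' @param rgb_kernels weight array `(kh, kw, 3, cout)`.
#' @param bias bias vector (returned unchanged).
#' @return List with `weights` of shape `(kh, kw, 2, cout)` and `bias`.
#' @export
adapt_first_conv <- function(rgb_kernels, bias = NULL) {
  d <- dim(rgb_kernels)
  if (length(d) != 4L || d[3] != 3L)
    stop("rgb_kernels must have input-channel extent 3, got ",
         if (length(d) == 4L) d[3] else "rank != 4")
  avg <- (rgb_kernels[, , 1, , drop = FALSE] +
            rgb_kernels[, , 2, , drop = FALSE] +
            rgb_kernels[, , 3, , drop = FALSE]) / 3
  w2 <- array(0, c(d[1], d[2], 2, d[4]))
  w2[, , 1, ] <- avg
  w2[, , 2, ] <- avg
  list(weights = w2, bias = bias)
}

#' Load pretrained backbone weights (optional hook)
#'
#' Replaces the randomly initialized first-stage convolution of a model's
#' encoder with channel-adapted pretrained RGB weights, and any further
#' provided arrays by parameter name. No pretrained weights ship with the
#' package; this is the hook for users who have them.
#'
#' @param model a `bcr_model`.
#' @param first_conv_rgb optional `(kh, kw, 3, cout)` array for the stem.
#' @param extra named list of additional parameter arrays to overwrite
#'   (names as in `model$ps$params`, shapes must match).
#' @return The model with weights replaced.
#' @export
load_pretrained <- function(model, first_conv_rgb = NULL, extra = list()) {
  if (!is.null(first_conv_rgb)) {
    ad <- adapt_first_conv(first_conv_rgb)
    stopifnot(identical(dim(ad$weights),
                        dim(model$ps$params[["enc.stem.conv.w"]])))
    model$ps$params[["enc.stem.conv.w"]] <- ad$weights
  }
  for (nm in names(extra)) {
    cur <- model$ps$params[[nm]]
    if (is.null(cur)) stop("unknown parameter: ", nm)
    stopifnot(identical(dim(cur) %||% length(cur),
                        dim(extra[[nm]]) %||% length(extra[[nm]])))
    model$ps$params[[nm]] <- extra[[nm]]
  }
  model
}
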