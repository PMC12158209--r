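# Backbone / neck blocks and whole-model assembly.
#
# The layout follows the published v11-nano one-stage lineage: a stride-2
# convolutional stem, C3k2 stages, SPPF, and a C2PSA attention stage, then
# a top-down + bottom-up neck feeding three detection levels at strides
# 8/16/32.  `variant = "mas"` swaps the C2PSA attention for MSDA and the
# detection head for the adaptive spatial feature-fusion head.

make_divisible <- function(x, d = 8L) as.integer(ceiling(x / d) * d)

scaled_ch <- function(base, width, max_ch = 1024L) {
  make_divisible(min(base, max_ch) * width, 8L)
}

#' Model configuration
#'
#' @param variant `"baseline"` (stock layout) or `"mas"` (MSDA attention in
#'   the backbone C2PSA plus the ASFF detection head)
#' @param num_classes number of object classes (default 4: holothurian,
#'   echinus, scallop, starfish)
#' @param width_multiple,depth_multiple nano scaling is 0.25 / 0.5
#' @param reg_max number of distribution bins per box side
#' @param attention an [attention_config()] for the MSDA variant
#' @param max_channels channel cap before width scaling
#' @return `model_config` object
#' @export
model_config <- function(variant = c("baseline", "mas"), num_classes = 4L,
                         width_multiple = 0.25, depth_multiple = 0.5,
                         reg_max = 16L, attention = attention_config(),
                         max_channels = 1024L) {
  variant <- match.arg(variant)
  if (num_classes < 1L) stop("num_classes must be >= 1", call. = FALSE)
  structure(list(variant = variant, num_classes = as.integer(num_classes),
                 strides = c(8L, 16L, 32L),
                 width_multiple = width_multiple,
                 depth_multiple = depth_multiple,
                 reg_max = as.integer(reg_max), attention = attention,
                 max_channels = as.integer(max_channels)),
            class = "model_config")
}

n_rep <- function(n, depth) max(1L, round(n * depth))

# ---- composite blocks -------------------------------------------------

new_bottleneck <- function(c1, c2, shortcut = TRUE, k = c(3L, 3L), e = 0.5) {
  ch <- as.integer(c2 * e)
  list(type = "bottleneck", shortcut = shortcut && c1 == c2,
       cv1 = new_conv(c1, ch, k[1]), cv2 = new_conv(ch, c2, k[2]))
}

fwd_bottleneck <- function(tp, x, m, training) {
  y <- fwd_conv(tp, fwd_conv(tp, x, m$cv1, training), m$cv2, training)
  if (m$shortcut) op_add(tp, x, y) else y
}

new_c3k <- function(c1, c2, n = 2L, shortcut = TRUE, e = 0.5) {
  ch <- as.integer(c2 * e)
  list(type = "c3k",
       cv1 = new_conv(c1, ch, 1L), cv2 = new_conv(c1, ch, 1L),
       cv3 = new_conv(2L * ch, c2, 1L),
       m = lapply(seq_len(n), function(i)
         new_bottleneck(ch, ch, shortcut, k = c(3L, 3L), e = 1.0)))
}

fwd_c3k <- function(tp, x, m, training) {
  a <- fwd_conv(tp, x, m$cv1, training)
  for (b in m$m) a <- fwd_bottleneck(tp, a, b, training)
  b <- fwd_conv(tp, x, m$cv2, training)
  fwd_conv(tp, op_concat_c(tp, c(a, b)), m$cv3, training)
}

new_c3k2 <- function(c1, c2, n = 1L, c3k = FALSE, e = 0.5, shortcut = TRUE) {
  ch <- as.integer(c2 * e)
  list(type = "c3k2", c = ch,
       cv1 = new_conv(c1, 2L * ch, 1L),
       cv2 = new_conv((2L + n) * ch, c2, 1L),
       m = lapply(seq_len(n), function(i)
         if (c3k) new_c3k(ch, ch, 2L, shortcut)
         else new_bottleneck(ch, ch, shortcut, k = c(3L, 3L), e = 0.5)))
}

fwd_c3k2 <- function(tp, x, m, training) {
  y <- fwd_conv(tp, x, m$cv1, training)
  y0 <- op_slice_c(tp, y, 1L, m$c)
  y1 <- op_slice_c(tp, y, m$c + 1L, 2L * m$c)
  ys <- c(y0, y1)
  cur <- y1
  for (b in m$m) {
    cur <- if (b$type == "c3k") fwd_c3k(tp, cur, b, training)
           else fwd_bottleneck(tp, cur, b, training)
    ys <- c(ys, cur)
  }
  fwd_conv(tp, op_concat_c(tp, ys), m$cv2, training)
}

new_sppf <- function(c1, c2, k = 5L) {
  ch <- c1 %/% 2L
  list(type = "sppf", k = k,
       cv1 = new_conv(c1, ch, 1L), cv2 = new_conv(4L * ch, c2, 1L))
}

fwd_sppf <- function(tp, x, m, training) {
  y <- fwd_conv(tp, x, m$cv1, training)
  p1 <- op_maxpool(tp, y, m$k, 1L, m$k %/% 2L)
  p2 <- op_maxpool(tp, p1, m$k, 1L, m$k %/% 2L)
  p3 <- op_maxpool(tp, p2, m$k, 1L, m$k %/% 2L)
  fwd_conv(tp, op_concat_c(tp, c(y, p1, p2, p3)), m$cv2, training)
}

# stock position-sensitive attention (global softmax attention with a
# depthwise positional-encoding branch), used by the baseline C2PSA
new_psa_attn <- function(dim, num_heads = max(1L, dim %/% 64L),
                         attn_ratio = 0.5) {
  head_dim <- dim %/% num_heads
  key_dim <- as.integer(head_dim * attn_ratio)
  h <- dim + 2L * key_dim * num_heads
  list(type = "psa_attn", dim = dim, num_heads = num_heads,
       key_dim = key_dim, head_dim = head_dim, scale = key_dim^-0.5,
       qkv = new_conv(dim, h, 1L, act = FALSE),
       proj = new_conv(dim, dim, 1L, act = FALSE),
       pe = new_conv(dim, dim, 3L, groups = dim, act = FALSE))
}

# global softmax attention over all positions for one head
op_global_attn <- function(tp, q, k, v, scale) {
  vq <- tpf(tp, q); vk <- tpf(tp, k); vv <- tpf(tp, v)
  d <- dim(vq); dv <- dim(vv)
  HW <- d[1] * d[2]; N <- d[4]
  out <- array(0, dim = dv)
  caches <- vector("list", N)
  for (n in seq_len(N)) {
    Q <- matrix(vq[, , , n], HW, d[3])      # positions x kd
    K <- matrix(vk[, , , n], HW, d[3])
    V <- matrix(vv[, , , n], HW, dv[3])     # positions x hd
    A <- (Q %*% t(K)) * scale               # s x t
    A <- exp(A - apply(A, 1, max))
    P <- A / rowSums(A)
    out[, , , n] <- array(P %*% V, dim = c(d[1], d[2], dv[3]))
    caches[[n]] <- list(Q = Q, K = K, V = V, P = P)
  }
  tp_node(tp, out, c(q, k, v), function(g) {
    dq <- array(0, dim = d); dk <- array(0, dim = d); dvv <- array(0, dim = dv)
    for (n in seq_len(N)) {
      ca <- caches[[n]]
      G <- matrix(g[, , , n], HW, dv[3])
      dV <- t(ca$P) %*% G
      dP <- G %*% t(ca$V)
      dA <- ca$P * (dP - rowSums(ca$P * dP))
      dq[, , , n] <- array(scale * (dA %*% ca$K), dim = c(d[1], d[2], d[3]))
      dk[, , , n] <- array(scale * (t(dA) %*% ca$Q), dim = c(d[1], d[2], d[3]))
      dvv[, , , n] <- array(dV, dim = c(d[1], d[2], dv[3]))
    }
    list(dq, dk, dvv)
  })
}

fwd_psa_attn <- function(tp, x, m, training) {
  qkv <- fwd_conv(tp, x, m$qkv, training)
  nh <- m$num_heads; kd <- m$key_dim; hd <- m$head_dim
  nh_kd <- nh * kd
  outs <- vector("list", nh)
  vs_all <- op_slice_c(tp, qkv, 2L * nh_kd + 1L, 2L * nh_kd + m$dim)
  for (h in seq_len(nh)) {
    qh <- op_slice_c(tp, qkv, (h - 1L) * kd + 1L, h * kd)
    kh <- op_slice_c(tp, qkv, nh_kd + (h - 1L) * kd + 1L, nh_kd + h * kd)
    vh <- op_slice_c(tp, vs_all, (h - 1L) * hd + 1L, h * hd)
    outs[[h]] <- op_global_attn(tp, qh, kh, vh, m$scale)
  }
  att <- if (nh > 1L) op_concat_c(tp, unlist(outs)) else outs[[1]]
  pe <- fwd_conv(tp, vs_all, m$pe, training)
  fwd_conv(tp, op_add(tp, att, pe), m$proj, training)
}

new_psa_block <- function(c, attn_cfg = NULL) {
  attn <- if (is.null(attn_cfg)) new_psa_attn(c) else new_msda(c, attn_cfg)
  list(type = "psa_block", msda = !is.null(attn_cfg), attn = attn,
       ffn1 = new_conv(c, 2L * c, 1L), ffn2 = new_conv(2L * c, c, 1L,
                                                       act = FALSE))
}

fwd_psa_block <- function(tp, x, m, training) {
  a <- if (m$msda) fwd_msda(tp, x, m$attn, training)
       else fwd_psa_attn(tp, x, m$attn, training)
  y <- op_add(tp, x, a)
  f <- fwd_conv(tp, fwd_conv(tp, y, m$ffn1, training), m$ffn2, training)
  op_add(tp, y, f)
}

new_c2psa <- function(c1, n = 1L, attn_cfg = NULL, e = 0.5) {
  ch <- as.integer(c1 * e)
  list(type = "c2psa", c = ch,
       cv1 = new_conv(c1, 2L * ch, 1L), cv2 = new_conv(2L * ch, c1, 1L),
       m = lapply(seq_len(n), function(i) new_psa_block(ch, attn_cfg)))
}

fwd_c2psa <- function(tp, x, m, training) {
  y <- fwd_conv(tp, x, m$cv1, training)
  a <- op_slice_c(tp, y, 1L, m$c)
  b <- op_slice_c(tp, y, m$c + 1L, 2L * m$c)
  for (blk in m$m) b <- fwd_psa_block(tp, b, blk, training)
  fwd_conv(tp, op_concat_c(tp, c(a, b)), m$cv2, training)
}

#' PSA block with MSDA attention applied to a feature map
#'
#' Residual attention plus residual feed-forward:
#' `y = x + MSDA(x); z = y + FFN(y)`.
#'
#' @param x array (H, W, C, N)
#' @param cfg an [attention_config()]
#' @param module optional prebuilt block (from `new_psa_block`)
#' @return array of the same shape
#' @export
psa_block_msda <- function(x, cfg = attention_config(), module = NULL) {
  if (is.null(module)) module <- new_psa_block(dim(x)[3], cfg)
  tp <- new_tape()
  tp_value(tp, fwd_psa_block(tp, op_input(tp, x), module, FALSE))
}

#' C2PSA block with MSDA attention applied to a feature map
#'
#' A 1x1 convolution splits channels into two halves; one half passes
#' through `n_blocks` stacked [psa_block_msda()] units; the halves are
#' concatenated and fused by a 1x1 convolution.
#'
#' @param x array (H, W, C, N) with even C
#' @param n_blocks number of stacked attention blocks
#' @param cfg an [attention_config()]
#' @param module optional prebuilt block (from `new_c2psa`)
#' @return array of the same shape
#' @export
c2psa_msda <- function(x, n_blocks = 1L, cfg = attention_config(),
                       module = NULL) {
  if (dim(x)[3] %% 2L != 0L)
    stop("channel count must be even", call. = FALSE)
  if (is.null(module)) module <- new_c2psa(dim(x)[3], n_blocks, cfg)
  tp <- new_tape()
  tp_value(tp, fwd_c2psa(tp, op_input(tp, x), module, FALSE))
}

# ---- whole model ------------------------------------------------------

#' Assemble a detector
#'
#' Builds the full one-stage detector at the configured scaling: the
#' published v11-nano backbone/neck layout, with the backbone C2PSA
#' replaced by its MSDA variant and the detection head replaced by the
#' adaptive spatial feature-fusion head when `cfg$variant == "mas"`.
#'
#' @param cfg a [model_config()]
#' @return an `rd_model` object with three output levels (strides 8/16/32)
#' @export
build_model <- function(cfg) {
  if (!inherits(cfg, "model_config")) stop("cfg must be a model_config",
                                           call. = FALSE)
  w <- cfg$width_multiple; dmul <- cfg$depth_multiple; mc <- cfg$max_channels
  ch <- function(b) scaled_ch(b, w, mc)
  nr <- function(n) n_rep(n, dmul)
  mas <- cfg$variant == "mas"
  L <- list()
  # backbone
  L$l0 <- list(from = 0L, type = "conv", m = new_conv(3L, ch(64), 3L, 2L))
  L$l1 <- list(from = -1L, type = "conv", m = new_conv(ch(64), ch(128), 3L, 2L))
  L$l2 <- list(from = -1L, type = "c3k2",
               m = new_c3k2(ch(128), ch(256), nr(2), FALSE, 0.25))
  L$l3 <- list(from = -1L, type = "conv", m = new_conv(ch(256), ch(256), 3L, 2L))
  L$l4 <- list(from = -1L, type = "c3k2",
               m = new_c3k2(ch(256), ch(512), nr(2), FALSE, 0.25))
  L$l5 <- list(from = -1L, type = "conv", m = new_conv(ch(512), ch(512), 3L, 2L))
  L$l6 <- list(from = -1L, type = "c3k2",
               m = new_c3k2(ch(512), ch(512), nr(2), TRUE))
  L$l7 <- list(from = -1L, type = "conv", m = new_conv(ch(512), ch(1024), 3L, 2L))
  L$l8 <- list(from = -1L, type = "c3k2",
               m = new_c3k2(ch(1024), ch(1024), nr(2), TRUE))
  L$l9 <- list(from = -1L, type = "sppf", m = new_sppf(ch(1024), ch(1024)))
  L$l10 <- list(from = -1L, type = "c2psa",
                m = new_c2psa(ch(1024), nr(2),
                              if (mas) cfg$attention else NULL))
  # neck
  L$l11 <- list(from = -1L, type = "upsample", f = 2L)
  L$l12 <- list(from = c(-1L, 6L), type = "concat")
  L$l13 <- list(from = -1L, type = "c3k2",
                m = new_c3k2(ch(1024) + ch(512), ch(512), nr(2), FALSE))
  L$l14 <- list(from = -1L, type = "upsample", f = 2L)
  L$l15 <- list(from = c(-1L, 4L), type = "concat")
  L$l16 <- list(from = -1L, type = "c3k2",
                m = new_c3k2(ch(512) + ch(512), ch(256), nr(2), FALSE))
  L$l17 <- list(from = -1L, type = "conv", m = new_conv(ch(256), ch(256), 3L, 2L))
  L$l18 <- list(from = c(-1L, 13L), type = "concat")
  L$l19 <- list(from = -1L, type = "c3k2",
                m = new_c3k2(ch(256) + ch(512), ch(512), nr(2), FALSE))
  L$l20 <- list(from = -1L, type = "conv", m = new_conv(ch(512), ch(512), 3L, 2L))
  L$l21 <- list(from = c(-1L, 10L), type = "concat")
  L$l22 <- list(from = -1L, type = "c3k2",
                m = new_c3k2(ch(512) + ch(1024), ch(1024), nr(2), TRUE))
  ch_levels <- c(ch(256), ch(512), ch(1024)) # P3, P4, P5
  head <- if (mas) new_asff_head(ch_levels, cfg$num_classes, cfg$reg_max)
          else new_detect_head(ch_levels, cfg$num_classes, cfg$reg_max)
  model <- list(cfg = cfg, layers = L, head = head,
                ch_levels = ch_levels,
                save_idx = c(4L, 6L, 10L, 13L, 16L, 19L, 22L))
  class(model) <- "rd_model"
  model
}

# run backbone + neck, return tape ids of P3/P4/P5
fwd_neck <- function(tp, x, model, training = FALSE) {
  outs <- vector("list", 23L)
  prev <- x
  for (i in 0:22) {
    ly <- model$layers[[paste0("l", i)]]
    from <- ly$from
    y <- switch(ly$type,
      conv = fwd_conv(tp, prev, ly$m, training),
      c3k2 = fwd_c3k2(tp, prev, ly$m, training),
      sppf = fwd_sppf(tp, prev, ly$m, training),
      c2psa = fwd_c2psa(tp, prev, ly$m, training),
      upsample = op_upsample(tp, prev, ly$f),
      concat = op_concat_c(tp, c(prev, outs[[from[2] + 1L]])),
      stop("unknown layer type ", ly$type)
    )
    outs[[i + 1L]] <- y
    prev <- y
  }
  list(p3 = outs[[17L]], p4 = outs[[20L]], p5 = outs[[23L]])
}

# full forward: returns per-level raw head outputs
fwd_model <- function(tp, x, model, training = FALSE) {
  pyr <- fwd_neck(tp, x, model, training)
  if (model$head$type == "asff") {
    fwd_asff_head(tp, pyr, model$head, training)
  } else {
    fwd_detect_head(tp, pyr, model$head, training)
  }
}

#' Forward pass of a detector on a plain array
#'
#' @param model an `rd_model` from [build_model()]
#' @param x input array (H, W, 3, N), H and W divisible by 32
#' @param training logical; training-mode batch statistics when `TRUE`
#' @return list of three levels (strides 8, 16, 32), each with `cls`
#'   (H, W, num_classes, N) logits and `box` (H, W, 4*reg_max, N)
#'   distribution logits
#' @export
model_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4 || d[3] != 3)
    stop("x must be (H, W, 3, N)", call. = FALSE)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("input side must be divisible by 32", call. = FALSE)
  tp <- new_tape()
  out <- fwd_model(tp, op_input(tp, x), model, training)
  lapply(out, function(l) list(cls = tp_value(tp, l$cls),
                               box = tp_value(tp, l$box),
                               stride = l$stride))
}

#' Count learnable parameters
#'
#' Counts every learnable scalar (weights and biases; batch-norm running
#' statistics and the fixed distribution-decode projection are excluded)
#' per top-level module and in total.
#'
#' @param model an `rd_model`, or any nested layer structure
#' @return a `model_summary`: list with `total_params` and
#'   `per_module_params` (named numeric vector)
#' @export
count_parameters <- function(model) {
  groups <- if (inherits(model, "rd_model")) {
    c(model$layers, list(head = model$head))
  } else {
    list(module = model)
  }
  per <- vapply(groups, function(g) {
    ps <- layer_params(g)
    sum(vapply(ps, function(p) length(p$value), numeric(1)))
  }, numeric(1))
  structure(list(total_params = sum(per), per_module_params = per),
            class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("total learnable parameters: %s (%.2f M)\n",
              format(x$total_params, big.mark = ","),
              x$total_params / 1e6))
  df <- data.frame(module = names(x$per_module_params),
                   params = as.integer(x$per_module_params))
  print(df, row.names = FALSE)
  invisible(x)
}
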