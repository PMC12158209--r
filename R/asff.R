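# Detection heads.
#
# Level indexing for adaptive fusion follows the downsampling direction:
# Level 0 is the deepest map (stride 32), Level 1 stride 16, Level 2
# stride 8.  Every output level rescales the other two maps to its own
# resolution and channel count, computes per-position fusion weights by a
# three-way softmax over 1x1-convolution control maps, blends the three
# maps convexly, and feeds the result to decoupled classification /
# box-distribution branches.

LEVEL_STRIDES <- c(32L, 16L, 8L)

level_channels <- function(ch_levels, level) {
  # ch_levels is (P3, P4, P5) = strides (8, 16, 32)
  ch_levels[c(3L, 2L, 1L)][level + 1L]
}

cls_bias_init <- -log(99) # prior foreground probability ~1%

new_branches <- function(ch_levels, nc, reg_max) {
  c2 <- max(16L, ch_levels[1] %/% 4L, 4L * reg_max)
  c3 <- max(ch_levels[1], min(nc, 100L))
  box <- lapply(ch_levels, function(ci) {
    b <- list(cv1 = new_conv(ci, c2, 3L), cv2 = new_conv(c2, c2, 3L),
              out = new_conv(c2, 4L * reg_max, 1L, bn = FALSE, act = FALSE,
                             bias = TRUE))
    b$out$b$value[] <- 1.0
    b
  })
  cls <- lapply(ch_levels, function(ci) {
    b <- list(dw1 = new_conv(ci, ci, 3L, groups = ci),
              pw1 = new_conv(ci, c3, 1L),
              dw2 = new_conv(c3, c3, 3L, groups = c3),
              pw2 = new_conv(c3, c3, 1L),
              out = new_conv(c3, nc, 1L, bn = FALSE, act = FALSE,
                             bias = TRUE))
    b$out$b$value[] <- cls_bias_init
    b
  })
  list(box = box, cls = cls)
}

fwd_branches <- function(tp, x, br_box, br_cls, training) {
  b <- fwd_conv(tp, fwd_conv(tp, x, br_box$cv1, training), br_box$cv2,
                training)
  b <- fwd_conv(tp, b, br_box$out, training)
  cl <- fwd_conv(tp, x, br_cls$dw1, training)
  cl <- fwd_conv(tp, cl, br_cls$pw1, training)
  cl <- fwd_conv(tp, cl, br_cls$dw2, training)
  cl <- fwd_conv(tp, cl, br_cls$pw2, training)
  cl <- fwd_conv(tp, cl, br_cls$out, training)
  list(cls = cl, box = b)
}

new_detect_head <- function(ch_levels, nc, reg_max) {
  br <- new_branches(ch_levels, nc, reg_max)
  list(type = "detect", nc = nc, reg_max = reg_max, branches = br)
}

fwd_detect_head <- function(tp, pyr, head, training) {
  xs <- list(pyr$p3, pyr$p4, pyr$p5)
  strides <- c(8L, 16L, 32L)
  lapply(1:3, function(i) {
    o <- fwd_branches(tp, xs[[i]], head$branches$box[[i]],
                      head$branches$cls[[i]], training)
    o$stride <- strides[i]
    o
  })
}

# ---- ASFF -------------------------------------------------------------

new_rescaler <- function(c_from, c_to, from_level, to_level) {
  if (from_level == to_level) return(list(kind = "identity"))
  sf <- LEVEL_STRIDES[from_level + 1L]
  st <- LEVEL_STRIDES[to_level + 1L]
  if (sf > st) {
    # coarser -> finer: 1x1 channel match then nearest-neighbour upsample
    list(kind = "up", f = sf %/% st,
         cv = new_conv(c_from, c_to, 1L))
  } else if (st %/% sf == 2L) {
    list(kind = "down2", cv = new_conv(c_from, c_to, 3L, 2L))
  } else {
    # two levels finer -> coarser: stride-2 max-pool then 3x3 stride-2 conv
    list(kind = "down4", cv = new_conv(c_from, c_to, 3L, 2L))
  }
}

fwd_rescaler <- function(tp, x, rs, training) {
  switch(rs$kind,
    identity = x,
    up = op_upsample(tp, fwd_conv(tp, x, rs$cv, training), rs$f),
    down2 = fwd_conv(tp, x, rs$cv, training),
    down4 = fwd_conv(tp, op_maxpool(tp, x, 2L, 2L, 0L), rs$cv, training))
}

new_asff_level <- function(ch_levels, level, compression = 8L) {
  c_l <- level_channels(ch_levels, level)
  rescalers <- lapply(0:2, function(n)
    new_rescaler(level_channels(ch_levels, n), c_l, n, level))
  list(level = level, c_l = c_l,
       rescalers = rescalers,
       compress = lapply(1:3, function(i) new_conv(c_l, compression, 1L)),
       joint = new_conv(3L * compression, 3L, 1L, bn = FALSE, act = FALSE,
                        bias = TRUE),
       expand = new_conv(c_l, c_l, 3L))
}

new_asff_head <- function(ch_levels, nc, reg_max, compression = 8L) {
  br <- new_branches(ch_levels, nc, reg_max)
  list(type = "asff", nc = nc, reg_max = reg_max,
       levels = lapply(0:2, function(l)
         new_asff_level(ch_levels, l, compression)),
       branches = br)
}

# softmax over the 3-channel lambda axis of an (H, W, 3, N) node
op_softmax3 <- function(tp, lam) {
  v <- tpf(tp, lam)
  mx <- pmax(v[, , 1, , drop = FALSE], v[, , 2, , drop = FALSE],
             v[, , 3, , drop = FALSE])
  e <- exp(sweep_c3(v, mx, `-`))
  z <- e[, , 1, , drop = FALSE] + e[, , 2, , drop = FALSE] +
    e[, , 3, , drop = FALSE]
  p <- sweep_c3(e, z, `/`)
  tp_node(tp, p, lam, function(g) {
    s <- g[, , 1, , drop = FALSE] * p[, , 1, , drop = FALSE] +
      g[, , 2, , drop = FALSE] * p[, , 2, , drop = FALSE] +
      g[, , 3, , drop = FALSE] * p[, , 3, , drop = FALSE]
    list(p * sweep_c3(g, s, `-`))
  })
}

# apply a single-channel map `m` (H,W,1,N) to every channel of v via `f`
sweep_c3 <- function(v, m, f) {
  out <- v
  for (c in seq_len(dim(v)[3])) out[, , c, ] <- f(v[, , c, , drop = FALSE], m)
  out
}

# weight one (H,W,C,N) node by a (H,W,1,N) scalar-map node
op_scale_map <- function(tp, x, w) {
  vx <- tpf(tp, x); vw <- tpf(tp, w)
  tp_node(tp, sweep_c3(vx, vw, `*`), c(x, w), function(g) {
    gw <- g[, , 1, , drop = FALSE] * 0
    for (c in seq_len(dim(vx)[3]))
      gw <- gw + g[, , c, , drop = FALSE] * vx[, , c, , drop = FALSE]
    list(sweep_c3(g, vw, `*`), gw)
  })
}

fwd_asff_level <- function(tp, xs, lv, training) {
  # xs: list of level-0/1/2 tape ids (strides 32/16/8)
  resc <- lapply(1:3, function(i)
    fwd_rescaler(tp, xs[[i]], lv$rescalers[[i]], training))
  comp <- lapply(1:3, function(i)
    fwd_conv(tp, resc[[i]], lv$compress[[i]], training))
  lam <- fwd_conv(tp, op_concat_c(tp, unlist(comp)), lv$joint, training)
  w3 <- op_softmax3(tp, lam)
  wa <- op_slice_c(tp, w3, 1L, 1L)
  wb <- op_slice_c(tp, w3, 2L, 2L)
  wc <- op_slice_c(tp, w3, 3L, 3L)
  fused <- op_add(tp, op_add(tp, op_scale_map(tp, resc[[1]], wa),
                             op_scale_map(tp, resc[[2]], wb)),
                  op_scale_map(tp, resc[[3]], wc))
  fwd_conv(tp, fused, lv$expand, training)
}

fwd_asff_head <- function(tp, pyr, head, training) {
  xs <- list(pyr$p5, pyr$p4, pyr$p3) # level 0, 1, 2
  fused <- lapply(1:3, function(i)
    fwd_asff_level(tp, xs, head$levels[[i]], training))
  # branch index by pyramid order (P3 first) to share c2/c3 conventions
  out <- lapply(1:3, function(i) {
    lvl <- 3L - i # fused[[1]] is level 0 = stride 32
    bi <- c(3L, 2L, 1L)[i]
    o <- fwd_branches(tp, fused[[i]], head$branches$box[[bi]],
                      head$branches$cls[[bi]], training)
    o$stride <- LEVEL_STRIDES[i]
    o
  })
  # return in stride order 8, 16, 32
  list(out[[3]], out[[2]], out[[1]])
}

# ---- user-facing functional pieces ------------------------------------

#' Rescale a pyramid level feature map to another level's geometry
#'
#' Levels are numbered from the deepest map: level 0 = stride 32,
#' level 1 = stride 16, level 2 = stride 8.  Coarser-to-finer rescaling is
#' a 1x1 channel-matching convolution followed by nearest-neighbour
#' upsampling; one step finer-to-coarser is a 3x3 stride-2 convolution;
#' two steps finer-to-coarser prepends a stride-2 max-pool.
#'
#' @param feature array (H, W, C, N)
#' @param from_level,to_level integers in 0:2
#' @param channels_out channel count of the target level (defaults to C)
#' @param module optional prebuilt rescaler (reused across calls)
#' @return array at the target level's spatial size with `channels_out`
#'   channels
#' @export
rescale_to_level <- function(feature, from_level, to_level,
                             channels_out = NULL, module = NULL) {
  if (!from_level %in% 0:2 || !to_level %in% 0:2)
    stop("levels must be in {0, 1, 2}", call. = FALSE)
  if (is.null(channels_out)) channels_out <- dim(feature)[3]
  if (is.null(module))
    module <- new_rescaler(dim(feature)[3], channels_out, from_level,
                           to_level)
  tp <- new_tape()
  tp_value(tp, fwd_rescaler(tp, op_input(tp, feature), module, FALSE))
}

#' Position-wise fusion weights from pre-softmax control maps
#'
#' Applies the three-way softmax to a 3-channel lambda map, yielding
#' `alpha`, `beta`, `gamma` maps in `[0, 1]` that sum to 1 at every
#' position.
#'
#' @param lambda array (H, W, 3, N) of control values
#' @return list with `alpha`, `beta`, `gamma` (each (H, W, 1, N)) and the
#'   input `lambda`
#' @export
fusion_weights_from_lambda <- function(lambda) {
  if (dim(lambda)[3] != 3) stop("lambda must have 3 channels", call. = FALSE)
  tp <- new_tape()
  w <- tp_value(tp, op_softmax3(tp, op_input(tp, lambda)))
  list(alpha = w[, , 1, , drop = FALSE], beta = w[, , 2, , drop = FALSE],
       gamma = w[, , 3, , drop = FALSE], lambda = lambda)
}

#' Compute adaptive fusion weights for one output level
#'
#' Each rescaled map is compressed by a 1x1 convolution (width
#' `compression`), the compressed maps are concatenated, and a final 1x1
#' convolution produces the three lambda control maps that are softmaxed
#' position-wise into `alpha`, `beta`, `gamma`.
#'
#' @param rescaled list of three arrays (H, W, C, N) already rescaled to a
#'   common level geometry
#' @param compression width of the compression convolutions
#' @param module optional prebuilt ASFF level module
#' @return list with `alpha`, `beta`, `gamma`, `lambda`
#' @export
compute_fusion_weights <- function(rescaled, compression = 8L,
                                   module = NULL) {
  d <- dim(rescaled[[1]])
  for (x in rescaled) {
    if (!identical(dim(x)[c(1, 2)], d[c(1, 2)]))
      stop("rescaled maps must share spatial size", call. = FALSE)
  }
  if (is.null(module)) {
    cl <- d[3]
    module <- list(compress = lapply(1:3, function(i)
      new_conv(cl, compression, 1L)),
      joint = new_conv(3L * compression, 3L, 1L, bn = FALSE,
                       act = FALSE, bias = TRUE))
  }
  tp <- new_tape()
  comp <- lapply(1:3, function(i)
    fwd_conv(tp, op_input(tp, rescaled[[i]]), module$compress[[i]], FALSE))
  lam <- fwd_conv(tp, op_concat_c(tp, unlist(comp)), module$joint, FALSE)
  fusion_weights_from_lambda(tp_value(tp, lam))
}

#' Adaptive weighted fusion of three rescaled maps
#'
#' Position-wise convex blend: at each position (i, j) the output is
#' `alpha * x0 + beta * x1 + gamma * x2`, with the scalar weights
#' broadcast over channels.
#'
#' @param rescaled list of three arrays (H, W, C, N)
#' @param weights list with `alpha`, `beta`, `gamma` maps (H, W, 1, N)
#' @return fused array (H, W, C, N)
#' @export
asff_fuse <- function(rescaled, weights) {
  d <- dim(rescaled[[1]])
  for (x in rescaled) {
    if (!identical(dim(x), d)) stop("shape mismatch", call. = FALSE)
  }
  sweep_c3(rescaled[[1]], weights$alpha, `*`) +
    sweep_c3(rescaled[[2]], weights$beta, `*`) +
    sweep_c3(rescaled[[3]], weights$gamma, `*`)
}

#' Full adaptive-fusion head forward pass on plain arrays
#'
#' @param levels list with `p3`, `p4`, `p5` arrays (strides 8/16/32)
#' @param head an ASFF head (built inside [build_model()]), or `NULL` to
#'   construct one matching the input channels
#' @param num_classes,reg_max head output widths when building fresh
#' @return list of three levels (strides 8/16/32) with `cls` and `box`
#'   arrays
#' @export
asff_head_forward <- function(levels, head = NULL, num_classes = 4L,
                              reg_max = 16L) {
  if (!all(c("p3", "p4", "p5") %in% names(levels)))
    stop("levels must name p3, p4, p5", call. = FALSE)
  if (is.null(head)) {
    ch <- vapply(levels[c("p3", "p4", "p5")], function(x) dim(x)[3],
                 numeric(1))
    head <- new_asff_head(as.integer(ch), num_classes, reg_max)
  }
  tp <- new_tape()
  pyr <- list(p3 = op_input(tp, levels$p3), p4 = op_input(tp, levels$p4),
              p5 = op_input(tp, levels$p5))
  out <- fwd_asff_head(tp, pyr, head, FALSE)
  lapply(out, function(l) list(cls = tp_value(tp, l$cls),
                               box = tp_value(tp, l$box),
                               stride = l$stride))
}
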