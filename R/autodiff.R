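#' @useDynLib reefdet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Reverse-mode autodiff tape.
#
# Activations are tape nodes (integer handles); learnable parameters live in
# environments (`value`, `grad`, `mom`) and receive gradients directly from
# op closures, so the tape only tracks the activation graph.  Ops append a
# node with its value, parent ids and a backward closure mapping the upstream
# gradient to a list of parent gradients.

new_tape <- function(capacity = 1024L) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", capacity)
  tp$parents <- vector("list", capacity)
  tp$bwd <- vector("list", capacity)
  tp$cap <- capacity
  tp$n <- 0L
  tp
}

# Fetch a node value, forcing the id promise FIRST: nested op calls in
# argument position append nodes to the tape, so `tp$vals` must be read
# only after the id argument has been evaluated.
tpf <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

tp_value <- function(tp, id) tpf(tp, id)

tp_node <- function(tp, value, parents = integer(0), backward = NULL) {
  # force arguments before claiming a node id (see tpf)
  force(value)
  parents <- as.integer(parents)
  if (tp$n >= tp$cap) { # grow by doubling
    tp$cap <- tp$cap * 2L
    length(tp$vals) <- tp$cap
    length(tp$parents) <- tp$cap
    length(tp$bwd) <- tp$cap
  }
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- value
  tp$parents[[tp$n]] <- parents
  tp$bwd[tp$n] <- list(backward)
  tp$n
}

# Backpropagate from scalar node `root`; parameter gradients are
# accumulated inside the op closures.  `wrt` optionally names node ids
# whose activation gradients should be returned.
tp_backward <- function(tp, root, seed = 1, wrt = integer(0)) {
  grads <- vector("list", tp$n)
  g0 <- tpf(tp, root)
  g0[] <- seed
  grads[[root]] <- g0
  keep <- vector("list", length(wrt))
  for (id in seq(tp$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    if (length(wrt) && id %in% wrt) keep[[match(id, wrt)]] <- g
    fn <- tp$bwd[[id]]
    if (is.null(fn)) {
      grads[id] <- list(NULL)
      next
    }
    pg <- fn(g)
    ps <- tp$parents[[id]]
    for (i in seq_along(ps)) {
      if (is.null(pg[[i]])) next
      p <- ps[i]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[i]] else grads[[p]] + pg[[i]]
    }
    grads[id] <- list(NULL) # free memory without shifting indices
  }
  invisible(keep)
}

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$mom <- NULL
  p
}

param_zero_grad <- function(p) {
  p$grad <- NULL
  invisible(p)
}

acc_grad <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(p)
}

# ---- generic ops ------------------------------------------------------

op_input <- function(tp, x) tp_node(tp, x)

op_add <- function(tp, a, b) {
  va <- tpf(tp, a); vb <- tpf(tp, b)
  tp_node(tp, va + vb, c(a, b), function(g) list(g, g))
}

op_sub <- function(tp, a, b) {
  va <- tpf(tp, a); vb <- tpf(tp, b)
  tp_node(tp, va - vb, c(a, b), function(g) list(g, -g))
}

op_mul <- function(tp, a, b) {
  va <- tpf(tp, a); vb <- tpf(tp, b)
  tp_node(tp, va * vb, c(a, b), function(g) list(g * vb, g * va))
}

op_div <- function(tp, a, b) {
  va <- tpf(tp, a); vb <- tpf(tp, b)
  tp_node(tp, va / vb, c(a, b),
          function(g) list(g / vb, -g * va / (vb * vb)))
}

op_const_mul <- function(tp, a, k) {
  tp_node(tp, tpf(tp, a) * k, a, function(g) list(g * k))
}

op_const_add <- function(tp, a, k) {
  tp_node(tp, tpf(tp, a) + k, a, function(g) list(g))
}

op_square <- function(tp, a) {
  va <- tpf(tp, a)
  tp_node(tp, va * va, a, function(g) list(2 * g * va))
}

op_sqrt <- function(tp, a, eps = 1e-12) {
  va <- sqrt(tpf(tp, a) + eps)
  tp_node(tp, va, a, function(g) list(g / (2 * va)))
}

op_exp <- function(tp, a) {
  va <- exp(tpf(tp, a))
  tp_node(tp, va, a, function(g) list(g * va))
}

op_atan <- function(tp, a) {
  va <- tpf(tp, a)
  tp_node(tp, atan(va), a, function(g) list(g / (1 + va * va)))
}

op_sigmoid <- function(tp, a) {
  s <- stats::plogis(tpf(tp, a))
  tp_node(tp, s, a, function(g) list(g * s * (1 - s)))
}

op_silu <- function(tp, a) {
  va <- tpf(tp, a)
  s <- stats::plogis(va)
  tp_node(tp, va * s, a, function(g) list(g * (s * (1 + va * (1 - s)))))
}

# clamp with straight-through zero gradient outside the range
op_clamp <- function(tp, a, lo, hi) {
  va <- tpf(tp, a)
  inside <- (va >= lo) & (va <= hi)
  tp_node(tp, pmin(pmax(va, lo), hi), a, function(g) list(g * inside))
}

op_pmax <- function(tp, a, b) {
  va <- tpf(tp, a); vb <- tpf(tp, b)
  amax <- va >= vb
  tp_node(tp, pmax(va, vb), c(a, b),
          function(g) list(g * amax, g * !amax))
}

op_pmin <- function(tp, a, b) {
  va <- tpf(tp, a); vb <- tpf(tp, b)
  amin <- va <= vb
  tp_node(tp, pmin(va, vb), c(a, b),
          function(g) list(g * amin, g * !amin))
}

op_sum <- function(tp, a) {
  va <- tpf(tp, a)
  tp_node(tp, sum(va), a, function(g) {
    gg <- va
    gg[] <- as.numeric(g)
    list(gg)
  })
}

op_mean <- function(tp, a) {
  va <- tpf(tp, a)
  n <- length(va)
  tp_node(tp, sum(va) / n, a, function(g) {
    gg <- va
    gg[] <- as.numeric(g) / n
    list(gg)
  })
}

# gather elements by linear index (values become a plain vector)
op_gather <- function(tp, a, idx) {
  va <- tpf(tp, a)
  tp_node(tp, as.numeric(va[idx]), a, function(g) {
    gg <- array(0, dim = if (is.null(dim(va))) length(va) else dim(va))
    # scatter-add (idx may repeat)
    ag <- rowsum(as.numeric(g), idx)
    gg[as.numeric(rownames(ag))] <- ag[, 1]
    list(gg)
  })
}

# channel-slice of an (H,W,C,N) node
op_slice_c <- function(tp, a, c0, c1) {
  va <- tpf(tp, a)
  d <- dim(va)
  tp_node(tp, va[, , c0:c1, , drop = FALSE], a, function(g) {
    gg <- array(0, dim = d)
    gg[, , c0:c1, ] <- g
    list(gg)
  })
}

# channel concat of (H,W,C,N) nodes
op_concat_c <- function(tp, ids) {
  vs <- lapply(ids, function(i) tpf(tp, i))
  cs <- vapply(vs, function(v) dim(v)[3], numeric(1))
  d <- dim(vs[[1]])
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0
  for (v in vs) {
    out[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  offs <- cumsum(c(0, cs))
  tp_node(tp, out, ids, function(g) {
    lapply(seq_along(ids), function(i) {
      g[, , (offs[i] + 1):offs[i + 1], , drop = FALSE]
    })
  })
}

op_upsample <- function(tp, a, f) {
  tp_node(tp, cpp_upsample_nn_fwd(tpf(tp, a), f), a,
          function(g) list(cpp_upsample_nn_bwd(g, f)))
}

op_maxpool <- function(tp, a, k, stride, pad = 0L) {
  va <- tpf(tp, a)
  r <- cpp_maxpool_fwd(va, k, stride, pad)
  xd <- dim(va)
  idx <- r$idx + 1L
  tp_node(tp, r$y, a, function(g) {
    list(cpp_maxpool_bwd(g, idx - 1L, as.integer(xd)))
  })
}

op_swda <- function(tp, q, k, v, rate, kern, scale, head_dim) {
  vq <- tpf(tp, q); vk <- tpf(tp, k); vv <- tpf(tp, v)
  y <- cpp_swda_fwd(vq, vk, vv, rate, kern, scale, head_dim)
  tp_node(tp, y, c(q, k, v), function(g) {
    r <- cpp_swda_bwd(vq, vk, vv, g, rate, kern, scale, head_dim)
    list(r$dq, r$dk, r$dv)
  })
}

# weighted binary cross-entropy from logits; w and y are constants
op_wbce <- function(tp, logits, y, w) {
  p <- tpf(tp, logits)
  # stable: max(p,0) - p*y + log1p(exp(-|p|))
  l <- pmax(p, 0) - p * y + log1p(exp(-abs(p)))
  tp_node(tp, w * l, logits, function(g) {
    list(g * w * (stats::plogis(p) - y))
  })
}

# distribution focal loss: logits is (reg_max x M) matrix node, t in
# [0, reg_max-1] continuous targets; returns vector of M losses
op_dfl <- function(tp, logits, t) {
  L <- tpf(tp, logits)
  reg_max <- nrow(L)
  tl <- pmin(floor(t), reg_max - 2)
  wr <- t - tl
  wl <- 1 - wr
  mx <- apply(L, 2, max)
  eL <- exp(sweep(L, 2, mx))
  Z <- colSums(eL)
  logp <- sweep(L, 2, mx + log(Z))
  M <- ncol(L)
  il <- cbind(tl + 1, seq_len(M))
  ir <- cbind(tl + 2, seq_len(M))
  loss <- -(wl * logp[il] + wr * logp[ir])
  P <- sweep(eL, 2, Z, "/")
  tp_node(tp, loss, logits, function(g) {
    tgt <- matrix(0, reg_max, M)
    tgt[il] <- wl
    tgt[ir] <- wr
    dl <- sweep(P, 2, colSums(tgt), "*") - tgt # = P - tgt (colSums(tgt)=1)
    list(sweep(dl, 2, as.numeric(g), "*"))
  })
}

op_reshape <- function(tp, a, d) {
  va <- tpf(tp, a)
  od <- dim(va)
  tp_node(tp, array(va, dim = d), a, function(g) {
    list(if (is.null(od)) as.numeric(g) else array(g, dim = od))
  })
}

# softmax-expectation decode of a (reg_max x M) logit matrix -> M values
op_dfl_expect <- function(tp, logits) {
  L <- tpf(tp, logits)
  reg_max <- nrow(L)
  bins <- 0:(reg_max - 1)
  mx <- apply(L, 2, max)
  eL <- exp(sweep(L, 2, mx))
  P <- sweep(eL, 2, colSums(eL), "/")
  ev <- as.numeric(bins %*% P)
  tp_node(tp, ev, logits, function(g) {
    dl <- P * (bins - matrix(ev, reg_max, length(ev), byrow = TRUE))
    list(sweep(dl, 2, as.numeric(g), "*"))
  })
}
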