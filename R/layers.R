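# Layer constructors and tape-aware forward passes.
#
# A layer is a plain list (class "rd_layer") carrying its hyperparameters
# and parameter environments.  `layer_params()` walks any nested structure
# of layers and returns the named list of parameter environments, which is
# what the optimizer and the checkpoint writer consume.

rd_rng_normal <- function(n, sd) stats::rnorm(n, 0, sd)

#' @keywords internal
new_conv <- function(c1, c2, k = 1L, stride = 1L, pad = NULL, groups = 1L,
                     bn = TRUE, act = TRUE, bias = !bn) {
  if (is.null(pad)) pad <- k %/% 2L
  cin_g <- c1 %/% groups
  fan_in <- cin_g * k * k
  w <- array(rd_rng_normal(k * k * cin_g * c2, sqrt(2 / fan_in)),
             dim = c(k, k, cin_g, c2))
  ly <- list(
    type = "conv", c1 = c1, c2 = c2, k = as.integer(k),
    stride = as.integer(stride), pad = as.integer(pad),
    groups = as.integer(groups), bn = bn, act = act,
    w = new_param(w),
    b = if (bias) new_param(numeric(c2)) else NULL
  )
  if (bn) {
    ly$gamma <- new_param(rep(1, c2))
    ly$beta <- new_param(numeric(c2))
    ly$bn_momentum <- 0.1
    ly$bn_env <- new.env(parent = emptyenv())
    ly$bn_env$rmean <- numeric(c2)
    ly$bn_env$rvar <- rep(1, c2)
  }
  class(ly) <- "rd_layer"
  ly
}

fwd_conv <- function(tp, x, ly, training = FALSE) {
  w <- ly$w$value
  xv <- tpf(tp, x)
  st <- ly$stride; pd <- ly$pad; gr <- ly$groups
  wp <- ly$w
  if (ly$bn) {
    # fused conv + batch-norm (+ SiLU) kernel
    gm <- ly$gamma; bt <- ly$beta
    if (training) {
      r <- cpp_cbs_fwd(xv, w, st, pd, gr, gm$value, bt$value, 1e-5,
                       ly$act)
      # update running statistics (side effect, not part of the graph)
      m <- ly$bn_momentum
      n_eff <- prod(dim(r$y)[c(1, 2, 4)])
      ube <- if (n_eff > 1) n_eff / (n_eff - 1) else 1
      ly$bn_env$rmean <- (1 - m) * ly$bn_env$rmean + m * r$mean
      ly$bn_env$rvar <- (1 - m) * ly$bn_env$rvar + m * r$var * ube
      xhat <- r$xhat; vv <- r$var; z <- r$z
      act <- ly$act
      return(tp_node(tp, r$y, x, function(g) {
        rb <- cpp_cbs_bwd(xv, w, g, xhat, z, gm$value, vv, 1e-5, st, pd,
                          gr, act)
        acc_grad(wp, rb$dw)
        acc_grad(gm, rb$dgamma)
        acc_grad(bt, rb$dbeta)
        list(rb$dx)
      }))
    }
    scale <- gm$value / sqrt(ly$bn_env$rvar + 1e-5)
    shift <- bt$value - ly$bn_env$rmean * scale
    return(tp_node(tp, cpp_cbs_eval(xv, w, st, pd, gr, scale, shift,
                                    ly$act), x, NULL))
  }
  b <- if (!is.null(ly$b)) ly$b$value else NULL
  has_b <- !is.null(ly$b)
  bp <- ly$b
  out <- tp_node(tp, cpp_conv2d_fwd(xv, w, b, st, pd, gr), x, function(g) {
    r <- cpp_conv2d_bwd(xv, w, g, st, pd, gr, has_b)
    acc_grad(wp, r$dw)
    if (has_b) acc_grad(bp, r$db)
    list(r$dx)
  })
  if (ly$act) out <- op_silu(tp, out)
  out
}

is_param <- function(x) is.environment(x) && !is.null(x$value)

#' Collect parameter environments from a nested layer structure
#' @keywords internal
layer_params <- function(x, prefix = "") {
  out <- list()
  if (is_param(x)) {
    out[[prefix]] <- x
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      el <- x[[i]]
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      if (is_param(el) || is.list(el)) {
        sub <- layer_params(el, paste0(prefix, if (nzchar(prefix)) ".", nm))
        out <- c(out, sub)
      }
    }
  }
  out
}

# BN running-stat environments, for checkpointing
layer_bn_envs <- function(x, prefix = "") {
  out <- list()
  if (is.list(x)) {
    if (identical(x$type, "conv") && isTRUE(x$bn)) {
      out[[paste0(prefix, ".bn")]] <- x$bn_env
    }
    nms <- names(x)
    for (i in seq_along(x)) {
      el <- x[[i]]
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      if (is.list(el)) {
        out <- c(out, layer_bn_envs(el, paste0(prefix,
                                               if (nzchar(prefix)) ".", nm)))
      }
    }
  }
  out
}

# SGD with momentum and decoupled-style weight decay on conv weights only
sgd_step <- function(params, lr, momentum = 0.937, weight_decay = 0) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad
    decay <- weight_decay > 0 && grepl("\\.w$|^w$", nm)
    if (decay) g <- g + weight_decay * p$value
    if (is.null(p$mom)) p$mom <- g * 0
    p$mom <- momentum * p$mom + g
    p$value <- p$value - lr * p$mom
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) param_zero_grad(p)
  invisible(NULL)
}
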