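# Multi-scale dilated attention (MSDA) and its per-head primitive, the
# sliding-window dilated attention (SWDA).
#
# Feature maps are numeric arrays with dim (H, W, C, N): spatial rows,
# spatial columns, channels, batch.  SWDA attends from every query position
# to a kernel x kernel window of keys/values spaced `rate` pixels apart;
# neighbours falling outside the image are masked out of the softmax, so
# every output position is a convex combination of in-bounds value vectors.

#' Attention configuration for multi-scale dilated attention
#'
#' @param num_heads number of attention heads; must be a multiple of
#'   `length(rates)` so heads can be assigned to dilation rates round-robin.
#' @param rates ordered dilation rates, one receptive-field scale per group
#'   of heads.  The default `c(1, 2, 3, 4)` spans 3x3 to 9x9 windows for a
#'   3-point kernel.
#' @param kernel odd window size (points per axis).
#' @param head_dim channels per head (set when the host block knows its
#'   width; may be `NULL` at construction).
#' @param scale attention logit scale; defaults to `1/sqrt(head_dim)`.
#' @return an object of class `attention_config`
#' @export
attention_config <- function(num_heads = 4L, rates = c(1L, 2L, 3L, 4L),
                             kernel = 3L, head_dim = NULL, scale = NULL) {
  num_heads <- as.integer(num_heads)
  rates <- as.integer(rates)
  kernel <- as.integer(kernel)
  if (num_heads < 1L) stop("num_heads must be positive", call. = FALSE)
  if (any(rates < 1L)) stop("dilation rates must be >= 1", call. = FALSE)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("kernel must be an odd positive integer", call. = FALSE)
  if (num_heads %% length(rates) != 0L)
    stop("num_heads must be a multiple of length(rates)", call. = FALSE)
  if (!is.null(head_dim)) {
    head_dim <- as.integer(head_dim)
    if (head_dim < 1L) stop("head_dim must be positive", call. = FALSE)
  }
  if (is.null(scale) && !is.null(head_dim)) scale <- 1 / sqrt(head_dim)
  structure(list(num_heads = num_heads, rates = rates, kernel = kernel,
                 head_dim = head_dim, scale = scale),
            class = "attention_config")
}

#' Side length of the dilated attention window
#'
#' For a `kernel`-point window dilated at `rate`, the attended positions
#' span a square of side `(kernel - 1) * rate + 1` pixels.
#'
#' @param kernel odd positive window size
#' @param rate positive dilation rate
#' @return integer side length of the bounding square
#' @examples
#' effective_extent(3, 1) # 3
#' effective_extent(3, 4) # 9
#' @export
effective_extent <- function(kernel, rate) {
  if (any(kernel < 1) || any(kernel %% 2 == 0))
    stop("kernel must be an odd positive integer", call. = FALSE)
  if (any(rate < 1)) stop("rate must be >= 1", call. = FALSE)
  as.integer((kernel - 1) * rate + 1)
}

#' Sliding-window dilated attention on a projected triple
#'
#' Single-rate attention: at each position the query attends to the
#' `kernel x kernel` neighbourhood of keys spaced `rate` apart;
#' out-of-bounds neighbours are excluded from the softmax.
#'
#' @param query,key,value numeric arrays of identical dim (H, W, C, N)
#' @param rate positive dilation rate
#' @param kernel odd window size
#' @param scale logit scale (default `1/sqrt(C)`)
#' @param head_dim channels per head; the channel axis is processed in
#'   contiguous slices of this width (default: all channels, one head)
#' @return array of the same dim as `value`
#' @export
swda <- function(query, key, value, rate, kernel = 3L, scale = NULL,
                 head_dim = NULL) {
  d <- dim(query)
  if (is.null(d) || length(d) != 4)
    stop("query must be a 4-d (H, W, C, N) array", call. = FALSE)
  if (!identical(dim(key), d) || !identical(dim(value), d))
    stop("query, key and value must share one shape", call. = FALSE)
  if (kernel %% 2 == 0 || kernel < 1 || rate < 1)
    stop("invalid kernel/rate", call. = FALSE)
  if (is.null(head_dim)) head_dim <- d[3]
  if (d[3] %% head_dim != 0)
    stop("channels not divisible by head_dim", call. = FALSE)
  if (is.null(scale)) scale <- 1 / sqrt(head_dim)
  cpp_swda_fwd(query, key, value, as.integer(rate), as.integer(kernel),
               scale, as.integer(head_dim))
}

#' Create an MSDA block
#'
#' Q, K, V are produced by one 1x1 convolution each (bias, no
#' normalisation); head `h` runs SWDA at `rates[(h - 1) %% length(rates) + 1]`;
#' head outputs are concatenated in input order and mixed by an output 1x1
#' convolution.
#'
#' @param channels input (= output) channel count; must be divisible by
#'   `cfg$num_heads`
#' @param cfg an [attention_config()]
#' @return an `rd_msda` module
#' @export
new_msda <- function(channels, cfg = attention_config()) {
  channels <- as.integer(channels)
  if (channels %% cfg$num_heads != 0L)
    stop("channels (", channels, ") not divisible by num_heads (",
         cfg$num_heads, ")", call. = FALSE)
  head_dim <- channels %/% cfg$num_heads
  if (is.null(cfg$scale)) cfg$scale <- 1 / sqrt(head_dim)
  cfg$head_dim <- head_dim
  m <- list(
    type = "msda", channels = channels, cfg = cfg,
    q = new_conv(channels, channels, 1L, bn = FALSE, act = FALSE, bias = TRUE),
    k = new_conv(channels, channels, 1L, bn = FALSE, act = FALSE, bias = TRUE),
    v = new_conv(channels, channels, 1L, bn = FALSE, act = FALSE, bias = TRUE),
    proj = new_conv(channels, channels, 1L, bn = FALSE, act = FALSE,
                    bias = TRUE)
  )
  class(m) <- "rd_msda"
  m
}

fwd_msda <- function(tp, x, m, training = FALSE) {
  cfg <- m$cfg
  q <- fwd_conv(tp, x, m$q, training)
  k <- fwd_conv(tp, x, m$k, training)
  v <- fwd_conv(tp, x, m$v, training)
  hd <- cfg$head_dim
  heads <- vector("list", cfg$num_heads)
  for (h in seq_len(cfg$num_heads)) {
    rate <- cfg$rates[(h - 1L) %% length(cfg$rates) + 1L]
    c0 <- (h - 1L) * hd + 1L
    c1 <- h * hd
    qs <- op_slice_c(tp, q, c0, c1)
    ks <- op_slice_c(tp, k, c0, c1)
    vs <- op_slice_c(tp, v, c0, c1)
    heads[[h]] <- op_swda(tp, qs, ks, vs, rate, cfg$kernel, cfg$scale, hd)
  }
  cat_h <- op_concat_c(tp, unlist(heads))
  fwd_conv(tp, cat_h, m$proj, training)
}

#' Run a multi-scale dilated attention forward pass
#'
#' @param x numeric array (H, W, C, N) with `C` divisible by
#'   `cfg$num_heads`
#' @param cfg an [attention_config()]
#' @param module optionally, an existing [new_msda()] module (so projection
#'   weights are reused); built fresh when `NULL`
#' @return array of the same shape as `x`
#' @export
msda_forward <- function(x, cfg = attention_config(), module = NULL) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4)
    stop("x must be a 4-d (H, W, C, N) array", call. = FALSE)
  if (d[3] %% cfg$num_heads != 0)
    stop("channels not divisible by num_heads", call. = FALSE)
  if (is.null(module)) module <- new_msda(d[3], cfg)
  tp <- new_tape()
  xid <- op_input(tp, x)
  tp_value(tp, fwd_msda(tp, xid, module, training = FALSE))
}
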