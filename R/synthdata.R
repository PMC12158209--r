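# Seedable generator of synthetic benthic scenes.
#
# Scenes emulate the detectability structure of shallow-water benthic
# imagery: four organism classes with long-tailed frequencies drawn as
# class-distinct parametric shapes (elongated ellipse ~ holothurian,
# spiky disk ~ echinus, ridged fan ~ scallop, five-armed star ~ starfish)
# on a textured blue-green background, with optional overlap/occlusion,
# red-channel attenuation (underwater colour cast) and Gaussian blur.
# Labels are YOLO-format normalised (class cx cy w h) axis-aligned hulls
# of the drawn (pre-occlusion) shapes.

#' Scene generator specification
#'
#' @param image_size `(H, W)`, both divisible by 32
#' @param classes ordered class names
#' @param class_probs sampling probabilities (simplex); the default is
#'   long-tailed and echinus-dominant
#' @param n_objects inclusive integer range of objects per scene
#' @param size_range object side as a fraction of the shorter image side
#' @param occlusion_prob probability a new object is placed to overlap an
#'   existing one (box IoU >= 0.3)
#' @param color_cast multiplicative red-channel attenuation in (0, 1]
#' @param blur_sigma Gaussian blur standard deviation (pixels)
#' @param seed integer seed; scene `index` streams are derived from it
#' @return a `scene_spec`
#' @export
scene_spec <- function(image_size = c(160L, 160L),
                       classes = c("holothurian", "echinus", "scallop",
                                   "starfish"),
                       class_probs = c(0.10, 0.62, 0.08, 0.20),
                       n_objects = c(1L, 12L),
                       size_range = c(0.05, 0.35),
                       occlusion_prob = 0.3,
                       color_cast = 0.45,
                       blur_sigma = 1.0,
                       seed = 0L) {
  if (any(image_size %% 32L != 0L))
    stop("image_size must be divisible by 32", call. = FALSE)
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("class_probs must sum to 1", call. = FALSE)
  if (length(class_probs) != length(classes))
    stop("class_probs length must match classes", call. = FALSE)
  if (size_range[1] <= 0 || size_range[2] > 1 ||
      size_range[2] * min(image_size) < 3)
    stop("size_range incompatible with image_size", call. = FALSE)
  if (occlusion_prob < 0 || occlusion_prob > 1)
    stop("occlusion_prob must lie in [0, 1]", call. = FALSE)
  if (blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  structure(list(image_size = as.integer(image_size), classes = classes,
                 class_probs = class_probs,
                 n_objects = as.integer(n_objects),
                 size_range = size_range, occlusion_prob = occlusion_prob,
                 color_cast = color_cast, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# run fn under a derived deterministic RNG stream, restoring global state
with_scene_rng <- function(seed, index, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.numeric(seed) * 1000003 + as.numeric(index)) %% 2147483629)
  fn()
}

gaussian_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - r):min(n, i + r)
    w <- exp(-((j - i)^2) / (2 * sigma^2))
    K[i, j] <- w / sum(w)
  }
  K
}

# shape mask on the full image grid; returns logical H x W
shape_mask <- function(H, W, class_id, cx, cy, size, theta) {
  R <- size / 2
  x <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - cx
  y <- matrix(rep(seq_len(H) - 0.5, times = W), H, W) - cy
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  rad <- sqrt(xr^2 + yr^2)
  phi <- atan2(yr, xr)
  switch(class_id,
    # holothurian: elongated ellipse, aspect ~ 2.8
    (xr / R)^2 + (yr / (R / 2.8))^2 <= 1,
    # echinus: spiky disk
    rad <= R * (0.72 + 0.28 * cos(18 * phi)),
    # scallop: fan (half-disk wedge)
    rad <= R & abs(phi) <= 100 * pi / 180,
    # starfish: five-armed star
    rad <= R * (0.55 + 0.45 * cos(5 * phi))
  )
}

shape_color <- function(class_id) {
  base <- switch(class_id,
                 c(0.48, 0.36, 0.24),   # holothurian: brown
                 c(0.13, 0.10, 0.16),   # echinus: dark purple
                 c(0.78, 0.68, 0.55),   # scallop: light tan
                 c(0.85, 0.45, 0.18))   # starfish: orange
  pmin(pmax(base + stats::rnorm(3, 0, 0.04), 0), 1)
}

box_from_mask <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  c(x1 = min(w[, 2]) - 1, y1 = min(w[, 1]) - 1,
    x2 = max(w[, 2]), y2 = max(w[, 1]))
}

iou_xyxy <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (un <= 0) 0 else inter / un
}

#' Generate one labelled synthetic scene
#'
#' Deterministic given `(spec$seed, index)`.
#'
#' @param spec a [scene_spec()]
#' @param index scene index within the seed stream
#' @return a `labeled_scene`: `image` (H, W, 3 integer array, 0..255) and
#'   `boxes` data.frame (`class` 0-based id, `cx`, `cy`, `w`, `h`
#'   normalised)
#' @export
generate_scene <- function(spec, index = 1L) {
  with_scene_rng(spec$seed, index, function() {
    H <- spec$image_size[1]; W <- spec$image_size[2]
    img <- array(0, dim = c(H, W, 3))
    base <- c(0.16, 0.42, 0.46) + stats::rnorm(3, 0, 0.03)
    xg <- matrix(rep(seq_len(W), each = H), H, W) / W
    yg <- matrix(rep(seq_len(H), times = W), H, W) / H
    for (ch in 1:3) {
      tex <- 0
      for (k in 1:3) {
        tex <- tex + stats::runif(1, 0.015, 0.05) *
          cos(2 * pi * (stats::runif(1, 0.5, 3) * xg +
                          stats::runif(1, 0.5, 3) * yg +
                          stats::runif(1)))
      }
      img[, , ch] <- base[ch] + tex +
        stats::rnorm(H * W, 0, 0.015)
    }
    n_obj <- if (spec$n_objects[1] >= spec$n_objects[2]) spec$n_objects[1]
             else sample(spec$n_objects[1]:spec$n_objects[2], 1)
    boxes <- NULL
    placed <- list()
    if (n_obj > 0) {
      for (o in seq_len(n_obj)) {
        cls <- sample(length(spec$classes), 1, prob = spec$class_probs)
        size <- stats::runif(1, spec$size_range[1], spec$size_range[2]) *
          min(H, W)
        half <- size / 2 + 1
        occlude <- length(placed) > 0 && stats::runif(1) < spec$occlusion_prob
        ok <- FALSE
        for (try in 1:30) {
          if (occlude) {
            ref <- placed[[sample(length(placed), 1)]]
            cx <- stats::runif(1, ref$box[1], ref$box[3])
            cy <- stats::runif(1, ref$box[2], ref$box[4])
          } else {
            cx <- stats::runif(1, half, W - half)
            cy <- stats::runif(1, half, H - half)
          }
          if (cx < half || cx > W - half || cy < half || cy > H - half)
            next
          if (occlude) {
            cand <- c(cx - half, cy - half, cx + half, cy + half)
            if (iou_xyxy(cand, ref$box) < 0.3) next
          }
          ok <- TRUE
          break
        }
        if (!ok) next
        theta <- stats::runif(1, 0, pi)
        mask <- shape_mask(H, W, cls, cx, cy, size, theta)
        if (!any(mask)) next
        col <- shape_color(cls)
        shade <- 1 + 0.25 * (matrix(rep(seq_len(W), each = H), H, W) - cx) /
          max(size, 1)
        for (ch in 1:3) {
          layer <- img[, , ch]
          layer[mask] <- (col[ch] * shade)[mask]
          img[, , ch] <- layer
        }
        bx <- box_from_mask(mask)
        placed[[length(placed) + 1]] <- list(box = bx)
        boxes <- rbind(boxes, data.frame(
          class = cls - 1L,
          cx = (bx[1] + bx[3]) / 2 / W, cy = (bx[2] + bx[4]) / 2 / H,
          w = (bx[3] - bx[1]) / W, h = (bx[4] - bx[2]) / H))
      }
    }
    img[, , 1] <- img[, , 1] * spec$color_cast
    if (spec$blur_sigma > 0) {
      Kh <- gaussian_band(H, spec$blur_sigma)
      Kw <- gaussian_band(W, spec$blur_sigma)
      for (ch in 1:3) img[, , ch] <- Kh %*% img[, , ch] %*% t(Kw)
    }
    img <- pmin(pmax(img, 0), 1)
    storage <- array(as.integer(round(img * 255)), dim = c(H, W, 3))
    if (is.null(boxes)) boxes <- data.frame(class = integer(0),
                                            cx = numeric(0), cy = numeric(0),
                                            w = numeric(0), h = numeric(0))
    rownames(boxes) <- NULL
    structure(list(image = storage, boxes = boxes,
                   classes = spec$classes),
              class = "labeled_scene")
  })
}

#' Add signal-dependent Poisson noise
#'
#' Each pixel is replaced by a Poisson draw with mean `pixel * scale`,
#' divided by `scale` and clipped to 0..255; smaller `scale` means
#' stronger noise (`scale = 1` is the natural photon-counting level).
#'
#' @param image integer array, 0..255
#' @param scale positive noise scale
#' @return noisy image, same shape, 0..255 integers
#' @export
add_poisson_noise <- function(image, scale) {
  if (!is.finite(scale) || scale <= 0)
    stop("scale must be > 0", call. = FALSE)
  lam <- as.numeric(image) * scale
  out <- stats::rpois(length(lam), lam) / scale
  array(as.integer(pmin(pmax(round(out), 0), 255)), dim = dim(image))
}

#' Add Gaussian sensor noise
#'
#' Adds independent zero-mean normal noise with standard deviation
#' `sigma` (8-bit intensity units) and clips to 0..255.
#'
#' @param image integer array, 0..255
#' @param sigma noise standard deviation, `>= 0`
#' @return noisy image
#' @export
add_gaussian_noise <- function(image, sigma) {
  if (!is.finite(sigma) || sigma < 0)
    stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(image)
  out <- as.numeric(image) + stats::rnorm(length(image), 0, sigma)
  array(as.integer(pmin(pmax(round(out), 0), 255)), dim = dim(image))
}

#' Write / read YOLO-format labels
#'
#' One `class cx cy w h` line per box, normalised coordinates printed
#' with six decimals.
#'
#' @param boxes data.frame with `class`, `cx`, `cy`, `w`, `h`
#' @param path output file
#' @return (read) the boxes data.frame
#' @export
write_yolo_labels <- function(boxes, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class, boxes$cx,
                   boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_labels
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  parts <- strsplit(trimws(lines), "\\s+")
  for (i in seq_along(parts)) {
    p <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(p) != 5 || any(is.na(p)))
      stop(sprintf("malformed label line %d in %s", i, path), call. = FALSE)
  }
  m <- do.call(rbind, lapply(parts, as.numeric))
  data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' Shuffled train/val/test split
#'
#' Floor allocation to train and validation; the remainder is the test
#' set.  Deterministic given `seed`.
#'
#' @param n_items number of items, `>= 3`
#' @param ratios split ratios (train, val, test)
#' @param seed integer seed
#' @return list of disjoint, exhaustive index vectors `train`, `val`,
#'   `test`
#' @export
split_dataset <- function(n_items, ratios = c(0.7, 0.2, 0.1), seed = 0L) {
  if (n_items < 3) stop("need at least 3 items", call. = FALSE)
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1",
                                        call. = FALSE)
  with_scene_rng(seed, 777L, function() {
    ord <- sample(n_items)
    n_tr <- floor(ratios[1] * n_items)
    n_va <- floor(ratios[2] * n_items)
    list(train = sort(ord[seq_len(n_tr)]),
         val = sort(ord[n_tr + seq_len(n_va)]),
         test = sort(ord[(n_tr + n_va + 1):n_items]))
  })
}

#' Generate a dataset directory in YOLO layout
#'
#' Writes `images/{split}/scene_XXXX.png`, `labels/{split}/scene_XXXX.txt`
#' and a `dataset.yaml` naming classes and splits.
#'
#' @param spec a [scene_spec()]
#' @param n number of scenes
#' @param dir output directory
#' @param ratios split ratios
#' @return invisibly, the split index list
#' @export
generate_dataset <- function(spec, n, dir, ratios = c(0.7, 0.2, 0.1)) {
  splits <- split_dataset(n, ratios, spec$seed)
  for (s in names(splits)) {
    dir.create(file.path(dir, "images", s), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "labels", s), recursive = TRUE,
               showWarnings = FALSE)
    for (i in splits[[s]]) {
      sc <- generate_scene(spec, i)
      nm <- sprintf("scene_%04d", i)
      png::writePNG(sc$image / 255,
                    file.path(dir, "images", s, paste0(nm, ".png")))
      write_yolo_labels(sc$boxes,
                        file.path(dir, "labels", s, paste0(nm, ".txt")))
    }
  }
  yaml::write_yaml(list(classes = spec$classes,
                        splits = lapply(splits, as.integer),
                        image_size = as.integer(spec$image_size)),
                   file.path(dir, "dataset.yaml"))
  invisible(splits)
}
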