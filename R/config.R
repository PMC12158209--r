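# Run configuration: defaults, YAML merging and validation.

rd_default_config <- function() {
  list(
    lr0 = 0.01,
    momentum = 0.937,
    weight_decay = 0.0005,
    batch_size = 16L,
    optimizer = "sgd",
    image_size = 640L,
    epochs = 200L,
    patience = 20L,
    eval_every = 1L,
    seed = 0L,
    model = list(variant = "mas", num_classes = 4L,
                 width_multiple = 0.25, depth_multiple = 0.5,
                 reg_max = 16L),
    attention = list(num_heads = 4L, rates = c(1L, 2L, 3L, 4L),
                     kernel = 3L),
    head = list(compression = 8L, reg_max = 16L),
    loss = list(cls = 0.5, box = 7.5, dfl = 1.5,
                slide = list(enabled = TRUE, init_mu = 0.5)),
    nms = list(iou = 0.7, score = 0.25),
    paths = list(data = "", out = "")
  )
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop("unknown config key '", full, "'; valid keys here: ",
           paste(names(base), collapse = ", "), call. = FALSE)
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], override[[k]], full)
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Precedence: built-in defaults, then the YAML file, then explicit
#' overrides.  Unknown keys raise an error naming the valid keys.
#'
#' @param path optional YAML file
#' @param overrides optional named list applied last (highest precedence)
#' @return a validated `run_config` list
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- rd_default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    f <- yaml::read_yaml(path)
    if (length(f)) cfg <- merge_config(cfg, f)
  }
  if (!is.null(overrides) && length(overrides))
    cfg <- merge_config(cfg, overrides)
  if (cfg$patience > cfg$epochs) cfg$patience <- cfg$epochs
  if (!identical(cfg$optimizer, "sgd"))
    stop("only the sgd optimizer is supported", call. = FALSE)
  if (cfg$image_size %% 32 != 0)
    stop("image_size must be divisible by 32", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration to YAML
#'
#' @param cfg a `run_config`
#' @param path output path
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

run_model_config <- function(cfg) {
  model_config(variant = cfg$model$variant,
               num_classes = cfg$model$num_classes,
               width_multiple = cfg$model$width_multiple,
               depth_multiple = cfg$model$depth_multiple,
               reg_max = cfg$model$reg_max,
               attention = attention_config(
                 num_heads = cfg$attention$num_heads,
                 rates = cfg$attention$rates,
                 kernel = cfg$attention$kernel))
}
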