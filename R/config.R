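# Run configuration: one nested defaults tree carrying every tunable with
# its documented default, merged with an optional YAML file and explicit
# overrides (defaults < file < flags), with unknown keys rejected.

#' Package defaults
#'
#' The complete defaults tree: preprocessing (target width 1024 px,
#' histogram equalization on, 256 gray levels), detector (tiny backbone,
#' output stride R = 4, size prediction off, score threshold 0.3, at most
#' 2000 detections), loss weights (lambda_off = 1, lambda_size = 0.1,
#' lambda_d = 0.1, lambda_r = 0.01, focal alpha = 2, beta = 4, sparse
#' thresholds tau1 = 0.7, tau2 = 0.5), training (Adam lr 1.25e-4,
#' exemplar of 200 annotations per dataset, exemplar mix 0.5), evaluation
#' (IoU threshold 0.5) and fiber tracing (candidate radius r = 100 px at
#' width-1024 scale, smoothing threshold 0.1 rad).
#'
#' @return Nested named list.
#' @export
cp_defaults <- function() {
  list(
    seed = 1L,
    log_level = "info",
    preprocess = list(target_width = 1024L, equalize = TRUE,
                      quantize_levels = 256L),
    detector = list(backbone = "tiny", stride = 4L, predict_size = FALSE,
                    head_channels = 32L, score_threshold = 0.3,
                    max_detections = 2000L),
    loss = list(lambda_off = 1, lambda_size = 0.1, lambda_d = 0.1,
                lambda_r = 0.01, alpha = 2, beta = 4, tau1 = 0.7,
                tau2 = 0.5, sparse_mode = FALSE),
    train = list(epochs = 1L, batch_size = 4L, learning_rate = 1.25e-4,
                 exemplar_n = 200L, exemplar_mix = 0.5,
                 augment_flip = TRUE, augment_crop = FALSE),
    eval = list(iou_threshold = 0.5),
    trace = list(r = 100, ang = 0.4, smooth_threshold = 0.1)
  )
}

merge_config <- function(base, upd, path = "") {
  for (k in names(upd)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop("unknown config key: ", full)
    if (is.list(base[[k]]) && is.list(upd[[k]]))
      base[[k]] <- merge_config(base[[k]], upd[[k]], full)
    else
      base[[k]] <- upd[[k]]
  }
  base
}

#' Resolve a run configuration
#'
#' Precedence: package defaults < YAML config file < explicit flags.
#' Unknown keys at any level are an error naming the key.
#'
#' @param file Optional YAML config file.
#' @param flags Optional named (possibly nested) list of overrides.
#' @return A `run_config` (nested list); `print()` dumps every resolved
#'   key=value line.
#' @export
resolve_config <- function(file = NULL, flags = list()) {
  cfg <- cp_defaults()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    cfg <- merge_config(cfg, yaml::read_yaml(file))
  }
  if (length(flags)) cfg <- merge_config(cfg, flags)
  structure(cfg, class = "run_config")
}

#' Flatten a configuration to key=value lines
#' @param cfg A `run_config` or nested list.
#' @return Character vector `"a.b=value"`.
#' @export
config_flatten <- function(cfg) {
  out <- character(0)
  walk <- function(x, path) {
    for (k in names(x)) {
      full <- if (nzchar(path)) paste0(path, ".", k) else k
      if (is.list(x[[k]])) walk(x[[k]], full)
      else out <<- c(out, paste0(full, "=",
                                 format(x[[k]], scientific = FALSE)))
    }
  }
  walk(unclass(cfg), "")
  out
}

#' @export
print.run_config <- function(x, ...) {
  writeLines(config_flatten(x))
  invisible(x)
}
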