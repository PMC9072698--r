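# Model checkpoints: a single binary file of little-endian doubles (the
# flat parameter vector theta) plus a JSON sidecar manifest carrying the
# detector configuration, the architecture fingerprint and the exemplar
# manifest.  Loading rebuilds the architecture from the manifest and
# refuses any fingerprint mismatch — never a silent partial load.

#' Save a detector checkpoint
#'
#' Writes `path` (binary parameter vector) and `path.json` (manifest).
#' A checkpoint produced after a continual step contains the single-path
#' branch-B parameters only; the frozen reference branch is never stored.
#'
#' @param model A `model_state`.
#' @param path Checkpoint file.
#' @return `path`, invisibly.
#' @export
save_model_state <- function(model, path) {
  stopifnot(inherits(model, "model_state"))
  theta <- model_parameters(model)
  con <- file(path, "wb")
  writeBin(theta, con, size = 8, endian = "little")
  close(con)
  manifest <- list(config = unclass(model$config),
                   fingerprint = model_fingerprint(model),
                   exemplar_manifest = model$exemplar_manifest)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Load a detector checkpoint
#'
#' @param path Checkpoint file written by [save_model_state()].
#' @param expected_config Optional [detector_config()]; loading fails if
#'   the checkpoint's architecture differs.
#' @return A `model_state` whose forward pass reproduces the saved model
#'   bitwise.
#' @export
load_model_state <- function(path, expected_config = NULL) {
  if (!file.exists(path) || !file.exists(paste0(path, ".json")))
    stop("checkpoint or its .json manifest missing: ", path)
  manifest <- jsonlite::read_json(paste0(path, ".json"),
                                  simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  cfg <- manifest$config
  config <- detector_config(backbone = cfg$backbone, stride = cfg$stride,
                            predict_size = cfg$predict_size,
                            head_channels = cfg$head_channels,
                            trunk_channels = cfg$trunk_channels,
                            alpha = cfg$alpha, beta = cfg$beta,
                            score_threshold = cfg$score_threshold,
                            max_detections = cfg$max_detections,
                            default_radius = cfg$default_radius)
  if (!is.null(expected_config)) {
    keys <- c("backbone", "stride", "predict_size", "head_channels",
              "trunk_channels")
    for (k in keys)
      if (!identical(unname(unlist(expected_config[[k]])),
                     unname(unlist(config[[k]]))))
        stop("checkpoint incompatible with expected config: field ", k)
  }
  model <- new_detector(config, seed = 0L)
  n <- length(model_parameters(model))
  if (!identical(as.integer(manifest$fingerprint$n_params), as.integer(n)))
    stop("checkpoint fingerprint mismatch: parameter count differs")
  sz <- file.info(path)$size
  if (sz != 8 * n)
    stop("checkpoint incompatible: expected ", n, " parameters, file has ",
         sz / 8)
  con <- file(path, "rb")
  theta <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  close(con)
  model <- model_set_parameters(model, theta)
  em <- manifest$exemplar_manifest
  model$exemplar_manifest <- if (is.null(em) || length(em) == 0) list()
    else em
  model
}
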