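# Micrograph standardization: down-sample to a fixed width of 1024 px
# (aspect-preserving, local-mean kernel), histogram-equalize, quantize to
# 8-bit (256 gray levels).  Picking is tolerant to the resulting centering
# error of a few original pixels, and the reduced size dominates the
# speed of both training and inference.

#' Preprocessing configuration
#'
#' @param target_width Output width in px (default 1024, minimum 64).
#' @param equalize Apply global 256-bin histogram equalization.
#' @param quantize_levels Gray levels of the output (only 256 supported).
#' @param allow_upscale Permit inputs narrower than `target_width`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_width = 1024L, equalize = TRUE,
                              quantize_levels = 256L,
                              allow_upscale = FALSE) {
  if (target_width < 64) stop("target_width must be >= 64")
  if (quantize_levels != 256L)
    stop("only quantize_levels = 256 is supported")
  structure(list(target_width = as.integer(target_width),
                 equalize = isTRUE(equalize),
                 quantize_levels = as.integer(quantize_levels),
                 allow_upscale = isTRUE(allow_upscale)),
            class = "preprocess_config")
}

# 1-D area (local-mean) resampling: each output sample is the exact mean
# of the piecewise-constant input over its footprint, computed from the
# cumulative integral.  Exact box-averaging for integer ratios.
area_resample_1d <- function(v, n_out) {
  n_in <- length(v)
  if (n_out == n_in) return(v)
  s <- n_in / n_out
  cs <- c(0, cumsum(v))
  integral_to <- function(t) {
    i <- pmin(floor(t), n_in - 1e-9)
    fi <- floor(i)
    cs[fi + 1] + (t - fi) * v[pmin(fi + 1, n_in)]
  }
  a <- (seq_len(n_out) - 1) * s
  b <- a + s
  (integral_to(b) - integral_to(a)) / s
}

# separable: rows then columns
area_resample <- function(px, out_h, out_w) {
  h_in <- nrow(px)
  tmp <- matrix(0, nrow = h_in, ncol = out_w)
  for (i in seq_len(h_in)) tmp[i, ] <- area_resample_1d(px[i, ], out_w)
  out <- matrix(0, nrow = out_h, ncol = out_w)
  for (j in seq_len(out_w)) out[, j] <- area_resample_1d(tmp[, j], out_h)
  out
}

# Global histogram equalization on 256 bins, output integers 0..255.
hist_equalize_256 <- function(px) {
  rng <- range(px)
  if (rng[2] == rng[1]) return(matrix(0L, nrow(px), ncol(px)))
  bins <- pmin(floor((px - rng[1]) / (rng[2] - rng[1]) * 256), 255)
  cnt <- tabulate(as.vector(bins) + 1L, nbins = 256L)
  cdf <- cumsum(cnt) / length(px)
  cdf_min <- cdf[which(cnt > 0)[1]]
  lut <- round((cdf - cdf_min) / (1 - cdf_min + 1e-12) * 255)
  out <- matrix(lut[bins + 1L], nrow(px), ncol(px))
  pmin(pmax(out, 0), 255)
}

#' Standardize a micrograph for detection and training
#'
#' Down-samples to `target_width` (aspect-preserving height
#' `round(H * target_width / W)`, local-mean kernel), then histogram-
#' equalizes and quantizes to 256 integer gray levels.  The scale factor
#' original-px / preprocessed-px is recorded on the result.
#'
#' @param m A [micrograph] (raw, `preprocess_scale = 1`, or already at the
#'   target width).
#' @param config A [preprocess_config()].
#' @return A standardized [micrograph]; values are integers in
#'   \[0, 255\] and `preprocess_scale = W_original / target_width`.
#' @export
standardize <- function(m, config = preprocess_config()) {
  stopifnot(inherits(m, "micrograph"))
  W <- ncol(m$pixels); H <- nrow(m$pixels)
  tw <- config$target_width
  if (W < tw && !config$allow_upscale)
    stop(sprintf("input width %d < target %d: refusing to upscale (set allow_upscale)",
                 W, tw))
  scale <- W / tw
  th <- max(1L, as.integer(round(H * tw / W)))
  px <- if (W == tw && th == H) m$pixels else
    area_resample(m$pixels, th, tw)
  px <- if (config$equalize) hist_equalize_256(px) else {
    rng <- range(px)
    if (rng[2] == rng[1]) matrix(0, th, tw) else
      round((px - rng[1]) / (rng[2] - rng[1]) * 255)
  }
  micrograph(px, pixel_size = if (is.na(m$pixel_size)) NA_real_ else
               m$pixel_size * scale,
             source_path = m$source_path,
             preprocess_scale = m$preprocess_scale * scale)
}

#' Map annotation coordinates between original and preprocessed space
#'
#' @param ann An [annotation_set].
#' @param scale Original-px per preprocessed-px (the micrograph's
#'   `preprocess_scale`).
#' @param direction `"to_preprocessed"` (divide by scale) or
#'   `"to_original"` (multiply).
#' @return The mapped [annotation_set] with its `coordinate_space` updated.
#' @export
map_coordinates <- function(ann, scale,
                            direction = c("to_preprocessed",
                                          "to_original")) {
  direction <- match.arg(direction)
  stopifnot(inherits(ann, "annotation_set"), scale > 0)
  want_from <- if (direction == "to_preprocessed") "original" else
    "preprocessed"
  if (ann$coordinate_space != want_from)
    stop(sprintf("annotations are already in %s space", ann$coordinate_space))
  f <- if (direction == "to_preprocessed") 1 / scale else scale
  for (col in c("x", "y", "w", "h"))
    ann$records[[col]] <- ann$records[[col]] * f
  if (!is.null(ann$records$radius))
    ann$records$radius <- ann$records$radius * f
  ann$coordinate_space <- if (direction == "to_preprocessed")
    "preprocessed" else "original"
  ann
}
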