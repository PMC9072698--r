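# CenterNet-style anchor-free detector: a feature-extraction trunk followed
# by an object-location head group predicting a center-confidence heatmap,
# a sub-cell offset field and (optionally) a size field, all at output
# stride R.  Peaks of the center heatmap are decoded as particle centers.

#' Detector configuration
#'
#' @param backbone `"tiny"` (three stride-2 conv blocks plus one
#'   transposed-conv block, reaching stride 4) or `"dla34"` (a deeper
#'   hierarchical-aggregation trunk with stage channels 16/32/64/128 and an
#'   aggregation node on the upsampling path).
#' @param stride Output stride R between the input image and the prediction
#'   heatmaps. Only `4` is supported by the provided trunks.
#' @param predict_size Whether the size head (particle width/height
#'   regression) is attached. Off by default: single-particle samples are
#'   homogeneous in size, and dropping the head improves center accuracy.
#' @param head_channels Hidden channels in each prediction head.
#' @param trunk_channels Channels of the three tiny-trunk stages.
#' @param alpha,beta Focal-loss exponents used when training this detector.
#' @param score_threshold,max_detections Decoding defaults.
#' @param default_radius Particle radius (px) assumed when an annotation has
#'   no size, used for the ground-truth Gaussian splat.
#' @return A `detector_config` list.
#' @export
detector_config <- function(backbone = c("tiny", "dla34"),
                            stride = 4L,
                            predict_size = FALSE,
                            head_channels = 32L,
                            trunk_channels = c(16L, 24L, 32L),
                            alpha = 2, beta = 4,
                            score_threshold = 0.3,
                            max_detections = 2000L,
                            default_radius = 8) {
  backbone <- match.arg(backbone)
  stopifnot(alpha > 0, beta > 0)
  if (stride != 4L)
    stop("only output stride R = 4 is supported by the available trunks")
  structure(list(backbone = backbone, stride = as.integer(stride),
                 predict_size = isTRUE(predict_size),
                 head_channels = as.integer(head_channels),
                 trunk_channels = as.integer(trunk_channels),
                 alpha = alpha, beta = beta,
                 score_threshold = score_threshold,
                 max_detections = as.integer(max_detections),
                 default_radius = default_radius),
            class = "detector_config")
}

make_head <- function(Cin, Cmid, Cout, bias_init = 0) {
  list(new_conv_layer(Cin, Cmid, k = 3L, stride = 1L, pad = 1L, act = "relu"),
       new_conv_layer(Cmid, Cout, k = 1L, stride = 1L, pad = 0L,
                      act = "linear", bias_init = bias_init))
}

#' Create a randomly initialized detector
#'
#' The center head's final bias is initialized to `log(0.1/0.9)` so the
#' untrained heatmap starts near the background prior, the usual focal-loss
#' stabilization.
#'
#' @param config A [detector_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `model_state` object.
#' @export
new_detector <- function(config = detector_config(), seed = 1L) {
  set.seed(seed)
  ch <- config$trunk_channels
  if (config$backbone == "tiny") {
    trunk <- list(
      new_conv_layer(1L, ch[1], stride = 2L),
      new_conv_layer(ch[1], ch[2], stride = 2L),
      new_conv_layer(ch[2], ch[3], stride = 2L),
      new_deconv_layer(ch[3], ch[3]))
    feat_ch <- ch[3]
  } else {
    # miniature deep-layer-aggregation trunk: stem, three stride-2 stages,
    # transposed-conv upsampling with a projected skip from the stride-4
    # stage, then an aggregation conv.
    trunk <- list(
      stem = new_conv_layer(1L, 16L, stride = 1L),
      s1   = new_conv_layer(16L, 32L, stride = 2L),
      s2   = new_conv_layer(32L, 64L, stride = 2L),
      s3   = new_conv_layer(64L, 128L, stride = 2L),
      up   = new_deconv_layer(128L, 64L),
      proj = new_conv_layer(64L, 64L, k = 1L, pad = 0L, act = "linear"),
      agg  = new_conv_layer(64L, 64L))
    feat_ch <- 64L
  }
  hc <- config$head_channels
  heads <- list(
    center = make_head(feat_ch, hc, 1L, bias_init = log(0.1 / 0.9)),
    offset = make_head(feat_ch, hc, 2L))
  if (config$predict_size)
    heads$size <- make_head(feat_ch, hc, 2L)
  structure(list(trunk = trunk, heads = heads, config = config,
                 exemplar_manifest = list()),
            class = "model_state")
}

model_layers <- function(model) {
  c(model$trunk, do.call(c, unname(model$heads)))
}

#' Flat parameter vector of a detector
#' @param model A `model_state`.
#' @return Numeric vector theta (fixed layer order).
#' @export
model_parameters <- function(model) layers_flatten(model_layers(model))

#' Replace a detector's parameters from a flat vector
#' @param model A `model_state`.
#' @param theta Numeric vector from [model_parameters()].
#' @return The updated `model_state`.
#' @export
model_set_parameters <- function(model, theta) {
  nt <- length(layers_flatten(model$trunk))
  model$trunk <- layers_unflatten(model$trunk, theta[seq_len(nt)])
  pos <- nt
  for (h in names(model$heads)) {
    nh <- length(layers_flatten(model$heads[[h]]))
    model$heads[[h]] <- layers_unflatten(model$heads[[h]],
                                         theta[pos + seq_len(nh)])
    pos <- pos + nh
  }
  model
}

#' Architecture fingerprint of a detector
#'
#' Identifies the architecture (backbone, stride, heads, channel widths,
#' parameter count); checkpoints refuse to load into a model whose
#' fingerprint differs.
#' @param model A `model_state`.
#' @return A named list.
#' @export
model_fingerprint <- function(model) {
  cfg <- model$config
  list(backbone = cfg$backbone, stride = cfg$stride,
       predict_size = cfg$predict_size,
       head_channels = cfg$head_channels,
       trunk_channels = cfg$trunk_channels,
       n_params = length(model_parameters(model)))
}

detector_input_multiple <- function(config) 2L * config$stride

prep_input <- function(image) {
  px <- if (inherits(image, "micrograph")) image$pixels else image
  stopifnot(is.matrix(px), all(is.finite(px)))
  px / 255
}

trunk_fwd <- function(model, X) {
  if (model$config$backbone == "tiny") {
    r <- seq_fwd(model$trunk, X)
    list(feat = r$out, cache = r)
  } else {
    tr <- model$trunk
    c_stem <- layer_fwd(tr$stem, X)
    c_s1 <- layer_fwd(tr$s1, c_stem$Y)
    c_s2 <- layer_fwd(tr$s2, c_s1$Y)
    c_s3 <- layer_fwd(tr$s3, c_s2$Y)
    c_up <- layer_fwd(tr$up, c_s3$Y)
    c_pr <- layer_fwd(tr$proj, c_s2$Y)
    summed <- c_up$Y + c_pr$Y
    c_agg <- layer_fwd(tr$agg, summed)
    list(feat = c_agg$Y,
         cache = list(stem = c_stem, s1 = c_s1, s2 = c_s2, s3 = c_s3,
                      up = c_up, proj = c_pr, agg = c_agg))
  }
}

trunk_bwd <- function(model, cache, dFeat) {
  if (model$config$backbone == "tiny") {
    r <- seq_bwd(model$trunk, cache$caches, dFeat, need_dx = FALSE)
    r$grads
  } else {
    tr <- model$trunk
    g_agg <- layer_bwd(tr$agg, dFeat, cache$agg)
    g_up <- layer_bwd(tr$up, g_agg$dX, cache$up)
    g_pr <- layer_bwd(tr$proj, g_agg$dX, cache$proj)
    g_s3 <- layer_bwd(tr$s3, g_up$dX, cache$s3)
    d_s2 <- g_s3$dX + g_pr$dX
    g_s2 <- layer_bwd(tr$s2, d_s2, cache$s2)
    g_s1 <- layer_bwd(tr$s1, g_s2$dX, cache$s1)
    g_stem <- layer_bwd(tr$stem, g_s1$dX, cache$stem, need_dx = FALSE)
    keep <- function(g) list(dW = g$dW, db = g$db)
    list(keep(g_stem), keep(g_s1), keep(g_s2), keep(g_s3),
         keep(g_up), keep(g_pr), keep(g_agg))
  }
}

det_forward_full <- function(model, image) {
  X <- prep_input(image)
  mult <- detector_input_multiple(model$config)
  if (nrow(X) %% mult != 0L || ncol(X) %% mult != 0L)
    stop(sprintf("input %dx%d is not padded to a multiple of %d; pad first",
                 ncol(X), nrow(X), mult))
  tr <- trunk_fwd(model, X)
  hc <- seq_fwd(model$heads$center, tr$feat)
  ho <- seq_fwd(model$heads$offset, tr$feat)
  center_logit <- hc$out[, , 1]
  center <- sigmoid(center_logit)
  offset <- ho$out
  hs <- NULL; size <- NULL
  if (!is.null(model$heads$size)) {
    hs <- seq_fwd(model$heads$size, tr$feat)
    size <- hs$out
  }
  hm <- structure(list(center = center, offset = offset, size = size,
                       stride = model$config$stride,
                       features = tr$feat),
                  class = "heatmap_set")
  list(heatmaps = hm,
       cache = list(trunk = tr, center = hc, offset = ho, size = hs,
                    center_sig = center))
}

# d_center is the gradient w.r.t. the post-sigmoid center heatmap;
# d_offset / d_size / d_feat w.r.t. the raw head outputs / trunk features.
det_backward <- function(model, cache, d_center, d_offset,
                         d_size = NULL, d_feat = NULL) {
  s <- cache$center_sig
  d_logit <- d_center * s * (1 - s)
  dim(d_logit) <- c(dim(s), 1L)
  gc_ <- seq_bwd(model$heads$center, cache$center$caches, d_logit)
  go_ <- seq_bwd(model$heads$offset, cache$offset$caches, d_offset)
  dFeat <- gc_$dX + go_$dX
  gs_ <- NULL
  if (!is.null(model$heads$size)) {
    if (is.null(d_size)) d_size <- array(0, dim = dim(cache$size$out))
    gs_ <- seq_bwd(model$heads$size, cache$size$caches, d_size)
    dFeat <- dFeat + gs_$dX
  }
  if (!is.null(d_feat)) dFeat <- dFeat + d_feat
  gt_ <- trunk_bwd(model, cache$trunk$cache, dFeat)
  grads <- c(gt_, gc_$grads, go_$grads,
             if (!is.null(gs_)) gs_$grads)
  grads_flatten(grads)
}

#' Run the detector on a standardized micrograph
#'
#' @param model A `model_state`.
#' @param image A standardized [micrograph] (or bare matrix, gray levels
#'   0-255) whose height and width are multiples of `2 * stride`.
#' @return A `heatmap_set`: `center` (matrix in \[0,1\], H/R x W/R),
#'   `offset` (H/R x W/R x 2, x then y), `size` (same shape, or `NULL` when
#'   the size head is off), `stride`, and the trunk `features` used for
#'   knowledge distillation.
#' @export
forward <- function(model, image) {
  det_forward_full(model, image)$heatmaps
}

#' Render ground-truth target heatmaps for a set of annotations
#'
#' Each annotation at p = (x, y) contributes an unnormalized Gaussian splat
#' with peak 1 at the low-resolution cell floor(p/R) and sigma =
#' max(1, radius/(3R)); overlapping splats combine by elementwise max.  The
#' offset target at the peak cell is p/R - floor(p/R); when the size head is
#' on, the size target is the annotation's (w, h).
#'
#' @param ann An [annotation_set] in preprocessed coordinates.
#' @param shape `c(W, H)` of the (preprocessed, padded) image in px.
#' @param config A [detector_config()].
#' @return A `heatmap_set` with additional fields `pos_mask` (logical matrix
#'   of positive cells), `n_particles` (annotations rendered; colliding
#'   annotations still count individually) and `n_rejected`.
#' @export
render_targets <- function(ann, shape, config = detector_config()) {
  R <- config$stride
  W <- shape[1]; H <- shape[2]
  wo <- W %/% R; ho <- H %/% R
  Y <- matrix(0, nrow = ho, ncol = wo)
  off <- array(0, dim = c(ho, wo, 2L))
  sz <- if (config$predict_size) array(0, dim = c(ho, wo, 2L)) else NULL
  pos <- matrix(FALSE, nrow = ho, ncol = wo)
  rec <- ann_records(ann)
  inside <- rec$x >= 0 & rec$x < W & rec$y >= 0 & rec$y < H
  n_rej <- sum(!inside)
  if (n_rej > 0) {
    warning(sprintf("%d annotation(s) outside the %dx%d image were dropped",
                    n_rej, W, H))
    rec <- rec[inside, , drop = FALSE]
  }
  for (i in seq_len(nrow(rec))) {
    cx <- rec$x[i] / R; cy <- rec$y[i] / R
    ix <- floor(cx); iy <- floor(cy)           # 0-based cell
    radius <- if (!is.na(rec$w[i])) rec$w[i] / 2 else config$default_radius
    sigma <- max(1, radius / (3 * R))
    ext <- ceiling(3 * sigma)
    xs <- max(0L, ix - ext):min(wo - 1L, ix + ext)
    ys <- max(0L, iy - ext):min(ho - 1L, iy + ext)
    g <- exp(-(outer((ys - iy)^2, (xs - ix)^2, "+")) / (2 * sigma^2))
    sub <- Y[ys + 1L, xs + 1L, drop = FALSE]
    Y[ys + 1L, xs + 1L] <- pmax(sub, g)
    if (!pos[iy + 1L, ix + 1L]) {
      pos[iy + 1L, ix + 1L] <- TRUE
      off[iy + 1L, ix + 1L, ] <- c(cx - ix, cy - iy)
      if (!is.null(sz)) sz[iy + 1L, ix + 1L, ] <- c(rec$w[i], rec$h[i])
    }
    Y[iy + 1L, ix + 1L] <- 1
  }
  structure(list(center = Y, offset = off, size = sz, stride = R,
                 pos_mask = pos, n_particles = nrow(rec),
                 n_rejected = n_rej),
            class = "heatmap_set")
}

#' Decode heatmap peaks into particle detections
#'
#' A cell is a peak when its score is not exceeded anywhere in its 3x3
#' neighborhood; among equal-valued neighboring peaks only the first in
#' row-major scan order is kept.  Centers are (peak + offset) * stride,
#' optionally mapped back to original-micrograph pixels through
#' `preprocess_scale`.
#'
#' @param h A `heatmap_set` from [forward()] or [render_targets()].
#' @param score_threshold Minimum center score.
#' @param max_detections Keep at most this many, by descending score.
#' @param constant_size Box side (px, preprocessed space) used when the
#'   heatmap has no size channel; `NA` leaves sizes absent.
#' @param preprocess_scale Original-px per preprocessed-px; coordinates and
#'   sizes are multiplied by it.
#' @return A data frame of detections `(x, y, score, w, h)`, score sorted
#'   non-increasing.
#' @export
decode <- function(h, score_threshold = 0.3, max_detections = 2000L,
                   constant_size = NA_real_, preprocess_scale = 1) {
  Y <- h$center
  ho <- nrow(Y); wo <- ncol(Y)
  Yp <- matrix(-Inf, ho + 2L, wo + 2L)
  Yp[2:(ho + 1L), 2:(wo + 1L)] <- Y
  nb_max <- matrix(-Inf, ho, wo)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb_max <- pmax(nb_max, Yp[2:(ho + 1L) + dy, 2:(wo + 1L) + dx])
  }
  cand <- which(Y >= nb_max & Y >= score_threshold)
  if (length(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0),
                      w = numeric(0), h = numeric(0)))
  ci <- (cand - 1L) %% ho          # 0-based row (y)
  cj <- (cand - 1L) %/% ho         # 0-based col (x)
  scan <- ci * wo + cj             # row-major scan order
  ord <- order(scan)
  ci <- ci[ord]; cj <- cj[ord]; cand <- cand[ord]
  keep <- rep(TRUE, length(cand))
  for (a in seq_along(cand)) {
    if (!keep[a]) next
    later <- which(keep & seq_along(cand) > a &
                     abs(ci - ci[a]) <= 1 & abs(cj - cj[a]) <= 1 &
                     Y[cand] == Y[cand[a]])
    keep[later] <- FALSE
  }
  ci <- ci[keep]; cj <- cj[keep]; cand <- cand[keep]
  scores <- Y[cand]
  R <- h$stride
  idx3 <- cbind(ci + 1L, cj + 1L)
  ox <- h$offset[cbind(idx3, 1L)]
  oy <- h$offset[cbind(idx3, 2L)]
  x <- (cj + ox) * R
  y <- (ci + oy) * R
  if (!is.null(h$size)) {
    w <- h$size[cbind(idx3, 1L)]
    hh <- h$size[cbind(idx3, 2L)]
  } else {
    w <- rep(constant_size, length(x)); hh <- w
  }
  ord2 <- order(-scores, ci * wo + cj)
  ord2 <- ord2[seq_len(min(length(ord2), max_detections))]
  data.frame(x = x[ord2] * preprocess_scale,
             y = y[ord2] * preprocess_scale,
             score = scores[ord2],
             w = w[ord2] * preprocess_scale,
             h = hh[ord2] * preprocess_scale)
}

#' Pad a standardized micrograph so the detector accepts it
#'
#' Pads on the bottom/right with the edge value up to the next multiple of
#' `2 * stride`.
#' @param m A [micrograph] or matrix.
#' @param config A [detector_config()].
#' @return A micrograph (input class preserved for matrices).
#' @export
pad_for_detector <- function(m, config = detector_config()) {
  px <- if (inherits(m, "micrograph")) m$pixels else m
  mult <- detector_input_multiple(config)
  H <- nrow(px); W <- ncol(px)
  Hp <- ceiling(H / mult) * mult; Wp <- ceiling(W / mult) * mult
  if (Hp != H || Wp != W) {
    out <- matrix(0, Hp, Wp)
    out[seq_len(H), seq_len(W)] <- px
    if (Hp > H) out[(H + 1):Hp, seq_len(W)] <- rep(px[H, ], each = Hp - H)
    if (Wp > W) out[, (W + 1):Wp] <- out[, W]
    px <- out
  }
  if (inherits(m, "micrograph")) { m$pixels <- px; m } else px
}
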