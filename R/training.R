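# Training: the exemplar store, data augmentation, and the three modes —
# joint training from scratch, fine-tuning (no rehearsal; the mode that
# exhibits catastrophic forgetting), and continual learning with a frozen
# reference branch, exemplar rehearsal, knowledge distillation and
# parameter regularization.  All three share one inner loop, so a
# continual step with zero distillation/regularization weights and no
# exemplar mixing follows the exact fine-tuning parameter trajectory.

#' Bundle a particle dataset
#'
#' @param id Dataset identifier.
#' @param images List of standardized [micrograph]s (or bare matrices,
#'   gray levels 0-255).
#' @param annotations Parallel list of [annotation_set]s in preprocessed
#'   coordinates.
#' @param particle_size Constant particle box side (px) assigned to the
#'   sample, used for evaluation when size prediction is off.
#' @return A `particle_dataset` list.
#' @export
particle_dataset <- function(id, images, annotations, particle_size) {
  stopifnot(length(images) == length(annotations), length(images) >= 1)
  structure(list(id = id, images = images, annotations = annotations,
                 particle_size = particle_size),
            class = "particle_dataset")
}

#' Training configuration
#'
#' @param mode `"joint"`, `"finetune"` or `"continual"`.
#' @param epochs Epochs over the training images (>= 1; 0 allowed as an
#'   explicit no-op).
#' @param batch_size Images per gradient step.
#' @param learning_rate Adam learning rate (default 1.25e-4).
#' @param seed Master seed for sampling, augmentation and initialization.
#' @param augment Flags `list(flip =, crop =)`; random flips mirror
#'   coordinates exactly, random crops drop annotations outside the
#'   window.
#' @param crop_size Side of the random crop window (multiple of twice the
#'   output stride), used when `augment$crop` is on.
#' @param weights A [loss_weights()].
#' @param exemplar_mix Fraction of each continual-mode batch drawn from
#'   the exemplar store (default 0.5).
#' @param exemplar_n Annotations retained per dataset in the exemplar
#'   (default 200).
#' @param iterations Optional explicit gradient-step count, overriding the
#'   epoch-derived one.
#' @param detector A [detector_config()] (used by joint training to build
#'   the model).
#' @return A `train_config` list.
#' @export
train_config <- function(mode = c("joint", "finetune", "continual"),
                         epochs = 1L, batch_size = 4L,
                         learning_rate = 1.25e-4, seed = 1L,
                         augment = list(flip = TRUE, crop = FALSE),
                         crop_size = NULL,
                         weights = loss_weights(),
                         exemplar_mix = 0.5, exemplar_n = 200L,
                         iterations = NULL,
                         detector = detector_config()) {
  mode <- match.arg(mode)
  stopifnot(epochs >= 0, batch_size >= 1,
            exemplar_mix >= 0, exemplar_mix <= 1)
  structure(list(mode = mode, epochs = epochs,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 augment = augment, crop_size = crop_size,
                 weights = weights, exemplar_mix = exemplar_mix,
                 exemplar_n = as.integer(exemplar_n),
                 iterations = iterations, detector = detector),
            class = "train_config")
}

# ---- exemplar store ------------------------------------------------------

#' Create an empty exemplar store
#'
#' Per-dataset retained micrographs and annotations used for rehearsal and
#' distillation during continual learning.  Entries are immutable once
#' written.
#'
#' @param target_annotations_per_dataset Annotations retained per dataset
#'   (default 200).
#' @return An `exemplar_store`.
#' @export
exemplar_store <- function(target_annotations_per_dataset = 200L) {
  structure(list(entries = list(),
                 target_annotations_per_dataset =
                   as.integer(target_annotations_per_dataset)),
            class = "exemplar_store")
}

#' Build an exemplar entry for one dataset
#'
#' Selects a random contiguous run of `n` annotations in file order
#' (spanning micrograph boundaries when needed) and retains the referenced
#' micrographs; datasets with fewer than `n` annotations are kept whole.
#'
#' @param dataset_id Dataset identifier.
#' @param micrographs List of (downsampled) [micrograph]s or matrices.
#' @param annotations Parallel list of [annotation_set]s.
#' @param n Target number of annotations (default 200).
#' @param seed Seed for the start index.
#' @param particle_size Constant particle size stored with the entry.
#' @return An `exemplar_entry` list.
#' @export
build_exemplar <- function(dataset_id, micrographs, annotations, n = 200L,
                           seed = 1L, particle_size = NA_real_) {
  stopifnot(length(micrographs) == length(annotations))
  counts <- vapply(annotations, n_annotations, 0L)
  total <- sum(counts)
  if (total == 0) stop("empty dataset: no annotations to build an exemplar")
  set.seed(seed)
  n <- min(n, total)
  start <- if (total == n) 1L else sample.int(total - n + 1L, 1L)
  idx <- start:(start + n - 1L)
  mic_of <- rep(seq_along(annotations), counts)
  within <- unlist(lapply(counts, seq_len))
  keep_mics <- sort(unique(mic_of[idx]))
  sel_ann <- vector("list", length(keep_mics))
  for (k in seq_along(keep_mics)) {
    m <- keep_mics[k]
    rows <- within[idx[mic_of[idx] == m]]
    a <- annotations[[m]]
    a$records <- a$records[rows, , drop = FALSE]
    rownames(a$records) <- NULL
    sel_ann[[k]] <- a
  }
  structure(list(dataset_id = dataset_id,
                 micrographs = micrographs[keep_mics],
                 annotations = sel_ann,
                 constant_particle_size = particle_size,
                 n_annotations = n),
            class = "exemplar_entry")
}

#' Add an entry to an exemplar store
#'
#' @param store An [exemplar_store()].
#' @param entry An entry from [build_exemplar()].
#' @return The extended store; existing entries are never modified.
#' @export
store_add <- function(store, entry) {
  stopifnot(inherits(store, "exemplar_store"),
            inherits(entry, "exemplar_entry"))
  if (entry$dataset_id %in% names(store$entries))
    stop("exemplar entry for '", entry$dataset_id,
         "' already exists; entries are immutable")
  store$entries[[entry$dataset_id]] <- entry
  store
}

store_manifest <- function(store) {
  lapply(store$entries, function(e)
    list(dataset_id = e$dataset_id, n_annotations = e$n_annotations,
         n_micrographs = length(e$micrographs),
         constant_particle_size = e$constant_particle_size))
}

# ---- augmentation --------------------------------------------------------

get_pixels <- function(image)
  if (inherits(image, "micrograph")) image$pixels else image

set_pixels <- function(image, px) {
  if (inherits(image, "micrograph")) { image$pixels <- px; image } else px
}

#' Mirror a scene horizontally
#' @param image Micrograph or matrix.
#' @param ann Matching [annotation_set].
#' @return `list(image, ann)` with x coordinates mapped to W - 1 - x.
#' @export
flip_horizontal <- function(image, ann) {
  px <- get_pixels(image)
  W <- ncol(px)
  ann$records$x <- W - 1 - ann$records$x
  list(image = set_pixels(image, px[, W:1, drop = FALSE]), ann = ann)
}

#' Mirror a scene vertically
#' @inheritParams flip_horizontal
#' @return `list(image, ann)` with y coordinates mapped to H - 1 - y.
#' @export
flip_vertical <- function(image, ann) {
  px <- get_pixels(image)
  H <- nrow(px)
  ann$records$y <- H - 1 - ann$records$y
  list(image = set_pixels(image, px[H:1, , drop = FALSE]), ann = ann)
}

#' Crop a scene window
#'
#' Keeps only annotations whose centers lie inside the window and shifts
#' their coordinates by the origin.
#'
#' @param image Micrograph or matrix.
#' @param ann Matching [annotation_set].
#' @param origin `c(x, y)` of the window's top-left corner (0-based).
#' @param size `c(w, h)` of the window in px (at least 8, i.e. twice the
#'   output stride).
#' @return `list(image, ann)`.
#' @export
crop_scene <- function(image, ann, origin, size) {
  if (any(size < 8)) stop("crop window smaller than twice the output stride")
  px <- get_pixels(image)
  ox <- origin[1]; oy <- origin[2]
  if (ox < 0 || oy < 0 || ox + size[1] > ncol(px) ||
      oy + size[2] > nrow(px))
    stop("crop window exceeds the image")
  sub <- px[(oy + 1):(oy + size[2]), (ox + 1):(ox + size[1]),
            drop = FALSE]
  rec <- ann$records
  keep <- rec$x >= ox & rec$x < ox + size[1] &
    rec$y >= oy & rec$y < oy + size[2]
  rec <- rec[keep, , drop = FALSE]
  rec$x <- rec$x - ox
  rec$y <- rec$y - oy
  rownames(rec) <- NULL
  ann$records <- rec
  list(image = set_pixels(image, sub), ann = ann)
}

#' Random flip / crop augmentation
#'
#' @param image Micrograph or matrix (standardized).
#' @param ann Matching [annotation_set] (preprocessed coordinates).
#' @param flags `list(flip =, crop =)`.
#' @param seed Optional seed; `NULL` continues the caller's RNG stream.
#' @param crop_size `c(w, h)` of the random crop window.
#' @return `list(image, ann)`, deterministic under a fixed seed.
#' @export
augment <- function(image, ann, flags = list(flip = TRUE, crop = FALSE),
                    seed = NULL, crop_size = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (isTRUE(flags$flip)) {
    if (stats::runif(1) < 0.5) {
      r <- flip_horizontal(image, ann); image <- r$image; ann <- r$ann
    }
    if (stats::runif(1) < 0.5) {
      r <- flip_vertical(image, ann); image <- r$image; ann <- r$ann
    }
  }
  if (isTRUE(flags$crop)) {
    px <- get_pixels(image)
    if (is.null(crop_size))
      stop("augment: crop requested but no crop_size given")
    cw <- crop_size[1]; ch <- crop_size[length(crop_size)]
    ox <- sample.int(ncol(px) - cw + 1L, 1L) - 1L
    oy <- sample.int(nrow(px) - ch + 1L, 1L) - 1L
    r <- crop_scene(image, ann, c(ox, oy), c(cw, ch))
    image <- r$image; ann <- r$ann
  }
  list(image = image, ann = ann)
}

# ---- shared inner loop ---------------------------------------------------

# One gradient step's worth of forward/backward on a single image.
# `od_scale` divides the detection-loss gradients (batch averaging);
# `distill_scale` divides the distillation gradients (average over the
# exemplar images of the batch).  Returns the flat gradient and the loss
# components.
image_grads <- function(model, image, ann, weights, od_scale,
                        teacher = NULL, distill_scale = 1) {
  cfg <- model$config
  px <- get_pixels(image)
  tg <- render_targets(ann, c(ncol(px), nrow(px)), cfg)
  fb <- det_forward_full(model, px)
  hm <- fb$heatmaps
  N <- tg$n_particles
  if (weights$sparse_mode) {
    l_k <- sparse_center_loss(hm$center, tg$center, N, weights$alpha,
                              weights$beta, weights$tau1, weights$tau2)
    d_center <- sparse_center_grad(hm$center, tg$center, N, weights$alpha,
                                   weights$beta, weights$tau1,
                                   weights$tau2)
  } else {
    l_k <- focal_center_loss(hm$center, tg$center, N, weights$alpha,
                             weights$beta)
    d_center <- focal_center_grad(hm$center, tg$center, N, weights$alpha,
                                  weights$beta)
  }
  l_off <- offset_loss(hm$offset, ann, cfg$stride)
  d_offset <- offset_grad(hm$offset, ann, cfg$stride) * weights$lambda_off
  d_center <- d_center / od_scale
  d_offset <- d_offset / od_scale
  l_size <- NULL; d_size <- NULL
  if (cfg$predict_size) {
    l_size <- size_loss(hm$size, ann, cfg$stride)
    d_size <- size_grad(hm$size, ann, cfg$stride) *
      (weights$lambda_size / od_scale)
  }
  l_distill <- NULL; d_feat <- NULL
  if (!is.null(teacher)) {
    t_hm <- forward(teacher, px)
    l_distill <- distill_loss(hm$features, t_hm$features,
                              hm$center, t_hm$center,
                              hm$offset, t_hm$offset)
    dfac <- weights$lambda_d / distill_scale
    d_feat <- dfac * 2 * (hm$features - t_hm$features) /
      length(hm$features)
    d_center <- d_center + dfac * 2 * (hm$center - t_hm$center) /
      length(hm$center)
    d_offset <- d_offset + dfac * 2 * (hm$offset - t_hm$offset) /
      length(hm$offset)
  }
  grad <- det_backward(model, fb$cache, d_center, d_offset, d_size, d_feat)
  list(grad = grad, l_k = l_k, l_off = l_off, l_size = l_size,
       l_distill = l_distill)
}

train_loop <- function(model, new_images, new_anns, cfg,
                       exemplar_images = list(), exemplar_anns = list(),
                       teacher = NULL, theta_old = NULL) {
  w <- cfg$weights
  n_new <- length(new_images)
  n_ex <- length(exemplar_images)
  iters <- if (!is.null(cfg$iterations)) cfg$iterations else
    cfg$epochs * max(1L, ceiling((n_new + n_ex) / cfg$batch_size))
  theta <- model_parameters(model)
  opt <- adam_init(length(theta))
  hist <- vector("list", iters)
  set.seed(cfg$seed)
  k_ex <- if (n_ex > 0) round(cfg$exemplar_mix * cfg$batch_size) else 0L
  for (it in seq_len(iters)) {
    take_new <- cfg$batch_size - k_ex
    idx_new <- if (take_new > 0)
      sample.int(n_new, take_new, replace = TRUE) else integer(0)
    idx_ex <- if (k_ex > 0)
      sample.int(n_ex, k_ex, replace = TRUE) else integer(0)
    grad <- numeric(length(theta))
    sum_k <- sum_off <- sum_size <- 0
    sum_dist <- 0; n_dist <- 0
    for (i in idx_new) {
      a <- augment(new_images[[i]], new_anns[[i]], cfg$augment,
                   crop_size = cfg$crop_size)
      g <- image_grads(model, a$image, a$ann, w, cfg$batch_size)
      grad <- grad + g$grad
      sum_k <- sum_k + g$l_k; sum_off <- sum_off + g$l_off
      if (!is.null(g$l_size)) sum_size <- sum_size + g$l_size
    }
    for (i in idx_ex) {
      a <- augment(exemplar_images[[i]], exemplar_anns[[i]], cfg$augment,
                   crop_size = cfg$crop_size)
      g <- image_grads(model, a$image, a$ann, w, cfg$batch_size,
                       teacher = teacher, distill_scale = k_ex)
      grad <- grad + g$grad
      sum_k <- sum_k + g$l_k; sum_off <- sum_off + g$l_off
      if (!is.null(g$l_size)) sum_size <- sum_size + g$l_size
      sum_dist <- sum_dist + g$l_distill; n_dist <- n_dist + 1
    }
    l_reg <- 0
    if (!is.null(theta_old)) {
      l_reg <- reg_loss(theta, theta_old)
      grad <- grad + w$lambda_r * 2 * (theta - theta_old)
    }
    b <- cfg$batch_size
    l_k <- sum_k / b; l_off <- sum_off / b
    l_size <- if (model$config$predict_size) sum_size / b else NULL
    l_od <- detection_loss(l_k, l_off, l_size, w)
    l_dist <- if (n_dist > 0) sum_dist / n_dist else 0
    total <- l_od + w$lambda_d * l_dist + w$lambda_r * l_reg
    if (!is.finite(total))
      stop(sprintf("training diverged at step %d (total loss %g; l_k %g, l_off %g)",
                   it, total, l_k, l_off))
    st <- adam_step(opt, theta, grad, cfg$learning_rate)
    opt <- st$state; theta <- st$theta
    model <- model_set_parameters(model, theta)
    hist[[it]] <- data.frame(step = it, l_k = l_k, l_off = l_off,
                             l_size = if (is.null(l_size)) NA_real_ else
                               l_size,
                             l_distill = l_dist, l_reg = l_reg,
                             total = total)
  }
  model$history <- if (iters > 0) do.call(rbind, hist) else
    data.frame(step = integer(0), l_k = numeric(0), l_off = numeric(0),
               l_size = numeric(0), l_distill = numeric(0),
               l_reg = numeric(0), total = numeric(0))
  model
}

pool_datasets <- function(datasets) {
  if (inherits(datasets, "particle_dataset")) datasets <- list(datasets)
  list(images = do.call(c, lapply(datasets, `[[`, "images")),
       anns = do.call(c, lapply(datasets, `[[`, "annotations")),
       datasets = datasets)
}

derive_seed <- function(seed, k) (seed * 1009L + k * 7919L) %% 2147483647L

# ---- training modes ------------------------------------------------------

#' Joint training from scratch
#'
#' Optimizes a single-path detector from random initialization on the
#' combined datasets under the plain detection loss, and builds a fresh
#' exemplar entry for every dataset.
#'
#' @param datasets A [particle_dataset()] or list of them.
#' @param cfg A [train_config()].
#' @return `list(model, store)`: the trained `model_state` (with a
#'   per-step loss `history`) and an [exemplar_store()] holding one entry
#'   per dataset.
#' @export
train_joint <- function(datasets, cfg = train_config("joint")) {
  p <- pool_datasets(datasets)
  model <- new_detector(cfg$detector, seed = derive_seed(cfg$seed, 1L))
  model <- train_loop(model, p$images, p$anns, cfg)
  store <- exemplar_store(cfg$exemplar_n)
  for (k in seq_along(p$datasets)) {
    d <- p$datasets[[k]]
    store <- store_add(store,
                       build_exemplar(d$id, d$images, d$annotations,
                                      n = cfg$exemplar_n,
                                      seed = derive_seed(cfg$seed, 100L + k),
                                      particle_size = d$particle_size))
  }
  model$exemplar_manifest <- store_manifest(store)
  list(model = model, store = store)
}

#' Fine-tuning on new data
#'
#' Continues optimizing an existing model on the new datasets with the
#' same loss as joint training — no exemplar, no distillation.  This is
#' the mode that exhibits catastrophic forgetting of old datasets.
#'
#' @param model A trained `model_state`.
#' @param datasets New [particle_dataset()](s).
#' @param cfg A [train_config()]; zero epochs leave the parameters
#'   untouched.
#' @return The fine-tuned `model_state`.
#' @export
train_finetune <- function(model, datasets,
                           cfg = train_config("finetune")) {
  p <- pool_datasets(datasets)
  train_loop(model, p$images, p$anns, cfg)
}

#' Continual learning with exemplar rehearsal
#'
#' Dual-path procedure: branch A is a frozen copy of the old model kept as
#' the reference for old knowledge; branch B is initialized from the same
#' parameters and optimized.  Every step draws a mixed batch —
#' `exemplar_mix` of it from the exemplar store, the rest from the new
#' dataset.  The detection loss is computed on all batch images; the
#' distillation loss (features, center and offset heatmaps against branch
#' A) only on exemplar-origin images; the regularization loss penalizes
#' drift from the old parameters.  Branch A is discarded afterwards: only
#' the single-path branch-B parameters are returned.
#'
#' @param old The old `model_state` (time t).
#' @param store The [exemplar_store()] of the old datasets (must be
#'   non-empty; with no old datasets use [train_joint()]).
#' @param new_dataset The new [particle_dataset()].
#' @param cfg A [train_config()].
#' @return `list(model, store)`: branch B as the new model, and the store
#'   extended with an entry for the new dataset (old entries untouched).
#' @export
train_continual <- function(old, store, new_dataset,
                            cfg = train_config("continual")) {
  stopifnot(inherits(old, "model_state"))
  if (!inherits(store, "exemplar_store") || length(store$entries) == 0)
    stop("empty exemplar store: train the first dataset with train_joint()")
  ex_images <- do.call(c, lapply(store$entries, `[[`, "micrographs"))
  ex_anns <- do.call(c, lapply(store$entries, `[[`, "annotations"))
  teacher <- old                       # branch A, frozen
  model <- train_loop(old, new_dataset$images, new_dataset$annotations,
                      cfg,
                      exemplar_images = ex_images,
                      exemplar_anns = ex_anns,
                      teacher = teacher,
                      theta_old = model_parameters(old))
  store <- store_add(store,
                     build_exemplar(new_dataset$id, new_dataset$images,
                                    new_dataset$annotations,
                                    n = cfg$exemplar_n,
                                    seed = derive_seed(cfg$seed, 200L),
                                    particle_size =
                                      new_dataset$particle_size))
  model$exemplar_manifest <- store_manifest(store)
  list(model = model, store = store)
}

# ---- inference / evaluation helpers -------------------------------------

#' Pick particles on a standardized micrograph
#'
#' Pads the image for the detector, runs the forward pass and decodes the
#' heatmap peaks.
#'
#' @param model A `model_state`.
#' @param image Standardized [micrograph] or matrix.
#' @param score_threshold,max_detections Decoding parameters (defaults
#'   from the model's config).
#' @param constant_size Box side used when the size head is off.
#' @param to_original Map coordinates back to original-micrograph pixels
#'   through the micrograph's `preprocess_scale`.
#' @return Detection data frame `(x, y, score, w, h)`.
#' @export
pick_particles <- function(model, image, score_threshold = NULL,
                           max_detections = NULL, constant_size = NA_real_,
                           to_original = FALSE) {
  cfg <- model$config
  if (is.null(score_threshold)) score_threshold <- cfg$score_threshold
  if (is.null(max_detections)) max_detections <- cfg$max_detections
  scale <- if (to_original && inherits(image, "micrograph"))
    image$preprocess_scale else 1
  hm <- forward(model, pad_for_detector(image, cfg))
  decode(hm, score_threshold, max_detections, constant_size,
         preprocess_scale = scale)
}

#' Evaluate a model on a labeled set of micrographs
#'
#' @param model A `model_state`.
#' @param images List of standardized micrographs.
#' @param anns Parallel list of ground-truth [annotation_set]s
#'   (preprocessed coordinates).
#' @param constant_size Box side for matching when sizes are absent.
#' @param iou_threshold IoU threshold (default 0.5).
#' @param score_threshold Low decode threshold so the full
#'   precision-recall sweep is available (default 0.05).
#' @return An `eval_report` (see [evaluate_picking()]).
#' @export
evaluate_model <- function(model, images, anns, constant_size,
                           iou_threshold = 0.5, score_threshold = 0.05) {
  dets <- lapply(images, function(im)
    pick_particles(model, im, score_threshold = score_threshold,
                   constant_size = constant_size))
  evaluate_picking(dets, anns, iou_threshold, constant_size)
}
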