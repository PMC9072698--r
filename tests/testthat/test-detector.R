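test_that("forward produces stride-4 heatmaps of the right shape, deterministically", {
  cfg <- detector_config()
  m <- new_detector(cfg, seed = 2)
  set.seed(1)
  img <- matrix(runif(64 * 48, 0, 255), 48, 64)   # W=64, H=48
  hm <- forward(m, img)
  expect_equal(dim(hm$center), c(12, 16))
  expect_equal(dim(hm$offset), c(12, 16, 2))
  expect_null(hm$size)                            # size prediction off
  expect_true(all(hm$center >= 0 & hm$center <= 1))
  expect_identical(hm$center, forward(m, img)$center)
  expect_error(forward(m, matrix(0, 30, 30)), "multiple")
  # with the size head on, the size channel appears
  cfg2 <- detector_config(predict_size = TRUE, trunk_channels = c(4L, 4L, 4L),
                          head_channels = 4L)
  hm2 <- forward(new_detector(cfg2, 1), matrix(0, 16, 16))
  expect_equal(dim(hm2$size), c(4, 4, 2))
})

test_that("forward is shape-covariant over padded input sizes", {
  cfg <- detector_config(trunk_channels = c(3L, 3L, 3L), head_channels = 3L)
  m <- new_detector(cfg, 1)
  for (wh in list(c(16, 16), c(32, 16), c(40, 64))) {
    hm <- forward(m, matrix(0, wh[2], wh[1]))
    expect_equal(dim(hm$center), c(wh[2] / 4, wh[1] / 4))
  }
})

test_that("target rendering follows the floor/offset arithmetic and collision rule", {
  cfg <- detector_config()
  ann <- annotation_set(x = 10, y = 10, coordinate_space = "preprocessed")
  tg <- render_targets(ann, c(32, 32), cfg)
  expect_equal(tg$center[3, 3], 1)                 # cell (2,2), 0-based
  expect_equal(tg$offset[3, 3, ], c(0.5, 0.5))
  expect_equal(tg$n_particles, 1)
  expect_true(all(tg$center >= 0 & tg$center <= 1))
  # empty set: all-zero target, no positives
  tg0 <- render_targets(annotation_set(coordinate_space = "preprocessed"),
                        c(32, 32), cfg)
  expect_true(all(tg0$center == 0))
  expect_equal(sum(tg0$pos_mask), 0)
  # two annotations in one cell: one positive cell, N = 2
  ann2 <- annotation_set(x = c(9, 10.5), y = c(9, 10.5),
                         coordinate_space = "preprocessed")
  tg2 <- render_targets(ann2, c(32, 32), cfg)
  expect_equal(sum(tg2$pos_mask), 1)
  expect_equal(tg2$center[3, 3], 1)
  expect_equal(tg2$n_particles, 2)
  # out-of-image annotation dropped with a warning
  expect_warning(
    tg3 <- render_targets(annotation_set(x = c(5, 100), y = c(5, 5),
                                         coordinate_space = "preprocessed"),
                          c(32, 32), cfg),
    "dropped")
  expect_equal(tg3$n_particles, 1)
})

test_that("render then decode recovers annotation centers exactly", {
  cfg <- detector_config()
  set.seed(5)
  for (rep in 1:5) {
    n <- 6
    xs <- runif(n, 2, 93); ys <- runif(n, 2, 93)
    # enforce separation so splats have distinct peak cells
    keep <- rep(TRUE, n)
    for (i in 2:n)
      if (any(sqrt((xs[seq_len(i - 1)][keep[seq_len(i - 1)]] - xs[i])^2 +
                     (ys[seq_len(i - 1)][keep[seq_len(i - 1)]] - ys[i])^2) < 12))
        keep[i] <- FALSE
    xs <- xs[keep]; ys <- ys[keep]
    ann <- annotation_set(xs, ys, w = 10, h = 10,
                          coordinate_space = "preprocessed")
    tg <- render_targets(ann, c(96, 96), cfg)
    dets <- decode(tg, score_threshold = 0.999, constant_size = 10)
    expect_equal(nrow(dets), length(xs))
    expect_equal(sort(dets$x), sort(xs), tolerance = 1e-12)
    expect_equal(sort(dets$y), sort(ys), tolerance = 1e-12)
  }
})

test_that("decoding handles the empty heatmap and suppresses tied neighbors", {
  mk <- function(center) structure(
    list(center = center, offset = array(0, c(dim(center), 2)),
         size = NULL, stride = 4L), class = "heatmap_set")
  # all-zero heatmap: nothing decoded
  expect_equal(nrow(decode(mk(matrix(0, 8, 8)), 0.1)), 0)
  # two equal adjacent peaks inside one 3x3 window: one detection, the
  # first in row-major scan order wins
  y <- matrix(0, 8, 8)
  y[4, 4] <- 0.9; y[4, 5] <- 0.9
  d <- decode(mk(y), 0.1, constant_size = 8)
  expect_equal(nrow(d), 1)
  expect_equal(d$x, 3 * 4)        # column index 3 (0-based), x first
  # scores come from the heatmap and are sorted non-increasing
  y2 <- matrix(0, 8, 8)
  y2[2, 2] <- 0.5; y2[6, 6] <- 0.8
  d2 <- decode(mk(y2), 0.1, constant_size = 8)
  expect_equal(d2$score, c(0.8, 0.5))
  # max_detections caps the list
  expect_equal(nrow(decode(mk(y2), 0.1, max_detections = 1,
                           constant_size = 8)), 1)
  # preprocess_scale maps decoded centers back to original pixels
  d3 <- decode(mk(y2), 0.1, constant_size = 8, preprocess_scale = 2)
  expect_equal(d3$x, 2 * d2$x)
})

test_that("network gradients agree with finite differences", {
  cfg <- detector_config(trunk_channels = c(4L, 5L, 6L), head_channels = 5L,
                         predict_size = TRUE)
  md <- new_detector(cfg, seed = 3)
  set.seed(9)
  x <- matrix(runif(32 * 24, 0, 255), 24, 32)
  ann <- annotation_set(x = c(5.5, 20.25), y = c(9.75, 15.5), w = 8, h = 8,
                        coordinate_space = "preprocessed")
  w <- loss_weights()
  loss_of <- function(model) {
    tg <- render_targets(ann, c(32, 24), cfg)
    fb <- centerpick:::det_forward_full(model, x)
    hm <- fb$heatmaps
    detection_loss(focal_center_loss(hm$center, tg$center, tg$n_particles),
                   offset_loss(hm$offset, ann, 4),
                   size_loss(hm$size, ann, 4), w)
  }
  g <- centerpick:::image_grads(md, x, ann, w, od_scale = 1)
  theta <- model_parameters(md)
  set.seed(11)
  probe <- sample(length(theta), 12)
  eps <- 1e-5
  num <- vapply(probe, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (loss_of(model_set_parameters(md, tp)) -
       loss_of(model_set_parameters(md, tm))) / (2 * eps)
  }, 0)
  expect_equal(num, g$grad[probe], tolerance = 1e-5)
})

test_that("the hierarchical-aggregation backbone forwards and backprops correctly", {
  cfg <- detector_config(backbone = "dla34")
  md <- new_detector(cfg, seed = 5)
  set.seed(13)
  x <- matrix(runif(16 * 16, 0, 255), 16, 16)
  hm <- forward(md, x)
  expect_equal(dim(hm$center), c(4, 4))
  ann <- annotation_set(x = 6.5, y = 9.25, coordinate_space = "preprocessed")
  w <- loss_weights()
  g <- centerpick:::image_grads(md, x, ann, w, od_scale = 1)
  loss_of <- function(model) {
    tg <- render_targets(ann, c(16, 16), cfg)
    hm <- forward(model, x)
    focal_center_loss(hm$center, tg$center, 1) +
      offset_loss(hm$offset, ann, 4)
  }
  theta <- model_parameters(md)
  set.seed(14)
  probe <- sample(length(theta), 8)
  eps <- 1e-5
  num <- vapply(probe, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (loss_of(model_set_parameters(md, tp)) -
       loss_of(model_set_parameters(md, tm))) / (2 * eps)
  }, 0)
  expect_equal(num, g$grad[probe], tolerance = 1e-5)
})

test_that("pad_for_detector pads to the required multiple with edge values", {
  m <- micrograph(matrix(runif(30 * 21, 0, 255), 21, 30))
  p <- pad_for_detector(m, detector_config())
  expect_equal(dim(p$pixels), c(24, 32))
  expect_equal(p$pixels[1:21, 1:30], m$pixels)
})
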