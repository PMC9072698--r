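test_that("focal center loss matches the double-loop reference on random grids", {
  for (s in 1:20) {
    y_hat <- rand_heat(8, s)
    y <- rand_target(8, npos = 3, seed = s)
    expect_equal(focal_center_loss(y_hat, y, 3),
                 oracle_focal(y_hat, y, 3), tolerance = 1e-6)
  }
  # different exponents
  y_hat <- rand_heat(8, 99); y <- rand_target(8, 2, 99)
  expect_equal(focal_center_loss(y_hat, y, 2, alpha = 1, beta = 2),
               oracle_focal(y_hat, y, 2, alpha = 1, beta = 2),
               tolerance = 1e-6)
})

test_that("focal loss hand value and perfect-prediction limits", {
  # single positive cell, y_hat = 0.5: -(0.5)^2 * log(0.5)
  expect_equal(focal_center_loss(matrix(0.5), matrix(1), 1),
               0.25 * log(2), tolerance = 1e-9)
  # perfect limits go to ~0 under the epsilon clamp
  expect_lt(focal_center_loss(matrix(1), matrix(1), 1), 1e-7)
  expect_lt(focal_center_loss(matrix(0), matrix(0), 1), 1e-7)
  # N = 0 with positives present is an error; without positives allowed
  expect_error(focal_center_loss(matrix(0.2), matrix(1), 0), "positives")
  expect_equal(focal_center_loss(matrix(0.2), matrix(0), 0),
               oracle_focal(matrix(0.2), matrix(0), 0))
})

test_that("sparse center loss implements the pseudo-label and ignore-band rules", {
  for (s in 1:20) {
    y_hat <- rand_heat(8, s + 40)
    y <- rand_target(8, npos = 2, seed = s + 40)
    expect_equal(sparse_center_loss(y_hat, y, 2),
                 oracle_sparse(y_hat, y, 2), tolerance = 1e-6)
  }
  # unlabeled cell inside the band contributes exactly 0
  expect_equal(sparse_center_loss(matrix(0.6), matrix(0), 1), 0)
  # unlabeled cell above tau1 is treated as a positive (pseudo-label)
  expect_equal(sparse_center_loss(matrix(0.8), matrix(0), 1),
               -(1 - 0.8)^2 * log(0.8), tolerance = 1e-9)
  expect_lt(sparse_center_loss(matrix(1), matrix(1), 1), 1e-7)
  expect_error(sparse_center_loss(matrix(0.5), matrix(0), 1, tau1 = 0.4,
                                  tau2 = 0.6), "tau")
})

test_that("sparse loss is invariant to perturbations inside the ignore band", {
  y <- rand_target(8, 2, 7)
  y_hat <- rand_heat(8, 7)
  base <- sparse_center_loss(y_hat, y, 2)
  set.seed(8)
  for (k in 1:10) {
    y2 <- y_hat
    band <- which(y < 1 & y_hat > 0.5 & y_hat < 0.7)
    free <- which(y < 1 & y_hat >= 0.5 & y_hat <= 0.7)
    if (length(free) == 0) next
    y2[free] <- runif(length(free), 0.51, 0.69)
    expect_equal(sparse_center_loss(y2, y, 2), base, tolerance = 1e-12)
  }
})

test_that("offset loss reproduces hand values and the loop reference", {
  R <- 4L
  ann <- annotation_set(x = 10, y = 10, coordinate_space = "preprocessed")
  o <- array(0, c(8, 8, 2))
  # target (0.5, 0.5), prediction (0, 0) -> 1.0
  expect_equal(offset_loss(o, ann, R), 1.0)
  # perfect prediction -> 0
  o[3, 3, ] <- 0.5
  expect_equal(offset_loss(o, ann, R), 0)
  # two particles, one perfect, one off by 0.25 in x -> 0.125
  ann2 <- annotation_set(x = c(10, 22), y = c(10, 22),
                         coordinate_space = "preprocessed")
  o2 <- array(0, c(8, 8, 2))
  o2[3, 3, ] <- 0.5
  o2[6, 6, ] <- c(0.75, 0.5)
  expect_equal(offset_loss(o2, ann2, R), 0.125)
  # random instances against the loop oracle
  for (s in 1:10) {
    set.seed(s)
    xs <- runif(5, 0, 31); ys <- runif(5, 0, 31)
    o3 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
    a3 <- annotation_set(xs, ys, coordinate_space = "preprocessed")
    expect_equal(offset_loss(o3, a3, R), oracle_offset(o3, xs, ys, R),
                 tolerance = 1e-9)
  }
  expect_equal(offset_loss(o, annotation_set(), R), 0)
})

test_that("size loss reproduces hand values and averages over particles", {
  R <- 4L
  s_hat <- array(0, c(8, 8, 2))
  ann <- annotation_set(x = 10, y = 10, w = 20, h = 20,
                        coordinate_space = "preprocessed")
  s_hat[3, 3, ] <- c(18, 24)
  expect_equal(size_loss(s_hat, ann, R), 6)      # |18-20| + |24-20|
  s_hat[3, 3, ] <- c(20, 20)
  expect_equal(size_loss(s_hat, ann, R), 0)
  set.seed(21)
  xs <- runif(4, 0, 31); ys <- runif(4, 0, 31)
  ws <- runif(4, 5, 20); hs <- runif(4, 5, 20)
  sh <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  a <- annotation_set(xs, ys, w = ws, h = hs,
                      coordinate_space = "preprocessed")
  expect_equal(size_loss(sh, a, R), oracle_size(sh, xs, ys, ws, hs, R),
               tolerance = 1e-9)
  expect_error(size_loss(NULL, ann, R), "size head")
})

test_that("detection loss composes its terms with the printed weights", {
  w <- loss_weights()
  expect_equal(detection_loss(1, 0.5, 1, w), 1.6)
  expect_equal(detection_loss(0, 0, 0, w), 0)
  expect_equal(detection_loss(1, 0.5, NULL, w),
               detection_loss(1, 0.5, 5, loss_weights(lambda_size = 0)))
})

test_that("distillation loss is a per-term-normalized squared difference", {
  set.seed(3)
  f0 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  y0 <- matrix(runif(16), 4); o0 <- array(rnorm(32), c(4, 4, 2))
  expect_equal(distill_loss(f0, f0, y0, y0, o0, o0), 0)
  expect_equal(distill_loss(f0 + 1, f0, y0, y0, o0, o0), 1.0)
  cc <- 0.3
  expect_equal(distill_loss(f0 + cc, f0, y0 + cc, y0, o0 + cc, o0),
               3 * cc^2, tolerance = 1e-12)
  f1 <- f0 + rnorm(length(f0)); y1 <- y0 + rnorm(16); o1 <- o0 + rnorm(32)
  expect_equal(distill_loss(f1, f0, y1, y0, o1, o0),
               oracle_distill(f1, f0, y1, y0, o1, o0), tolerance = 1e-9)
  # symmetry
  expect_equal(distill_loss(f1, f0, y1, y0, o1, o0),
               distill_loss(f0, f1, y0, y1, o0, o1))
  expect_error(distill_loss(f0, f0[, 1:2, ], y0, y0, o0, o0), "shape")
})

test_that("regularization loss is the unnormalized squared parameter drift", {
  expect_equal(reg_loss(1:5, 1:5), 0)
  expect_equal(reg_loss(c(1, 2, 0, 0), c(0, 0, 0, 0)), 5)
  set.seed(4)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(reg_loss(a, b), oracle_reg(a, b), tolerance = 1e-9)
  expect_equal(reg_loss(a, b), reg_loss(b, a))
  expect_equal(reg_loss(a + 2 * (b - a), b), reg_loss(a, b))  # symmetry about b
  expect_equal(reg_loss(2 * a, 2 * a - 2 * (a - b)), 4 * reg_loss(a, b),
               tolerance = 1e-9)   # quadratic scaling
  expect_error(reg_loss(1:3, 1:4), "length")
})

test_that("total loss selects the mode composition", {
  w <- loss_weights()
  expect_equal(total_loss("continual",
                          list(l_od = 1, l_distill = 2, l_reg = 10), w),
               1.3)
  expect_equal(total_loss("joint", list(l_od = 0.7), w), 0.7)
  expect_equal(total_loss("finetune", list(l_od = 0.7), w), 0.7)
  expect_equal(total_loss("continual",
                          list(l_od = 1, l_distill = 2, l_reg = 10),
                          loss_weights(lambda_d = 0, lambda_r = 0)), 1)
  expect_equal(total_loss("continual",
                          list(l_od = 0, l_distill = 0, l_reg = 0), w), 0)
  expect_error(total_loss("continual", list(l_od = 1), w), "requires")
})

test_that("loss gradients agree with finite differences", {
  y <- rand_target(6, 2, 31)
  y_hat <- rand_heat(6, 31) * 0.9 + 0.05
  eps <- 1e-6
  g <- centerpick:::focal_center_grad(y_hat, y, 2)
  gs <- centerpick:::sparse_center_grad(y_hat, y, 2)
  set.seed(32)
  for (k in sample(36, 8)) {
    yp <- y_hat; yp[k] <- yp[k] + eps
    ym <- y_hat; ym[k] <- ym[k] - eps
    expect_equal(g[k],
                 (focal_center_loss(yp, y, 2) -
                    focal_center_loss(ym, y, 2)) / (2 * eps),
                 tolerance = 1e-4)
    # skip cells whose branch membership flips inside the probe interval
    if (!(y[k] < 1 && (abs(y_hat[k] - 0.7) < eps ||
                         abs(y_hat[k] - 0.5) < eps)))
      expect_equal(gs[k],
                   (sparse_center_loss(yp, y, 2) -
                      sparse_center_loss(ym, y, 2)) / (2 * eps),
                   tolerance = 1e-4)
  }
})

test_that("loss weight validation rejects inconsistent settings", {
  expect_error(loss_weights(tau1 = 0.4, tau2 = 0.6), "tau")
  expect_error(loss_weights(lambda_d = -1), "non-negative")
})
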