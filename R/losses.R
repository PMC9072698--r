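# Loss functions of the detector and of the continual-learning objective.
# Each is independently callable on plain matrices/arrays; the training
# loop uses the companion *_grad functions (exact analytic gradients,
# finite-difference-checked in the test suite).

.YHAT_EPS <- 1e-4

clamp01 <- function(x, eps = .YHAT_EPS) pmin(pmax(x, eps), 1 - eps)

#' Loss weights and thresholds
#'
#' Collects every tunable of the training objective with its default:
#' lambda_off = 1 and lambda_size = 0.1 weight the offset and size terms of
#' the detection loss; lambda_d = 0.1 and lambda_r = 0.01 weight the
#' distillation and regularization terms of the continual objective;
#' alpha = 2 and beta = 4 are the focal exponents; tau1 = 0.7 and
#' tau2 = 0.5 are the pseudo-label and ignore-band thresholds of the
#' sparse-annotation center loss.
#'
#' @param lambda_off,lambda_size,lambda_d,lambda_r Non-negative weights.
#' @param alpha,beta Focal exponents (positive).
#' @param tau1,tau2 Sparse-annotation thresholds, 0 <= tau2 <= tau1 <= 1.
#' @param sparse_mode Use the sparse center loss instead of the dense one.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_off = 1, lambda_size = 0.1,
                         lambda_d = 0.1, lambda_r = 0.01,
                         alpha = 2, beta = 4,
                         tau1 = 0.7, tau2 = 0.5,
                         sparse_mode = FALSE) {
  if (!(tau2 >= 0 && tau2 <= tau1 && tau1 <= 1))
    stop("invalid thresholds: need 0 <= tau2 <= tau1 <= 1")
  if (any(c(lambda_off, lambda_size, lambda_d, lambda_r) < 0))
    stop("loss weights must be non-negative")
  stopifnot(alpha > 0, beta > 0)
  structure(list(lambda_off = lambda_off, lambda_size = lambda_size,
                 lambda_d = lambda_d, lambda_r = lambda_r,
                 alpha = alpha, beta = beta, tau1 = tau1, tau2 = tau2,
                 sparse_mode = isTRUE(sparse_mode)),
            class = "loss_weights")
}

check_focal_n <- function(y, n_particles) {
  if (n_particles == 0) {
    if (any(y == 1))
      stop("n_particles = 0 but the target grid contains positives")
    return(1)   # negative-only term divided by 1, by convention
  }
  n_particles
}

#' Pixel-wise focal loss on the center heatmap
#'
#' Cells with target 1 contribute (1-Yhat)^alpha * log(Yhat); all other
#' cells contribute (1-Y)^beta * Yhat^alpha * log(1-Yhat).  The negated sum
#' is divided by the particle count N.  Predictions are clamped to
#' \[1e-4, 1-1e-4\] before the logarithms.
#'
#' @param y_hat Predicted center heatmap (values in \[0,1\]).
#' @param y Target heatmap (Gaussian-splatted, peaks exactly 1).
#' @param n_particles N, the number of particles in the image.
#' @param alpha,beta Focal exponents.
#' @return Non-negative scalar.
#' @export
focal_center_loss <- function(y_hat, y, n_particles, alpha = 2, beta = 4) {
  stopifnot(all(dim(y_hat) == dim(y)))
  n <- check_focal_n(y, n_particles)
  p <- clamp01(y_hat)
  pos <- y == 1
  s <- sum((1 - p[pos])^alpha * log(p[pos])) +
    sum((1 - y[!pos])^beta * p[!pos]^alpha * log(1 - p[!pos]))
  -s / n
}

focal_center_grad <- function(y_hat, y, n_particles, alpha = 2, beta = 4) {
  n <- check_focal_n(y, n_particles)
  p <- clamp01(y_hat)
  g <- y_hat * 0
  pos <- y == 1
  g[pos] <- -(-alpha * (1 - p[pos])^(alpha - 1) * log(p[pos]) +
                (1 - p[pos])^alpha / p[pos])
  g[!pos] <- -((1 - y[!pos])^beta *
                 (alpha * p[!pos]^(alpha - 1) * log(1 - p[!pos]) -
                    p[!pos]^alpha / (1 - p[!pos])))
  g / n
}

#' Sparse-annotation focal center loss with pseudo-labels
#'
#' The positive branch of [focal_center_loss()] additionally applies where
#' the prediction exceeds tau1 (a pseudo-label for a likely unlabeled
#' particle); the negative branch applies only where the prediction is
#' below tau2.  Unlabeled cells with predictions inside \[tau2, tau1\] are
#' ignored, removing the penalty on potential unlabeled positives.
#'
#' @inheritParams focal_center_loss
#' @param tau1 Pseudo-label threshold.
#' @param tau2 Negative-branch threshold (tau2 <= tau1).
#' @return Non-negative scalar.
#' @export
sparse_center_loss <- function(y_hat, y, n_particles, alpha = 2, beta = 4,
                               tau1 = 0.7, tau2 = 0.5) {
  if (tau2 > tau1) stop("invalid thresholds: tau2 > tau1")
  stopifnot(all(dim(y_hat) == dim(y)))
  n <- check_focal_n(y, n_particles)
  p <- clamp01(y_hat)
  pos <- y == 1 | y_hat > tau1
  neg <- !pos & y_hat < tau2
  s <- sum((1 - p[pos])^alpha * log(p[pos])) +
    sum((1 - y[neg])^beta * p[neg]^alpha * log(1 - p[neg]))
  -s / n
}

sparse_center_grad <- function(y_hat, y, n_particles, alpha = 2, beta = 4,
                               tau1 = 0.7, tau2 = 0.5) {
  if (tau2 > tau1) stop("invalid thresholds: tau2 > tau1")
  n <- check_focal_n(y, n_particles)
  p <- clamp01(y_hat)
  g <- y_hat * 0
  pos <- y == 1 | y_hat > tau1
  neg <- !pos & y_hat < tau2
  g[pos] <- -(-alpha * (1 - p[pos])^(alpha - 1) * log(p[pos]) +
                (1 - p[pos])^alpha / p[pos])
  g[neg] <- -((1 - y[neg])^beta *
                (alpha * p[neg]^(alpha - 1) * log(1 - p[neg]) -
                   p[neg]^alpha / (1 - p[neg])))
  g / n
}

offset_targets <- function(ann, stride) {
  rec <- ann_records(ann)
  cx <- rec$x / stride; cy <- rec$y / stride
  ix <- floor(cx); iy <- floor(cy)
  data.frame(ix = ix, iy = iy, tx = cx - ix, ty = cy - iy)
}

#' Local-offset regression loss
#'
#' Mean (over particles) L1 distance between the predicted offset at each
#' particle's low-resolution cell and the true sub-cell offset
#' p/R - floor(p/R); the absolute differences of the two components are
#' summed.
#'
#' @param o_hat Predicted offset field, (H/R x W/R x 2) array (x, y).
#' @param ann An [annotation_set] in preprocessed coordinates.
#' @param stride Output stride R.
#' @return Non-negative scalar (0 when there are no particles).
#' @export
offset_loss <- function(o_hat, ann, stride = 4L) {
  tg <- offset_targets(ann, stride)
  n <- nrow(tg)
  if (n == 0) return(0)
  px <- o_hat[cbind(tg$iy + 1L, tg$ix + 1L, 1L)]
  py <- o_hat[cbind(tg$iy + 1L, tg$ix + 1L, 2L)]
  sum(abs(px - tg$tx) + abs(py - tg$ty)) / n
}

offset_grad <- function(o_hat, ann, stride = 4L) {
  g <- o_hat * 0
  tg <- offset_targets(ann, stride)
  n <- nrow(tg)
  if (n == 0) return(g)
  for (i in seq_len(n)) {
    ii <- cbind(tg$iy[i] + 1L, tg$ix[i] + 1L, 1:2)
    g[ii] <- g[ii] + sign(o_hat[ii] - c(tg$tx[i], tg$ty[i])) / n
  }
  g
}

#' Particle-size regression loss
#'
#' Mean L1 distance between predicted and true (w, h) at each particle's
#' low-resolution cell.  Only meaningful when the size head is on.
#'
#' @param s_hat Predicted size field (H/R x W/R x 2) or `NULL`.
#' @param ann An [annotation_set] with sizes, preprocessed coordinates.
#' @param stride Output stride R.
#' @return Non-negative scalar.
#' @export
size_loss <- function(s_hat, ann, stride = 4L) {
  if (is.null(s_hat))
    stop("size head is off: no size predictions to score")
  rec <- ann_records(ann)
  n <- nrow(rec)
  if (n == 0) return(0)
  ix <- floor(rec$x / stride); iy <- floor(rec$y / stride)
  pw <- s_hat[cbind(iy + 1L, ix + 1L, 1L)]
  ph <- s_hat[cbind(iy + 1L, ix + 1L, 2L)]
  sum(abs(pw - rec$w) + abs(ph - rec$h)) / n
}

size_grad <- function(s_hat, ann, stride = 4L) {
  g <- s_hat * 0
  rec <- ann_records(ann)
  n <- nrow(rec)
  if (n == 0) return(g)
  ix <- floor(rec$x / stride); iy <- floor(rec$y / stride)
  for (i in seq_len(n)) {
    ii <- cbind(iy[i] + 1L, ix[i] + 1L, 1:2)
    g[ii] <- g[ii] + sign(s_hat[ii] - c(rec$w[i], rec$h[i])) / n
  }
  g
}

#' Object-detection loss
#'
#' L_OD = L_k + lambda_off * L_off + lambda_size * L_size.  When the size
#' head is off the size term is omitted.
#'
#' @param l_k Center (focal or sparse-focal) loss.
#' @param l_off Offset loss.
#' @param l_size Size loss, or `NULL` when the size head is off.
#' @param weights A [loss_weights()].
#' @return Non-negative scalar.
#' @export
detection_loss <- function(l_k, l_off, l_size = NULL,
                           weights = loss_weights()) {
  l_k + weights$lambda_off * l_off +
    if (is.null(l_size)) 0 else weights$lambda_size * l_size
}

#' Knowledge-distillation loss
#'
#' Sum of three mean-squared differences — trunk feature maps, center
#' heatmaps and offset fields of the new (student) versus old frozen
#' (teacher) network — each normalized by its own element count.  Applied
#' only to exemplar images (caller contract); the size heatmap is not
#' distilled.
#'
#' @param f_new,f_old Feature maps (same shape).
#' @param y_new,y_old Center heatmaps (same shape).
#' @param o_new,o_old Offset fields (same shape).
#' @return Non-negative scalar; 0 iff all three pairs are identical.
#' @export
distill_loss <- function(f_new, f_old, y_new, y_old, o_new, o_old) {
  if (!all(dim(as_hwc(f_new)) == dim(as_hwc(f_old))) ||
      length(y_new) != length(y_old) || length(o_new) != length(o_old))
    stop("distillation pairs must be shape-identical")
  mean((f_new - f_old)^2) + mean((y_new - y_old)^2) +
    mean((o_new - o_old)^2)
}

#' Parameter-regularization loss
#'
#' Plain sum of squared differences between the new and old parameter
#' vectors (no normalization); penalizes drifting far from the old model
#' while rehearsing the exemplar.
#'
#' @param theta_new,theta_old Parameter vectors of equal length.
#' @return Non-negative scalar.
#' @export
reg_loss <- function(theta_new, theta_old) {
  if (length(theta_new) != length(theta_old))
    stop("parameter vectors differ in length")
  sum((theta_new - theta_old)^2)
}

#' Total training loss
#'
#' Joint training and fine-tuning minimize the detection loss alone;
#' continual learning adds the distillation and regularization terms:
#' L_Total = L_OD + lambda_d * L_Distill + lambda_r * L_Reg.
#'
#' @param mode `"joint"`, `"finetune"` or `"continual"`.
#' @param components Named list with `l_od` and, in continual mode,
#'   `l_distill` and `l_reg`.
#' @param weights A [loss_weights()].
#' @return Non-negative scalar.
#' @export
total_loss <- function(mode = c("joint", "finetune", "continual"),
                       components, weights = loss_weights()) {
  mode <- match.arg(mode)
  if (mode != "continual") return(components$l_od)
  if (is.null(components$l_distill) || is.null(components$l_reg))
    stop("continual mode requires distillation and regularization components")
  components$l_od + weights$lambda_d * components$l_distill +
    weights$lambda_r * components$l_reg
}
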