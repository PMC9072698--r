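# Independent reference implementations used as oracles: literal
# double-loop evaluations of the loss formulas and an exhaustive
# threshold-enumeration computation of average precision.  These stay
# deliberately naive and share no code with the package internals.

oracle_focal <- function(y_hat, y, n, alpha = 2, beta = 4, eps = 1e-4) {
  s <- 0
  for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y))) {
    p <- min(max(y_hat[i, j], eps), 1 - eps)
    s <- s + if (y[i, j] == 1) {
      (1 - p)^alpha * log(p)
    } else {
      (1 - y[i, j])^beta * p^alpha * log(1 - p)
    }
  }
  -s / if (n == 0) 1 else n
}

oracle_sparse <- function(y_hat, y, n, alpha = 2, beta = 4,
                          tau1 = 0.7, tau2 = 0.5, eps = 1e-4) {
  s <- 0
  for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y))) {
    p <- min(max(y_hat[i, j], eps), 1 - eps)
    raw <- y_hat[i, j]
    if (y[i, j] == 1 || raw > tau1) {
      s <- s + (1 - p)^alpha * log(p)
    } else if (raw < tau2) {
      s <- s + (1 - y[i, j])^beta * p^alpha * log(1 - p)
    }
  }
  -s / if (n == 0) 1 else n
}

oracle_offset <- function(o_hat, xs, ys, R) {
  n <- length(xs)
  if (n == 0) return(0)
  s <- 0
  for (k in seq_len(n)) {
    ix <- floor(xs[k] / R); iy <- floor(ys[k] / R)
    tx <- xs[k] / R - ix; ty <- ys[k] / R - iy
    s <- s + abs(o_hat[iy + 1, ix + 1, 1] - tx) +
      abs(o_hat[iy + 1, ix + 1, 2] - ty)
  }
  s / n
}

oracle_size <- function(s_hat, xs, ys, ws, hs, R) {
  n <- length(xs)
  if (n == 0) return(0)
  s <- 0
  for (k in seq_len(n)) {
    ix <- floor(xs[k] / R); iy <- floor(ys[k] / R)
    s <- s + abs(s_hat[iy + 1, ix + 1, 1] - ws[k]) +
      abs(s_hat[iy + 1, ix + 1, 2] - hs[k])
  }
  s / n
}

oracle_distill <- function(f1, f0, y1, y0, o1, o0) {
  sum((f1 - f0)^2) / length(f1) + sum((y1 - y0)^2) / length(y1) +
    sum((o1 - o0)^2) / length(o1)
}

oracle_reg <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s
}

# box IoU recomputed from corner coordinates
oracle_iou <- function(a, b) {
  ax1 <- a[1] - a[3] / 2; ax2 <- a[1] + a[3] / 2
  ay1 <- a[2] - a[4] / 2; ay2 <- a[2] + a[4] / 2
  bx1 <- b[1] - b[3] / 2; bx2 <- b[1] + b[3] / 2
  by1 <- b[2] - b[4] / 2; by2 <- b[2] + b[4] / 2
  iw <- max(0, min(ax2, bx2) - max(ax1, bx1))
  ih <- max(0, min(ay2, by2) - max(ay1, by1))
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

oracle_greedy_match <- function(dets, gt, thr, size) {
  taken <- logical(nrow(gt))
  tp <- 0
  for (i in order(-dets$score)) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gt))) {
      if (taken[j]) next
      v <- oracle_iou(c(dets$x[i], dets$y[i], size, size),
                      c(gt$x[j], gt$y[j], size, size))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= thr) { taken[bj] <- TRUE; tp <- tp + 1 }
  }
  list(tp = tp, fp = nrow(dets) - tp, fn = nrow(gt) - tp)
}

# AP by sweeping every score threshold, computing (precision, recall) at
# each, and integrating the all-point-interpolated precision over recall.
oracle_ap_sweep <- function(dets, gt, thr, size) {
  if (nrow(gt) == 0) return(NA_real_)
  if (nrow(dets) == 0) return(0)
  cuts <- sort(unique(dets$score), decreasing = TRUE)
  P <- R <- numeric(length(cuts))
  for (k in seq_along(cuts)) {
    sub <- dets[dets$score >= cuts[k], , drop = FALSE]
    m <- oracle_greedy_match(sub, gt, thr, size)
    P[k] <- if (nrow(sub) > 0) m$tp / nrow(sub) else 0
    R[k] <- m$tp / nrow(gt)
  }
  rs <- sort(unique(R[R > 0]))
  ap <- 0; prev <- 0
  for (r in rs) {
    p_at <- max(P[R >= r])
    ap <- ap + (r - prev) * p_at
    prev <- r
  }
  ap
}

rand_heat <- function(n = 8, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

rand_target <- function(n = 8, npos = 3, seed = 1) {
  set.seed(seed + 1000)
  y <- matrix(runif(n * n)^3, n, n)   # splat-like soft values
  pos <- sample(n * n, npos)
  y[pos] <- 1
  y
}
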