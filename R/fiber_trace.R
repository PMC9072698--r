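# Line tracing algorithm (LTA): link picked fiber points into ordered
# chains under a maximum-turn constraint, then simplify nearly straight
# stretches.  Works on the point set produced by ordinary particle
# picking of a fiber micrograph.

#' Tracing configuration
#'
#' @param r Candidate radius in px (default 100 at width-1024 scale):
#'   only unused points within `r` of the current chain head are
#'   candidates for the next link.
#' @param ang Maximum turning angle between consecutive segments, radians
#'   (0 = perfectly straight).
#' @param smooth_threshold Turn angle below which an interior point is
#'   removed by [smooth_path()] (default 0.1 rad).
#' @param seed Seed for the random start-point choice.
#' @param deterministic_start Start each fiber at the lowest-index unused
#'   point instead of a seeded random one.
#' @param first_link_unbounded Allow the first link of each fiber to
#'   ignore the candidate radius `r`. Off by default: an unbounded first
#'   link can bridge distinct fibers.
#' @return A `trace_config` list.
#' @export
trace_config <- function(r = 100, ang = 0.4, smooth_threshold = 0.1,
                         seed = 1L, deterministic_start = FALSE,
                         first_link_unbounded = FALSE) {
  stopifnot(r > 0, ang >= 0, ang <= pi, smooth_threshold >= 0)
  structure(list(r = r, ang = ang, smooth_threshold = smooth_threshold,
                 seed = as.integer(seed),
                 deterministic_start = isTRUE(deterministic_start),
                 first_link_unbounded = isTRUE(first_link_unbounded)),
            class = "trace_config")
}

turn_angle <- function(ax, ay, bx, by) {
  # angle between successive direction vectors a, b; 0 = straight on
  na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
  if (na == 0 || nb == 0) return(0)
  cosv <- (ax * bx + ay * by) / (na * nb)
  acos(pmin(pmax(cosv, -1), 1))
}

#' Trace fibers through a point set
#'
#' Starting from a (seeded-random or lowest-index) unused point, the
#' tracer repeatedly links the nearest unused point within radius `r`
#' whose turning angle relative to the previous segment does not exceed
#' `ang`; nearer candidates failing the angle test are skipped.  When no
#' candidate qualifies the fiber is closed and a new one is started, so
#' every input point ends up in exactly one fiber.
#'
#' @param points Data frame with columns `x`, `y` (pairwise distinct
#'   points).
#' @param config A [trace_config()].
#' @return List of fiber paths, each a data frame `(x, y)` in traced
#'   order; empty input gives an empty list.
#' @export
trace_fibers <- function(points, config = trace_config()) {
  n <- nrow(points)
  if (is.null(n) || n == 0) return(list())
  if (anyDuplicated(points[, c("x", "y")]))
    stop("points must be pairwise distinct")
  if (!config$deterministic_start) set.seed(config$seed)
  px <- points$x; py <- points$y
  used <- logical(n)
  fibers <- list()
  while (any(!used)) {
    free <- which(!used)
    start <- if (config$deterministic_start) free[1]
      else free[sample.int(length(free), 1)]
    used[start] <- TRUE
    chain <- start
    prev_dir <- NULL
    repeat {
      head_i <- chain[length(chain)]
      cand <- which(!used)
      if (length(cand) == 0) break
      d <- sqrt((px[cand] - px[head_i])^2 + (py[cand] - py[head_i])^2)
      within <- if (is.null(prev_dir) && config$first_link_unbounded)
        rep(TRUE, length(cand)) else d <= config$r
      cand <- cand[within]; d <- d[within]
      if (length(cand) == 0) break
      ord <- order(d)
      nxt <- NA_integer_
      for (j in ord) {
        cj <- cand[j]
        dir_x <- px[cj] - px[head_i]; dir_y <- py[cj] - py[head_i]
        if (is.null(prev_dir) ||
            turn_angle(prev_dir[1], prev_dir[2], dir_x, dir_y) <=
              config$ang) {
          nxt <- cj
          prev_dir <- c(dir_x, dir_y)
          break
        }
      }
      if (is.na(nxt)) break
      used[nxt] <- TRUE
      chain <- c(chain, nxt)
    }
    fibers[[length(fibers) + 1L]] <-
      data.frame(x = px[chain], y = py[chain])
  }
  fibers
}

#' Simplify a fiber path by removing nearly straight interior points
#'
#' Single left-to-right pass: an interior point is removed when the turn
#' angle between the segment arriving from the last kept point and the
#' segment leaving toward the next point is below `threshold`.  Endpoints
#' are always kept; corners (large turns) survive.
#'
#' @param path Data frame `(x, y)` in traced order.
#' @param threshold Removal threshold in radians (default 0.1).
#' @return The simplified path data frame.
#' @export
smooth_path <- function(path, threshold = 0.1) {
  n <- nrow(path)
  if (n < 3) return(path)
  keep <- 1L
  last <- 1L
  for (i in 2:(n - 1)) {
    a <- c(path$x[i] - path$x[last], path$y[i] - path$y[last])
    b <- c(path$x[i + 1] - path$x[i], path$y[i + 1] - path$y[i])
    if (turn_angle(a[1], a[2], b[1], b[2]) >= threshold) {
      keep <- c(keep, i)
      last <- i
    }
  }
  keep <- c(keep, n)
  path[keep, , drop = FALSE]
}
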