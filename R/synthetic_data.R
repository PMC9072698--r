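# Synthetic micrograph generator: scenes of rendered particle "species"
# (standing in for distinct datasets), fibers as smooth point chains, and
# vesicles as rings with known radii — each with exact ground truth, so the
# detector, the training modes and the tracing algorithm are all testable
# without any external data.  Rendering uses anti-aliased analytic shapes
# plus Gaussian white noise and large low-frequency contamination blobs;
# no attempt is made at physical image formation (CTF, dose, ice
# gradients).

#' Particle species specification
#'
#' Distinct species emulate datasets with different particle features:
#' they must differ in at least one of radius, shape or contrast.
#'
#' @param species_id Short label.
#' @param particle_radius Radius in px (>= 2).
#' @param shape `"disk"`, `"ring"`, `"blob"` or `"rod"`.
#' @param contrast Signed particle-to-background intensity delta (gray
#'   levels; negative = dark particles, the usual cryo-EM convention).
#' @param texture_seed Integer seed for per-particle texture jitter.
#' @return A `species_spec` list.
#' @export
species_spec <- function(species_id, particle_radius,
                         shape = c("disk", "ring", "blob", "rod"),
                         contrast = -60, texture_seed = 0L) {
  shape <- match.arg(shape)
  if (particle_radius < 2) stop("particle_radius must be >= 2 px")
  structure(list(species_id = species_id,
                 particle_radius = particle_radius, shape = shape,
                 contrast = contrast,
                 texture_seed = as.integer(texture_seed)),
            class = "species_spec")
}

#' Scene specification
#'
#' @param width,height Image size in px.
#' @param n_particles Number of particles to place.
#' @param species List of [species_spec()]s; particles cycle through them.
#' @param noise_sigma Gaussian white-noise standard deviation (gray
#'   levels).
#' @param n_contaminants Number of large low-frequency contamination blobs.
#' @param min_separation Minimum pairwise center distance in px.
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   scene.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 256L, height = 256L, n_particles = 20L,
                       species = list(species_spec("A", 6)),
                       noise_sigma = 10, n_contaminants = 0L,
                       min_separation = 20, seed = 1L) {
  stopifnot(width >= 8, height >= 8, n_particles >= 0, noise_sigma >= 0,
            n_contaminants >= 0, min_separation >= 0)
  if (inherits(species, "species_spec")) species <- list(species)
  if (n_particles > 0 && length(species) == 0)
    stop("at least one species is required")
  if (n_particles * max(1, min_separation)^2 > width * height)
    stop("overcrowded scene: n_particles * min_separation^2 exceeds the field of view")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_particles = as.integer(n_particles), species = species,
                 noise_sigma = noise_sigma,
                 n_contaminants = as.integer(n_contaminants),
                 min_separation = min_separation, seed = as.integer(seed)),
            class = "scene_spec")
}

# Rejection-sample n centers with pairwise distance >= min_sep, margin from
# the border.  Bounded retries; failure signals an overcrowded spec.
place_centers <- function(n, width, height, min_sep, margin,
                          max_tries = 500L) {
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, margin, width - 1 - margin)
      y <- stats::runif(1, margin, height - 1 - margin)
      if (length(xs) == 0 ||
          all((xs - x)^2 + (ys - y)^2 >= min_sep^2)) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf("placement failed after %d retries: overcrowded scene",
                   max_tries))
  }
  list(x = xs, y = ys)
}

# Render one particle onto `img` (modified in place by the caller).
# Profiles are radial with a 1-px anti-aliased edge, peak |amplitude| =
# |contrast|.
render_particle <- function(img, cx, cy, sp, rot = 0) {
  r <- sp$particle_radius
  ext <- ceiling(r + 2)
  H <- nrow(img); W <- ncol(img)
  xs <- max(0, floor(cx) - ext):min(W - 1, ceiling(cx) + ext)
  ys <- max(0, floor(cy) - ext):min(H - 1, ceiling(cy) + ext)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  if (sp$shape == "rod") {
    u <- dx * cos(rot) + dy * sin(rot)
    v <- -dx * sin(rot) + dy * cos(rot)
    d <- pmax(abs(u) - r, 0)
    d <- sqrt(d^2 + v^2)
    prof <- pmin(pmax((r / 3 - d) + 0.5, 0), 1)
  } else {
    d <- sqrt(dx^2 + dy^2)
    prof <- switch(sp$shape,
      disk = pmin(pmax((r - d) + 0.5, 0), 1),
      ring = pmin(pmax((r / 3 - abs(d - r * 0.8)) + 0.5, 0), 1),
      blob = exp(-d^2 / (2 * (r / 1.8)^2)))
  }
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + sp$contrast * prof
  img
}

render_contaminant <- function(img, width, height) {
  cx <- stats::runif(1, 0, width - 1)
  cy <- stats::runif(1, 0, height - 1)
  r <- stats::runif(1, 0.08, 0.2) * min(width, height)
  amp <- stats::runif(1, -40, -15)
  ext <- ceiling(3 * r)
  xs <- max(0, floor(cx) - ext):min(width - 1, ceiling(cx) + ext)
  ys <- max(0, floor(cy) - ext):min(height - 1, ceiling(cy) + ext)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amp * exp(-d2 / (2 * r^2))
  img
}

#' Generate a particle scene with exact ground truth
#'
#' @param spec A [scene_spec()].
#' @return List with `micrograph` (raw, background level 128 gray) and
#'   `annotations` (an [annotation_set] with true centers, diameters and
#'   species labels).
#' @export
make_particle_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  img <- matrix(128, nrow = spec$height, ncol = spec$width)
  n <- spec$n_particles
  sp_idx <- if (n > 0) rep_len(seq_along(spec$species), n) else integer(0)
  margin <- if (n > 0)
    max(vapply(spec$species, function(s) s$particle_radius, 0)) + 1 else 0
  ctr <- place_centers(n, spec$width, spec$height, spec$min_separation,
                       margin)
  rots <- stats::runif(max(n, 1), 0, pi)
  for (k in seq_len(spec$n_contaminants))
    img <- render_contaminant(img, spec$width, spec$height)
  for (i in seq_len(n))
    img <- render_particle(img, ctr$x[i], ctr$y[i],
                           spec$species[[sp_idx[i]]], rots[i])
  if (spec$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                        nrow = spec$height)
  sp_ids <- vapply(spec$species, function(s) s$species_id, "")
  diam <- 2 * vapply(spec$species, function(s) s$particle_radius, 0)
  ann <- annotation_set(x = ctr$x, y = ctr$y,
                        w = if (n > 0) diam[sp_idx] else NA_real_,
                        h = if (n > 0) diam[sp_idx] else NA_real_,
                        species = if (n > 0) sp_ids[sp_idx] else
                          NA_character_,
                        micrograph_ref = sprintf("scene_seed%d", spec$seed),
                        coordinate_space = "original")
  list(micrograph = micrograph(img, source_path = "synthetic"),
       annotations = ann)
}

#' Generate a fiber scene: smooth point chains rendered as particles
#'
#' Each fiber is an ordered chain of points with consecutive spacing
#' `step` and per-vertex turning angle at most `max_turn`; chains keep an
#' enforced mutual gap so ground-truth membership is unambiguous.
#'
#' @param n_fibers Number of fibers.
#' @param points_per_fiber Points per chain.
#' @param step Spacing between consecutive points, px.
#' @param max_turn Maximum per-vertex turning angle, radians.
#' @param seed Integer seed.
#' @param width,height Image size.
#' @param gap Minimum distance between points of different fibers.
#' @param noise_sigma White-noise level.
#' @param point_radius Rendered spot radius.
#' @return List with `micrograph`, `chains` (list of ordered data frames
#'   `(x, y)`) and `points` (all points with a `fiber` membership column).
#' @export
make_fiber_scene <- function(n_fibers = 2L, points_per_fiber = 10L,
                             step = 30, max_turn = 0.3, seed = 1L,
                             width = 512L, height = 512L, gap = 150,
                             noise_sigma = 8, point_radius = 4) {
  stopifnot(step > 0, max_turn >= 0, n_fibers >= 0, points_per_fiber >= 1)
  set.seed(seed)
  chains <- list()
  all_x <- numeric(0); all_y <- numeric(0)
  margin <- 4
  for (f in seq_len(n_fibers)) {
    ok <- FALSE
    for (try in 1:500) {
      x0 <- stats::runif(1, margin, width - 1 - margin)
      y0 <- stats::runif(1, margin, height - 1 - margin)
      # aim roughly at the image center so straight chains stay in frame
      theta <- atan2(height / 2 - y0, width / 2 - x0) +
        stats::runif(1, -0.3, 0.3)
      xs <- x0; ys <- y0
      good <- TRUE
      for (p in seq_len(points_per_fiber - 1)) {
        if (max_turn > 0 && p > 1)
          theta <- theta + stats::runif(1, -max_turn, max_turn)
        xn <- xs[p] + step * cos(theta)
        yn <- ys[p] + step * sin(theta)
        if (xn < margin || xn > width - 1 - margin ||
            yn < margin || yn > height - 1 - margin) { good <- FALSE; break }
        xs <- c(xs, xn); ys <- c(ys, yn)
      }
      if (good && length(all_x) > 0) {
        dmin <- min(sqrt(outer(xs, all_x, "-")^2 +
                           outer(ys, all_y, "-")^2))
        if (dmin < gap) good <- FALSE
      }
      if (good) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place fiber ", f,
                  ": scene too small for the requested gap")
    chains[[f]] <- data.frame(x = xs, y = ys)
    all_x <- c(all_x, xs); all_y <- c(all_y, ys)
  }
  img <- matrix(128, nrow = height, ncol = width)
  sp <- species_spec("fiberpt", max(2, point_radius), "disk",
                     contrast = -60)
  for (ch in chains)
    for (i in seq_len(nrow(ch)))
      img <- render_particle(img, ch$x[i], ch$y[i], sp)
  if (noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sigma),
                        nrow = height)
  pts <- if (n_fibers > 0)
    data.frame(x = all_x, y = all_y,
               fiber = rep(seq_len(n_fibers), each = points_per_fiber))
  else data.frame(x = numeric(0), y = numeric(0), fiber = integer(0))
  list(micrograph = micrograph(img, source_path = "synthetic"),
       chains = chains, points = pts)
}

#' Generate a vesicle scene: rings with known radii
#'
#' @param n_vesicles Number of vesicles.
#' @param radius_range Interval `c(min, max)` of radii, px.
#' @param allow_overlap If `TRUE`, at least one overlapping pair is forced
#'   whenever `n_vesicles >= 2`; if `FALSE`, all center distances exceed
#'   the sum of the radii.
#' @param seed Integer seed.
#' @param width,height Image size.
#' @param noise_sigma White-noise level.
#' @param contrast Membrane intensity delta.
#' @return List with `micrograph` and `annotations` (centers plus radii;
#'   `w = h = 2 * radius`, and a `radius` column on the records).
#' @export
make_vesicle_scene <- function(n_vesicles = 3L, radius_range = c(20, 50),
                               allow_overlap = FALSE, seed = 1L,
                               width = 512L, height = 512L,
                               noise_sigma = 8, contrast = -50) {
  stopifnot(length(radius_range) == 2, all(radius_range > 0),
            radius_range[1] <= radius_range[2], n_vesicles >= 0)
  set.seed(seed)
  rad <- stats::runif(n_vesicles, radius_range[1], radius_range[2])
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n_vesicles)) {
    margin <- rad[i] + 2
    if (allow_overlap && i == 2) {
      # force an overlapping pair
      ang <- stats::runif(1, 0, 2 * pi)
      d <- 0.6 * (rad[1] + rad[2])
      x <- min(max(xs[1] + d * cos(ang), margin), width - 1 - margin)
      y <- min(max(ys[1] + d * sin(ang), margin), height - 1 - margin)
      xs <- c(xs, x); ys <- c(ys, y)
      next
    }
    placed <- FALSE
    for (try in 1:500) {
      x <- stats::runif(1, margin, width - 1 - margin)
      y <- stats::runif(1, margin, height - 1 - margin)
      if (allow_overlap || length(xs) == 0 ||
          all(sqrt((xs - x)^2 + (ys - y)^2) >
                rad[seq_along(xs)] + rad[i] + 2)) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place vesicle ", i,
                      " without overlap: reduce n or radii")
  }
  img <- matrix(128, nrow = height, ncol = width)
  for (i in seq_len(n_vesicles)) {
    ext <- ceiling(rad[i] + 3)
    cx <- xs[i]; cy <- ys[i]
    gx <- max(0, floor(cx) - ext):min(width - 1, ceiling(cx) + ext)
    gy <- max(0, floor(cy) - ext):min(height - 1, ceiling(cy) + ext)
    d <- sqrt(outer((gy - cy)^2, (gx - cx)^2, "+"))
    prof <- pmin(pmax((2 - abs(d - rad[i])) + 0.5, 0), 1)
    img[gy + 1, gx + 1] <- img[gy + 1, gx + 1] + contrast * prof
  }
  if (noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sigma),
                        nrow = height)
  ann <- annotation_set(x = xs, y = ys, w = 2 * rad, h = 2 * rad,
                        micrograph_ref = sprintf("vesicles_seed%d", seed),
                        coordinate_space = "original")
  ann$records$radius <- rad
  list(micrograph = micrograph(img, source_path = "synthetic"),
       annotations = ann)
}
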