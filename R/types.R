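# Core containers.  Coordinate convention, used everywhere: 0-based pixel
# indices, x = column, y = row, positions refer to particle centers.

#' Micrograph container
#'
#' @param pixels Numeric matrix, H rows x W columns, finite values.
#' @param pixel_size Physical pixel size in Angstrom/px, `NA` if unknown.
#' @param source_path Provenance string.
#' @param preprocess_scale Original-px per current-px (1 for raw images).
#' @return A `micrograph` object.
#' @export
micrograph <- function(pixels, pixel_size = NA_real_, source_path = "",
                       preprocess_scale = 1) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1, ncol(pixels) >= 1,
            all(is.finite(pixels)), preprocess_scale > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 source_path = source_path,
                 preprocess_scale = preprocess_scale),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph %dx%d px, pixel size %s, scale %.3g%s>\n",
              ncol(x$pixels), nrow(x$pixels),
              ifelse(is.na(x$pixel_size), "unknown",
                     sprintf("%.3g A", x$pixel_size)),
              x$preprocess_scale,
              ifelse(nzchar(x$source_path),
                     paste0(", from ", x$source_path), "")))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

#' Particle annotation set
#'
#' Ground-truth or predicted particle records tied to one micrograph.
#' Sizes are full box widths/heights; a circular particle of radius r is
#' stored as w = h = 2r.
#'
#' @param x,y Particle center coordinates (0-based px).
#' @param score Optional confidence in \[0,1\] (`NA` if absent).
#' @param w,h Optional box size in px (`NA` if absent).
#' @param micrograph_ref Identifier of the source micrograph.
#' @param coordinate_space `"original"` or `"preprocessed"`.
#' @param species Optional species/class label.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(x = numeric(0), y = numeric(0),
                           score = NA_real_, w = NA_real_, h = NA_real_,
                           micrograph_ref = "",
                           coordinate_space = c("original", "preprocessed"),
                           species = NA_character_) {
  coordinate_space <- match.arg(coordinate_space)
  n <- length(x)
  stopifnot(length(y) == n)
  rec <- data.frame(x = as.numeric(x), y = as.numeric(y),
                    score = rep_len(as.numeric(score), n),
                    w = rep_len(as.numeric(w), n),
                    h = rep_len(as.numeric(h), n),
                    species = rep_len(as.character(species), n))
  ok <- is.na(rec$score) | (rec$score >= 0 & rec$score <= 1)
  if (!all(ok)) stop("annotation scores must lie in [0, 1]")
  structure(list(records = rec, micrograph_ref = micrograph_ref,
                 coordinate_space = coordinate_space),
            class = "annotation_set")
}

ann_records <- function(ann) {
  if (inherits(ann, "annotation_set")) ann$records
  else if (is.data.frame(ann)) {
    for (col in c("score", "w", "h"))
      if (is.null(ann[[col]])) ann[[col]] <- NA_real_
    ann
  } else stop("expected an annotation_set or data frame")
}

#' Number of annotations
#' @param ann An `annotation_set`.
#' @return Integer count.
#' @export
n_annotations <- function(ann) nrow(ann_records(ann))

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set: %d records, %s coordinates%s>\n",
              nrow(x$records), x$coordinate_space,
              ifelse(nzchar(x$micrograph_ref),
                     paste0(", micrograph ", x$micrograph_ref), "")))
  invisible(x)
}
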