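# Coordinate-table I/O.  Canonical dialect is TSV with header
# `x y score radius`; EMAN BOX and RELION coordinate STAR are supported
# for interoperability.  BOX corners are top-left in image (row-down)
# coordinates: center = corner + box/2.

#' Read particle coordinates
#'
#' Dialects:
#' \describe{
#'   \item{tsv}{Columns `x y [score] [radius]` (tab- or space-separated;
#'     a header line starting with `x` is skipped). Radius r becomes box
#'     size w = h = 2r.}
#'   \item{box}{EMAN rows `corner_x corner_y box_w box_h`; the corner is
#'     the top-left in row-down image coordinates, so the center is
#'     corner + box/2.}
#'   \item{star}{RELION coordinate table: `_rlnCoordinateX`/`_rlnCoordinateY`
#'     columns of the first `loop_` block.}
#' }
#'
#' @param path Coordinate file.
#' @param dialect `"tsv"`, `"box"` or `"star"`.
#' @param image_height Accepted for interface compatibility with
#'   bottom-up coordinate conventions; unused (all dialects are read
#'   row-down).
#' @param coordinate_space Declared space of the coordinates.
#' @return An [annotation_set].
#' @export
read_coordinates <- function(path, dialect = c("tsv", "box", "star"),
                             image_height = NULL,
                             coordinate_space = "original") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  switch(dialect,
         tsv = read_coords_tsv(lines, path, coordinate_space),
         box = read_coords_box(lines, path, coordinate_space),
         star = read_coords_star(lines, path, coordinate_space))
}

parse_num_rows <- function(lines, path, min_fields) {
  keep <- which(nzchar(trimws(lines)))
  rows <- list()
  for (i in keep) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v) & f != "NA") || length(v) < min_fields ||
        anyNA(v[seq_len(min_fields)]))
      stop(sprintf("%s: malformed row at line %d", path, i))
    rows[[length(rows) + 1L]] <- v
  }
  rows
}

read_coords_tsv <- function(lines, path, space) {
  # skip an optional header line starting with "x"
  if (length(lines) > 0 && grepl("^\\s*x\\b", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  rows <- parse_num_rows(lines, path, 2L)
  if (length(rows) == 0)
    return(annotation_set(micrograph_ref = path, coordinate_space = space))
  x <- vapply(rows, `[`, 0, 1)
  y <- vapply(rows, `[`, 0, 2)
  score <- vapply(rows, function(r) if (length(r) >= 3) r[3] else NA_real_, 0)
  rad <- vapply(rows, function(r) if (length(r) >= 4) r[4] else NA_real_, 0)
  annotation_set(x = x, y = y, score = score,
                 w = 2 * rad, h = 2 * rad,
                 micrograph_ref = path, coordinate_space = space)
}

read_coords_box <- function(lines, path, space) {
  rows <- parse_num_rows(lines, path, 4L)
  if (length(rows) == 0)
    return(annotation_set(micrograph_ref = path, coordinate_space = space))
  cx <- vapply(rows, `[`, 0, 1); cy <- vapply(rows, `[`, 0, 2)
  bw <- vapply(rows, `[`, 0, 3); bh <- vapply(rows, `[`, 0, 4)
  if (any(bw <= 0 | bh <= 0))
    stop(path, ": BOX rows must have positive box sizes")
  annotation_set(x = cx + bw / 2, y = cy + bh / 2, w = bw, h = bh,
                 micrograph_ref = path, coordinate_space = space)
}

read_coords_star <- function(lines, path, space) {
  loop_at <- grep("^\\s*loop_", lines)
  if (length(loop_at) == 0) stop(path, ": no loop_ block in STAR file")
  i <- loop_at[1] + 1L
  cols <- character(0)
  while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
    tag <- sub("\\s*#.*$", "", trimws(lines[i]))
    cols <- c(cols, tag)
    i <- i + 1L
  }
  xi <- match("_rlnCoordinateX", cols)
  yi <- match("_rlnCoordinateY", cols)
  if (is.na(xi) || is.na(yi))
    stop(path, ": STAR loop lacks _rlnCoordinateX/_rlnCoordinateY")
  x <- numeric(0); y <- numeric(0)
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^data_|^loop_", ln)) break
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (length(f) < length(cols))
      stop(sprintf("%s: malformed row at line %d", path, i))
    vx <- suppressWarnings(as.numeric(f[xi]))
    vy <- suppressWarnings(as.numeric(f[yi]))
    if (is.na(vx) || is.na(vy))
      stop(sprintf("%s: malformed row at line %d", path, i))
    x <- c(x, vx); y <- c(y, vy)
    i <- i + 1L
  }
  annotation_set(x = x, y = y, micrograph_ref = path,
                 coordinate_space = space)
}

#' Write particle coordinates
#'
#' @param ann An [annotation_set].
#' @param path Destination file.
#' @param dialect `"tsv"` (header `x y score radius`; radius = w/2),
#'   `"box"` (corner = center - box/2; sizes required) or `"star"`.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(ann, path, dialect = c("tsv", "box", "star")) {
  dialect <- match.arg(dialect)
  rec <- ann_records(ann)
  if (dialect == "tsv") {
    rad <- rec$w / 2
    lines <- c("x\ty\tscore\tradius",
               sprintf("%.6f\t%.6f\t%s\t%s", rec$x, rec$y,
                       ifelse(is.na(rec$score), "NA",
                              sprintf("%.6f", rec$score)),
                       ifelse(is.na(rad), "NA", sprintf("%.6f", rad))))
  } else if (dialect == "box") {
    if (anyNA(rec$w) || anyNA(rec$h))
      stop("BOX output requires box sizes on every record")
    lines <- sprintf("%.2f\t%.2f\t%.2f\t%.2f",
                     rec$x - rec$w / 2, rec$y - rec$h / 2, rec$w, rec$h)
  } else {
    lines <- c("", "data_", "", "loop_",
               "_rlnCoordinateX #1", "_rlnCoordinateY #2",
               sprintf("%12.6f %12.6f", rec$x, rec$y))
  }
  writeLines(lines, path)
  invisible(path)
}
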