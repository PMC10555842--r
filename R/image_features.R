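#' Integer bounding box of a contour
#'
#' Floor of the minimum and ceiling of the maximum coordinate in x and
#' y; degenerate boxes are widened to at least 1 px.
#'
#' @param contour Two-column matrix (x, y) of vertices, >= 1 row.
#' @return Named integer vector `c(x0, y0, x1, y1)`.
#' @export
bounding_box <- function(contour) {
  contour <- as.matrix(contour)
  if (!nrow(contour)) stop("contour has no vertices", call. = FALSE)
  x0 <- floor(min(contour[, 1])); x1 <- ceiling(max(contour[, 1]))
  y0 <- floor(min(contour[, 2])); y1 <- ceiling(max(contour[, 2]))
  if (x1 <= x0) x1 <- x0 + 1
  if (y1 <= y0) y1 <- y0 + 1
  c(x0 = as.integer(x0), y0 = as.integer(y0),
    x1 = as.integer(x1), y1 = as.integer(y1))
}

#' Expand a bounding box to capture the surrounding environment
#'
#' Adds `offset_px` to each side and clamps the result to the image
#' bounds; the default offset of 1000 px captures the tissue context
#' around a shape.
#'
#' @param box `c(x0, y0, x1, y1)` as from [bounding_box()].
#' @param offset_px Expansion per side (default 1000).
#' @param image_bounds `c(width, height)` in pixels; the box is
#'   clamped to `[0, width] x [0, height]`.
#' @return Expanded, clamped integer box.
#' @export
offset_box <- function(box, offset_px = 1000, image_bounds) {
  out <- c(
    x0 = max(0L, as.integer(box[[1]] - offset_px)),
    y0 = max(0L, as.integer(box[[2]] - offset_px)),
    x1 = min(as.integer(image_bounds[1]), as.integer(box[[3]] + offset_px)),
    y1 = min(as.integer(image_bounds[2]), as.integer(box[[4]] + offset_px))
  )
  out
}

#' Shape area from a contour polygon
#'
#' Absolute shoelace area of the vertex polygon, converted to square
#' micrometre through the pixel size.
#'
#' @param contour Two-column matrix (x, y), >= 3 vertices.
#' @param pixel_size Micrometre per pixel (default 1, i.e. contour
#'   already in micrometre).
#' @return Area in square micrometre.
#' @export
shape_area <- function(contour, pixel_size = 1) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) stop("contour needs >= 3 vertices", call. = FALSE)
  x <- contour[, 1]; y <- contour[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * abs(sum(x * yn - xn * y)) * pixel_size^2
}

# Even-odd point-in-polygon test for the masked feature variant.
points_in_polygon <- function(px, py, contour) {
  vx <- contour[, 1]; vy <- contour[, 2]
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & px < xint)
    j <- i
  }
  inside
}

#' Canonical names of the 17 image features
#'
#' Channels ascend by wavelength (425, 488, 568, 647 nm); per channel
#' the statistics are mean, median, min, max; the shape area comes
#' last.
#' @return Character vector of length 17.
#' @export
feature_names <- function() {
  c(as.vector(t(outer(c("ch425", "ch488", "ch568", "ch647"),
                      c("mean", "median", "min", "max"), paste, sep = "_"))),
    "area_um2")
}

#' Extract the 17-feature vector of a cell
#'
#' Per-channel summary statistics (mean, median, min, max) over all
#' pixels of the shape's bounding box in each of the four stain
#' channels, plus the shape area: 4 x 4 + 1 = 17 features. By default
#' the statistics run over the full bounding box, including the
#' surrounding pixels; `mask_to_polygon = TRUE` restricts them to
#' pixels inside the contour.
#'
#' @param patch 3-dimensional array `height x width x 4` covering the
#'   bounding box, channels ordered 425, 488, 568, 647.
#' @param contour Two-column vertex matrix used for the area (and the
#'   mask when requested), in the patch's pixel coordinates.
#' @param pixel_size Micrometre per pixel for the area (default 1).
#' @param mask_to_polygon Restrict statistics to in-polygon pixels
#'   (default FALSE).
#' @return Named numeric vector of length 17 (see [feature_names()]).
#' @export
extract_features <- function(patch, contour, pixel_size = 1,
                             mask_to_polygon = FALSE) {
  if (length(dim(patch)) != 3 || dim(patch)[3] != 4) {
    stop("patch must be a height x width x 4 array", call. = FALSE)
  }
  if (mask_to_polygon) {
    grid <- expand.grid(y = seq_len(dim(patch)[1]) - 0.5,
                        x = seq_len(dim(patch)[2]) - 0.5)
    sel <- points_in_polygon(grid$x, grid$y, as.matrix(contour))
    if (!any(sel)) sel <- rep(TRUE, nrow(grid))
  }
  vals <- numeric(0)
  for (ch in 1:4) {
    px <- as.vector(patch[, , ch])
    if (mask_to_polygon) px <- px[sel]
    vals <- c(vals, mean(px), stats::median(px), min(px), max(px))
  }
  out <- c(vals, shape_area(contour, pixel_size))
  names(out) <- feature_names()
  out
}

#' Decimate a contour to a fraction of its vertices
#'
#' Uniform decimation: keeps every `ceil(1 / (1 - remove_fraction))`-th
#' vertex starting at the first, so a `remove_fraction` of 0.99 keeps
#' 1 in 100 vertices. If fewer than 3 vertices would remain, 3 evenly
#' spaced vertices are kept instead (with a warning).
#'
#' @param contour Two-column vertex matrix.
#' @param remove_fraction Fraction of vertices to drop, in `[0, 1)`
#'   (default 0.99).
#' @return List: `contour` (the retained vertices, a subsequence of
#'   the input), `removed_fraction` (realized).
#' @export
simplify_contour <- function(contour, remove_fraction = 0.99) {
  contour <- as.matrix(contour)
  n <- nrow(contour)
  if (remove_fraction < 0 || remove_fraction >= 1) {
    stop("remove_fraction must be in [0, 1)", call. = FALSE)
  }
  step <- ceiling(1 / (1 - remove_fraction))
  keep <- seq.int(1L, n, by = step)
  if (length(keep) < 3) {
    warning("decimation would leave < 3 vertices; keeping 3 evenly ",
            "spaced vertices", call. = FALSE)
    keep <- unique(round(seq(1, n, length.out = 4)[1:3]))
    keep <- keep[keep <= n]
    if (length(keep) < 3) keep <- seq_len(min(3L, n))
  }
  list(contour = contour[keep, , drop = FALSE],
       removed_fraction = 1 - length(keep) / n)
}

#' Distances from a centroid to the nearest PV and CV landmarks
#'
#' Euclidean distance to the nearest portal-vein landmark and the
#' nearest central-vein landmark of a lobule geometry.
#'
#' @param centroid `c(x, y)` in micrometre.
#' @param geometry A [lobule_geometry()].
#' @return Named numeric `c(d_pv, d_cv)` in micrometre.
#' @export
landmark_distances <- function(centroid, geometry) {
  nearest <- function(landmarks) {
    d <- sqrt((landmarks[, 1] - centroid[1])^2 +
              (landmarks[, 2] - centroid[2])^2)
    min(d)
  }
  if (!nrow(geometry$pv) || !nrow(geometry$cv)) {
    stop("geometry needs at least one PV and one CV landmark", call. = FALSE)
  }
  c(d_pv = nearest(geometry$pv), d_cv = nearest(geometry$cv))
}
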