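#' Rotate a segmented movie so a given axis maps to the horizontal
#'
#' Aligns a movie to the anterior-posterior (AP) axis before scaled
#' average cell analysis. Every frame is rotated about the image centre by
#' `-axis_angle`; the label stack with nearest-neighbour sampling (labels
#' stay integers), the intensity channels with bilinear interpolation.
#' Pixels rotated in from outside the frame are 0.
#'
#' @param movie a `segmented_movie` (see [render_cell_movie()]).
#' @param axis_angle angle of the AP axis in radians, counter-clockwise
#'   from horizontal; defaults to the angle stored in the movie.
#' @return the aligned `segmented_movie` (with `axis_angle = 0`).
#' @export
align_to_axis <- function(movie, axis_angle = movie$axis_angle) {
  stopifnot(inherits(movie, "segmented_movie"))
  if (axis_angle == 0) return(movie)
  nt <- dim(movie$labels)[3L]
  for (f in seq_len(nt)) {
    movie$labels[, , f] <- rotate_image(movie$labels[, , f], -axis_angle,
                                        bilinear = FALSE)
    for (ch in names(movie$channels))
      movie$channels[[ch]][, , f] <-
        rotate_image(movie$channels[[ch]][, , f], -axis_angle,
                     bilinear = TRUE)
  }
  movie$axis_angle <- 0
  movie
}

# rotate a [y, x] matrix counter-clockwise by `theta` about the image
# centre, by inverse mapping; nearest-neighbour or bilinear sampling
rotate_image <- function(img, theta, bilinear = TRUE) {
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr - 1) / 2; cx <- (nc - 1) / 2
  xs <- matrix(rep(0:(nc - 1L), each = nr), nr, nc) - cx
  ys <- matrix(rep(0:(nr - 1L), times = nc), nr, nc) - cy
  # inverse rotation of the output grid into source coordinates
  # (y axis points down, so a CCW rotation in conventional axes is CW in
  # raster axes; the convention only needs to be self-consistent)
  ct <- cos(theta); st <- sin(theta)
  sx <- ct * xs + st * ys + cx
  sy <- -st * xs + ct * ys + cy
  sample_image(img, sx, sy, bilinear)
}

# sample img ([y, x], 0-based coords) at (sx, sy); out of bounds -> 0
sample_image <- function(img, sx, sy, bilinear = TRUE) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nrow(sx), ncol(sx))
  if (!bilinear) {
    xi <- round(sx); yi <- round(sy)
    ok <- xi >= 0 & xi <= nc - 1L & yi >= 0 & yi <= nr - 1L
    out[ok] <- img[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    return(out)
  }
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- x0 >= 0 & x0 <= nc - 2L & y0 >= 0 & y0 <= nr - 2L
  # clamp the one-past-edge case so exact right/bottom borders sample
  edge_x <- x0 == nc - 1L & abs(fx) < 1e-9
  edge_y <- y0 == nr - 1L & abs(fy) < 1e-9
  ok <- ok | (edge_x & y0 >= 0 & y0 <= nr - 2L) |
    (edge_y & x0 >= 0 & x0 <= nc - 2L) | (edge_x & edge_y)
  x0[edge_x] <- nc - 2L; fx[edge_x] <- 1
  y0[edge_y] <- nr - 2L; fy[edge_y] <- 1
  i <- which(ok)
  if (length(i)) {
    y1 <- y0[i] + 1L; x1 <- x0[i] + 1L
    v00 <- img[cbind(y1, x1)]; v01 <- img[cbind(y1, x1 + 1L)]
    v10 <- img[cbind(y1 + 1L, x1)]; v11 <- img[cbind(y1 + 1L, x1 + 1L)]
    out[i] <- v00 * (1 - fx[i]) * (1 - fy[i]) + v01 * fx[i] * (1 - fy[i]) +
      v10 * (1 - fx[i]) * fy[i] + v11 * fx[i] * fy[i]
  }
  out
}

#' Radial boundary contour of a single cell
#'
#' From the cell centroid (or a supplied centre), marches a supersampled
#' ray (step 0.25 px) at each angle and records the distance to the last
#' in-mask sample: the cell boundary position r(theta). Rays that re-enter
#' the mask after leaving it (strongly non-convex cells) are counted in
#' the `n_reentrant` field.
#'
#' @param mask logical or 0/1 matrix ([y, x]) of one cell.
#' @param center optional c(x, y) centre, 0-based pixels; defaults to the
#'   mask centroid, which must lie inside the mask.
#' @param n_angles number of angular bins over [0, 2 pi).
#' @param pixel_size micrometres per pixel.
#' @param step ray-marching step, pixels.
#' @return list of class `radial_contour`: `angles` (radians), `r_um`,
#'   `r_px`, `center`, `n_reentrant`.
#' @export
radial_contour <- function(mask, center = NULL, n_angles = 360L,
                           pixel_size = 1, step = 0.25) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  if (is.null(center)) {
    idx <- which(mask, arr.ind = TRUE)
    if (!nrow(idx)) stop("empty mask")
    center <- c(mean(idx[, 2L]) - 1, mean(idx[, 1L]) - 1)  # (x, y)
  }
  ci <- round(center) + 1L
  if (ci[2L] < 1L || ci[2L] > nr || ci[1L] < 1L || ci[1L] > nc ||
      !mask[ci[2L], ci[1L]])
    stop("`center` falls outside the mask")
  angles <- (0:(n_angles - 1L)) * 2 * pi / n_angles
  rmax_img <- sqrt(nr^2 + nc^2)
  r_px <- numeric(n_angles); reentrant <- logical(n_angles)
  rr <- seq(step, rmax_img, by = step)
  mnum <- matrix(as.numeric(mask), nr, nc)
  for (a in seq_len(n_angles)) {
    xs <- center[1L] + rr * cos(angles[a])
    ys <- center[2L] + rr * sin(angles[a])
    inb <- xs >= 0 & xs <= nc - 1L & ys >= 0 & ys <= nr - 1L
    last_inb <- if (any(inb)) max(which(inb)) else 0L
    if (!last_inb) stop("ray leaves the image immediately")
    # bilinear interpolation of the mask gives a sub-pixel boundary
    # estimate: the crossing of the 0.5 level
    val <- numeric(length(rr))
    val[inb] <- sample_image(mnum, matrix(xs[inb], 1L), matrix(ys[inb], 1L),
                             bilinear = TRUE)
    inmask <- val >= 0.5
    last <- if (any(inmask)) max(which(inmask)) else 0L
    if (last == last_inb && last_inb < length(rr))
      stop("mask touches the image border along a ray; cannot locate boundary")
    if (last) {
      r_px[a] <- if (last < length(rr)) {
        drop <- val[last] - val[last + 1L]
        rr[last] + step * (val[last] - 0.5) / max(drop, 1e-12)
      } else rr[last]
    } else r_px[a] <- step / 2
    runs <- rle(inmask[seq_len(max(last, 1L))])
    reentrant[a] <- sum(runs$values) > 1L
  }
  structure(list(angles = angles, r_um = r_px * pixel_size, r_px = r_px,
                 center = center, n_reentrant = sum(reentrant)),
            class = "radial_contour")
}

#' Morphological top-hat background removal
#'
#' White top-hat filtering with a disc structuring element (rolling-ball
#' background subtraction): removes any structure wider than the disc,
#' keeping puncta and thin junctional signal. Output is non-negative.
#'
#' @param image intensity matrix.
#' @param radius disc radius in pixels (default 50).
#' @return background-subtracted matrix of the same size.
#' @export
tophat_background <- function(image, radius = 50) {
  stopifnot(radius >= 1)
  r <- as.integer(radius)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  # replicate-pad so the erosion does not see an artificial zero border
  nr <- nrow(image); nc <- ncol(image)
  ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  padded <- image[ri, ci]
  # grayscale morphology clamps to [0, 1]: rescale around the filter
  lo <- min(padded); hi <- max(padded)
  if (hi > lo) {
    out <- EBImage::whiteTopHat((padded - lo) / (hi - lo), brush)
    out <- as.matrix(out) * (hi - lo)
  } else out <- matrix(0, nrow(padded), ncol(padded))
  pmax(out[r + seq_len(nr), r + seq_len(nc)], 0)
}

#' Shape-normalised radial intensity profile of one cell
#'
#' Samples a (background-subtracted) channel along each ray of a
#' [radial_contour()] at `n_radial` evenly spaced fractions of that ray's
#' own centroid-boundary distance (bilinear interpolation). Radius 0 is
#' the centroid, radius 1 the boundary; cell shape is divided out, so
#' cells of different sizes and outlines become comparable.
#'
#' @param channel intensity matrix ([y, x]).
#' @param contour a [radial_contour()] of the cell.
#' @param n_radial number of radial samples over [0, 1].
#' @return `n_angles x n_radial` intensity matrix (rows = angles).
#' @export
scaled_cell_profile <- function(channel, contour, n_radial = 100L) {
  stopifnot(inherits(contour, "radial_contour"), n_radial >= 2L)
  fr <- seq(0, 1, length.out = n_radial)
  na <- length(contour$angles)
  sx <- matrix(0, na, n_radial); sy <- matrix(0, na, n_radial)
  for (a in seq_len(na)) {
    d <- fr * contour$r_px[a]
    sx[a, ] <- contour$center[1L] + d * cos(contour$angles[a])
    sy[a, ] <- contour$center[2L] + d * sin(contour$angles[a])
  }
  sample_image(channel, sx, sy, bilinear = TRUE)
}

#' Scaled average cell (SAC)
#'
#' Averages shape-normalised radial profiles over a set of cells (many
#' cells at one time point, or one cell over time): per-angle mean contour
#' radius and the mean angle x radius intensity map per channel.
#'
#' @param cells list of cells, each a list with elements `mask` (single
#'   cell binary matrix), `channels` (named list of intensity matrices),
#'   and optional `center` c(x, y).
#' @param n_angles,n_radial map resolution (defaults 360 x 100).
#' @param pixel_size micrometres per pixel.
#' @return object of class `scaled_average_cell`: `angles`, `radii`,
#'   `intensity` (named list of angle x radius matrices), `mean_contour`
#'   (um per angle), `n_cells`.
#' @export
scaled_average_cell <- function(cells, n_angles = 360L, n_radial = 100L,
                                pixel_size = 1) {
  stopifnot(length(cells) >= 1L)
  ch_names <- names(cells[[1L]]$channels)
  maps <- stats::setNames(
    lapply(ch_names, function(x) matrix(0, n_angles, n_radial)), ch_names)
  contour_sum <- numeric(n_angles)
  for (cell in cells) {
    ct <- radial_contour(cell$mask, center = cell$center,
                         n_angles = n_angles, pixel_size = pixel_size)
    contour_sum <- contour_sum + ct$r_um
    for (ch in ch_names)
      maps[[ch]] <- maps[[ch]] +
        scaled_cell_profile(cell$channels[[ch]], ct, n_radial = n_radial)
  }
  n <- length(cells)
  structure(list(angles = (0:(n_angles - 1L)) * 2 * pi / n_angles,
                 radii = seq(0, 1, length.out = n_radial),
                 intensity = lapply(maps, function(m) m / n),
                 mean_contour = contour_sum / n, n_cells = n),
            class = "scaled_average_cell")
}

#' @export
print.scaled_average_cell <- function(x, ...) {
  cat(sprintf(
    "<scaled_average_cell> %d cells, %d angles x %d radii; channels: %s\n",
    x$n_cells, length(x$angles), length(x$radii),
    paste(names(x$intensity), collapse = ", ")))
  invisible(x)
}

#' Split a movie frame into per-cell SAC inputs
#'
#' Convenience extractor: builds the `cells` list consumed by
#' [scaled_average_cell()] from one frame of a segmented movie, applying
#' optional top-hat background removal to each channel first.
#'
#' @param movie a `segmented_movie`.
#' @param frame frame index.
#' @param tophat_radius disc radius for [tophat_background()]; `NULL`
#'   disables background removal.
#' @param min_area cells smaller than this (pixels) are skipped.
#' @return list of cells (mask + channels), suitable for
#'   [scaled_average_cell()].
#' @export
movie_frame_cells <- function(movie, frame = 1L, tophat_radius = 50,
                              min_area = 50L) {
  stopifnot(inherits(movie, "segmented_movie"))
  lab <- movie$labels[, , frame]
  chans <- lapply(movie$channels, function(ch) ch[, , frame])
  if (!is.null(tophat_radius))
    chans <- lapply(chans, tophat_background, radius = tophat_radius)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  cells <- list()
  for (id in ids) {
    mask <- lab == id
    if (sum(mask) < min_area) next
    cells[[length(cells) + 1L]] <- list(mask = mask, channels = chans,
                                        id = id)
  }
  cells
}
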