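#' Cell outline (segmented junction) mask
#'
#' The junction pixels of a cell mask: in-mask pixels whose Euclidean
#' distance to the outside is at most `width` (computed on the distance
#' transform of the mask).
#'
#' @param mask binary cell mask.
#' @param width band width in pixels (inclusive).
#' @return logical matrix.
#' @export
cell_outline_mask <- function(mask, width = 1) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  d <- EBImage::distmap(m)
  mask != 0 & as.matrix(d) <= width
}

#' Mean intensity along a junction path
#'
#' Rasterises a junction polyline, dilates it to the requested width with
#' a box structuring element, and returns the mean channel intensity over
#' the resulting band — e.g. myosin within a 3-pixel-wide path following
#' the junction.
#'
#' @param channel intensity matrix ([y, x]).
#' @param path a [junction_polyline()] (um) or two-column matrix of pixel
#'   coordinates.
#' @param width band width in pixels (odd; default 3).
#' @param pixel_size micrometres per pixel used to convert `path`.
#' @return mean intensity over the band.
#' @export
junctional_intensity <- function(channel, path, width = 3L, pixel_size = 1) {
  pts <- if (inherits(path, "junction_polyline"))
    path$points / pixel_size else as.matrix(path)
  if (!nrow(pts)) stop("empty junction path")
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) stop("`width` must be odd and >= 1")
  mask <- rasterize_path(pts, nrow(channel), ncol(channel))
  if (!any(mask)) stop("junction path falls outside the image")
  if (width > 1L) {
    mask <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                            EBImage::makeBrush(width, shape = "box"))
    mask <- as.matrix(mask) > 0
  }
  mean(channel[mask])
}

# rasterise a polyline (0-based pixel coords) into a logical matrix by
# supersampling each segment at 0.25 px
rasterize_path <- function(pts, nr, nc) {
  mask <- matrix(FALSE, nr, nc)
  if (nrow(pts) == 1L) {
    x <- round(pts[1L, 1L]); y <- round(pts[1L, 2L])
    if (x >= 0 && x < nc && y >= 0 && y < nr) mask[y + 1L, x + 1L] <- TRUE
    return(mask)
  }
  for (k in seq_len(nrow(pts) - 1L)) {
    d <- sqrt(sum((pts[k + 1L, ] - pts[k, ])^2))
    n <- max(2L, ceiling(d / 0.25) + 1L)
    xs <- round(seq(pts[k, 1L], pts[k + 1L, 1L], length.out = n))
    ys <- round(seq(pts[k, 2L], pts[k + 1L, 2L], length.out = n))
    ok <- xs >= 0 & xs < nc & ys >= 0 & ys < nr
    mask[cbind(ys[ok] + 1L, xs[ok] + 1L)] <- TRUE
  }
  mask
}

#' Junctional-to-medial intensity ratio of a cell
#'
#' Partitions a cell into a junctional region (within `margin` pixels of
#' the segmented junction) and a medial region (farther than `margin`) and
#' returns the ratio of mean intensities. This is the summary used to
#' compare myosin partitioning across conditions (stretched and E-cadherin
#' knockdown cells shift it up; E-cadherin overexpression shifts it down).
#'
#' @param channel intensity matrix.
#' @param cell_mask binary mask of the cell.
#' @param junction_mask binary mask of the junction pixels; defaults to
#'   the cell outline ([cell_outline_mask()]).
#' @param margin distance threshold in pixels (default 3).
#' @param cap ratio returned (with attribute `capped = TRUE`) when the
#'   medial mean is zero.
#' @return the ratio (scalar), possibly with attribute `capped`.
#' @export
junction_medial_ratio <- function(channel, cell_mask, junction_mask = NULL,
                                  margin = 3, cap = 1e6) {
  cell_mask <- cell_mask != 0
  if (is.null(junction_mask)) junction_mask <- cell_outline_mask(cell_mask)
  jm <- matrix(as.numeric(!(junction_mask != 0)), nrow(channel), ncol(channel))
  d <- as.matrix(EBImage::distmap(jm))  # distance to nearest junction pixel
  junctional <- cell_mask & d <= margin
  medial <- cell_mask & d > margin
  if (!any(medial)) stop("medial region empty: cell too small for this margin")
  if (!any(junctional)) stop("junctional region empty")
  mj <- mean(channel[junctional]); mm <- mean(channel[medial])
  if (mm <= 0) {
    out <- cap
    attr(out, "capped") <- TRUE
    return(out)
  }
  mj / mm
}

#' Mean junctional-to-medial ratio over the cells of a movie frame
#'
#' Applies [junction_medial_ratio()] to every cell of one frame of a
#' segmented movie (after optional top-hat background removal) and
#' averages the per-cell ratios.
#'
#' @param movie a `segmented_movie`.
#' @param channel channel name (default `"myosin"`).
#' @param frame frame index.
#' @param margin distance threshold in pixels.
#' @param tophat_radius background-removal disc radius; `NULL` to skip.
#' @return list with `mean_ratio`, `ratios` (per cell), `n_cells`.
#' @export
movie_junction_medial_ratio <- function(movie, channel = "myosin",
                                        frame = 1L, margin = 3,
                                        tophat_radius = 50) {
  cells <- movie_frame_cells(movie, frame = frame,
                             tophat_radius = tophat_radius)
  ratios <- vapply(cells, function(cell) {
    as.numeric(junction_medial_ratio(cell$channels[[channel]], cell$mask,
                                     margin = margin))
  }, numeric(1L))
  list(mean_ratio = mean(ratios), ratios = ratios, n_cells = length(cells))
}

#' Paired boundary-pixel intensities of two channels
#'
#' Extracts, for one cell, the pixels within `max_dist` of the cell edge
#' (inclusive, on the Euclidean distance transform), normalises each
#' channel by its cell-centre reference (mean in a disc of radius
#' `ref_radius` at the centroid), and returns the paired values — the
#' substrate for the junctional E-cadherin versus myosin association plot
#' — together with binned means and the sample correlation.
#'
#' @param channel_a,channel_b intensity matrices (e.g. cadherin, myosin).
#' @param cell_mask binary mask of the cell.
#' @param max_dist boundary distance threshold, pixels (default 1.5).
#' @param ref_radius cell-centre normalisation disc radius, pixels.
#' @param n_bins number of bins of channel A for the binned means.
#' @return list with `pairs` (data.frame `a`, `b`), `binned` (`a_center`,
#'   `mean_b`, `se_b`, `n`), and `correlation`.
#' @export
boundary_pixel_pairs <- function(channel_a, channel_b, cell_mask,
                                 max_dist = 1.5, ref_radius = 3,
                                 n_bins = 8L) {
  cell_mask <- cell_mask != 0
  m <- matrix(as.numeric(cell_mask), nrow(cell_mask), ncol(cell_mask))
  d <- as.matrix(EBImage::distmap(m))
  boundary <- cell_mask & d <= max_dist
  if (!any(boundary)) stop("no boundary pixels at this distance threshold")
  idx <- which(cell_mask, arr.ind = TRUE)
  center <- c(mean(idx[, 2L]) - 1, mean(idx[, 1L]) - 1)
  ref <- function(ch) {
    xs <- matrix(rep(0:(ncol(ch) - 1L), each = nrow(ch)), nrow(ch))
    ys <- matrix(rep(0:(nrow(ch) - 1L), times = ncol(ch)), nrow(ch))
    disc <- (xs - center[1L])^2 + (ys - center[2L])^2 <= ref_radius^2
    v <- mean(ch[disc & cell_mask])
    if (!is.finite(v) || v <= 0) 1 else v
  }
  a <- channel_a[boundary] / ref(channel_a)
  b <- channel_b[boundary] / ref(channel_b)
  br <- cut(a, breaks = n_bins)
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  binned <- do.call(rbind, lapply(split(data.frame(a, b), br), function(dd) {
    if (!nrow(dd)) return(NULL)
    data.frame(a_center = mean(dd$a), mean_b = mean(dd$b),
               se_b = sem(dd$b), n = nrow(dd))
  }))
  rownames(binned) <- NULL
  list(pairs = data.frame(a = a, b = b), binned = binned,
       correlation = if (stats::sd(a) > 0 && stats::sd(b) > 0)
         stats::cor(a, b) else NA_real_)
}

#' Kymograph of a channel stack within a box
#'
#' For each frame, averages the intensity horizontally across the box and
#' stacks the resulting vertical profiles as columns: a position x time
#' image in which moving structures appear as oblique ridges.
#'
#' @param stack 3D array ([y, x, t]).
#' @param box integer vector `c(x0, x1, y0, y1)` of 0-based inclusive
#'   pixel bounds.
#' @return matrix with one row per y position in the box and one column
#'   per frame.
#' @export
kymograph <- function(stack, box) {
  stopifnot(length(dim(stack)) == 3L, length(box) == 4L)
  x0 <- box[1L] + 1L; x1 <- box[2L] + 1L
  y0 <- box[3L] + 1L; y1 <- box[4L] + 1L
  if (x0 < 1L || y0 < 1L || x1 > dim(stack)[2L] || y1 > dim(stack)[1L] ||
      x1 < x0 || y1 < y0)
    stop("`box` must be a non-empty rectangle inside the image")
  nt <- dim(stack)[3L]
  out <- matrix(0, y1 - y0 + 1L, nt)
  for (f in seq_len(nt))
    out[, f] <- rowMeans(matrix(stack[y0:y1, x0:x1, f], y1 - y0 + 1L))
  out
}
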