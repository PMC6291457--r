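#' Configuration for the synthetic movie generator
#'
#' Bundles the imaging and phenotype parameters used by
#' [render_cell_movie()]. Phenotypes emulate the qualitative regimes seen
#' in amnioserosa imaging:
#' \describe{
#'   \item{wt_pulsatile}{straight junctions (s ~ 0.95); drifting medial
#'     myosin foci with sinusoidal intensity and a periodic cell-area
#'     oscillation; moderate junctional myosin.}
#'   \item{stretched}{straight junctions, static area, punctate junctional
#'     myosin, no medial foci.}
#'   \item{rab5dn}{ruffled junctions (s ~ 0.8) with persistent medial foci
#'     (endocytosis block: excess junctional material).}
#'   \item{shg_rnai}{low E-cadherin amplitude, junctional myosin, no foci,
#'     static area.}
#'   \item{shg_oe}{high E-cadherin amplitude, ruffled junctions, medial
#'     myosin.}
#' }
#'
#' @param seed integer seed; a fixed seed makes the rendered movie
#'   bit-identical across calls.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval minutes between frames.
#' @param noise_sd Gaussian intensity noise SD (arbitrary units).
#' @param phenotype one of `"wt_pulsatile"`, `"stretched"`, `"rab5dn"`,
#'   `"shg_rnai"`, `"shg_oe"`.
#' @param oscillation_period pulsation period, min (free knob; the medial
#'   pulses have no canonical printed period).
#' @param oscillation_amp fractional area-oscillation amplitude.
#' @param coupling strength in [0, 1] of the local anti-correlation
#'   between junctional myosin puncta and E-cadherin.
#' @param background additive background offset (intensity units).
#' @param uniform_myosin logical; override the myosin channel with a
#'   uniform value inside every cell (control for flat SAC maps).
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, pixel_size = 0.2,
                             frame_interval = 0.5, noise_sd = 0.01,
                             phenotype = c("wt_pulsatile", "stretched",
                                           "rab5dn", "shg_rnai", "shg_oe"),
                             oscillation_period = 4,
                             oscillation_amp = 0.04,
                             coupling = 0.6, background = 0.05,
                             uniform_myosin = FALSE) {
  phenotype <- match.arg(phenotype)
  stopifnot(noise_sd >= 0, frame_interval > 0, pixel_size > 0,
            coupling >= 0, coupling <= 1)
  structure(list(seed = as.integer(seed), pixel_size = pixel_size,
                 frame_interval = frame_interval, noise_sd = noise_sd,
                 phenotype = phenotype,
                 oscillation_period = oscillation_period,
                 oscillation_amp = oscillation_amp,
                 coupling = coupling, background = background,
                 uniform_myosin = uniform_myosin),
            class = "generator_config")
}

# phenotype recipe: target junction straightness, myosin partition
# (fraction of the per-cell myosin budget deposited junctionally),
# medial foci behaviour and E-cadherin amplitude
phenotype_recipe <- function(phenotype) {
  switch(phenotype,
    wt_pulsatile = list(s = 0.95, phi_j = 0.30, foci = "pulsatile",
                        cad_amp = 1.0, oscillate = TRUE),
    stretched    = list(s = 0.95, phi_j = 0.80, foci = "none",
                        cad_amp = 1.0, oscillate = FALSE),
    rab5dn       = list(s = 0.80, phi_j = 0.35, foci = "persistent",
                        cad_amp = 1.0, oscillate = TRUE),
    shg_rnai     = list(s = 0.95, phi_j = 0.80, foci = "none",
                        cad_amp = 0.4, oscillate = FALSE),
    shg_oe       = list(s = 0.80, phi_j = 0.15, foci = "persistent",
                        cad_amp = 1.6, oscillate = TRUE))
}

#' Render a synthetic segmented multi-channel cell movie
#'
#' Generates a time-lapse of polygonal cells tiling a rectangular patch,
#' with persistent integer labels, a "myosin" and a "cadherin" intensity
#' channel, and exact ground-truth tables. Cells sit on a jittered grid;
#' every cell-cell and cell-background interface is a ruffled polyline of
#' the phenotype's target straightness (calibrated by
#' [make_ruffled_polyline()]), so junction geometry ground truth is known
#' by construction. Myosin is deposited as a junctional component (puncta
#' and baseline along the cell outline) and a medial component (drifting
#' Gaussian foci of sigma ~ 15% of the cell radius and/or a diffuse pool),
#' in phenotype-specific proportions; E-cadherin lines the junctions with
#' a phenotype-scaled amplitude, locally depressed under myosin puncta by
#' the configured coupling. Intensity images carry a constant background
#' offset plus Gaussian noise.
#'
#' `n_cells` is rounded up to a full `nx x ny` grid so that the patch
#' tiles; the realised count is in the output.
#'
#' @param config a [generator_config()].
#' @param n_cells requested number of cells (>= 1).
#' @param n_frames number of frames (>= 1).
#' @param image_size side of the square image, pixels.
#' @return a list of class `segmented_movie`: `labels` (y, x, t integer
#'   array), `channels` (named list of y, x, t arrays: `myosin`,
#'   `cadherin`), `pixel_size`, `frame_interval`, `axis_angle` (radians; 0
#'   here), `n_cells`, `ground_truth` (list of data.frames `cells`,
#'   `junctions`, `myosin_split`), and `config`.
#' @export
render_cell_movie <- function(config = generator_config(), n_cells = 4L,
                              n_frames = 5L, image_size = 200L) {
  stopifnot(inherits(config, "generator_config"), n_cells >= 1L,
            n_frames >= 1L, image_size >= 40L)
  rec <- phenotype_recipe(config$phenotype)
  with_seed(config$seed,
            render_movie_impl(config, rec, n_cells, n_frames, image_size))
}

render_movie_impl <- function(config, rec, n_cells, n_frames, image_size) {
  S <- as.integer(image_size)
  nx <- ceiling(sqrt(n_cells)); ny <- ceiling(n_cells / nx)
  n_cells <- nx * ny
  margin <- ceiling(0.10 * S)
  wx <- (S - 1 - 2 * margin) / nx; wy <- (S - 1 - 2 * margin) / ny
  if (min(wx, wy) < 12)
    stop("cells would be degenerate: too many cells for this image size")

  # jittered mesh nodes (0-based pixel coordinates), interior nodes only
  nodes <- array(0, dim = c(nx + 1L, ny + 1L, 2L))
  jit <- 0.12 * min(wx, wy)
  for (i in 0:nx) for (j in 0:ny) {
    p <- c(margin + i * wx, margin + j * wy)
    if (i > 0 && i < nx) p[1] <- p[1] + stats::runif(1, -jit, jit)
    if (j > 0 && j < ny) p[2] <- p[2] + stats::runif(1, -jit, jit)
    nodes[i + 1L, j + 1L, ] <- p
  }

  # ruffled edge polylines between adjacent nodes, shared between cells
  edge_key <- function(i1, j1, i2, j2) paste(i1, j1, i2, j2, sep = ".")
  edges <- list(); ekey <- 0L
  for (i in 0:nx) for (j in 0:ny) {
    for (d in list(c(1L, 0L), c(0L, 1L))) {
      i2 <- i + d[1L]; j2 <- j + d[2L]
      if (i2 > nx || j2 > ny) next
      p <- nodes[i + 1L, j + 1L, ]; q <- nodes[i2 + 1L, j2 + 1L, ]
      dv <- sqrt(sum((q - p)^2))
      ekey <- ekey + 1L
      # hull edges border the background, not another cell: keep straight
      interior <- if (d[1L] == 1L) (j > 0 && j < ny) else (i > 0 && i < nx)
      pl <- make_ruffled_polyline(dv, if (interior) rec$s else 1,
                                  n_modes = 2L,
                                  n_points = max(24L, ceiling(2 * dv)),
                                  seed = stats::runif(1, 1, 2^30))
      u <- (q - p) / dv; nvec <- c(-u[2L], u[1L])
      pts <- pl$points
      world <- cbind(p[1L] + pts[, 1L] * u[1L] + pts[, 2L] * nvec[1L],
                     p[2L] + pts[, 1L] * u[2L] + pts[, 2L] * nvec[2L])
      edges[[edge_key(i, j, i2, j2)]] <- world
      attr(edges[[edge_key(i, j, i2, j2)]], "interior") <- interior
    }
  }

  # cell polygons: four shared ruffled edges, counter-clockwise
  polys <- vector("list", n_cells)
  id <- 0L
  for (j in 0:(ny - 1L)) for (i in 0:(nx - 1L)) {
    id <- id + 1L
    bottom <- edges[[edge_key(i, j, i + 1L, j)]]
    right <- edges[[edge_key(i + 1L, j, i + 1L, j + 1L)]]
    top <- edges[[edge_key(i, j + 1L, i + 1L, j + 1L)]]
    left <- edges[[edge_key(i, j, i, j + 1L)]]
    poly <- rbind(bottom, right[-1L, , drop = FALSE],
                  top[(nrow(top) - 1L):1L, , drop = FALSE],
                  left[(nrow(left) - 1L):2L, , drop = FALSE])
    if (abs(polygon_area(poly)) < 1e-6) stop("degenerate cell polygon")
    polys[[id]] <- poly
  }
  if (any(vapply(polys, function(p) any(p < 0 | p > S - 1), logical(1L))))
    stop("cells overflow the image bounds")

  tissue_center <- c(mean(range(vapply(polys, function(p) mean(p[, 1L]),
                                       numeric(1L)))),
                     mean(range(vapply(polys, function(p) mean(p[, 2L]),
                                       numeric(1L)))))

  # per-cell medial focus state (random walk) and pulse phase
  radius0 <- sqrt(abs(polygon_area(polys[[1L]])) / pi)
  foci_pos <- lapply(polys, function(p) c(mean(p[, 1L]), mean(p[, 2L])))
  phases <- stats::runif(n_cells, 0, 2 * pi)
  n_punct <- 6L
  punct_frac <- lapply(seq_len(n_cells),
                       function(i) stats::runif(n_punct))

  labels <- array(0L, dim = c(S, S, n_frames))
  myo <- array(0, dim = c(S, S, n_frames))
  cad <- array(0, dim = c(S, S, n_frames))
  gt_cells <- list(); gt_split <- list()

  tvec <- (seq_len(n_frames) - 1L) * config$frame_interval
  for (f in seq_len(n_frames)) {
    scale_f <- if (rec$oscillate && config$phenotype == "wt_pulsatile")
      1 + config$oscillation_amp *
        sin(2 * pi * tvec[f] / config$oscillation_period) else 1
    pf <- lapply(polys, function(p) {
      sweep(sweep(p, 2L, tissue_center) * scale_f, 2L, tissue_center, `+`)
    })
    lab <- rasterize_cells(pf, S)
    labels[, , f] <- lab

    myo_f <- matrix(0, S, S); cad_f <- matrix(0, S, S)
    for (ci in seq_len(n_cells)) {
      mask <- lab == ci
      npx <- sum(mask)
      if (!npx) next
      dist_in <- EBImage::distmap(matrix(as.numeric(mask), S, S))
      outline_band <- mask & dist_in <= 1.5
      medial_reg <- mask & !outline_band
      budget <- npx * 0.5

      if (config$uniform_myosin) {
        myo_f[mask] <- myo_f[mask] + 0.5
      } else {
        # junctional pool: baseline along the outline + puncta
        jmap <- matrix(0, S, S)
        jmap[outline_band] <- 1
        poly <- pf[[ci]]
        per <- cumsum(c(0, sqrt(rowSums(diff(poly)^2))))
        at <- punct_frac[[ci]] * per[length(per)]
        pts <- t(vapply(at, function(a) {
          k <- findInterval(a, per, all.inside = TRUE)
          w <- (a - per[k]) / (per[k + 1L] - per[k])
          poly[k, ] * (1 - w) + poly[k + 1L, ] * w
        }, numeric(2L)))
        punct <- gaussian_blobs(S, pts, sigma = 1.5)
        jmap <- jmap + 4 * punct
        jmap[!mask] <- 0
        if (sum(jmap) > 0) jmap <- jmap * (rec$phi_j * budget / sum(jmap))

        # medial pool: drifting focus and/or diffuse pool
        mmap <- matrix(0, S, S)
        if (rec$foci != "none") {
          step <- 0.06 * radius0
          cand <- foci_pos[[ci]] + stats::rnorm(2L, 0, step)
          ctr <- c(mean(poly[, 1L]), mean(poly[, 2L]))
          if (sqrt(sum((cand - ctr)^2)) > 0.5 * radius0) cand <- ctr
          foci_pos[[ci]] <- cand
          amp <- if (rec$foci == "pulsatile")
            0.5 * (1 + sin(2 * pi * tvec[f] / config$oscillation_period +
                             phases[ci])) else 1
          mmap <- amp * gaussian_blobs(S, matrix(cand, 1L),
                                       sigma = 0.15 * radius0)
        }
        mmap[medial_reg] <- mmap[medial_reg] + 0.15
        mmap[!medial_reg] <- 0
        if (sum(mmap) > 0)
          mmap <- mmap * ((1 - rec$phi_j) * budget / sum(mmap))
        myo_f <- myo_f + jmap + mmap

        # ground truth myosin split under the margin-3 definition
        dist_j <- EBImage::distmap(matrix(as.numeric(!outline_band), S, S))
        junc_reg <- mask & dist_j <= 3
        med_reg <- mask & dist_j > 3
        dep <- jmap + mmap
        gt_split[[length(gt_split) + 1L]] <- data.frame(
          cell_id = ci, frame = f,
          junctional_mean = mean(dep[junc_reg]),
          medial_mean = mean(dep[med_reg]),
          ratio = mean(dep[junc_reg]) / mean(dep[med_reg]))
      }

      # E-cadherin lines the junction, depressed under myosin puncta
      cband <- matrix(0, S, S)
      cband[outline_band] <- rec$cad_amp
      if (!config$uniform_myosin && config$coupling > 0) {
        # depress cadherin under myosin with correlation ~ -coupling:
        # mix the standardised junctional myosin profile with an
        # independent standardised component
        jm <- myo_f[outline_band]
        if (stats::sd(jm) > 0) {
          z <- (jm - mean(jm)) / stats::sd(jm)
          xi <- stats::rnorm(length(jm))
          xi <- (xi - mean(xi)) / stats::sd(xi)
          mix <- config$coupling * z +
            sqrt(1 - config$coupling^2) * xi
          cband[outline_band] <- pmax(rec$cad_amp * (1 - 0.25 * mix), 0)
        }
      }
      cad_f <- cad_f + cband

      area_um2 <- abs(polygon_area(pf[[ci]])) * config$pixel_size^2
      per_um <- sum(sqrt(rowSums(diff(rbind(pf[[ci]], pf[[ci]][1L, ]))^2))) *
        config$pixel_size
      gt_cells[[length(gt_cells) + 1L]] <- data.frame(
        cell_id = ci, frame = f, area_um2 = area_um2,
        perimeter_um = per_um,
        centroid_x = mean(pf[[ci]][, 1L]), centroid_y = mean(pf[[ci]][, 2L]))
    }
    myo[, , f] <- pmax(myo_f + config$background +
                         stats::rnorm(S * S, 0, config$noise_sd), 0)
    cad[, , f] <- pmax(cad_f + config$background +
                         stats::rnorm(S * S, 0, config$noise_sd), 0)
  }

  # junction ground truth from the constructed shared edges (scale 1;
  # uniform oscillation leaves straightness unchanged)
  keep <- names(edges)[vapply(edges, function(e)
    isTRUE(attr(e, "interior")), logical(1L))]
  gt_junc <- do.call(rbind, lapply(keep, function(k) {
    e <- edges[[k]]
    data.frame(edge_id = k,
               L_um = path_length(junction_polyline(e)) * config$pixel_size,
               d_v_um = intervertex_distance(junction_polyline(e)) *
                 config$pixel_size,
               s = straightness(junction_polyline(e)))
  }))

  structure(list(labels = labels,
                 channels = list(myosin = myo, cadherin = cad),
                 pixel_size = config$pixel_size,
                 frame_interval = config$frame_interval,
                 axis_angle = 0, n_cells = n_cells,
                 ground_truth = list(
                   cells = do.call(rbind, gt_cells),
                   junctions = gt_junc,
                   myosin_split = if (length(gt_split))
                     do.call(rbind, gt_split) else NULL),
                 config = config),
            class = "segmented_movie")
}

#' @export
print.segmented_movie <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<segmented_movie> %dx%d px, %d frames, %d cells, phenotype %s\n",
    d[1L], d[2L], d[3L], x$n_cells, x$config$phenotype))
  invisible(x)
}

# signed polygon area (shoelace), vertices as (x, y) rows, open polygon
polygon_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

# label image from a list of polygons via even-odd point-in-polygon on
# pixel centres (0-based coordinates)
rasterize_cells <- function(polys, S) {
  lab <- matrix(0L, S, S)  # [y, x]
  for (ci in seq_along(polys)) {
    poly <- polys[[ci]]
    xr <- floor(min(poly[, 1L])):ceiling(max(poly[, 1L]))
    yr <- floor(min(poly[, 2L])):ceiling(max(poly[, 2L]))
    xr <- xr[xr >= 0 & xr <= S - 1L]; yr <- yr[yr >= 0 & yr <= S - 1L]
    if (!length(xr) || !length(yr)) next
    g <- expand.grid(x = xr, y = yr)
    inside <- point_in_polygon(g$x, g$y, poly)
    sel <- g[inside, , drop = FALSE]
    lab[cbind(sel$y + 1L, sel$x + 1L)] <- ci
  }
  lab
}

# vectorised even-odd crossing test
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  inside <- logical(length(px))
  for (k in seq_len(n)) {
    if (y1[k] == y2[k]) next
    crosses <- (y1[k] > py) != (y2[k] > py)
    if (!any(crosses)) next
    xi <- (x2[k] - x1[k]) * (py[crosses] - y1[k]) / (y2[k] - y1[k]) + x1[k]
    flip <- px[crosses] < xi
    inside[crosses] <- xor(inside[crosses], flip)
  }
  inside
}

# sum of unit-peak Gaussian blobs at the given (x, y) centres
gaussian_blobs <- function(S, centers, sigma) {
  xs <- matrix(rep(0:(S - 1L), each = S), S, S)   # [y, x] -> x coord
  ys <- matrix(rep(0:(S - 1L), times = S), S, S)  # y coord
  out <- matrix(0, S, S)
  for (k in seq_len(nrow(centers)))
    out <- out + exp(-((xs - centers[k, 1L])^2 + (ys - centers[k, 2L])^2) /
                       (2 * sigma^2))
  out
}
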