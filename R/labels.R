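#' Extract junction polylines from a segmented label image
#'
#' Finds, for every pair of neighbouring cells, the shared boundary pixels
#' and orders them into a junction path running from one tricellular point
#' (a pixel whose 3x3 neighbourhood touches >= 3 distinct cells, or the
#' image border) to the next. A pixel belongs to the junction of the cell
#' pair \{a, b\} when the set of distinct nonzero labels in its 3x3
#' neighbourhood is exactly \{a, b\}; to obtain a single-pixel-wide chain,
#' only pixels of the lower-numbered label are kept. Pixels are taken at
#' their centres (0-based, row-major) and scaled to micrometres.
#'
#' Junctions of fully enclosed cells (no tricellular endpoint) are skipped
#' with a message. Staircase pixelation inflates the measured arc length of
#' oblique paths; `smooth_sigma` applies a Gaussian smoothing of the pixel
#' chain (in pixel units, endpoints fixed) that suppresses this bias.
#'
#' @param labels integer matrix, rows = y, columns = x; 0 = background.
#' @param pixel_size micrometres per pixel.
#' @param smooth_sigma Gaussian smoothing bandwidth for the pixel chain, in
#'   pixels; 0 (default) disables smoothing.
#' @param min_pixels junctions with fewer boundary pixels are dropped.
#' @return named list of [junction_polyline()], names `"a-b"` with a < b.
#' @export
junction_paths_from_labels <- function(labels, pixel_size = 1,
                                       smooth_sigma = 0, min_pixels = 4L) {
  labels <- as.matrix(labels)
  stopifnot(pixel_size > 0)
  nr <- nrow(labels); nc <- ncol(labels)
  if (length(unique(labels[labels > 0])) < 2L) return(list())

  # pad with zeros so every pixel has a full 3x3 neighbourhood
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- labels
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  neigh <- array(0L, dim = c(nr, nc, nrow(shifts)))
  for (k in seq_len(nrow(shifts)))
    neigh[, , k] <- pad[2:(nr + 1L) + shifts$dy[k], 2:(nc + 1L) + shifts$dx[k]]

  # per-pixel distinct nonzero neighbourhood labels
  nlab <- apply(neigh, c(1, 2), function(v) {
    u <- unique(v[v > 0])
    length(u)
  })
  on_border <- matrix(FALSE, nr, nc)
  on_border[c(1L, nr), ] <- TRUE; on_border[, c(1L, nc)] <- TRUE
  triple <- nlab >= 3L | (on_border & nlab >= 2L)

  # candidate pixels: exactly two labels in neighbourhood, pixel on the
  # lower-label side
  cand <- which(nlab == 2L & labels > 0, arr.ind = TRUE)
  if (!nrow(cand)) return(list())
  pair_key <- character(nrow(cand)); side <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    v <- neigh[cand[i, 1L], cand[i, 2L], ]
    u <- sort(unique(v[v > 0]))
    pair_key[i] <- paste0(u[1L], "-", u[2L])
    side[i] <- labels[cand[i, 1L], cand[i, 2L]] == u[1L]
  }

  out <- list()
  for (key in unique(pair_key)) {
    sel <- pair_key == key & side
    px <- cand[sel, , drop = FALSE]
    if (nrow(px) < min_pixels) next
    # endpoints: adjacent to a tricellular pixel or on the image border
    is_end <- logical(nrow(px))
    for (i in seq_len(nrow(px))) {
      y <- px[i, 1L]; x <- px[i, 2L]
      yy <- max(1L, y - 1L):min(nr, y + 1L)
      xx <- max(1L, x - 1L):min(nc, x + 1L)
      is_end[i] <- any(triple[yy, xx]) || on_border[y, x]
    }
    chain <- order_chain(px, which(is_end))
    if (is.null(chain)) {
      message("junction ", key, " has no tricellular endpoint; skipped")
      next
    }
    pts <- cbind(x = px[chain, 2L] - 1, y = px[chain, 1L] - 1)
    if (smooth_sigma > 0) pts <- smooth_chain(pts, smooth_sigma)
    out[[key]] <- junction_polyline(pts * pixel_size)
  }
  out
}

# order boundary pixels into a chain by greedy nearest-neighbour walking,
# starting from an endpoint pixel; NULL when no endpoint exists (loop)
order_chain <- function(px, end_idx) {
  n <- nrow(px)
  if (!length(end_idx)) return(NULL)
  visited <- logical(n)
  cur <- end_idx[1L]
  path <- integer(0)
  repeat {
    visited[cur] <- TRUE
    path <- c(path, cur)
    d2 <- (px[, 1L] - px[cur, 1L])^2 + (px[, 2L] - px[cur, 2L])^2
    d2[visited] <- Inf
    nxt <- which.min(d2)
    if (!is.finite(d2[nxt]) || d2[nxt] > 8) break  # allow small gaps
    cur <- nxt
  }
  if (length(path) < 2L) NULL else path
}

# Gaussian smoothing of an ordered point chain; endpoints pinned
smooth_chain <- function(pts, sigma) {
  n <- nrow(pts)
  if (n < 5L) return(pts)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  pad <- function(v) {
    # reflect about the endpoint values so ends are not dragged inward
    c(2 * v[1L] - v[(half + 1L):2L], v, 2 * v[n] - v[(n - 1L):(n - half)])
  }
  sm <- function(v) stats::filter(pad(v), kern, sides = 2)[(half + 1L):(half + n)]
  out <- cbind(sm(pts[, 1L]), sm(pts[, 2L]))
  out[1L, ] <- pts[1L, ]; out[n, ] <- pts[n, ]
  colnames(out) <- colnames(pts)
  out
}
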