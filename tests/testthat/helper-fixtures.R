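# shared fixtures; movies are cached so each phenotype renders once per run

wt_model <- function() removal_rate_model()

.fixture_cache <- new.env(parent = emptyenv())

test_movie <- function(phenotype, n_cells = 4L, n_frames = 1L,
                       image_size = 180L, seed = 11L, ...) {
  key <- paste(phenotype, n_cells, n_frames, image_size, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- render_cell_movie(
      generator_config(seed = seed, phenotype = phenotype, ...),
      n_cells = n_cells, n_frames = n_frames, image_size = image_size)
  }
  .fixture_cache[[key]]
}

# analytic star-shaped blob mask: r(theta) = R0 (1 + a1 sin(theta + p1)
# + a2 sin(2 theta + p2)), centred in a square image
blob_mask <- function(S, R0, a1, a2, p1, p2) {
  c0 <- (S - 1) / 2
  xs <- matrix(rep(0:(S - 1), each = S), S) - c0
  ys <- matrix(rep(0:(S - 1), times = S), S) - c0
  th <- atan2(ys, xs)
  rr <- sqrt(xs^2 + ys^2)
  rb <- R0 * (1 + a1 * sin(th + p1) + a2 * sin(2 * th + p2))
  rr <= rb
}

# disk mask helper
disk_mask <- function(S, R, cx = (S - 1) / 2, cy = (S - 1) / 2) {
  xs <- matrix(rep(0:(S - 1), each = S), S)
  ys <- matrix(rep(0:(S - 1), times = S), S)
  (xs - cx)^2 + (ys - cy)^2 <= R^2
}
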