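#' Write junction traces to CSV
#'
#' Long-format table with one row per (junction, time point):
#' `junction_id, t, L, d_v, s`.
#'
#' @param traces list of [junction_trace()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(junction_id = attr(tr, "junction_id") %||% NA,
               t = tr$time, L = tr$L, d_v = tr$d_v, s = tr$s)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read junction traces from CSV
#'
#' Inverse of [write_traces_csv()].
#'
#' @param path CSV path with columns `junction_id, t, L, d_v`.
#' @return list of [junction_trace()] objects.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("junction_id", "t", "L", "d_v") %in% names(df)))
  lapply(split(df, df$junction_id), function(d) {
    d <- d[order(d$t), ]
    junction_trace(d$t, d$L, d$d_v, junction_id = d$junction_id[1L])
  })
}

#' Write / read rate samples CSV
#'
#' @param samples a `rate_samples` data.frame ([estimate_rates()]).
#' @param path CSV path.
#' @return `path` (write) or the `rate_samples` data.frame (read).
#' @export
write_rates_csv <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rates_csv
#' @export
read_rates_csv <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(c("s_mid", "k_j", "k_c") %in% names(out)))
  class(out) <- c("rate_samples", "data.frame")
  out
}

#' Write a fitted removal-rate model to JSON
#'
#' Stores the sigmoid parameters, the contraction rate, and the derived
#' fixed point and relaxation timescale.
#'
#' @param model a [removal_rate_model()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  fp <- steady_state_straightness(model)
  jsonlite::write_json(
    list(k_j0 = model$k_j0, s0 = model$s0, r = model$r, k_c = model$k_c,
         s_star = fp$s_star, tau = fp$tau, exists = fp$exists),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a removal-rate model from JSON
#'
#' @param path JSON path written by [write_model_json()] (or any JSON with
#'   fields `k_j0`, `s0`, `r`, `k_c`).
#' @return a [removal_rate_model()].
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  removal_rate_model(k_j0 = x$k_j0, s0 = x$s0, r = x$r, k_c = x$k_c)
}

#' Write a segmented movie as multi-page TIFF files
#'
#' Writes the label stack as `<prefix>_labels.tif` (one 16-bit page per
#' frame, integer labels) and each intensity channel as
#' `<prefix>_<channel>.tif` (16-bit, linearly scaled to the stack
#' maximum), plus `<prefix>_meta.json` holding pixel size, frame interval
#' and the channel scale factors.
#'
#' @param movie a `segmented_movie`.
#' @param prefix output path prefix.
#' @return named character vector of the written files, invisibly.
#' @export
write_movie_tiff <- function(movie, prefix) {
  stopifnot(inherits(movie, "segmented_movie"))
  nt <- dim(movie$labels)[3L]
  files <- c(labels = paste0(prefix, "_labels.tif"))
  pages <- lapply(seq_len(nt), function(f) movie$labels[, , f] / 65535)
  tiff::writeTIFF(pages, files[["labels"]], bits.per.sample = 16L)
  scales <- list()
  for (ch in names(movie$channels)) {
    mx <- max(movie$channels[[ch]], 1e-12)
    scales[[ch]] <- mx
    fn <- paste0(prefix, "_", ch, ".tif")
    pages <- lapply(seq_len(nt),
                    function(f) pmin(movie$channels[[ch]][, , f] / mx, 1))
    tiff::writeTIFF(pages, fn, bits.per.sample = 16L)
    files[[ch]] <- fn
  }
  meta <- paste0(prefix, "_meta.json")
  jsonlite::write_json(list(pixel_size = movie$pixel_size,
                            frame_interval = movie$frame_interval,
                            axis_angle = movie$axis_angle,
                            n_cells = movie$n_cells,
                            channel_scales = scales),
                       meta, auto_unbox = TRUE, digits = NA)
  files[["meta"]] <- meta
  invisible(files)
}

#' Read a segmented movie from TIFF files written by [write_movie_tiff()]
#'
#' @param prefix path prefix used at write time.
#' @return a `segmented_movie` (without ground-truth tables).
#' @export
read_movie_tiff <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, "_labels.tif"), all = TRUE)
  nt <- length(pages)
  dims <- dim(pages[[1L]])
  labels <- array(0L, dim = c(dims, nt))
  for (f in seq_len(nt))
    labels[, , f] <- as.integer(round(pages[[f]] * 65535))
  channels <- list()
  for (ch in names(meta$channel_scales)) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    arr <- array(0, dim = c(dims, nt))
    for (f in seq_len(nt))
      arr[, , f] <- pages[[f]] * meta$channel_scales[[ch]]
    channels[[ch]] <- arr
  }
  structure(list(labels = labels, channels = channels,
                 pixel_size = meta$pixel_size,
                 frame_interval = meta$frame_interval,
                 axis_angle = meta$axis_angle, n_cells = meta$n_cells,
                 ground_truth = NULL, config = NULL),
            class = "segmented_movie")
}

#' Write a run manifest
#'
#' JSON record accompanying every pipeline output: the configuration used,
#' package version, seed, and MD5 checksums of the declared inputs.
#'
#' @param path output JSON path.
#' @param config list of run parameters (must include any seed used).
#' @param inputs character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), inputs = character()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(package = "ajdyn",
         version = as.character(utils::packageVersion("ajdyn")),
         r_version = as.character(getRversion()),
         config = config, input_md5 = sums),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
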