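test_that("axis alignment is the identity at 0 and preserves area", {
  mv <- test_movie("wt_pulsatile", seed = 5)
  expect_identical(align_to_axis(mv, 0), mv)
  # rotate forward then align back: label areas preserved within 1%
  fwd <- align_to_axis(mv, -0.4)
  fwd$axis_angle <- 0.4
  back <- align_to_axis(fwd)
  for (id in 1:4) {
    a0 <- sum(mv$labels[, , 1] == id)
    a1 <- sum(back$labels[, , 1] == id)
    expect_lt(abs(a1 - a0) / a0, 0.01)
  }
})

test_that("a 90-degree rotation shifts the angular SAC profile by 90 degrees", {
  # asymmetric cell: half-disk
  S <- 101
  mask <- disk_mask(S, 35)
  xs <- matrix(rep(0:(S - 1), each = S), S)
  mask[xs > (S - 1) / 2 + 10] <- FALSE
  n_ang <- 72
  ct <- radial_contour(mask, n_angles = n_ang)
  rot <- ajdyn:::rotate_image(mask * 1, pi / 2, bilinear = FALSE)
  ct_rot <- radial_contour(rot > 0, n_angles = n_ang)
  shift <- n_ang / 4
  # contour rotates with the mask (centres differ slightly; 1 px slack)
  expect_lt(stats::median(abs(ct_rot$r_px[(seq_len(n_ang) + shift - 1) %%
                                            n_ang + 1] - ct$r_px)), 1)
})

test_that("radial contour matches analytic discs, ellipses and brute force", {
  ct <- radial_contour(disk_mask(121, 50), n_angles = 90, pixel_size = 0.2)
  expect_true(all(abs(ct$r_um - 10) <= 0.1 + 1e-9))
  # axis-aligned ellipse semi-axes 30 x 20
  S <- 101
  xs <- matrix(rep(0:(S - 1), each = S), S) - 50
  ys <- matrix(rep(0:(S - 1), times = S), S) - 50
  em <- (xs / 30)^2 + (ys / 20)^2 <= 1
  ct <- radial_contour(em, n_angles = 360)
  expect_lt(abs(ct$r_px[1] - 30), 1)
  expect_lt(abs(ct$r_px[91] - 20), 1)
  # brute-force oracle on random star-shaped blobs: per angle, the
  # farthest in-mask pixel within the half-bin angular window
  for (seed in 1:20) {
    pars <- ajdyn:::with_seed(seed, runif(4))
    mask <- blob_mask(91, 25, 0.05 + 0.05 * pars[1], 0.04 * pars[2],
                      2 * pi * pars[3], 2 * pi * pars[4])
    n_ang <- 60
    ct <- radial_contour(mask, n_angles = n_ang)
    idx <- which(mask, arr.ind = TRUE)
    px <- idx[, 2] - 1 - ct$center[1]; py <- idx[, 1] - 1 - ct$center[2]
    pa <- atan2(py, px) %% (2 * pi); pr <- sqrt(px^2 + py^2)
    brute <- vapply(ct$angles, function(a) {
      d <- abs((pa - a + pi) %% (2 * pi) - pi)
      max(pr[d <= pi / n_ang])
    }, numeric(1))
    expect_lt(max(abs(ct$r_px - brute)), 0.5 + 1e-9)
  }
  # error handling
  expect_error(radial_contour(disk_mask(61, 20), center = c(1, 1)),
               "outside")
  expect_error(radial_contour(matrix(TRUE, 21, 21)), "border")
})

test_that("top-hat filtering removes smooth background, keeps puncta", {
  expect_true(all(tophat_background(matrix(3, 40, 40), 10) == 0))
  img <- matrix(0.2, 40, 40); img[20, 20] <- 1.7
  th <- tophat_background(img, 10)
  expect_equal(th[20, 20], 1.5)
  expect_equal(sum(th) - th[20, 20], 0)
  # Gaussian blob on a linear ramp: residual ramp < 2% of blob peak
  S <- 101
  xs <- matrix(rep(0:(S - 1), each = S), S)
  ys <- matrix(rep(0:(S - 1), times = S), S)
  blob <- exp(-((xs - 50)^2 + (ys - 50)^2) / (2 * 5^2))
  ramp <- 0.3 * xs / S
  th_ramp <- tophat_background(blob + ramp, 50)
  th_ref <- tophat_background(blob, 50)
  off_blob <- (xs - 50)^2 + (ys - 50)^2 > 30^2
  expect_lt(max(abs(th_ramp - th_ref)[off_blob]), 0.02)
})

test_that("scaled profiles divide out cell shape and size", {
  ct <- radial_contour(disk_mask(121, 50), n_angles = 60)
  # uniform field -> flat map
  pr <- scaled_cell_profile(matrix(2.5, 121, 121), ct, n_radial = 40)
  expect_equal(as.vector(pr), rep(2.5, length(pr)))
  # intensity proportional to scaled radius -> map equals the radius
  # coordinate, independent of angle
  S <- 151
  xs <- matrix(rep(0:(S - 1), each = S), S) - 75
  ys <- matrix(rep(0:(S - 1), times = S), S) - 75
  em <- (xs / 60)^2 + (ys / 40)^2 <= 1
  rad <- sqrt((xs / 60)^2 + (ys / 40)^2)  # equals scaled radius in ellipse
  ct2 <- radial_contour(em, n_angles = 60)
  pr2 <- scaled_cell_profile(rad, ct2, n_radial = 50)
  target <- matrix(rep(seq(0, 1, length.out = 50), each = 60), 60)
  expect_lt(max(abs(pr2 - target)), 0.05)
  # scale invariance: a 2x enlarged cell gives the same map within 2%
  cosfield <- function(S, R) {
    c0 <- (S - 1) / 2
    dd <- sqrt((matrix(rep(0:(S - 1), each = S), S) - c0)^2 +
                 (matrix(rep(0:(S - 1), times = S), S) - c0)^2)
    cos(pi * pmin(dd / R, 1))^2
  }
  m_s <- scaled_cell_profile(cosfield(101, 40),
                             radial_contour(disk_mask(101, 40),
                                            n_angles = 45), n_radial = 30)
  m_b <- scaled_cell_profile(cosfield(201, 80),
                             radial_contour(disk_mask(201, 80),
                                            n_angles = 45), n_radial = 30)
  expect_lt(max(abs(m_s - m_b)), 0.02)
})

test_that("scaled average cell is idempotent and linear", {
  mv <- test_movie("wt_pulsatile", seed = 5)
  cells <- movie_frame_cells(mv, 1, tophat_radius = 25)
  one <- scaled_average_cell(cells[1], n_angles = 60, n_radial = 30,
                             pixel_size = mv$pixel_size)
  # idempotence: averaging N copies equals the single-cell profile
  rep3 <- scaled_average_cell(cells[c(1, 1, 1)], n_angles = 60,
                              n_radial = 30, pixel_size = mv$pixel_size)
  expect_equal(rep3$intensity$myosin, one$intensity$myosin)
  expect_equal(rep3$mean_contour, one$mean_contour)
  expect_equal(rep3$n_cells, 3L)
  # two uniform cells at 1 and 3 average to 2
  mk <- function(v) list(mask = disk_mask(61, 20),
                         channels = list(ch = matrix(v, 61, 61)))
  two <- scaled_average_cell(list(mk(1), mk(3)), n_angles = 30,
                             n_radial = 20)
  expect_equal(as.vector(two$intensity$ch), rep(2, 600))
  # linearity: SAC(a A + b B) = a SAC(A) + b SAC(B)
  cellA <- cells[[1]]; cellB <- cells[[1]]
  cellA$channels <- list(x = cellA$channels$myosin)
  cellB$channels <- list(x = cellB$channels$cadherin)
  cellC <- cellA
  cellC$channels <- list(x = 2 * cellA$channels$x + 0.5 * cellB$channels$x)
  sA <- scaled_average_cell(list(cellA), n_angles = 45, n_radial = 25)
  sB <- scaled_average_cell(list(cellB), n_angles = 45, n_radial = 25)
  sC <- scaled_average_cell(list(cellC), n_angles = 45, n_radial = 25)
  expect_equal(sC$intensity$x, 2 * sA$intensity$x + 0.5 * sB$intensity$x,
               tolerance = 1e-10)
})

test_that("junctional enrichment shows up at the SAC boundary row", {
  mv <- test_movie("stretched", seed = 11)
  cells <- movie_frame_cells(mv, 1, tophat_radius = 25)
  sac <- scaled_average_cell(cells, n_angles = 90, n_radial = 50,
                             pixel_size = mv$pixel_size)
  map <- sac$intensity$myosin
  boundary_mean <- mean(map[, 48:50])
  interior_mean <- mean(map[, 5:40])
  expect_gt(boundary_mean, 2 * interior_mean)
})

test_that("junctional intensity averages a fixed-width band on the path", {
  ch <- matrix(0.8, 30, 30)
  path <- cbind(5:24, 15)
  expect_equal(junctional_intensity(ch, path, width = 3), 0.8)
  # bright one-pixel line on black: width-3 band averages in two dark rows
  ch2 <- matrix(0, 30, 30); ch2[16, ] <- 0.9
  expect_equal(junctional_intensity(ch2, cbind(0:29, 15), width = 3),
               0.3, tolerance = 1e-9)
  expect_error(junctional_intensity(ch, path[0, , drop = FALSE]), "empty")
  expect_error(junctional_intensity(ch, path, width = 2), "odd")
})

test_that("junction/medial ratio is 1 for uniform fields, capped when degenerate", {
  for (mask in list(disk_mask(61, 22),
                    blob_mask(71, 24, 0.15, 0.05, 0.3, 1.2))) {
    expect_equal(junction_medial_ratio(matrix(4, nrow(mask), ncol(mask)),
                                       mask), 1)
  }
  # all intensity on the junction: capped with flag
  mask <- disk_mask(61, 22)
  jm <- cell_outline_mask(mask)
  ch <- matrix(0, 61, 61); ch[jm] <- 1
  r <- junction_medial_ratio(ch, mask)
  expect_true(isTRUE(attr(r, "capped")))
  expect_error(junction_medial_ratio(ch, disk_mask(61, 3), margin = 3),
               "medial")
})

test_that("boundary pixel pairs expose the cadherin-myosin association", {
  mask <- disk_mask(81, 30)
  S <- 81
  xs <- matrix(rep(0:(S - 1), each = S), S)
  # identical channels: correlation +1
  ch <- matrix(runif(S * S, 0.5, 1.5), S)
  bp <- boundary_pixel_pairs(ch, ch, mask)
  expect_equal(bp$correlation, 1)
  # constructed complement: perfect negative association
  bp2 <- boundary_pixel_pairs(ch, 2 - ch, mask)
  expect_equal(bp2$correlation, -1)
  expect_true(all(c("a_center", "mean_b", "se_b", "n") %in%
                    colnames(bp2$binned)))
  expect_error(boundary_pixel_pairs(ch, ch, mask, max_dist = 0), "boundary")
  # generator coupling rho = 0.6: per-cell sample correlations average
  # near -0.6 across the ensemble
  cors <- unlist(lapply(c(5L, 9L), function(seed) {
    mv <- test_movie("wt_pulsatile", n_cells = 9, image_size = 240,
                     seed = seed, coupling = 0.6)
    cells <- movie_frame_cells(mv, 1, tophat_radius = 25)
    vapply(cells, function(cell)
      boundary_pixel_pairs(cell$channels$cadherin, cell$channels$myosin,
                           cell$mask)$correlation, numeric(1))
  }))
  expect_gt(mean(cors), -0.7)
  expect_lt(mean(cors), -0.5)
})

test_that("kymographs stack horizontal averages over time", {
  st <- array(0.4, dim = c(30, 30, 4))
  ky <- kymograph(st, c(5, 25, 0, 29))
  expect_true(all(ky == 0.4))
  expect_equal(dim(ky), c(30L, 4L))
  # band moving 1 px/frame: diagonal ridge of slope 1
  st2 <- array(0, dim = c(30, 30, 5))
  for (f in 1:5) st2[10 + f, , f] <- 1
  ky2 <- kymograph(st2, c(0, 29, 0, 29))
  expect_equal(apply(ky2, 2, which.max), 11:15)
  expect_error(kymograph(st, c(10, 5, 0, 29)), "rectangle")
})
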