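test_that("sigmoid removal rate has the right midpoint, plateau and root", {
  m <- wt_model()
  expect_equal(removal_rate(m$s0, m), m$k_j0 / 2)
  expect_equal(removal_rate(m$s0, m), 0.01025)
  expect_equal(removal_rate(-1e3, m), m$k_j0, tolerance = 1e-12)
  expect_lt(removal_rate(1e3, m), 1e-12)
  # decreasing everywhere, strictly so away from the flat plateaus
  sv <- seq(0, 1.2, by = 0.01)
  expect_true(all(diff(removal_rate(sv, m)) <= 0))
  sv <- seq(0.7, 1.1, by = 0.01)
  expect_true(all(diff(removal_rate(sv, m)) < 0))
  # closed-form root of k_j(s) = k_c
  s_root <- m$s0 + log(m$k_j0 / m$k_c - 1) / m$r
  expect_equal(removal_rate(s_root, m), m$k_c, tolerance = 1e-12)
  expect_equal(removal_rate(0.9235, m), 0.0091, tolerance = 1e-4)
})

test_that("fixed point matches closed form, bisection oracle and printed value", {
  m <- wt_model()
  fp <- steady_state_straightness(m)
  expect_true(fp$exists)
  expect_equal(round(fp$s_star, 3), 0.923)
  expect_equal(removal_rate(fp$s_star, m), m$k_c, tolerance = 1e-12)
  # independent bisection oracle on (0, 1)
  bisect <- function(model) {
    lo <- 1e-6; hi <- 1 - 1e-6
    g <- function(s) removal_rate(s, model) - model$k_c
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(fp$s_star, bisect(m), tolerance = 1e-10)
  for (kc in c(0.002, 0.005, 0.012, 0.019)) {
    mm <- removal_rate_model(k_c = kc)
    expect_equal(steady_state_straightness(mm)$s_star, bisect(mm),
                 tolerance = 1e-10)
  }
  # midpoint symmetry and non-existence
  expect_equal(steady_state_straightness(
    removal_rate_model(k_c = wt_model()$k_j0 / 2))$s_star, wt_model()$s0)
  expect_false(steady_state_straightness(
    removal_rate_model(k_c = 0.03))$exists)
  expect_false(steady_state_straightness(
    removal_rate_model(k_c = 0))$exists)
})

test_that("relaxation timescale is ~3.1 min and uses the exact derivative", {
  m <- wt_model()
  expect_equal(round(relaxation_timescale(m), 1), 3.1)
  # numeric-derivative oracle
  fp <- steady_state_straightness(m)
  h <- 1e-6
  kj_prime <- (removal_rate(fp$s_star + h, m) -
                 removal_rate(fp$s_star - h, m)) / (2 * h)
  expect_equal(relaxation_timescale(m), -1 / (kj_prime * fp$s_star),
               tolerance = 1e-6)
  # tau scales as 1/r when the fixed point sits at the midpoint
  m1 <- removal_rate_model(k_j0 = 0.02, k_c = 0.01, r = 50)
  m2 <- removal_rate_model(k_j0 = 0.02, k_c = 0.01, r = 100)
  expect_equal(relaxation_timescale(m1) / relaxation_timescale(m2), 2,
               tolerance = 1e-12)
  expect_error(relaxation_timescale(removal_rate_model(k_c = 0.03)),
               "fixed point")
})

test_that("straightness ODE: fixed point, closed form, monotone convergence", {
  m <- wt_model()
  tg <- seq(0, 200, by = 0.5)
  fp <- steady_state_straightness(m)
  # starting at the fixed point stays there
  s_fix <- integrate_straightness(fp$s_star, m, tg)
  expect_lt(max(abs(s_fix - fp$s_star)), 1e-8)
  # long-time limit from s(0) = 0.7
  s <- integrate_straightness(0.7, m, tg)
  expect_equal(s[length(s)], 0.923, tolerance = 1e-3)
  expect_true(all(diff(s) > -1e-12))
  # convergence is monotone from above as well
  s_hi <- integrate_straightness(0.99, m, tg)
  expect_true(all(diff(s_hi) < 1e-12))
  expect_equal(s_hi[length(s_hi)], fp$s_star, tolerance = 1e-6)
  # constant-rate model: closed form s(t) = s0 exp((k_j - k_c) t).
  # a flat sigmoid (tiny r never leaves the plateau neighbourhood):
  flat <- removal_rate_model(k_j0 = 0.02, s0 = 0.5, r = 1e-9, k_c = 0.0091)
  tg2 <- seq(0, 50, by = 1)
  s2 <- integrate_straightness(0.5, flat, tg2)
  expect_equal(s2, 0.5 * exp((0.01 - 0.0091) * tg2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(integrate_straightness(-0.1, m, tg2), "positive")
})

test_that("breakdown above s = 1 is flagged, not clamped", {
  # removal much faster than contraction drives s through 1
  m <- removal_rate_model(k_j0 = 0.05, s0 = 0.99, r = 5, k_c = 0.001)
  s <- integrate_straightness(0.95, m, seq(0, 100, by = 1))
  expect_true(attr(s, "breakdown"))
  expect_gt(max(s), 1)
})

test_that("linearised decay matches the relaxation timescale", {
  m <- wt_model()
  fp <- steady_state_straightness(m)
  tg <- seq(0, 4, by = 0.05)
  for (dev0 in c(0.005, -0.005)) {
    s <- integrate_straightness(fp$s_star + dev0, m, tg)
    dev <- abs(s - fp$s_star)
    efold <- -1 / stats::coef(stats::lm(log(dev) ~ tg))[["tg"]]
    expect_lt(abs(efold - fp$tau) / fp$tau, 0.05)
  }
})

test_that("phase-space and straightness integrations agree", {
  tg <- seq(0, 60, by = 1)
  for (seed in 1:10) {
    draw <- ajdyn:::with_seed(seed, {
      list(m = removal_rate_model(k_j0 = runif(1, 0.01, 0.05),
                                  s0 = runif(1, 0.6, 0.95),
                                  r = runif(1, 10, 120),
                                  k_c = runif(1, 0.002, 0.009)),
           dv0 = runif(1, 8, 13.9))
    })
    m <- draw$m; L0 <- 14; dv0 <- draw$dv0
    ph <- integrate_phase(L0, dv0, m, tg)
    s <- integrate_straightness(dv0 / L0, m, tg)
    expect_lt(max(abs(ph$s - s)), 1e-8)
    # d_v decouples: exponential to integrator tolerance at all times
    expect_equal(ph$d_v, dv0 * exp(-m$k_c * tg), tolerance = 1e-8)
  }
  # constant rates k_j = k_c: trajectory rides an iso-straightness line
  flat <- removal_rate_model(k_j0 = 0.0182, s0 = 0.5, r = 1e-9, k_c = 0.0091)
  ph <- integrate_phase(13.1, 12.3, flat, tg)
  expect_lt(diff(range(ph$s)), 1e-9)
  # long-time straightness from realistic initial lengths
  ph2 <- integrate_phase(13.1, 12.3, wt_model(), seq(0, 300, by = 1))
  expect_equal(ph2$s[nrow(ph2)],
               steady_state_straightness(wt_model())$s_star,
               tolerance = 1e-4)
})

test_that("sigmoid fit recovers parameters from clean and noisy samples", {
  m <- wt_model()
  sv <- seq(0.80, 1.00, by = 0.02)
  fit <- fit_removal_rate(sv, removal_rate(sv, m), k_c = rep(m$k_c, 5),
                          init = removal_rate_model(k_j0 = 0.03, s0 = 0.9,
                                                    r = 40))
  expect_equal(fit$model$k_j0, m$k_j0, tolerance = 1e-6)
  expect_equal(fit$model$s0, m$s0, tolerance = 1e-6)
  expect_equal(fit$model$r, m$r, tolerance = 1e-6)
  expect_equal(fit$model$k_c, m$k_c)
  expect_lt(fit$residual_ss, 1e-16)
  expect_error(fit_removal_rate(c(0.8, 0.9, 1.0), rep(0.01, 3)),
               "under-determined")
})

test_that("fitted 95% intervals achieve nominal coverage", {
  m <- wt_model()
  sv <- ajdyn:::with_seed(11L, runif(200, 0.80, 1.00))
  truth <- c(k_j0 = m$k_j0, s0 = m$s0, r = m$r)
  hits <- matrix(FALSE, 100, 3, dimnames = list(NULL, names(truth)))
  ajdyn:::with_seed(1100L, {
    for (rep in 1:100) {
      kj <- removal_rate(sv, m) + rnorm(200, 0, 0.002)
      f <- fit_removal_rate(sv, kj, init = m)
      ci_lo <- stats::coef(f$fit) - 1.96 * f$se
      ci_hi <- stats::coef(f$fit) + 1.96 * f$se
      hits[rep, ] <- truth >= ci_lo[names(truth)] &
        truth <= ci_hi[names(truth)]
    }
  })
  expect_true(all(colMeans(hits) >= 0.90))
})
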