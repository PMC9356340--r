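test_that("vector magnitude matches direct arithmetic", {
  expect_equal(vector_magnitude(0, 0, 1), 1)
  expect_equal(vector_magnitude(0.6, 0.8, 0), 1)
  expect_equal(vector_magnitude(0.3, 0.4, 1.2), 1.3)
})

test_that("ENMO matches the brute-force per-sample formula", {
  expect_equal(compute_enmo(c(0, 0), c(0, 0), c(1, 1)), 0)
  expect_equal(compute_enmo(c(1.2, 1.2), c(0, 0), c(0, 0)), 0.2)
  ## half the samples at r = 0.5, half at r = 1.5
  expect_equal(compute_enmo(c(rep(0.5, 40), rep(1.5, 40)), rep(0, 80),
                            rep(0, 80)), 0.25)
  set.seed(40)
  x <- rnorm(80, 0, 0.4); y <- rnorm(80, 0, 0.4); z <- 1 + rnorm(80, 0, 0.4)
  r <- sqrt(x^2 + y^2 + z^2)
  expect_equal(compute_enmo(x, y, z), mean(pmax(r - 1, 0)), tolerance = 1e-12)
  expect_true(is.na(compute_enmo(numeric(0), numeric(0), numeric(0))))
})

test_that("MAD matches the brute-force deviation formula", {
  expect_equal(compute_mad(rep(0.7, 50), rep(0, 50), rep(0, 50)), 0)
  expect_equal(compute_mad(rep(c(0.9, 1.1), 40), rep(0, 80), rep(0, 80)), 0.1)
  set.seed(41)
  x <- rnorm(80); y <- rnorm(80); z <- rnorm(80)
  r <- sqrt(x^2 + y^2 + z^2)
  expect_equal(compute_mad(x, y, z), sum(abs(r - mean(r))) / 80,
               tolerance = 1e-12)
  expect_true(is.na(compute_mad(1, 1, 1)))
})

test_that("AI accumulates sub-epoch root excess variances", {
  n <- 80 * 60
  expect_equal(compute_ai(rep(0.2, n), rep(0.5, n), rep(1, n), 80), 0)
  ## per-axis variance equal to the noise variance cancels exactly
  set.seed(42)
  v <- rnorm(80); v <- (v - mean(v)) / sd(v) * 0.3   # variance exactly 0.09
  xs <- rep(v, 60)
  expect_equal(compute_ai(xs, xs, xs, 80, noise_variance = 0.09), 0,
               tolerance = 1e-9)
  ## one active 1-s sub-epoch with axis variances (4, 4, 4), rest constant
  a <- rnorm(80); a <- (a - mean(a)) / sd(a) * 2     # variance exactly 4
  xs <- c(a, rep(0, 80 * 59))
  expect_equal(compute_ai(xs, xs, xs, 80), 2, tolerance = 1e-9)
})

test_that("ENMO and MAD depend on samples only through the magnitude", {
  set.seed(43)
  x <- rnorm(200); y <- rnorm(200); z <- rnorm(200)
  expect_equal(compute_enmo(x, y, z), compute_enmo(y, z, x))
  expect_equal(compute_mad(x, y, z), compute_mad(z, x, y))
  expect_equal(compute_ai(x, y, z, 80), compute_ai(z, x, y, 80))
})

test_that("MIMS is zero on all-zero and pure-gravity input", {
  n <- 80 * 120
  zero <- make_signal(rep(0, n), rep(0, n), rep(0, n))
  expect_equal(compute_mims(zero)$mims, c(0, 0))
  grav <- make_signal(rep(0, n), rep(0, n), rep(1, n))
  expect_equal(compute_mims(grav)$mims, c(0, 0))
})

test_that("MIMS is degree-1 homogeneous for in-band signals", {
  n <- 80 * 120
  tt <- (0:(n - 1)) / 80
  mims_at <- function(A) {
    s <- make_signal(A * sin(2 * pi * tt), rep(0, n), rep(1, n))
    compute_mims(s)$mims
  }
  m1 <- mims_at(0.5); m2 <- mims_at(1.0)
  expect_equal(m2, 2 * m1, tolerance = 1e-6)
  expect_true(all(m1 > 0))
})

test_that("MIMS is invariant to axis permutation", {
  set.seed(44)
  n <- 80 * 60
  x <- 0.3 * sin(2 * pi * (0:(n - 1)) / 80) + rnorm(n, 0, 0.01)
  y <- rnorm(n, 0, 0.02); z <- 1 + rnorm(n, 0, 0.02)
  m1 <- compute_mims(make_signal(x, y, z))$mims
  m2 <- compute_mims(make_signal(z, x, y))$mims
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("minutes with internal gaps longer than 1 s are missing", {
  n <- 80 * 120
  tt <- (0:(n - 1)) / 80
  keep <- tt < 20 | tt > 22  # 2 s hole in minute 1
  sig <- raw_signal(as.numeric(T0) + tt[keep], sin(tt[keep]), rep(0, sum(keep)),
                    rep(1, sum(keep)))
  mm <- compute_mims(sig)
  expect_true(is.na(mm$mims[1]))
  expect_false(is.na(mm$mims[2]))
})

test_that("autocalibration is a fixed point on calibrated still data", {
  set.seed(45)
  orients <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  xs <- ys <- zs <- numeric(0)
  for (k in seq_len(nrow(orients))) {
    m <- orients[k, ]
    xs <- c(xs, m[1] + rnorm(1600, 0, 0.002))
    ys <- c(ys, m[2] + rnorm(1600, 0, 0.002))
    zs <- c(zs, m[3] + rnorm(1600, 0, 0.002))
  }
  sig <- make_signal(xs, ys, zs)
  cm <- autocalibrate(sig)
  expect_lt(max(abs(cm$gain - 1)), 1e-3)
  expect_lt(max(abs(cm$offset)), 1e-3)
})

test_that("autocalibration recovers an injected gain/offset miscalibration", {
  set.seed(46)
  pts <- matrix(rnorm(80 * 3), ncol = 3)
  pts <- pts / sqrt(rowSums(pts ^ 2))
  gm <- c(1.02, 0.98, 1.01); om <- c(0.01, -0.02, 0)
  win <- 800
  xs <- ys <- zs <- numeric(0)
  for (i in seq_len(nrow(pts))) {
    obs <- gm * pts[i, ] + om
    xs <- c(xs, obs[1] + rnorm(win, 0, 0.002))
    ys <- c(ys, obs[2] + rnorm(win, 0, 0.002))
    zs <- c(zs, obs[3] + rnorm(win, 0, 0.002))
  }
  cm <- autocalibrate(make_signal(xs, ys, zs))
  ## composing the estimated correction with the miscalibration ~ identity
  expect_lt(max(abs(cm$gain * gm - 1)), 1e-3)
  expect_lt(max(abs(cm$gain * om + cm$offset)), 1e-3)
  ## applying the model reduces the sphere residual on its own still windows
  expect_lt(cm$diagnostics$err_end, cm$diagnostics$err_start)
})

test_that("single-orientation still data falls back to identity with a warning", {
  sig <- make_still_signal(minutes = 2, noise_sd = 0.002)
  expect_warning(cm <- autocalibrate(sig), "coverage")
  expect_equal(cm$gain, c(1, 1, 1))
  expect_equal(cm$offset, c(0, 0, 0))
})

test_that("summarize_minutes computes all four measures per minute", {
  set.seed(47)
  n <- 80 * 180
  tt <- (0:(n - 1)) / 80
  sig <- make_signal(0.2 * sin(2 * pi * tt) + rnorm(n, 0, 0.01),
                     rnorm(n, 0, 0.01), 1 + rnorm(n, 0, 0.01))
  out <- summarize_minutes(sig)
  expect_equal(nrow(out), 3)
  expect_identical(names(out), c("time", "mims", "enmo", "mad", "ai"))
  expect_true(all(out$mims >= 0 & out$enmo >= 0 & out$mad >= 0 & out$ai >= 0))
})
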