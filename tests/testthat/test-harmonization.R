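test_that("noise-free closed-form truths are recovered on the interior grid", {
  set.seed(70)
  ac <- exp(runif(20000, log(1), log(5000)))
  lin <- suppressWarnings(fit_mapping(ac, 0.005 * ac, "linear"))
  interior <- lin$grid >= quantile(ac, 0.05) & lin$grid <= quantile(ac, 0.95)
  expect_lt(max(abs(lin$fitted[interior] - 0.005 * lin$grid[interior]) /
                  (0.005 * lin$grid[interior])), 0.005)
  rt <- suppressWarnings(fit_mapping(ac, sqrt(ac), "root"))
  expect_lt(max(abs(rt$fitted[interior] - sqrt(rt$grid[interior])) /
                  sqrt(rt$grid[interior])), 0.01)
})

test_that("a constant measure yields a flat fitted function", {
  set.seed(71)
  ac <- runif(1000, 1, 100)
  mod <- suppressWarnings(fit_mapping(ac, rep(2.5, 1000), "const"))
  expect_equal(range(mod$fitted), c(2.5, 2.5), tolerance = 1e-6)
})

test_that("fitting contracts are enforced", {
  expect_error(fit_mapping(1:50, 1:50), "at least 100")
  expect_error(fit_mapping(rep(5, 200), rnorm(200)), "constant")
  ## ac = 0 pairs are excluded from fitting
  set.seed(72)
  ac <- c(rep(0, 5000), exp(runif(500, log(1), log(100))))
  y <- c(rep(99, 5000), 2 * ac[-(1:5000)])
  mod <- suppressWarnings(fit_mapping(ac, y, "m"))
  expect_equal(mod$n_fit, 500)
  g <- seq(5, 95, by = 5)
  expect_lt(max(abs(as.numeric(predict_measure(mod, g)) - 2 * g) / (2 * g)),
            0.02)
})

test_that("prediction clamps and flags out-of-range counts, rejects negatives", {
  mod <- identity_model()
  expect_equal(as.numeric(predict_measure(mod, mod$grid[500])),
               mod$fitted[500], tolerance = 1e-9)
  hi <- predict_measure(mod, 1e6)
  expect_equal(as.numeric(hi), mod$fitted[length(mod$fitted)],
               tolerance = 1e-6)
  expect_true(attr(hi, "extrapolated"))
  expect_error(predict_measure(mod, -1), "negative")
})

test_that("linear truth maps 2000 counts to ~10 at slope 0.005, both ways", {
  set.seed(73)
  ac <- exp(runif(20000, log(1), log(5000)))
  mod <- suppressWarnings(fit_mapping(ac, 0.005 * ac, "linear"))
  expect_equal(as.numeric(predict_measure(mod, 2000)), 10, tolerance = 0.01)
  expect_equal(as.numeric(invert_to_ac(mod, 10)), 2000, tolerance = 5)
  expect_equal(translate_cutoff(mod, 1853), 9.265, tolerance = 0.01)
})

test_that("inverse lookup honors the floor and ceiling contracts", {
  mod <- identity_model()
  expect_equal(as.numeric(invert_to_ac(mod, 0)), 0)
  big <- invert_to_ac(mod, 1e9)
  expect_equal(as.numeric(big), mod$grid[length(mod$grid)])
  expect_true(attr(big, "clamped_high"))
  expect_error(invert_to_ac(mod, -0.1), "negative")
})

test_that("invert after predict is the identity within one grid step", {
  set.seed(74)
  ac <- exp(runif(20000, log(1), log(5000)))
  y <- sqrt(ac) * (1 + rnorm(20000, 0, 0.1))
  mod <- suppressWarnings(fit_mapping(ac, y, "m"))
  interior <- seq(100, 1900, by = 50)
  g <- mod$grid[interior]
  back <- as.numeric(invert_to_ac(mod, as.numeric(predict_measure(mod, g))))
  step <- pmax(mod$grid[interior + 1] - mod$grid[interior - 1], 1e-9)
  expect_true(all(abs(back - g) <= step))
})

test_that("cut-off translation accepts the published count cut-offs", {
  set.seed(75)
  ac <- exp(runif(30000, log(1), log(8000)))
  mod <- suppressWarnings(fit_mapping(ac, 0.005 * ac, "linear"))
  out <- translate_cutoff(mod, c(1853, 2860, 3940))
  expect_equal(out, 0.005 * c(1853, 2860, 3940), tolerance = 0.01)
  mid <- identity_model(hi = 3000)
  expect_equal(translate_cutoff(mid, 1853), 1853, tolerance = 2)
  expect_error(translate_cutoff(mod, 1e7), "outside")
})

test_that("the penalized fit agrees with an independent GAM cross-check", {
  set.seed(76)
  ac <- exp(runif(8000, log(1), log(5000)))
  y <- 0.01 * ac ^ 0.9 * (1 + rnorm(8000, 0, 0.1))
  mod <- suppressWarnings(fit_mapping(ac, y, "m"))
  gam_fit <- mgcv::gam(y ~ s(ac, bs = "cr", k = 30))
  g <- seq(quantile(ac, 0.05), quantile(ac, 0.95), length.out = 200)
  ours <- as.numeric(predict_measure(mod, g))
  ref <- as.numeric(mgcv::predict.gam(gam_fit, data.frame(ac = g)))
  expect_lt(mean(abs(ours - ref) / ref), 0.02)
})

test_that("the model serializes to JSON and back faithfully", {
  mod <- identity_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_harmonization_json(mod, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$measure_name, "measure")
  expect_equal(obj$fitted, mod$fitted, tolerance = 1e-12)
  expect_equal(obj$basis$nbasis, mod$nbasis)
})
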