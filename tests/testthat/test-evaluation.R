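test_that("participant correlations hit the exact linear limits", {
  ac <- c(1, 5, 9, 20, 3, 7)
  d <- rbind(make_minutes(ac, list(m = 2 * ac + 3), id = "A"),
             make_minutes(ac, list(m = -ac), id = "B"))
  r <- participant_correlations(d, "m")
  expect_equal(r$r[r$participant_id == "A"], 1)
  expect_equal(r$r[r$participant_id == "B"], -1)
})

test_that("correlations only use valid minutes; zero variance gives NA", {
  ac <- c(1, 2, 3, 4, 100)
  d <- make_minutes(ac, list(m = c(1, 2, 3, 4, -50)),
                    valid = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(participant_correlations(d, "m")$r, 1)
  flat <- make_minutes(rep(3, 10), list(m = rnorm(10)))
  expect_message(r0 <- participant_correlations(flat, "m"), "zero-variance")
  expect_true(is.na(r0$r))
})

test_that("Monte-Carlo bivariate correlations concentrate near the truth", {
  set.seed(80)
  rho <- 0.9
  d <- do.call(rbind, lapply(1:8, function(i) {
    x <- rnorm(5000)
    y <- rho * x + sqrt(1 - rho ^ 2) * rnorm(5000)
    make_minutes(x - min(x), list(m = y), id = paste0("P", i))
  }))
  r <- participant_correlations(d, "m")
  expect_lt(abs(mean(r$r) - rho), 0.02)
})

test_that("intercept-only regression returns the mean correlation and its SE", {
  recs <- data.frame(participant_id = paste0("P", 1:20),
                     r = rep(0.93, 20))
  tab <- suppressWarnings(correlation_regression(recs))  # zero-residual lm
  expect_equal(tab$estimate, 0.93)
  expect_equal(tab$se, 0, tolerance = 1e-12)
})

test_that("adjusted regression recovers known coefficients within 2 SE", {
  set.seed(81)
  n <- 500
  recs <- data.frame(participant_id = paste0("P", 1:n),
                     age_years = runif(n, 25, 95),
                     bmi_kg_m2 = rnorm(n, 27, 5),
                     sex = factor(sample(c("female", "male"), n, TRUE),
                                  levels = c("female", "male")))
  beta <- c(age = -5e-4, bmi = 1e-3, male = -0.01)
  recs$r <- 0.95 + beta["age"] * recs$age_years +
    beta["bmi"] * recs$bmi_kg_m2 +
    beta["male"] * (recs$sex == "male") + rnorm(n, 0, 0.01)
  tab <- correlation_regression(recs, adjusted = TRUE)
  expect_identical(tab$term,
                   c("(Intercept)", "age_years", "bmi_kg_m2", "sexmale"))
  for (i in 2:4)
    expect_lt(abs(tab$estimate[i] - beta[i - 1]), 2 * tab$se[i])
})

test_that("collinear covariates are rejected", {
  recs <- data.frame(participant_id = paste0("P", 1:20), r = runif(20),
                     age_years = 1:20, bmi_kg_m2 = 2 * (1:20),
                     sex = factor(rep(c("female", "male"), 10),
                                  levels = c("female", "male")))
  recs$bmi_kg_m2 <- recs$age_years  # exactly collinear
  expect_error(correlation_regression(recs, adjusted = TRUE), "collinear")
})

test_that("daily total errors are zero under a perfect mapping", {
  mod <- identity_model()
  set.seed(82)
  ac <- runif(2 * 1440, 2, 90)
  d <- make_minutes(ac, list(measure = ac))
  err <- total_ac_errors(d, mod, "measure")
  expect_lt(max(abs(err$per_participant[, c("mpe", "mape")])), 0.05)
})

test_that("constant relative inflation gives MPE = MAPE = 10", {
  mod <- identity_model(hi = 200)
  ac <- rep(c(20, 40, 60), 960)  # 2 days
  d <- make_minutes(ac, list(measure = 1.1 * ac))
  err <- total_ac_errors(d, mod, "measure")
  expect_equal(err$per_participant$mpe, 10, tolerance = 0.2)
  expect_equal(err$per_participant$mape, 10, tolerance = 0.2)
})

test_that("symmetric daily errors cancel in MPE but not MAPE", {
  mod <- identity_model(hi = 200)
  ac <- rep(50, 2 * 1440)
  measure <- c(rep(45, 1440), rep(55, 1440))  # day errors -10%, +10%
  d <- make_minutes(ac, list(measure = measure))
  err <- total_ac_errors(d, mod, "measure")
  expect_equal(err$per_participant$mpe, 0, tolerance = 0.2)
  expect_equal(err$per_participant$mape, 10, tolerance = 0.2)
  expect_equal(err$per_participant$mdape, 10, tolerance = 0.2)
})

test_that("MAPE >= |MPE| and MdAPE >= |MdPE| on random error vectors", {
  mod <- identity_model(hi = 200)
  set.seed(83)
  d <- do.call(rbind, lapply(1:10, function(i) {
    ac <- rep(runif(1, 30, 70), 4 * 1440)
    make_minutes(ac * (1 + rnorm(4 * 1440, 0, 0.2)), list(measure = ac),
                 id = paste0("P", i))
  }))
  err <- total_ac_errors(d, mod, "measure")$per_participant
  expect_true(all(err$mape >= abs(err$mpe) - 1e-9))
  expect_true(all(err$mdape >= abs(err$mdpe) - 1e-9))
})

test_that("days with zero total count are excluded with a message", {
  mod <- identity_model(hi = 200)
  ac <- c(rep(0, 1440), rep(50, 1440))
  d <- make_minutes(ac, list(measure = ac))
  expect_message(err <- total_ac_errors(d, mod, "measure"), "excluded")
  expect_equal(nrow(err$per_participant), 1)
})

test_that("classification metrics reproduce direct 2x2 arithmetic", {
  mod <- identity_model(hi = 100)
  cutoff <- 50
  ac <- c(rep(70, 50), rep(30, 50))            # 50 positive, 50 negative
  measure <- c(rep(70, 40), rep(30, 10),        # TP = 40, FN = 10
               rep(70, 5), rep(30, 45))         # FP = 5,  TN = 45
  d <- make_minutes(ac, list(measure = measure))
  cl <- cutoff_classification(d, mod, cutoff, "measure")
  expect_equal(cl$per_participant$accuracy, 0.85)
  expect_equal(cl$per_participant$sensitivity, 0.80)
  expect_equal(cl$per_participant$specificity, 0.90)
})

test_that("perfect mapping classifies perfectly; degenerate cases flagged", {
  mod <- identity_model(hi = 100)
  ac <- runif(500, 1, 99)
  d <- make_minutes(ac, list(measure = ac))
  cl <- cutoff_classification(d, mod, 50, "measure")
  expect_equal(unname(unlist(cl$per_participant[, 2:4])), c(1, 1, 1))
  ## mapped counts all zero: specificity 1, sensitivity 0
  d0 <- make_minutes(ac, list(measure = rep(0, 500)))
  cl0 <- cutoff_classification(d0, mod, 50, "measure")
  expect_equal(cl0$per_participant$specificity, 1)
  expect_equal(cl0$per_participant$sensitivity, 0)
  ## no positive minutes: sensitivity NA with a message
  dneg <- make_minutes(rep(10, 200), list(measure = rep(10, 200)))
  expect_message(cln <- cutoff_classification(dneg, mod, 50, "measure"),
                 "sensitivity NA")
  expect_true(is.na(cln$per_participant$sensitivity))
})

test_that("accuracy identity holds on enumerated 2x2 tables", {
  set.seed(84)
  mod <- identity_model(hi = 100)
  for (k in 1:10) {
    tp <- sample(0:30, 1); fn <- sample(0:30, 1)
    fp <- sample(0:30, 1); tn <- sample(0:30, 1)
    if (tp + fn + fp + tn < 2) next
    ac <- c(rep(70, tp + fn), rep(30, fp + tn))
    measure <- c(rep(70, tp), rep(30, fn), rep(70, fp), rep(30, tn))
    d <- make_minutes(ac, list(measure = measure))
    cl <- suppressMessages(cutoff_classification(d, mod, 50, "measure"))
    pp <- cl$per_participant
    P <- tp + fn; N <- fp + tn
    sens <- if (P == 0) 0 else pp$sensitivity
    spec <- if (N == 0) 0 else pp$specificity
    expect_equal(pp$accuracy, (sens * P + spec * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("median curves are exact for identity mapping and scale linearly", {
  mod <- identity_model(hi = 200)
  set.seed(85)
  md <- data.frame(participant_id = c("A", "B"), age_years = c(45, 80),
                   sex = factor(c("female", "male"),
                                levels = c("female", "male")),
                   bmi_kg_m2 = c(25, 28))
  mkp <- function(id, amp) {
    modm <- 0:(2 * 1440 - 1) %% 1440
    ac <- amp * (1.2 + sin(2 * pi * modm / 1440)) + 5
    make_minutes(ac, list(measure = ac), id = id)
  }
  d <- rbind(mkp("A", 40), mkp("B", 25))
  cur <- daily_median_curves(d, mod, md, measure = "measure")
  expect_lt(cur$curve_mape, 0.5)
  ## a 5% uniform inflation of the measure gives curve MAPE ~ 5
  d2 <- d; d2$measure <- 1.05 * d$measure
  cur2 <- daily_median_curves(d2, mod, md, measure = "measure",
                              smooth = FALSE)
  expect_equal(cur2$curve_mape, 5, tolerance = 0.3)
})

test_that("unsmoothed group medians match the generative median curve", {
  mod <- identity_model(hi = 500)
  set.seed(86)
  md <- data.frame(participant_id = paste0("P", 1:12),
                   age_years = c(rep(40, 6), rep(80, 6)))
  md$sex <- factor(rep(c("female", "male"), 6), levels = c("female", "male"))
  md$bmi_kg_m2 <- 27
  base <- function(young) function(modm)
    (if (young) 120 else 60) * (1.3 + sin(2 * pi * modm / 1440)) + 10
  d <- do.call(rbind, lapply(1:12, function(i) {
    modm <- 0:(1440 - 1)
    mu <- base(i <= 6)(modm)
    ac <- mu * exp(rnorm(1440, 0, 0.05))
    make_minutes(ac, list(measure = ac), id = paste0("P", i))
  }))
  cur <- daily_median_curves(d, mod, md, measure = "measure", smooth = FALSE)
  g1 <- cur$curves[cur$curves$age_group == levels(factor(cur$curves$age_group))[1], ]
  young_grp <- cur$curves[grepl("-Inf,60", cur$curves$age_group), ]
  mu_true <- base(TRUE)(young_grp$minute - 1)
  expect_lt(median(abs(young_grp$ac_median - mu_true) / mu_true), 0.05)
})
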