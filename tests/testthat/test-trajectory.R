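test_that("the spline recovers a noiseless peak exactly", {
  age <- rep(4:91, each = 2)
  d <- data.frame(age = age, y = -(age - 25)^2)
  fit <- fit_trajectory(d, "y", bootstrap_reps = 0)
  # asymmetric age support shifts the smoothed argmax by at most one
  # half-year grid step
  expect_lte(abs(fit$peak_age - 25), 0.5)
  expect_false(fit$no_unique_peak)
})

test_that("a constant variable yields a flat fit and no unique peak", {
  d <- data.frame(age = rep(4:91, each = 2), y = 1)
  fit <- fit_trajectory(d, "y", bootstrap_reps = 0)
  expect_true(fit$no_unique_peak)
  expect_true(is.na(fit$peak_age))
})

test_that("trajectory preconditions are enforced", {
  d <- data.frame(age = rep(30:35, 7), y = rnorm(42))
  expect_error(fit_trajectory(d, "y"), "distinct ages")
  expect_error(fit_trajectory(data.frame(age = 1:10, y = 1:10), "y"),
               "at least 30")
  d2 <- data.frame(age = rep(4:91, 2), y = rnorm(176))
  expect_error(fit_trajectory(d2, "y", spline_df = 1.5), "spline_df")
})

test_that("at df near 2 the spline collapses to the least-squares line", {
  set.seed(8)
  age <- rep(seq(10, 80, 2), 3)
  y <- 0.3 + 0.01 * age + rnorm(length(age), 0, 0.05)
  d <- data.frame(age = age, y = y)
  fit <- fit_trajectory(d, "y", spline_df = 2.0001, bootstrap_reps = 0,
                        age_grid_step = 1)
  ls <- lm(y ~ age, d)
  pred <- unname(predict(ls, data.frame(age = fit$age)))
  expect_equal(fit$fitted, pred, tolerance = 1e-6)
})

test_that("confidence bands bracket the fit and cover the true curve", {
  tabs <- tt_tables_small()
  # pointwise sanity on one cohort
  coh <- sample_cohort(600, seed = 21)
  wide <- participant_summary(score_cohort(coh, tabs), coh)
  fit <- fit_trajectory(wide, "mean_z", bootstrap_reps = 100, seed = 2)
  expect_true(all(fit$ci_lower <= fit$fitted + 1e-9))
  expect_true(all(fit$ci_upper >= fit$fitted - 1e-9))
  # coverage of the generator truth at age 40 across replicate cohorts;
  # truth estimated once by Monte Carlo on a cohort pinned to age 40
  truth <- local({
    coh40 <- sample_cohort(8000, seed = 781, age_mean = 40, age_sd = 1e-6,
                           age_range = c(39.5, 40.5))
    wide40 <- participant_summary(score_cohort(coh40, tabs), coh40)
    mean(wide40$mean_z)
  })
  hits <- sapply(1:50, function(s) {
    coh <- sample_cohort(600, seed = 3000 + s)
    w <- participant_summary(score_cohort(coh, tabs), coh)
    f <- fit_trajectory(w, "mean_z", bootstrap_reps = 200, seed = s)
    i <- which.min(abs(f$age - 40))
    f$ci_lower[i] <= truth && truth <= f$ci_upper[i]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("peak-age estimates concentrate around the generator truth", {
  tabs <- tt_tables_full()
  peaks <- sapply(1:10, function(s) {
    coh <- sample_cohort(3429, seed = s)
    wide <- participant_summary(score_cohort(coh, tabs), coh)
    fit_trajectory(wide, "mean_z", spline_df = 7,
                   bootstrap_reps = 0)$peak_age
  })
  expect_true(median(peaks) >= 23 && median(peaks) <= 27)
  expect_true(all(peaks >= 20 & peaks <= 30))
})

test_that("the speed-accuracy path pairs the two fits by age", {
  age <- rep(4:91, each = 2)
  d <- data.frame(age = age, ct = 20 + 0.1 * age, z = -(age - 25)^2 / 1000)
  fct <- fit_trajectory(d, "ct", bootstrap_reps = 0)
  fz <- fit_trajectory(d, "z", bootstrap_reps = 0)
  path <- speed_accuracy_path(fct, fz)
  expect_equal(nrow(path), length(fct$age))
  expect_equal(path$age[1], 4)
  expect_equal(path$age[nrow(path)], 91)
  # grid mismatch is an error
  d2 <- d[d$age >= 10, ]
  f2 <- fit_trajectory(d2, "z", bootstrap_reps = 0)
  expect_error(speed_accuracy_path(fct, f2), "grids")
})

test_that("partial eta-squared matches hand-computed one-way ANOVA", {
  # groups A=(1,2,3), B=(3,4,5): SSB=6, SSW=4, eta_p^2 = 0.6
  d <- data.frame(age = c(20, 30, 40, 20, 30, 40),
                  sex = rep(c("male", "female"), each = 3),
                  y = c(1, 2, 3, 3, 4, 5))
  d <- do.call(rbind, replicate(4, d, simplify = FALSE))  # n for precondition
  g <- fit_glm(d, "y", iv = "sex")
  expect_equal(g$terms$partial_eta_sq[g$terms$term == "sex"],
               24 / (24 + 16), tolerance = 1e-9)
})

test_that("a perfectly linear predictor earns near-total partial eta-squared", {
  set.seed(1)
  d <- data.frame(age = round(runif(400, 16, 90)),
                  paranormal_belief = sample(1:6, 400, TRUE),
                  sex = sample(c("male", "female"), 400, TRUE))
  d$y <- 2 * d$paranormal_belief + rnorm(400, 0, 0.01)
  g <- fit_glm(d, "y", iv = c("age", "sex", "paranormal_belief"))
  expect_gt(g$terms$partial_eta_sq[g$terms$term == "paranormal_belief"],
            0.99)
})

test_that("independent predictors earn negligible partial eta-squared", {
  for (s in 0:4) {
    set.seed(s)
    d <- data.frame(age = round(runif(3000, 16, 90)),
                    education = sample(1:7, 3000, TRUE),
                    paranormal_belief = sample(1:6, 3000, TRUE),
                    sex = sample(c("male", "female"), 3000, TRUE),
                    field = sample(c("humanities", "science", "other"),
                                   3000, TRUE),
                    y = rnorm(3000))
    g <- fit_glm(d, "y")
    expect_true(all(g$terms$partial_eta_sq < 0.01))
  }
})

test_that("glm guards against rank deficiency and tiny samples", {
  d <- data.frame(age = round(runif(200, 16, 90)),
                  sex = sample(c("male", "female"), 200, TRUE))
  d$y <- rnorm(200)
  expect_error(fit_glm(d[1:25, ], "y", iv = c("age", "sex")),
               "too few complete cases")
  expect_error(fit_glm(d, "y"), "lacks columns")
  d$field <- "science"  # constant factor: unusable level structure
  expect_error(fit_glm(d, "y", iv = c("age", "sex", "field")))
})

test_that("Cronbach's alpha matches its closed form on fixtures", {
  # identical items
  d <- data.frame(a = 1:10, b = 1:10, c = 1:10)
  expect_equal(reliability_alpha(d, c("a", "b", "c"))$alpha, 1)
  # two-item fixture: x=(1,2,3,4), y=(2,4,5,7) gives alpha = 16/17
  d2 <- data.frame(x = c(1, 2, 3, 4), y = c(2, 4, 5, 7))
  expect_equal(reliability_alpha(d2, c("x", "y"))$alpha, 16 / 17,
               tolerance = 1e-9)
  # independent items are unreliable
  set.seed(2)
  d3 <- as.data.frame(matrix(rnorm(4e4), ncol = 4))
  expect_lt(abs(reliability_alpha(d3, names(d3))$alpha), 0.05)
  expect_error(reliability_alpha(d2[1:2, ], c("x", "y")), "3 complete")
  expect_error(reliability_alpha(data.frame(a = rep(1, 5), b = rep(2, 5)),
                                 c("a", "b")), "zero total variance")
})

test_that("age-window correlations behave on fixtures", {
  d <- data.frame(age = rep(30:50, 10))
  d$x <- seq_len(nrow(d))
  d$y <- 2 * d$x + 1
  r <- age_window_correlation(d, "x", "y", c(25, 60))
  expect_equal(r$r, 1, tolerance = 1e-12)
  set.seed(3)
  d$y2 <- rnorm(nrow(d))
  r2 <- age_window_correlation(d, "x", "y2", c(25, 60))
  expect_lt(abs(r2$r), 0.2)
  expect_error(age_window_correlation(d, "x", "y", c(80, 91)),
               "fewer than 10")
  d$cst <- 1
  expect_error(age_window_correlation(d, "x", "cst", c(25, 60)),
               "degenerate")
})
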