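test_that("cohort generation is seeded and validates inputs", {
  expect_error(sample_cohort(0), "n must be")
  c1 <- sample_cohort(150, seed = 4)
  c2 <- sample_cohort(150, seed = 4)
  expect_identical(c1, c2)
  c3 <- sample_cohort(150, seed = 5)
  expect_false(identical(c1$response_coin, c3$response_coin))
  expect_true(all(c1$age >= 4 & c1$age <= 91))
  expect_true(all(c1$paranormal_belief %in% 1:6))
  expect_true(all(c1$education %in% 1:7))
})

test_that("education and field are coarsely age-consistent", {
  coh <- sample_cohort(800, seed = 9)
  expect_true(all(is.na(coh$field[coh$age <= 15])))
  expect_true(all(coh$field[coh$age > 15] %in%
                    c("humanities", "science", "other")))
  expect_true(all(coh$education[coh$age < 11] <= 2))
  expect_true(all(coh$education[coh$age < 18] <= 4))
})

test_that("expected ability peaks at 25 and declines in old age", {
  curve <- lifespan_curve(noise_sd = 0)
  ages <- seq(4, 91, 0.5)
  ab <- ability_at(curve, ages)
  expect_equal(ages[which.max(ab)], 25)
  expect_gt(ability_at(curve, 25), ability_at(curve, 80))
  # non-increasing beyond the peak
  post <- ab[ages >= 25]
  expect_true(all(diff(post) <= 1e-12))
  # accelerated decline after the plateau
  expect_gt(ability_at(curve, 60) - ability_at(curve, 75),
            ability_at(curve, 40) - ability_at(curve, 55))
})

test_that("full-strength cycling visits every symbol before re-use", {
  prof <- bias_profile(cycling_strength = 1, ability = 0)
  for (s in 1:5) {
    r <- generate_response(rig_task("die"), prof, seed = s)
    expect_equal(sort(r[1:6]), 0:5)
  }
})

test_that("full-strength repetition avoidance alternates a binary sequence", {
  prof <- bias_profile(repetition_avoidance = 1, ability = 0,
                       alternation_excess = 0, cycling_strength = 0)
  for (s in 1:5) {
    r <- generate_response(rig_task("coin"), prof, seed = s)
    expect_true(all(diff(r) != 0))
  }
})

test_that("perfect ability produces a uniform next-symbol distribution", {
  for (s in 0:4) {
    m <- rigcomplexity:::cpp_generate_sequences(
      10L, 6L, rep(1, 1e4), 0.9, 0.7, 0.7, s)
    counts <- tabulate(as.vector(m) + 1L, nbins = 6L)
    p <- stats::chisq.test(counts)$p.value
    expect_gt(p, 1e-4)
  }
})

test_that("completion times are positive, fastest near 25, and male-faster", {
  ct25 <- generate_ct(rep(25, 1e4), "female", "die", seed = 1)
  ct80 <- generate_ct(rep(80, 1e4), "female", "die", seed = 2)
  expect_true(all(ct25 > 0) && all(ct80 > 0))
  expect_lt(median(ct25), median(ct80))
  ctm <- generate_ct(rep(40, 2e4), "male", "die", seed = 3)
  ctf <- generate_ct(rep(40, 2e4), "female", "die", seed = 3)
  expect_lt(mean(ctm), mean(ctf))
})

test_that("grid responses are binary 3x3 patterns with at least 5 clicks", {
  prof <- bias_profile(ability = 0.5)
  g <- generate_response(rig_task("grid"), prof, seed = 7)
  expect_equal(dim(g), c(3L, 3L))
  expect_true(all(g %in% 0:1))
  expect_gte(attr(g, "clicks"), 5)
})

test_that("mean coin complexity rises monotonically with ability", {
  tabs <- tt_tables_full()
  spec <- rig_task("coin")
  mom <- string_space_moments(spec, tabs$tm4_2)
  mean_z <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(ab) {
    m <- rigcomplexity:::cpp_generate_sequences(
      12L, 2L, rep(ab, 500), 0.9, 0.7, 0.7, 42L)
    keys <- rigcomplexity:::cpp_canonicalize(
      apply(m, 1, paste0, collapse = ""))
    mean((rigcomplexity:::score_keys(keys, spec, tabs$tm4_2)$K - mom$mu) /
           mom$sigma)
  })
  expect_true(all(diff(mean_z) > 0))
})

test_that("zeroing the belief effect removes the belief-complexity link", {
  tabs <- tt_tables_full()
  coh <- sample_cohort(3000, seed = 3, tasks = rig_tasks()["grid"],
                       belief_grid_effect = 0)
  wide <- participant_summary(
    score_cohort(coh, tabs, rig_tasks()["grid"]), coh)
  expect_lt(abs(cor(wide$paranormal_belief, wide$z_grid)), 0.05)
})

test_that("a generated cohort survives a write-read-score-analyze round trip", {
  tabs <- tt_tables_small()
  coh <- sample_cohort(200, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$response_coin, coh$response_coin)
  expect_equal(back$age, coh$age)
  v <- validate_cohort(back)
  expect_equal(nrow(v$errors), 0)
  scores <- score_cohort(v$cohort, tabs)
  expect_false(any(is.na(scores$z)))
  wide <- participant_summary(scores, v$cohort)
  fit <- fit_trajectory(wide, "mean_z", bootstrap_reps = 10, seed = 1)
  expect_s3_class(fit, "trajectory_fit")
  unlink(path)
})
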