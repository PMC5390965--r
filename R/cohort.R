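#' Lifespan curve of randomization ability
#'
#' Expected randomization ability (a latent 0-1 quantity scaling all
#' response biases toward zero) as a function of age: a steep rise through
#' childhood to a maximum at `peak_age`, a slow steady decline until
#' `plateau_end`, and an accelerated decline afterwards.  The curve is a
#' monotone Hermite spline through the knots implied by the slopes, so the
#' expected ability is maximal exactly at `peak_age` and non-increasing
#' beyond it.  `adult_slope` is the average loss per year between the peak
#' and `plateau_end`; the decline is front-loaded (an internal knot ten
#' years after the peak carries 1.7 times the average slope) so the
#' trajectory turns downward visibly right after the peak rather than
#' leaving a flat shoulder, as smoothed developmental curves of higher
#' cognitive abilities do.
#'
#' @param peak_age age of maximal ability (years, default 25).
#' @param plateau_end age at which decline accelerates (default 60).
#' @param child_slope ability gain per year before the peak.
#' @param adult_slope mean ability loss per year between peak and
#'   `plateau_end`; must be smaller in magnitude than `late_slope`.
#' @param late_slope ability loss per year after `plateau_end`.
#' @param noise_sd SD of the individual ability deviation around the
#'   curve.
#' @param peak_ability expected ability at the peak (0-1).
#' @return object of class `lifespan_curve`; evaluate it with
#'   [ability_at()].
#' @export
lifespan_curve <- function(peak_age = 25, plateau_end = 60,
                           child_slope = 0.016, adult_slope = 0.0077,
                           late_slope = 0.009, noise_sd = 0.1,
                           peak_ability = 0.55) {
  stopifnot(peak_age > 4, plateau_end > peak_age, plateau_end < 91,
            child_slope > 0, adult_slope >= 0, late_slope > adult_slope,
            noise_sd >= 0, peak_ability > 0, peak_ability <= 1)
  v_peak <- peak_ability
  v_child <- max(0, v_peak - child_slope * (peak_age - 4))
  v_plateau <- max(0, v_peak - adult_slope * (plateau_end - peak_age))
  v_end <- max(0, v_plateau - late_slope * (91 - plateau_end))
  mid_gap <- min(10, (plateau_end - peak_age) / 2)
  v_mid <- max(v_plateau, v_peak - 1.7 * adult_slope * mid_gap)
  knots_x <- c(4, peak_age, peak_age + mid_gap, plateau_end, 91)
  knots_v <- c(v_child, v_peak, v_mid, v_plateau, v_end)
  structure(
    list(peak_age = peak_age, plateau_end = plateau_end,
         child_slope = child_slope, adult_slope = adult_slope,
         late_slope = late_slope, noise_sd = noise_sd,
         peak_ability = peak_ability,
         fn = stats::splinefun(knots_x, knots_v, method = "monoH.FC")),
    class = "lifespan_curve")
}

#' @param curve a [lifespan_curve()].
#' @param age ages in years.
#' @rdname lifespan_curve
#' @return `ability_at()` returns the expected ability, clipped to the unit interval.
#' @export
ability_at <- function(curve, age) {
  stopifnot(inherits(curve, "lifespan_curve"))
  pmin(1, pmax(0, curve$fn(age)))
}

#' @export
print.lifespan_curve <- function(x, ...) {
  cat(sprintf(
    "<lifespan_curve> peak %.2f at age %g; slopes %.4f / -%.4f / -%.4f per year; noise sd %.3f\n",
    x$peak_ability, x$peak_age, x$child_slope, x$adult_slope, x$late_slope,
    x$noise_sd))
  invisible(x)
}

#' Response bias profile
#'
#' Parameters of the generative model of human randomization heuristics.
#' The next symbol is drawn from a uniform distribution reweighted by
#' three classic biases, all scaled by `1 - ability` (a perfect
#' randomizer, ability 1, is i.i.d. uniform):
#' repetition avoidance (the probability of immediately repeating the last
#' symbol is multiplied by `1 - b * repetition_avoidance`), alternation
#' excess (the symbol used two steps back is boosted by
#' `1 + b * alternation_excess`; strict alternation for binary alphabets),
#' and cycling (while unused symbols remain, used symbols are damped by
#' `1 - b * cycling_strength`, postponing re-use until every alternative
#' has appeared once).
#'
#' @param repetition_avoidance,alternation_excess,cycling_strength bias
#'   strengths in the unit interval.
#' @param ability randomization ability in the unit interval.
#' @return object of class `bias_profile`.
#' @export
bias_profile <- function(repetition_avoidance = 0.9,
                         alternation_excess = 0.7,
                         cycling_strength = 0.7, ability = 0.5) {
  vals <- c(repetition_avoidance, alternation_excess, cycling_strength,
            ability)
  stopifnot(all(vals >= 0), all(vals <= 1))
  structure(list(repetition_avoidance = repetition_avoidance,
                 alternation_excess = alternation_excess,
                 cycling_strength = cycling_strength, ability = ability),
            class = "bias_profile")
}

#' Grid response model
#'
#' The grid task differs from the sequential tasks: participants freely
#' toggle cells until the pattern "looks random", so the observable is a
#' final configuration shaped by revision behaviour rather than a
#' sequence of inhibited choices.  The model draws the number of clicks
#' (5 plus a geometric excess), then generates click positions over the 9
#' cells with two biases scaled by `1 - ability`: perseveration (the
#' just-clicked cell is boosted, i.e. toggling back and forth while
#' revising, which cancels pairs of clicks and leaves sparse, repetitive
#' patterns) and clustering (rook-neighbours of the last click are
#' boosted, favouring contiguous blobs).  Grid performance is known to be
#' almost uncorrelated with the sequential tasks --- arguably tapping
#' randomness perception rather than production --- so its effective
#' ability is only weakly coupled to the shared lifespan ability:
#' `offset + coupling * ability`, minus the paranormal-belief decrement.
#'
#' @param perseveration boost of the previously clicked cell per unit
#'   bias.
#' @param clustering boost of the rook-neighbours of the previous click
#'   per unit bias.
#' @param offset,coupling affine map from shared ability to grid-task
#'   ability.
#' @param click_excess_prob success probability of the geometric excess
#'   click count.
#' @return list of class `grid_model`.
#' @export
grid_model <- function(perseveration = 40, clustering = 6, offset = 0.55,
                       coupling = 0.5, click_excess_prob = 1 / 6.16) {
  stopifnot(perseveration >= 0, clustering >= 0, coupling >= 0,
            click_excess_prob > 0, click_excess_prob <= 1)
  structure(list(perseveration = perseveration, clustering = clustering,
                 offset = offset, coupling = coupling,
                 click_excess_prob = click_excess_prob),
            class = "grid_model")
}

#' Generate one task response from a bias profile
#'
#' Sequential sampling under the bias model of [bias_profile()].  For the
#' grid task the click-revision model of [grid_model()] is used (with the
#' profile's raw ability, i.e. no offset/coupling map): clicks toggle
#' cells and the final 3x3 configuration is returned with the click count
#' as attribute `clicks`.
#'
#' @param spec a [rig_task()] spec.
#' @param profile a [bias_profile()].
#' @param seed integer seed (mandatory; all generation is seeded).
#' @param grid a [grid_model()] (grid task only).
#' @return integer vector of symbols `0..k-1` (1-D tasks) or a 3x3 binary
#'   matrix with attribute `clicks` (grid).
#' @export
generate_response <- function(spec, profile, seed, grid = grid_model()) {
  stopifnot(inherits(spec, "task_spec"), inherits(profile, "bias_profile"))
  if (spec$task_id == "grid") {
    n_clicks <- withr::with_seed(derive_seed(seed, 17L),
                                 5L + stats::rgeom(1L, grid$click_excess_prob))
    clicks <- cpp_generate_clicks(n_clicks, profile$ability,
                                  grid$perseveration, grid$clustering,
                                  derive_seed(seed, 18L))[[1]]
    cells <- tabulate(clicks + 1L, nbins = 9L) %% 2L
    out <- matrix(cells, nrow = 3L, byrow = TRUE)
    attr(out, "clicks") <- n_clicks
    return(out)
  }
  drop(cpp_generate_sequences(spec$length, spec$alphabet_size,
                              profile$ability, profile$repetition_avoidance,
                              profile$alternation_excess,
                              profile$cycling_strength,
                              derive_seed(seed, 19L)))
}

#' Generate a completion time
#'
#' Lognormal completion time whose median follows a U-shaped age curve,
#' fastest at the curve's trough near age 25, with a multiplicative male
#' speed factor.
#'
#' @param age ages in years.
#' @param sex `"male"` or `"female"` (recycled).
#' @param task_id task identifier (sets the baseline median).
#' @param seed integer seed.
#' @param median_at_25 baseline median CT in seconds at age 25 (per-task
#'   defaults used when NULL).
#' @param child_coef,old_coef log-scale slowdown coefficients for the
#'   young and old ends of the age range.
#' @param male_factor multiplicative factor on the male median (< 1 means
#'   faster).
#' @param sdlog lognormal scale.
#' @return completion times in seconds (strictly positive).
#' @export
generate_ct <- function(age, sex, task_id, seed, median_at_25 = NULL,
                        child_coef = log(2.5), old_coef = log(2),
                        male_factor = 0.93, sdlog = 0.35) {
  base <- c(coin = 20, card = 18, die = 20, circles = 15, grid = 20)
  m25 <- median_at_25 %||% unname(base[task_id])
  if (is.na(m25)) m25 <- 20
  logmed <- log(m25) +
    child_coef * pmax(0, (25 - age) / 21)^2 +
    old_coef * pmax(0, (age - 25) / 66)^2 +
    ifelse(sex == "male", log(male_factor), 0)
  withr::with_seed(derive_seed(seed, 23L),
                   stats::rlnorm(length(logmed), logmed, sdlog))
}

#' Simulate a study cohort
#'
#' Draws a cohort with the demographic structure of a large online
#' randomization study --- ages from a truncated normal on ages 4-91,
#' roughly 2:1 male:female, education coarsely consistent with age, field
#' of education only for participants above 15 --- and generates every
#' task response and completion time from the lifespan ability curve:
#' each participant's ability is the curve value at their age plus
#' individual noise, clipped to the unit interval.  Paranormal belief (uniform
#' 1-6 Likert) lowers grid-task ability by `belief_grid_effect` per point
#' above 1, injecting the negative belief-complexity association on that
#' task only.
#'
#' All randomness derives from `seed`; the same seed reproduces the
#' cohort exactly.
#'
#' @param n cohort size (>= 1).
#' @param curve a [lifespan_curve()].
#' @param seed integer root seed.
#' @param tasks task specs to generate responses for.
#' @param age_mean,age_sd,age_range truncated-normal age distribution.
#' @param p_male probability of `"male"`.
#' @param belief_grid_effect grid-task ability decrement per belief point
#'   above 1 (default 0.01).
#' @param biases a [bias_profile()] carrying the population bias
#'   strengths (its `ability` field is ignored; ability comes from the
#'   curve).
#' @param grid a [grid_model()] for the grid task.
#' @param male_ct_factor multiplicative male completion-time factor.
#' @return data frame of class `rig_cohort`: demographics, latent
#'   `ability`, and per task `response_<task>` (digit string),
#'   `ct_<task>`, plus `clicks_grid`.
#' @export
sample_cohort <- function(n, curve = lifespan_curve(), seed = 1L,
                          tasks = rig_tasks(),
                          age_mean = 37.72, age_sd = 13.38,
                          age_range = c(4, 91), p_male = 2333 / 3418,
                          belief_grid_effect = 0.01,
                          biases = bias_profile(), grid = grid_model(),
                          male_ct_factor = 0.93) {
  if (n < 1) stop("n must be >= 1")
  if (age_range[1] < 4 || age_range[2] > 91 || age_range[1] >= age_range[2])
    stop("age_range must be within [4, 91]")
  demo <- withr::with_seed(derive_seed(seed, 1L), {
    age <- round(rtruncnorm(n, age_mean, age_sd, age_range[1], age_range[2]))
    sex <- ifelse(runif(n) < p_male, "male", "female")
    edu <- sample.int(7L, n, replace = TRUE,
                      prob = c(38, 83, 387, 621, 347, 1364, 538))
    edu <- pmin(edu, education_cap(age))
    field <- ifelse(age > 15,
                    sample(c("humanities", "science", "other"), n,
                           replace = TRUE, prob = c(609, 1684, 550)),
                    NA_character_)
    belief <- sample.int(6L, n, replace = TRUE)
    ability <- pmin(1, pmax(0, ability_at(curve, age) +
                                 rnorm(n, 0, curve$noise_sd)))
    data.frame(participant_id = sprintf("P%05d", seq_len(n)),
               age = age, sex = sex, education = edu, field = field,
               paranormal_belief = belief, ability = ability)
  })
  out <- demo
  for (spec in tasks) {
    tseed <- derive_seed(seed, 100L + match(spec$task_id, names(rig_tasks())))
    ability <- demo$ability
    if (spec$task_id == "grid") {
      ability <- pmin(1, pmax(0, grid$offset + grid$coupling * ability -
        belief_grid_effect * (demo$paranormal_belief - 1)))
      n_clicks <- withr::with_seed(derive_seed(tseed, 2L),
                                   5L + stats::rgeom(n, grid$click_excess_prob))
      clicks <- cpp_generate_clicks(n_clicks, ability, grid$perseveration,
                                    grid$clustering, derive_seed(tseed, 3L))
      resp <- vapply(clicks, function(cl)
        paste0(tabulate(cl + 1L, nbins = 9L) %% 2L, collapse = ""),
        character(1))
      out$clicks_grid <- n_clicks
    } else {
      mat <- cpp_generate_sequences(spec$length, spec$alphabet_size,
                                    ability, biases$repetition_avoidance,
                                    biases$alternation_excess,
                                    biases$cycling_strength,
                                    derive_seed(tseed, 3L))
      resp <- apply(mat, 1, paste0, collapse = "")
    }
    out[[paste0("response_", spec$task_id)]] <- resp
    out[[paste0("ct_", spec$task_id)]] <-
      generate_ct(demo$age, demo$sex, spec$task_id, derive_seed(tseed, 4L),
                  male_factor = male_ct_factor)
  }
  class(out) <- c("rig_cohort", "data.frame")
  out
}

# children cannot hold degrees: coarse age-consistency cap on the 7-level
# education ordinal (1 kindergarten ... 7 postgraduate)
education_cap <- function(age) {
  cap <- rep(7L, length(age))
  cap[age < 26] <- 6L
  cap[age < 21] <- 5L
  cap[age < 18] <- 4L
  cap[age < 15] <- 3L
  cap[age < 11] <- 2L
  cap[age < 6] <- 1L
  cap
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Read and write cohort files
#'
#' Cohorts are plain CSV, one row per participant: demographics, then per
#' task the response (symbols as digits, the grid as 9 row-major digits),
#' completion time in seconds, and the grid click count.  Responses are
#' read as character so leading zeros survive the round trip.
#'
#' @param cohort a cohort data frame.
#' @param path CSV path.
#' @return `read_cohort()` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  cols <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  classes <- ifelse(grepl("^response_", cols), "character", NA)
  out <- utils::read.csv(path, colClasses = classes, check.names = FALSE,
                         na.strings = "")
  class(out) <- c("rig_cohort", "data.frame")
  out
}
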