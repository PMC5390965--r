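#' Fit a developmental trajectory
#'
#' Smoothing-spline fit (fixed equivalent degrees of freedom, default 7)
#' of a score or completion-time variable on age, evaluated on a 0.5-year
#' age grid, with 95% pointwise confidence bands from a case-resampling
#' bootstrap (percentile method) and the peak age (grid argmax of the
#' fitted curve).
#'
#' @param data wide per-participant data frame (see
#'   [participant_summary()]) with an `age` column.
#' @param variable name of the column to fit (e.g. `"mean_z"`,
#'   `"total_ct"`, `"z_coin"`).
#' @param spline_df equivalent degrees of freedom of the smoothing spline
#'   (>= 2; at 2 the fit collapses to the least-squares line).
#' @param bootstrap_reps bootstrap replicates for the confidence bands
#'   (default 500; 0 skips the bands).
#' @param seed integer seed for the bootstrap.
#' @param age_grid_step grid resolution in years.
#' @return object of class `trajectory_fit`: `age`, `fitted`, `ci_lower`,
#'   `ci_upper`, `peak_age` (NA with `no_unique_peak = TRUE` for flat
#'   fits), `n`.
#' @export
fit_trajectory <- function(data, variable, spline_df = 7,
                           bootstrap_reps = 500, seed = 1L,
                           age_grid_step = 0.5) {
  stopifnot(is.data.frame(data), "age" %in% names(data),
            variable %in% names(data))
  if (spline_df < 2) stop("spline_df must be >= 2")
  keep <- is.finite(data$age) & is.finite(data[[variable]])
  age <- data$age[keep]
  y <- data[[variable]][keep]
  if (length(age) < 30)
    stop("need at least 30 participants with observed age and ", variable)
  if (length(unique(age)) < 20)
    stop("need at least 20 distinct ages to fit a df=", spline_df,
         " trajectory")
  grid <- seq(max(4, min(age)), min(91, max(age)), by = age_grid_step)
  fit <- stats::smooth.spline(age, y, df = spline_df)
  fitted <- stats::predict(fit, grid)$y
  ci_lower <- ci_upper <- rep(NA_real_, length(grid))
  if (bootstrap_reps > 0) {
    boots <- withr::with_seed(derive_seed(seed, 31L), {
      vapply(seq_len(bootstrap_reps), function(b) {
        idx <- sample.int(length(age), replace = TRUE)
        bf <- try(stats::smooth.spline(age[idx], y[idx], df = spline_df),
                  silent = TRUE)
        if (inherits(bf, "try-error")) return(rep(NA_real_, length(grid)))
        stats::predict(bf, grid)$y
      }, numeric(length(grid)))
    })
    ci_lower <- apply(boots, 1, stats::quantile, probs = 0.025, na.rm = TRUE)
    ci_upper <- apply(boots, 1, stats::quantile, probs = 0.975, na.rm = TRUE)
  }
  flat <- diff(range(fitted)) < 1e-8
  structure(
    list(variable = variable, spline_df = spline_df, age = grid,
         fitted = fitted, ci_lower = ci_lower, ci_upper = ci_upper,
         peak_age = if (flat) NA_real_ else grid[which.max(fitted)],
         no_unique_peak = flat, bootstrap_reps = bootstrap_reps,
         seed = seed, n = length(age)),
    class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %s ~ age, df = %g, n = %d\n", x$variable,
              x$spline_df, x$n))
  if (x$no_unique_peak) cat("  no unique peak (flat fit)\n")
  else cat(sprintf("  peak age: %.1f (fitted value %.4f)\n", x$peak_age,
                   max(x$fitted)))
  invisible(x)
}

#' Speed-accuracy developmental path
#'
#' Combines a completion-time trajectory and a complexity trajectory
#' fitted on the same age grid into the parametric curve
#' (CT(age), z(age)), the developmental path in the speed-accuracy plane.
#'
#' @param ct_fit,z_fit [fit_trajectory()] objects on identical age grids.
#' @return data frame `age`, `ct`, `z` of class `speed_accuracy_path`.
#' @export
speed_accuracy_path <- function(ct_fit, z_fit) {
  stopifnot(inherits(ct_fit, "trajectory_fit"),
            inherits(z_fit, "trajectory_fit"))
  if (!isTRUE(all.equal(ct_fit$age, z_fit$age)))
    stop("age grids of the two fits do not match")
  structure(data.frame(age = ct_fit$age, ct = ct_fit$fitted,
                       z = z_fit$fitted),
            class = c("speed_accuracy_path", "data.frame"))
}

#' General linear model of a score with effect sizes
#'
#' Least-squares linear model of a complexity or completion-time variable
#' on age (centered linear and quadratic terms by default, the quadratic
#' alone with `quadratic_only = TRUE`), sex, education (ordinal-numeric),
#' field and paranormal belief.  Reports, per term, the coefficient
#' (single-df terms), the Type II p-value and the partial eta-squared
#' `SS_term / (SS_term + SS_residual)`.  When field or belief is included
#' the analysis is restricted to participants above 15, who are the only
#' ones asked those questions.
#'
#' @param data wide per-participant data frame with an `age` column.
#' @param dv dependent-variable column name.
#' @param iv independent variables among `"age"`, `"sex"`, `"education"`,
#'   `"field"`, `"paranormal_belief"`.
#' @param quadratic_only include only the squared (centered) age term.
#' @return object of class `rig_glm`: data frame `terms` with columns
#'   `term`, `estimate`, `p_value`, `partial_eta_sq`, plus `n_used` and
#'   the formula.
#' @export
fit_glm <- function(data, dv,
                    iv = c("age", "sex", "education", "field",
                           "paranormal_belief"),
                    quadratic_only = FALSE) {
  stopifnot(is.data.frame(data), dv %in% names(data))
  iv <- match.arg(iv, several.ok = TRUE)
  missing_cols <- setdiff(iv, names(data))
  if (length(missing_cols) > 0)
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(c("field", "paranormal_belief") %in% iv)) {
    if (!"age" %in% names(data))
      stop("age column required to restrict to participants above 15")
    data <- data[!is.na(data$age) & data$age > 15, , drop = FALSE]
  }
  terms <- character(0)
  df <- data.frame(.dv = data[[dv]])
  if ("age" %in% iv) {
    age_c <- data$age - mean(data$age, na.rm = TRUE)
    df$age_sq <- age_c^2
    if (!quadratic_only) {
      df$age <- age_c
      terms <- c(terms, "age")
    }
    terms <- c(terms, "age_sq")
  }
  for (v in setdiff(iv, "age")) {
    df[[v]] <- if (v %in% c("sex", "field")) factor(data[[v]])
               else as.numeric(data[[v]])
    terms <- c(terms, v)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10 * (length(terms) + 1))
    stop("too few complete cases (", nrow(df), ") for ", length(terms),
         " model terms")
  form <- stats::as.formula(paste(".dv ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient model; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  a2 <- car::Anova(fit, type = 2)
  ss <- a2[["Sum Sq"]]
  names(ss) <- rownames(a2)
  ss_res <- ss[["Residuals"]]
  tnames <- setdiff(rownames(a2), "Residuals")
  asgn <- attr(stats::model.matrix(fit), "assign")
  labs <- attr(stats::terms(fit), "term.labels")
  est <- vapply(tnames, function(tn) {
    j <- which(asgn == match(tn, labs))
    if (length(j) == 1) unname(stats::coef(fit)[j]) else NA_real_
  }, numeric(1))
  res <- data.frame(term = tnames, estimate = est,
                    p_value = a2[tnames, "Pr(>F)"],
                    partial_eta_sq = ss[tnames] / (ss[tnames] + ss_res),
                    row.names = NULL)
  structure(list(dv = dv, terms = res, n_used = nrow(df),
                 formula = deparse(form)),
            class = "rig_glm")
}

#' @export
print.rig_glm <- function(x, ...) {
  cat(sprintf("<rig_glm> %s, n = %d\n", x$formula, x$n_used))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Internal-consistency reliability (Cronbach's alpha)
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of the sum)`,
#' computed on complete cases.
#'
#' @param data data frame holding the item columns.
#' @param variables names of the item columns (>= 2).
#' @return object of class `reliability_result` with `alpha`,
#'   `n_complete_cases` and `variables`.
#' @export
reliability_alpha <- function(data, variables) {
  stopifnot(is.data.frame(data), length(variables) >= 2,
            all(variables %in% names(data)))
  m <- data[, variables, drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 complete cases")
  k <- length(variables)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) stop("zero total variance; alpha undefined")
  alpha <- k / (k - 1) * (1 - sum(vapply(m, stats::var, numeric(1))) /
                            total_var)
  structure(list(alpha = alpha, n_complete_cases = nrow(m),
                 variables = variables),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> alpha = %.3f over %d items, n = %d\n",
              x$alpha, length(x$variables), x$n_complete_cases))
  invisible(x)
}

#' Correlation of two variables within an age window
#'
#' Pearson correlation (with its two-sided p-value) restricted to
#' participants whose age lies in the window, e.g. the 25-60 range where
#' age effects are weak.
#'
#' @param data wide per-participant data frame with an `age` column.
#' @param var1,var2 column names.
#' @param age_range two ages, inclusive window.
#' @return list with `r`, `p_value`, `n` and `age_range`.
#' @export
age_window_correlation <- function(data, var1, var2, age_range = c(25, 60)) {
  stopifnot(is.data.frame(data), all(c(var1, var2, "age") %in% names(data)))
  keep <- !is.na(data$age) & data$age >= age_range[1] &
    data$age <= age_range[2] & is.finite(data[[var1]]) &
    is.finite(data[[var2]])
  if (sum(keep) < 10) stop("fewer than 10 cases in the age window")
  x <- data[[var1]][keep]
  y <- data[[var2]][keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate variance in the age window")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep),
       age_range = age_range)
}
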