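#' Validate a cohort file
#'
#' Schema, range and alphabet checks for a cohort table: demographics must
#' lie in their admissible ranges (age 4-91, education 1-7, belief 1-6),
#' responses must have the task's length and alphabet, completion times
#' must be positive.  Row-level problems are reported per row and column;
#' valid rows remain loadable regardless of invalid ones.  Unreadable or
#' empty files and duplicated participant ids abort with an error.
#'
#' @param x path to a cohort CSV, or a cohort data frame.
#' @param tasks task specs whose response columns are checked (tasks
#'   without a response column are skipped).
#' @return list with `cohort` (the valid rows) and `errors` (data frame
#'   `row`, `participant_id`, `column`, `value`, `message`).
#' @export
validate_cohort <- function(x, tasks = rig_tasks()) {
  cohort <- if (is.character(x)) read_cohort(x) else x
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("empty cohort: no data rows")
  if (!"participant_id" %in% names(cohort))
    stop("cohort lacks a participant_id column")
  if (anyDuplicated(cohort$participant_id))
    stop("duplicate participant_id: ",
         paste(unique(cohort$participant_id[
           duplicated(cohort$participant_id)]), collapse = ", "))
  errors <- list()
  flag <- function(rows, column, values, message) {
    if (length(rows) == 0) return()
    errors[[length(errors) + 1]] <<- data.frame(
      row = rows, participant_id = cohort$participant_id[rows],
      column = column, value = as.character(values), message = message)
  }
  check_range <- function(column, lo, hi, required = TRUE) {
    if (!column %in% names(cohort)) return()
    v <- suppressWarnings(as.numeric(cohort[[column]]))
    bad <- which(if (required) is.na(v) | v < lo | v > hi
                 else !is.na(v) & (v < lo | v > hi))
    flag(bad, column, cohort[[column]][bad],
         sprintf("must be in [%g, %g]", lo, hi))
  }
  check_range("age", 4, 91)
  check_range("education", 1, 7, required = FALSE)
  check_range("paranormal_belief", 1, 6, required = FALSE)
  if ("sex" %in% names(cohort)) {
    bad <- which(!is.na(cohort$sex) & !cohort$sex %in% c("male", "female"))
    flag(bad, "sex", cohort$sex[bad], "must be 'male' or 'female'")
  }
  if ("field" %in% names(cohort)) {
    bad <- which(!is.na(cohort$field) &
                   !cohort$field %in% c("humanities", "science", "other"))
    flag(bad, "field", cohort$field[bad],
         "must be 'humanities', 'science' or 'other'")
  }
  for (spec in tasks) {
    col <- paste0("response_", spec$task_id)
    if (!col %in% names(cohort)) next
    v <- as.character(cohort[[col]])
    bad_len <- which(!is.na(v) & nchar(v) != spec$length)
    flag(bad_len, col, v[bad_len],
         sprintf("response must have %d symbols", spec$length))
    ok <- !is.na(v) & nchar(v) == spec$length
    pat <- sprintf("^[0-%d]*$", spec$alphabet_size - 1L)
    bad_sym <- which(ok & !grepl(pat, v))
    flag(bad_sym, col, v[bad_sym],
         sprintf("symbols must be digits 0-%d", spec$alphabet_size - 1L))
    ctc <- paste0("ct_", spec$task_id)
    if (ctc %in% names(cohort)) {
      ct <- suppressWarnings(as.numeric(cohort[[ctc]]))
      bad_ct <- which(!is.na(cohort[[ctc]]) & (is.na(ct) | ct <= 0))
      flag(bad_ct, ctc, cohort[[ctc]][bad_ct],
           "completion time must be a positive number")
    }
  }
  errors <- if (length(errors) == 0)
    data.frame(row = integer(0), participant_id = character(0),
               column = character(0), value = character(0),
               message = character(0))
  else do.call(rbind, errors)
  valid <- setdiff(seq_len(nrow(cohort)), unique(errors$row))
  list(cohort = cohort[valid, , drop = FALSE], errors = errors)
}

#' Pipeline configuration
#'
#' Assembles the parameters of a full run (simulate or load -> score ->
#' analyze) into a single config object.  The config plus its seeds
#' determines every output of a run; the manifest written by
#' [run_pipeline()] records a hash of it.
#'
#' @param n cohort size to simulate (ignored when `cohort_path` given).
#' @param seed root seed; per-stage seeds derive from it.
#' @param cohort_path optional path to an existing cohort CSV (skips
#'   simulation).
#' @param tables_dir optional directory of prebuilt tables
#'   (see [write_ctm_tables()]); otherwise tables are built.
#' @param table_sample_size,table_seed sampled-table parameters when
#'   building.
#' @param spline_df,bootstrap_reps trajectory-fit parameters.
#' @param glm_dvs dependent variables for the modulating-factor models.
#' @param plots write trajectory figures (PNG) into the run directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(n = 200, seed = 1L, cohort_path = NULL,
                       tables_dir = NULL, table_sample_size = 2e6,
                       table_seed = 7919L, spline_df = 7,
                       bootstrap_reps = 200,
                       glm_dvs = c("mean_z", "z_grid", "total_ct"),
                       plots = FALSE) {
  structure(list(n = n, seed = as.integer(seed), cohort_path = cohort_path,
                 tables_dir = tables_dir,
                 table_sample_size = table_sample_size,
                 table_seed = as.integer(table_seed),
                 spline_df = spline_df, bootstrap_reps = bootstrap_reps,
                 glm_dvs = glm_dvs, plots = isTRUE(plots),
                 version = as.character(utils::packageVersion("rigcomplexity"))),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> score -> analyze and writes all outputs
#' into a run directory: `cohort.csv`, `scores.csv`,
#' `participant_summary.csv`, `trajectories.csv`, `glm.csv`,
#' `reliability.csv`, `correlations.csv` and a `manifest.json` with the
#' config hash, seeds, table provenance, row counts and stage timings.
#' Reruns with the same config are bit-identical.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  tables <- stage("tables", {
    if (!is.null(config$tables_dir)) read_ctm_tables(config$tables_dir)
    else build_ctm_tables(sample_size = config$table_sample_size,
                          seed = config$table_seed)
  })
  for (spec in rig_tasks())
    if (is.null(tables[[spec$table_id]]))
      stop("stage 'tables' failed: table '", spec$table_id,
           "' missing from the table set", call. = FALSE)

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_path)) {
      v <- validate_cohort(config$cohort_path)
      if (nrow(v$errors) > 0)
        warning(nrow(v$errors), " invalid rows dropped during validation")
      v$cohort
    } else {
      sample_cohort(config$n, seed = config$seed)
    }
  })

  scores <- stage("score", score_cohort(cohort, tables))
  wide <- participant_summary(scores, cohort)

  analysis <- stage("analyze", {
    traj_vars <- c("mean_z", "total_ct",
                   paste0("z_", names(rig_tasks())),
                   paste0("ct_", names(rig_tasks())))
    fits <- lapply(traj_vars, function(v)
      fit_trajectory(wide, v, spline_df = config$spline_df,
                     bootstrap_reps = config$bootstrap_reps,
                     seed = derive_seed(config$seed, 7L)))
    names(fits) <- traj_vars
    traj <- do.call(rbind, lapply(fits, function(f)
      data.frame(variable = f$variable, age = f$age, fitted = f$fitted,
                 ci_lower = f$ci_lower, ci_upper = f$ci_upper,
                 peak_age = f$peak_age)))
    glms <- do.call(rbind, lapply(config$glm_dvs, function(dv) {
      g <- fit_glm(wide, dv)
      cbind(dv = dv, g$terms, n_used = g$n_used)
    }))
    glms$p_holm <- stats::p.adjust(glms$p_value, method = "holm")
    rel <- rbind(
      data.frame(variable_set = "ct",
                 alpha = reliability_alpha(wide,
                   paste0("ct_", names(rig_tasks())))$alpha),
      data.frame(variable_set = "z",
                 alpha = reliability_alpha(wide,
                   paste0("z_", names(rig_tasks())))$alpha))
    corr <- age_window_correlation(wide, "total_ct", "mean_z", c(25, 60))
    list(fits = fits, traj = traj, glms = glms, rel = rel, corr = corr)
  })

  stage("write", {
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(wide, file.path(out_dir, "participant_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$traj, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$glms, file.path(out_dir, "glm.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$rel, file.path(out_dir, "reliability.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(pair = "total_ct~mean_z", r = analysis$corr$r,
                 p_value = analysis$corr$p_value, n = analysis$corr$n,
                 age_min = 25, age_max = 60),
      file.path(out_dir, "correlations.csv"), row.names = FALSE)
    if (config$plots) {
      ggplot2::ggsave(file.path(out_dir, "trajectory_mean_z.png"),
                      plot_trajectory(analysis$fits$mean_z, wide),
                      width = 7, height = 5, dpi = 150)
      ggplot2::ggsave(file.path(out_dir, "speed_accuracy.png"),
                      plot_speed_accuracy(speed_accuracy_path(
                        analysis$fits$total_ct, analysis$fits$mean_z)),
                      width = 7, height = 5, dpi = 150)
    }
  })

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  hash_file <- tempfile()
  writeLines(cfg_json, hash_file)
  manifest <- list(
    config = unclass(config),
    config_hash = unname(tools::md5sum(hash_file)),
    n_participants = nrow(cohort), n_scores = nrow(scores),
    tables = lapply(tables, function(t)
      c(t$source, total_halting = t$total_halting)),
    timings = timings)
  unlink(hash_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}
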