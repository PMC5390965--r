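#' Canonical symbol-order form of a sequence
#'
#' Relabels symbols in order of first occurrence (first distinct symbol
#' becomes 0, the next 1, ...).  Any two sequences that differ only by a
#' permutation of the alphabet share a canonical form, so complexity
#' scores are invariant under relabelling (which side of the coin is
#' "heads" cannot matter).  Idempotent.
#'
#' @param x integer vector of symbols in `0..alphabet_size-1`, or a digit
#'   string.
#' @param alphabet_size number of symbols in the task alphabet.
#' @return The canonical sequence, in the same representation as the
#'   input.
#' @examples
#' canonical_form("221212", 3)  # "001010"
#' @export
canonical_form <- function(x, alphabet_size) {
  as_string <- is.character(x)
  if (as_string) {
    stopifnot(length(x) == 1L)
    x <- suppressWarnings(as.integer(strsplit(x, "")[[1]]))
  }
  x <- as.integer(x)
  bad <- which(is.na(x) | x < 0L | x >= alphabet_size)
  if (length(bad) > 0)
    stop(sprintf("symbol out of range 0..%d at position %d",
                 alphabet_size - 1L, bad[1]))
  lev <- unique(x)
  out <- match(x, lev) - 1L
  if (as_string) paste0(out, collapse = "") else out
}

#' Exact complexity moments over a full string space
#'
#' Computes the mean and standard deviation of the complexity estimate
#' over *all* `alphabet_size^length` possible responses of a task --- the
#' normalization baseline --- without enumerating the strings one by one.
#' Because scores depend only on the symbol-permutation class, it suffices
#' to iterate the canonical class representatives (restricted growth
#' strings) and weight each class having d distinct symbols by
#' `k!/(k-d)!`, the number of strings in the class.
#'
#' @param spec a [rig_task()] spec.
#' @param table the backing [coding_theorem()] table.
#' @return list with `mu` and `sigma` (bits) and `n_strings`.
#' @export
string_space_moments <- function(spec, table) {
  stopifnot(inherits(spec, "task_spec"), inherits(table, "ctm_table"))
  key <- moments_key(spec, table)
  hit <- .rig_cache$moments[[key]]
  if (!is.null(hit)) return(hit)
  k <- spec$alphabet_size
  rg <- cpp_rgs(spec$length, k)
  sc <- score_keys(rg$key, spec, table)
  w <- exp(lfactorial(k) - lfactorial(k - rg$n_distinct))
  n_strings <- k^spec$length
  stopifnot(isTRUE(all.equal(sum(w), n_strings)))
  mu <- sum(w * sc$K) / n_strings
  sigma2 <- sum(w * (sc$K - mu)^2) / n_strings
  if (sigma2 <= 1e-18)
    stop("degenerate table: complexity is constant over the string space (sigma = 0)")
  out <- list(mu = mu, sigma = sqrt(sigma2), n_strings = n_strings)
  .rig_cache$moments[[key]] <- out
  out
}

.rig_cache <- new.env(parent = emptyenv())
.rig_cache$moments <- list()

moments_key <- function(spec, table) {
  s <- table$source
  paste(spec$task_id, spec$length, spec$alphabet_size,
        paste(spec$block, collapse = "x"),
        s$n_states, s$n_symbols, s$dimension, s$mode, s$step_cap,
        s$sample_size %||% 0, s$seed %||% 0,
        table$total_halting, table$fallback, sep = "|")
}

# Vectorized complexity of full-length response keys (digit strings) under
# a task's block decomposition.  Blocks are canonicalized individually for
# the table lookup; multiplicities count raw (uncanonicalized) repeats, so
# the total is invariant under alphabet permutations of the whole
# response.
score_keys <- function(keys, spec, table) {
  L <- spec$length
  if (length(spec$block) == 2L &&
      !identical(as.integer(spec$block), c(1L, 3L))) {
    # general 2-D decomposition: per-response bdm()
    res <- lapply(keys, function(kk) {
      m <- matrix(as.integer(strsplit(kk, "")[[1]]), nrow = spec$shape[1],
                  byrow = TRUE)
      bdm(m, table, spec$block)
    })
    return(list(K = vapply(res, `[[`, numeric(1), "bits"),
                fallback_used = vapply(res, `[[`, logical(1),
                                       "fallback_used")))
  }
  b <- spec$block[length(spec$block)]
  st <- split_starts(L, b)
  m <- length(st$from)
  raw <- lapply(seq_len(m),
                function(i) substr(keys, st$from[i], st$to[i]))
  Kb <- matrix(0, nrow = length(keys), ncol = m)
  fb <- logical(length(keys))
  for (i in seq_len(m)) {
    lk <- ctm_lookup(table, raw[[i]])
    Kb[, i] <- lk$K
    fb <- fb | lk$fallback_used
  }
  K <- switch(as.character(m),
    "1" = Kb[, 1],
    "2" = ifelse(raw[[1]] == raw[[2]], Kb[, 1] + 1, Kb[, 1] + Kb[, 2]),
    "3" = {
      d12 <- raw[[1]] == raw[[2]]
      d13 <- raw[[1]] == raw[[3]]
      d23 <- raw[[2]] == raw[[3]]
      ifelse(d12 & d13, Kb[, 1] + log2(3),
      ifelse(d12, Kb[, 1] + 1 + Kb[, 3],
      ifelse(d13, Kb[, 1] + 1 + Kb[, 2],
      ifelse(d23, Kb[, 2] + 1 + Kb[, 1],
             Kb[, 1] + Kb[, 2] + Kb[, 3]))))
    },
    { # arbitrary block count: row-wise aggregation
      vapply(seq_along(keys), function(r) {
        tt <- table(unlist(lapply(raw, `[`, r)))
        lk <- ctm_lookup(table, names(tt))
        sum(lk$K + log2(as.numeric(tt)))
      }, numeric(1))
    })
  list(K = K, fallback_used = fb)
}

#' Score one task response
#'
#' Computes the complexity estimate of a response under its task's block
#' decomposition and standardizes it against the exact mean and standard
#' deviation of the complexity of *all* possible responses of that length
#' and alphabet (see [string_space_moments()]): a normalized complexity of
#' 0 is the mean over the full string space, and the population SD is 1.
#'
#' @param response integer vector (symbols `0..k-1`), digit string, or,
#'   for the grid task, a 3x3 binary matrix or 9-cell row-major vector.
#' @param spec a [rig_task()] spec.
#' @param table the backing [coding_theorem()] table (must match
#'   `spec$table_id` conceptually; not checked).
#' @return list with `K_bits`, `z` (normalized complexity) and
#'   `fallback_used`.
#' @export
score_response <- function(response, spec, table) {
  stopifnot(inherits(spec, "task_spec"))
  if (is.matrix(response)) {
    if (!identical(dim(response), as.integer(spec$shape)))
      stop("response shape does not match the task spec")
    response <- as.integer(t(response))
  }
  if (is.character(response)) {
    stopifnot(length(response) == 1L)
    response <- suppressWarnings(as.integer(strsplit(response, "")[[1]]))
  }
  if (length(response) == 0) stop("empty response")
  if (length(response) != spec$length)
    stop(sprintf("response has %d symbols, expected %d", length(response),
                 spec$length))
  key <- paste0(canonical_form(response, spec$alphabet_size), collapse = "")
  mom <- string_space_moments(spec, table)
  sc <- score_keys(key, spec, table)
  list(K_bits = sc$K, z = (sc$K - mom$mu) / mom$sigma,
       fallback_used = sc$fallback_used)
}

#' Score every response of a cohort
#'
#' @param cohort a cohort data frame (see [sample_cohort()] /
#'   [read_cohort()]): one row per participant with `response_<task>` and
#'   `ct_<task>` columns.
#' @param tables a [build_ctm_tables()] table set.
#' @param tasks task specs to score (default: all five built-ins).
#' @return Long data frame: `participant_id`, `task_id`, `K_bits`, `z`,
#'   `ct_seconds`, `fallback_used`.  Missing responses yield NA rows.
#' @export
score_cohort <- function(cohort, tables, tasks = rig_tasks()) {
  stopifnot(is.data.frame(cohort))
  out <- lapply(tasks, function(spec) {
    col <- paste0("response_", spec$task_id)
    ctc <- paste0("ct_", spec$task_id)
    if (!col %in% names(cohort))
      stop("cohort lacks column ", col)
    tab <- tables[[spec$table_id]]
    if (is.null(tab))
      stop("table set lacks table '", spec$table_id, "' needed by task '",
           spec$task_id, "'")
    resp <- as.character(cohort[[col]])
    ok <- !is.na(resp) & nchar(resp) == spec$length
    keys <- cpp_canonicalize(resp[ok])
    mom <- string_space_moments(spec, tab)
    K <- rep(NA_real_, nrow(cohort))
    fb <- rep(NA, nrow(cohort))
    if (any(ok)) {
      sc <- score_keys(keys, spec, tab)
      K[ok] <- sc$K
      fb[ok] <- sc$fallback_used
    }
    data.frame(participant_id = cohort$participant_id,
               task_id = spec$task_id, K_bits = K,
               z = (K - mom$mu) / mom$sigma,
               ct_seconds = if (ctc %in% names(cohort)) cohort[[ctc]]
                            else NA_real_,
               fallback_used = fb)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean normalized complexity per participant
#'
#' Arithmetic mean of the available per-task normalized complexities;
#' participants with no scored task get NA (missingness propagates, it is
#' not an error).
#'
#' @param scores long score table from [score_cohort()].
#' @return data frame `participant_id`, `mean_z`, `n_tasks`.
#' @export
mean_complexity <- function(scores) {
  stopifnot(all(c("participant_id", "z") %in% names(scores)))
  ids <- unique(scores$participant_id)
  z <- split(scores$z, factor(scores$participant_id, levels = ids))
  data.frame(
    participant_id = ids,
    mean_z = vapply(z, function(v) if (all(is.na(v))) NA_real_
                    else mean(v, na.rm = TRUE), numeric(1)),
    n_tasks = vapply(z, function(v) sum(!is.na(v)), integer(1)),
    row.names = NULL)
}

#' Wide per-participant summary for analysis
#'
#' Joins the long score table back to the cohort demographics: one row per
#' participant with `z_<task>`, `ct_<task>`, `mean_z`, `n_tasks` and
#' `total_ct`.
#'
#' @param scores long score table from [score_cohort()].
#' @param cohort the cohort the scores came from.
#' @return wide data frame.
#' @export
participant_summary <- function(scores, cohort) {
  wide <- mean_complexity(scores)
  for (task in unique(scores$task_id)) {
    s <- scores[scores$task_id == task, ]
    wide[[paste0("z_", task)]] <-
      s$z[match(wide$participant_id, s$participant_id)]
    wide[[paste0("ct_", task)]] <-
      s$ct_seconds[match(wide$participant_id, s$participant_id)]
  }
  ctcols <- grep("^ct_", names(wide), value = TRUE)
  wide$total_ct <- rowSums(wide[, ctcols, drop = FALSE])
  demo <- intersect(c("participant_id", "age", "sex", "education", "field",
                      "paranormal_belief", "ability"), names(cohort))
  merge(cohort[, demo, drop = FALSE], wide, by = "participant_id",
        sort = FALSE)
}

#' First-order (Shannon) entropy of a sequence
#'
#' Entropy of the empirical symbol distribution, in bits, with
#' `0 * log2(0)` taken as 0.  Ranges from 0 (constant sequence) to
#' `log2(alphabet_size)` (balanced use of all symbols).  A comparator for
#' the complexity score: a strictly alternating sequence attains maximal
#' first-order entropy yet is algorithmically trivial.
#'
#' @param x integer vector or digit string.
#' @param alphabet_size alphabet size (only bounds the theoretical
#'   maximum; the estimate uses empirical frequencies).
#' @return entropy in bits.
#' @examples
#' first_order_entropy("010101010101", 2)  # 1 bit
#' @export
first_order_entropy <- function(x, alphabet_size = NULL) {
  if (is.character(x)) x <- as.integer(strsplit(x, "")[[1]])
  if (length(x) == 0) stop("empty sequence")
  p <- as.numeric(table(x)) / length(x)
  -sum(p * log2(p))
}
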