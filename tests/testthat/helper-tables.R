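# shared complexity tables, built lazily once per test run
.tt_cache <- new.env(parent = emptyenv())

tt_table <- function(id) {
  if (is.null(.tt_cache[[id]])) {
    .tt_cache[[id]] <- switch(id,
      tm2_2 = coding_theorem(enumerate_space(machine_space(2, 2))),
      tm3_2 = coding_theorem(enumerate_space(machine_space(3, 2))),
      tm2_2_2d = coding_theorem(enumerate_space(
        machine_space(2, 2, dimension = 2))),
      stop("unknown test table ", id))
  }
  .tt_cache[[id]]
}

# small sampled tables: enough coverage for smoke tests, built in seconds
tt_tables_small <- function() {
  if (is.null(.tt_cache$small))
    .tt_cache$small <- build_ctm_tables(sample_size = 2e5, seed = 7919L)
  .tt_cache$small
}

# the default (shipped-scale) instrument used by the acceptance checks
tt_tables_full <- function() {
  if (is.null(.tt_cache$full))
    .tt_cache$full <- build_ctm_tables()
  .tt_cache$full
}

# weighted z moments of a task over its full string space, given any table
tt_weighted_z <- function(spec, table) {
  k <- spec$alphabet_size
  rg <- rigcomplexity:::cpp_rgs(spec$length, k)
  sc <- rigcomplexity:::score_keys(rg$key, spec, table)
  mom <- string_space_moments(spec, table)
  w <- exp(lfactorial(k) - lfactorial(k - rg$n_distinct))
  z <- (sc$K - mom$mu) / mom$sigma
  list(mean = sum(w * z) / mom$n_strings,
       sd = sqrt(sum(w * z^2) / mom$n_strings -
                   (sum(w * z) / mom$n_strings)^2),
       z = z, w = w, keys = rg$key)
}
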