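#' Enumerate a machine space and collect its output-frequency distribution
#'
#' Every machine in the space is run from an all-blank tape (or grid) with
#' the head at the origin.  A machine halting within `step_cap` steps
#' contributes one count to its output: the tape segment spanned by every
#' position the head occupied (minimal bounding rectangle in 2-D), read
#' left-to-right (row-major in 2-D) and relabelled to canonical symbol
#' order (first distinct symbol is 0, second is 1, ...).  Machines that do
#' not halt are excluded from both numerator and denominator.
#'
#' @param space an exhaustive-mode [machine_space()].  Spaces with more
#'   than `1e8` machines are refused.
#' @return An object of class `ctm_dist`: the canonical output counts, the
#'   number of halting machines, and provenance.
#' @examples
#' d <- enumerate_space(machine_space(2, 2))
#' d$n_machines   # 10000 = (2*2*2 + 2)^(2*2)
#' @export
enumerate_space <- function(space) {
  stopifnot(inherits(space, "machine_space"))
  if (space$mode != "exhaustive")
    stop("enumerate_space() requires an exhaustive-mode space; see sample_space()")
  nm <- n_machines(space)
  if (nm > 1e8)
    stop(sprintf(
      "space contains %.3g machines, above the 1e8 enumeration budget; use sampled mode",
      nm))
  known <- default_step_cap(space$n_states, space$n_symbols, space$dimension)
  if (space$step_cap < known)
    warning(sprintf(
      "step_cap %d is below the known maximal halting time %d for this space; the distribution will be truncated",
      space$step_cap, known))
  raw <- cpp_enumerate(space$n_states, space$n_symbols, space$dimension,
                       space$step_cap)
  new_ctm_dist(raw, space)
}

#' Sample a machine space at random
#'
#' Draws `sample_size` machines uniformly (each transition entry uniform
#' over its option set, with replacement) and simulates them exactly as
#' [enumerate_space()] does.  A Monte-Carlo stand-in for full enumeration
#' in spaces too large to visit exhaustively; reproducible given the seed.
#'
#' @param space a sampled-mode [machine_space()] with `sample_size` and
#'   `seed` set.
#' @return A `ctm_dist`.
#' @export
sample_space <- function(space) {
  stopifnot(inherits(space, "machine_space"))
  if (space$mode != "sampled")
    stop("sample_space() requires a sampled-mode space; see enumerate_space()")
  raw <- cpp_sample(space$n_states, space$n_symbols, space$dimension,
                    space$step_cap, space$sample_size, space$seed)
  new_ctm_dist(raw, space)
}

new_ctm_dist <- function(raw, space) {
  if (raw$total_halting > 0) {
    ord <- order(raw$key)
    counts <- setNames(raw$count[ord], raw$key[ord])
  } else {
    counts <- setNames(numeric(0), character(0))
  }
  structure(
    list(space = space, counts = counts,
         total_halting = raw$total_halting, n_machines = raw$n_machines,
         max_steps_halting = raw$max_steps_halting),
    class = "ctm_dist")
}

#' @export
print.ctm_dist <- function(x, ...) {
  cat(sprintf(
    "<ctm_dist> %d canonical outputs from %s halting machines (of %s run)\n",
    length(x$counts), format(x$total_halting, big.mark = ","),
    format(x$n_machines, big.mark = ",")))
  invisible(x)
}

#' Turn an output-frequency distribution into a complexity table
#'
#' Applies the coding theorem: the algorithmic probability of a string is
#' approximated by its output frequency among halting machines,
#' `m(s) = count(s) / total_halting`, and its complexity estimate is
#' `K(s) = -log2 m(s)` bits.  Strings absent from the table are assigned a
#' fallback value of `max(K) + fallback_margin` bits, which preserves the
#' frequency ordering (anything never produced is rarer than anything
#' produced) while keeping scores defined under partial coverage.
#'
#' @param dist a `ctm_dist` with at least one halting machine.
#' @param fallback_margin bits added above the maximum covered complexity
#'   for strings absent from the table (default 1).
#' @return An object of class `ctm_table` mapping canonical strings to
#'   complexity in bits.
#' @examples
#' tab <- coding_theorem(enumerate_space(machine_space(2, 2)))
#' ctm_lookup(tab, "010")
#' @export
coding_theorem <- function(dist, fallback_margin = 1) {
  stopifnot(inherits(dist, "ctm_dist"))
  if (dist$total_halting < 1)
    stop("empty distribution: no machine halted, cannot apply the coding theorem")
  stopifnot(fallback_margin > 0)
  K <- -log2(dist$counts / dist$total_halting)
  structure(
    list(K = K, counts = dist$counts, total_halting = dist$total_halting,
         fallback = max(K) + fallback_margin,
         fallback_margin = fallback_margin,
         dimension = dist$space$dimension,
         source = dist$space[c("n_states", "n_symbols", "dimension",
                               "step_cap", "mode", "sample_size", "seed")]),
    class = "ctm_table")
}

#' @export
print.ctm_table <- function(x, ...) {
  s <- x$source
  cat(sprintf(
    "<ctm_table> %d strings, K in [%.3f, %.3f] bits, fallback %.3f bits\n",
    length(x$K), min(x$K), max(x$K), x$fallback))
  cat(sprintf("  source: (%d,%d) %d-D, %s, step cap %d\n",
              s$n_states, s$n_symbols, s$dimension, s$mode, s$step_cap))
  invisible(x)
}

#' Look up complexity estimates in a table
#'
#' Keys are canonicalized (symbol relabelling by first occurrence) before
#' lookup, so `K(s)` is invariant under any permutation of the alphabet.
#' Two-dimensional keys use `/` as the row separator, e.g. `"01/10"`.
#'
#' @param table a [coding_theorem()] table.
#' @param keys character vector of strings (digits 0-8) or 2-D keys.
#' @param canonicalize relabel keys before lookup (default TRUE).
#' @return list with `K` (bits) and `fallback_used` (logical), both the
#'   length of `keys`.
#' @export
ctm_lookup <- function(table, keys, canonicalize = TRUE) {
  stopifnot(inherits(table, "ctm_table"), is.character(keys))
  if (canonicalize) keys <- cpp_canonicalize(keys)
  K <- unname(table$K[keys])
  fb <- is.na(K)
  K[fb] <- table$fallback
  list(K = K, fallback_used = fb)
}

#' Block decomposition complexity of a string or array
#'
#' Extends a base complexity table to inputs longer than the strings the
#' table covers: the input is cut into non-overlapping blocks (remainder
#' blocks keep their natural smaller size) and the total complexity is
#' `sum over distinct blocks [K(block) + log2(multiplicity)]`, i.e. each
#' repeated block costs its description once plus the bits needed to say
#' how often it occurs.
#'
#' @param x an integer vector (symbols 0..k-1), a digit string, or an
#'   integer matrix for 2-D inputs.
#' @param base_table a [coding_theorem()] table covering the block shapes
#'   (fallback allowed).
#' @param block_shape block length (1-D) or `c(rows, cols)` (2-D).  Must
#'   not exceed the input size.
#' @return list with `bits` (total complexity) and `fallback_used`
#'   (TRUE if any block was scored by the fallback rule).
#' @examples
#' tab <- coding_theorem(enumerate_space(machine_space(2, 2)))
#' bdm(c(0, 1, 0, 1, 0, 1), tab, block_shape = 3)
#' @export
bdm <- function(x, base_table, block_shape) {
  stopifnot(inherits(base_table, "ctm_table"))
  if (is.character(x) && length(x) == 1L)
    x <- as.integer(strsplit(x, "")[[1]])
  if (length(x) == 0) stop("empty input")
  if (is.matrix(x)) {
    stopifnot(length(block_shape) == 2L)
    if (any(block_shape > dim(x)))
      stop("block_shape is larger than the input")
    rs <- split_starts(nrow(x), block_shape[1])
    cs <- split_starts(ncol(x), block_shape[2])
    keys <- character(0)
    for (r in seq_along(rs$from))
      for (cc in seq_along(cs$from)) {
        blk <- x[rs$from[r]:rs$to[r], cs$from[cc]:cs$to[cc], drop = FALSE]
        keys <- c(keys, paste(apply(blk, 1, paste0, collapse = ""),
                              collapse = "/"))
      }
  } else {
    block_shape <- block_shape[1]
    if (block_shape > length(x)) stop("block_shape is larger than the input")
    st <- split_starts(length(x), block_shape)
    keys <- vapply(seq_along(st$from), function(i)
      paste0(x[st$from[i]:st$to[i]], collapse = ""), character(1))
  }
  bdm_from_keys(keys, base_table)
}

split_starts <- function(n, b) {
  from <- seq.int(1L, n, by = b)
  list(from = from, to = pmin(from + b - 1L, n))
}

# aggregate raw block keys: distinct blocks contribute K(canonical) +
# log2(multiplicity)
bdm_from_keys <- function(keys, base_table) {
  tab <- table(keys)
  lk <- ctm_lookup(base_table, names(tab))
  list(bits = sum(lk$K + log2(as.numeric(tab))),
       fallback_used = any(lk$fallback_used))
}
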