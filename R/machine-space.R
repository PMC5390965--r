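#' Define a space of small Turing machines
#'
#' A machine space is the set of all (n states, k symbols) Turing machines
#' under a fixed formalism: every transition entry, indexed by
#' (state, read symbol), either writes a symbol, moves the head and enters a
#' next state, or writes a symbol and halts.  One-dimensional machines move
#' left/right on a blank tape (blank = symbol 0); two-dimensional machines
#' move up/down/left/right on a blank grid.  The number of machines is
#' therefore `(2*k*n + k)^(n*k)` in one dimension and `(4*k*n + k)^(n*k)`
#' in two — e.g. `22^10` for the classic (5,2) space and `10^4` for (2,2).
#'
#' @param n_states number of states (positive integer).
#' @param n_symbols number of tape symbols including the blank (symbol 0).
#' @param dimension 1 for tape machines, 2 for grid machines ("turmites").
#' @param step_cap maximum number of steps before a run is declared
#'   non-halting.  Defaults to the exact maximal halting time of the space
#'   where known ((2,2) and (3,2) tapes, (2,2) grids, verified by
#'   enumeration; 107 for (4,2) tapes) and to 500 otherwise.
#' @param mode `"exhaustive"` to visit every machine, `"sampled"` to draw
#'   machines uniformly at random (with replacement) from the space.
#' @param sample_size number of machines to draw in sampled mode.
#' @param seed integer seed, mandatory in sampled mode.
#' @return An object of class `machine_space`.
#' @seealso [enumerate_space()], [sample_space()]
#' @export
machine_space <- function(n_states, n_symbols, dimension = 1L,
                          step_cap = NULL,
                          mode = c("exhaustive", "sampled"),
                          sample_size = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_states >= 1, n_symbols >= 1, dimension %in% c(1L, 2L))
  if (n_symbols > 9L)
    stop("machine spaces with more than 9 symbols are not supported")
  if (is.null(step_cap))
    step_cap <- default_step_cap(n_states, n_symbols, dimension)
  if (step_cap < 1) stop("step_cap must be >= 1 (got ", step_cap, ")")
  if (mode == "sampled") {
    if (is.null(sample_size) || sample_size < 1)
      stop("sampled mode requires sample_size >= 1")
    if (is.null(seed)) stop("sampled mode requires an explicit seed")
  }
  structure(
    list(n_states = as.integer(n_states), n_symbols = as.integer(n_symbols),
         dimension = as.integer(dimension), step_cap = as.integer(step_cap),
         mode = mode,
         sample_size = if (!is.null(sample_size)) as.numeric(sample_size),
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "machine_space")
}

# Exact maximal halting times, verified by enumerating the space with a
# generous cap: 6 for (2,2) tapes, 21 for (3,2) tapes, 6 for (2,2) grids.
# 107 is the classical bound for (4,2) tapes.  500 is a conservative
# default elsewhere.
default_step_cap <- function(n_states, n_symbols, dimension) {
  if (dimension == 1L) {
    if (n_states == 2 && n_symbols == 2) return(6L)
    if (n_states == 3 && n_symbols == 2) return(21L)
    if (n_states == 4 && n_symbols == 2) return(107L)
  } else if (n_states == 2 && n_symbols == 2) {
    return(6L)
  }
  500L
}

#' Number of machines in a space
#'
#' Closed form `(2*k*n + k)^(n*k)` (1-D) or `(4*k*n + k)^(n*k)` (2-D).
#'
#' @param space a [machine_space()].
#' @return A double (spaces easily exceed integer range).
#' @export
n_machines <- function(space) {
  stopifnot(inherits(space, "machine_space"))
  k <- space$n_symbols; n <- space$n_states
  base <- (if (space$dimension == 2L) 4 else 2) * k * n + k
  base^(n * k)
}

#' @export
print.machine_space <- function(x, ...) {
  cat(sprintf("<machine_space> (%d states, %d symbols, %d-D), %s mode\n",
              x$n_states, x$n_symbols, x$dimension, x$mode))
  cat(sprintf("  machines: %s, step cap: %d\n",
              format(n_machines(x), big.mark = ","), x$step_cap))
  if (x$mode == "sampled")
    cat(sprintf("  sample size: %s, seed: %d\n",
                format(x$sample_size, big.mark = ","), x$seed))
  invisible(x)
}
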