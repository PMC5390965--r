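#' Specifications of the five random item generation tasks
#'
#' The battery consists of five classic RIG tasks: producing 12 coin flips
#' (binary, the sequence invisible while typing), guessing 10 Zener cards
#' (5 alternatives), producing 10 die rolls (6 alternatives, previous
#' choices visible), pointing 10 times at one of 9 circles (previous
#' choices invisible), and blackening cells of a 3x3 grid until it "looks
#' random" (binary, freely revisable).  Symbols are coded 0..k-1
#' throughout; die faces 1-6 map to 0-5, circles 1-9 to 0-8.
#'
#' Each spec also fixes how the response is scored: the identifier of the
#' backing complexity table and the block decomposition used
#' (see [score_response()]).  Defaults: coin in two blocks of 6 over a
#' sampled (4,2) tape-machine table; card/die/circles in two blocks of 5
#' over sampled (2,5)/(2,6)/(2,9) tables; the grid read row-major and
#' scored in blocks of 5 over the (4,2) table (the exhaustive 2-D (2,2)
#' grid-machine space only produces line-shaped outputs at desk scale, so
#' its row scores are nearly flat; score against `"tm2_2_2d"` with
#' `block = c(1, 3)` to use it anyway).
#'
#' @param task_id one of `"coin"`, `"card"`, `"die"`, `"circles"`,
#'   `"grid"`.
#' @return `rig_task()` returns a single `task_spec`; `rig_tasks()` the
#'   named list of all five.
#' @export
rig_task <- function(task_id = c("coin", "card", "die", "circles", "grid")) {
  task_id <- match.arg(task_id)
  spec <- switch(task_id,
    coin = list(alphabet_size = 2L, length = 12L, shape = NULL,
                dimension = 1L, table_id = "tm4_2", block = 6L),
    card = list(alphabet_size = 5L, length = 10L, shape = NULL,
                dimension = 1L, table_id = "tm2_5", block = 5L),
    die = list(alphabet_size = 6L, length = 10L, shape = NULL,
               dimension = 1L, table_id = "tm2_6", block = 5L),
    circles = list(alphabet_size = 9L, length = 10L, shape = NULL,
                   dimension = 1L, table_id = "tm2_9", block = 5L),
    grid = list(alphabet_size = 2L, length = 9L, shape = c(3L, 3L),
                dimension = 2L, table_id = "tm4_2", block = 5L))
  structure(c(list(task_id = task_id), spec), class = "task_spec")
}

#' @rdname rig_task
#' @export
rig_tasks <- function() {
  ids <- c("coin", "card", "die", "circles", "grid")
  setNames(lapply(ids, rig_task), ids)
}

#' @export
print.task_spec <- function(x, ...) {
  shape <- if (is.null(x$shape)) sprintf("length %d", x$length)
           else sprintf("%dx%d grid", x$shape[1], x$shape[2])
  cat(sprintf("<task_spec> %s: %d symbols, %s; table %s, blocks %s\n",
              x$task_id, x$alphabet_size, shape, x$table_id,
              paste(x$block, collapse = "x")))
  invisible(x)
}
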