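# Independent, naive Turing-machine simulator used as the oracle for the
# optimized enumerator.  Deliberately different implementation: the tape
# is a growing R vector re-allocated on demand, machines are decoded from
# a base-(2kn+k) machine index, and canonicalization is done with
# match(x, unique(x)).

naive_canonical <- function(symbols) {
  paste0(match(symbols, unique(symbols)) - 1L, collapse = "")
}

naive_run <- function(entries, n_states, n_symbols, step_cap) {
  halt_base <- 2L * n_symbols * n_states
  tape <- 0L            # growing sequence
  pos <- 1L             # head index within tape
  offset <- 0L          # tape[1] corresponds to absolute position -offset
  visited_lo <- visited_hi <- 0L   # absolute positions visited by the head
  q <- 0L
  for (st in seq_len(step_cap)) {
    sym <- tape[pos]
    e <- entries[q * n_symbols + sym + 1L]
    if (e >= halt_base) {
      tape[pos] <- e - halt_base
      lo <- visited_lo + offset + 1L
      hi <- visited_hi + offset + 1L
      return(naive_canonical(tape[lo:hi]))
    }
    w <- e %% n_symbols
    t2 <- e %/% n_symbols
    mv <- if (t2 %% 2L == 0L) -1L else 1L
    q <- t2 %/% 2L
    tape[pos] <- w
    abs_pos <- pos - offset - 1L + mv
    if (abs_pos < -offset) {       # grow left
      tape <- c(0L, tape)
      offset <- offset + 1L
    } else if (abs_pos + offset + 1L > length(tape)) {
      tape <- c(tape, 0L)          # grow right
    }
    pos <- abs_pos + offset + 1L
    visited_lo <- min(visited_lo, abs_pos)
    visited_hi <- max(visited_hi, abs_pos)
  }
  NULL
}

naive_distribution <- function(n_states, n_symbols, step_cap) {
  base <- 2L * n_symbols * n_states + n_symbols
  nk <- n_states * n_symbols
  total <- base^nk
  counts <- list()
  for (m in 0:(total - 1)) {
    idx <- m
    entries <- integer(nk)
    for (i in seq_len(nk)) {
      entries[i] <- idx %% base
      idx <- idx %/% base
    }
    key <- naive_run(entries, n_states, n_symbols, step_cap)
    if (!is.null(key))
      counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  counts <- unlist(counts)
  counts[order(names(counts))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
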