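#' Build the desk-scale complexity tables backing the task battery
#'
#' Builds the set of coding-theorem tables the built-in task specs refer
#' to.  Small binary spaces are enumerated exhaustively; the larger spaces
#' needed for multi-symbol alphabets are sampled:
#'
#' * `tm2_2` - (2,2) tape machines, exhaustive (10,000 machines);
#' * `tm3_2` - (3,2) tape machines, exhaustive (~7.5M machines);
#' * `tm4_2` - (4,2) tape machines, sampled (coin task);
#' * `tm2_5`, `tm2_6`, `tm2_9` - (2,k) tape machines, sampled
#'   (card, die, circles tasks);
#' * `tm2_2_2d` - (2,2) grid machines, exhaustive (104,976 machines;
#'   grid task).
#'
#' Sampled tables are reproducible: the i-th sampled space uses
#' `seed + i`.  The default seed is fixed so that the default table set is
#' a stable measurement instrument; at full scale the published tables
#' come from vastly larger enumerations, so absolute K values here are
#' desk-scale estimates (coverage of long strings is partial, handled by
#' the fallback rule).
#'
#' @param which table identifiers to build (default: all of the above).
#' @param sample_size machines drawn per sampled space (default 2e6).
#' @param seed base seed for the sampled spaces.
#' @param fallback_margin bits above the maximum covered complexity for
#'   absent strings (see [coding_theorem()]).
#' @return A named list of [coding_theorem()] tables
#'   (class `ctm_table_set`).
#' @export
build_ctm_tables <- function(which = c("tm2_2", "tm3_2", "tm4_2", "tm2_5",
                                       "tm2_6", "tm2_9", "tm2_2_2d"),
                             sample_size = 2e6, seed = 7919L,
                             fallback_margin = 1) {
  which <- match.arg(which, several.ok = TRUE)
  specs <- list(
    tm2_2    = list(n = 2L, k = 2L, dim = 1L, mode = "exhaustive"),
    tm3_2    = list(n = 3L, k = 2L, dim = 1L, mode = "exhaustive"),
    tm4_2    = list(n = 4L, k = 2L, dim = 1L, mode = "sampled"),
    tm2_5    = list(n = 2L, k = 5L, dim = 1L, mode = "sampled"),
    tm2_6    = list(n = 2L, k = 6L, dim = 1L, mode = "sampled"),
    tm2_9    = list(n = 2L, k = 9L, dim = 1L, mode = "sampled"),
    tm2_2_2d = list(n = 2L, k = 2L, dim = 2L, mode = "exhaustive"))
  out <- lapply(seq_along(which), function(i) {
    s <- specs[[which[i]]]
    if (s$mode == "exhaustive") {
      sp <- machine_space(s$n, s$k, s$dim)
      coding_theorem(enumerate_space(sp), fallback_margin)
    } else {
      sp <- machine_space(s$n, s$k, s$dim, mode = "sampled",
                          sample_size = sample_size,
                          seed = derive_seed(seed, match(which[i], names(specs))))
      coding_theorem(sample_space(sp), fallback_margin)
    }
  })
  structure(setNames(out, which), class = "ctm_table_set")
}

#' @export
print.ctm_table_set <- function(x, ...) {
  cat("<ctm_table_set>", length(x), "tables:", paste(names(x), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read and write complexity tables
#'
#' Tables are stored as TSV (columns `canonical_string`, `count`,
#' `K_bits`) with a JSON sidecar (`<path>.json`) recording the machine
#' space parameters, seed, total halting count and fallback rule, so a
#' table file is a self-describing, reproducible artifact.
#'
#' @param table a [coding_theorem()] table.
#' @param path TSV file path (sidecar written alongside).
#' @return `read_ctm_table()` returns a `ctm_table`;
#'   `write_ctm_table()` returns `path` invisibly.
#' @export
write_ctm_table <- function(table, path) {
  stopifnot(inherits(table, "ctm_table"))
  df <- data.frame(canonical_string = names(table$K),
                   count = unname(table$counts),
                   K_bits = unname(table$K))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(source = table$source, total_halting = table$total_halting,
               fallback = table$fallback,
               fallback_margin = table$fallback_margin,
               dimension = table$dimension,
               fallback_rule = "max covered K + fallback_margin")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ctm_table
#' @export
read_ctm_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric", "numeric"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(K = setNames(df$K_bits, df$canonical_string),
         counts = setNames(df$count, df$canonical_string),
         total_halting = meta$total_halting,
         fallback = meta$fallback, fallback_margin = meta$fallback_margin,
         dimension = meta$dimension, source = as.list(meta$source)),
    class = "ctm_table")
}

#' @param tables a `ctm_table_set`.
#' @param dir directory for the table files (`<id>.tsv` plus sidecars).
#' @rdname write_ctm_table
#' @export
write_ctm_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(tables))
    write_ctm_table(tables[[id]], file.path(dir, paste0(id, ".tsv")))
  invisible(dir)
}

#' @rdname write_ctm_table
#' @export
read_ctm_tables <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0) stop("no .tsv table files found in ", dir)
  ids <- sub("\\.tsv$", "", basename(files))
  structure(setNames(lapply(files, read_ctm_table), ids),
            class = "ctm_table_set")
}
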