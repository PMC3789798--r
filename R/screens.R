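#' Screen table container
#'
#' A query x array matrix of values from one per-chromosome SGA screen file.
#' Duplicate query ids mark replicate screens and are preserved in order.
#' Missing cells are `NA`; `0` is a real measurement (complete linkage).
#'
#' @param chromosome chromosome name.
#' @param query_ids character vector (duplicates allowed).
#' @param array_ids character vector.
#' @param values numeric matrix, `length(query_ids)` x `length(array_ids)`.
#' @param value_kind `"raw_distance"` or `"fitness_triple_set"`.
#' @return object of class `screen_table`.
#' @export
screen_table <- function(chromosome, query_ids, array_ids, values,
                         value_kind = c("raw_distance", "fitness_triple_set")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (nrow(values) != length(query_ids) || ncol(values) != length(array_ids))
    .stopf("values matrix is %dx%d but ids imply %dx%d",
           nrow(values), ncol(values), length(query_ids), length(array_ids))
  dimnames(values) <- NULL
  structure(list(chromosome = chromosome,
                 query_ids = as.character(query_ids),
                 array_ids = as.character(array_ids),
                 values = values, value_kind = value_kind),
            class = "screen_table")
}

#' @export
print.screen_table <- function(x, ...) {
  cat(sprintf("screen_table [%s]: %d query row(s) x %d array column(s), %s\n",
              x$chromosome, length(x$query_ids), length(x$array_ids),
              x$value_kind))
  invisible(x)
}

#' Read a per-chromosome screen matrix
#'
#' Dialect: tab-delimited, UTF-8; first row holds array ORF names (first cell
#' may carry the chromosome name or be empty), first column holds query ORF
#' names. Numeric cells or empty (missing). Duplicate query rows (replicate
#' screens) are kept in order.
#'
#' @param path file path.
#' @param chromosome chromosome name; default taken from the header corner
#'   cell if non-empty, else from the file name.
#' @param value_kind see [screen_table()].
#' @return a [screen_table()].
#' @export
read_screen_matrix <- function(path, chromosome = NULL,
                               value_kind = "raw_distance") {
  if (!file.exists(path)) .stopf("screen file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) .stopf("empty screen file: %s", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  # trailing empty fields are dropped by strsplit; pad to header width
  header <- cells[[1]]
  ncol_total <- length(header)
  array_ids <- header[-1]
  if (is.null(chromosome)) {
    chromosome <- if (nzchar(header[1])) header[1] else
      sub("\\.[^.]*$", "", basename(path))
  }
  body <- cells[-1]
  qids <- character(length(body))
  vals <- matrix(NA_real_, length(body), length(array_ids))
  for (r in seq_along(body)) {
    f <- body[[r]]
    if (length(f) > ncol_total)
      .stopf("ragged row %d in %s: %d fields, expected %d", r + 1L, path,
             length(f), ncol_total)
    f <- c(f, rep("", ncol_total - length(f)))
    qids[r] <- f[1]
    v <- f[-1]
    num <- suppressWarnings(as.numeric(v))
    bad <- nzchar(v) & is.na(num)
    if (any(bad))
      .stopf("non-numeric cell '%s' at row %d in %s", v[bad][1], r + 1L, path)
    vals[r, ] <- ifelse(nzchar(v), num, NA_real_)
  }
  screen_table(chromosome, qids, array_ids, vals, value_kind)
}

#' Write a screen table of distances in the File S1 dialect
#'
#' Numbers are printed with `%.17g` so that write -> read -> write is
#' byte-identical and values round-trip exactly. Missing cells are empty.
#'
#' @param table a [screen_table()] with `value_kind = "raw_distance"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(table, path) {
  stopifnot(inherits(table, "screen_table"))
  if (table$value_kind != "raw_distance")
    .stopf("write_distance_matrix requires value_kind 'raw_distance', got '%s'",
           table$value_kind)
  header <- paste(c(table$chromosome, table$array_ids), collapse = "\t")
  rows <- vapply(seq_along(table$query_ids), function(r) {
    paste(c(table$query_ids[r], .fmt_num(table$values[r, ])), collapse = "\t")
  }, "")
  ok <- try(writeLines(c(header, rows), path), silent = TRUE)
  if (inherits(ok, "try-error"))
    .stopf("failed writing distance matrix to %s: %s", path,
           attr(ok, "condition")$message)
  invisible(path)
}

#' Fitness screen container
#'
#' One chromosome's SGA screen at the colony-size level: observed normalized
#' single-mutant sizes for each query row (replicate rows carry their own
#' measurement) and each array column, plus the double-mutant size matrix.
#'
#' @param chromosome chromosome name.
#' @param query_ids character, one per row (duplicates = replicate screens).
#' @param array_ids character.
#' @param f_query numeric, single-mutant size per query row.
#' @param f_array numeric, single-mutant size per array column.
#' @param f_double numeric matrix of double-mutant sizes.
#' @return object of class `fitness_screen`.
#' @export
fitness_screen <- function(chromosome, query_ids, array_ids,
                           f_query, f_array, f_double) {
  f_double <- as.matrix(f_double)
  stopifnot(length(f_query) == length(query_ids),
            length(f_array) == length(array_ids),
            nrow(f_double) == length(query_ids),
            ncol(f_double) == length(array_ids))
  dimnames(f_double) <- NULL
  structure(list(chromosome = chromosome,
                 query_ids = as.character(query_ids),
                 array_ids = as.character(array_ids),
                 f_query = as.numeric(f_query),
                 f_array = as.numeric(f_array),
                 f_double = f_double),
            class = "fitness_screen")
}

#' Write / read a fitness screen as plain text
#'
#' `write_fitness_screen` emits `<chrom>_double.tsv` (File S1 matrix dialect
#' holding f_ij), `<chrom>_query.tsv` (row, id, fitness; one row per replicate
#' row) and `<chrom>_array.tsv` (id, fitness). `read_fitness_screen`
#' reassembles them.
#'
#' @param screen a [fitness_screen()].
#' @param dir directory.
#' @param chromosome chromosome name (reader).
#' @return the directory (writer) / a [fitness_screen()] (reader).
#' @export
write_fitness_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "fitness_screen"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ch <- screen$chromosome
  tab <- screen_table(ch, screen$query_ids, screen$array_ids, screen$f_double,
                      "raw_distance")
  write_distance_matrix(tab, file.path(dir, paste0(ch, "_double.tsv")))
  writeLines(c("row\tid\tfitness",
               sprintf("%d\t%s\t%s", seq_along(screen$query_ids),
                       screen$query_ids, .fmt_num(screen$f_query))),
             file.path(dir, paste0(ch, "_query.tsv")))
  writeLines(c("id\tfitness",
               sprintf("%s\t%s", screen$array_ids, .fmt_num(screen$f_array))),
             file.path(dir, paste0(ch, "_array.tsv")))
  invisible(dir)
}

#' @rdname write_fitness_screen
#' @export
read_fitness_screen <- function(dir, chromosome) {
  dbl <- read_screen_matrix(file.path(dir, paste0(chromosome, "_double.tsv")),
                            chromosome = chromosome)
  q <- read.table(file.path(dir, paste0(chromosome, "_query.tsv")),
                  header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  a <- read.table(file.path(dir, paste0(chromosome, "_array.tsv")),
                  header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!identical(q$id, dbl$query_ids) || !identical(a$id, dbl$array_ids))
    .stopf("fitness screen files for %s disagree on ids", chromosome)
  fitness_screen(chromosome, dbl$query_ids, dbl$array_ids,
                 q$fitness, a$fitness, dbl$values)
}
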