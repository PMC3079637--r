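#' Read a fitness (or score) matrix from tab-delimited text
#'
#' The expected dialect is a plain TSV: the first row holds the array strain
#' identifiers (the leading corner cell is ignored), the first column holds
#' the query strain identifiers, and every remaining cell is either a decimal
#' number or the missing token.
#'
#' @param path Path to a tab-delimited file.
#' @param missing_token Text representing a missing measurement
#'   (default `"NA"`).
#' @param name Dataset label; defaults to the file name.
#' @param validate_nonnegative If `TRUE` (the default, appropriate for
#'   fitness values) a negative cell is an error. Set to `FALSE` when reading
#'   signed score matrices.
#'
#' @return A `fitness_matrix` (or, with `validate_nonnegative = FALSE`, a
#'   `score_matrix`) preserving the file's row and column order.
#' @seealso [write_matrix()] for the inverse operation.
#' @export
read_fitness_matrix <- function(path, missing_token = "NA",
                                name = basename(path),
                                validate_nonnegative = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    stop("malformed matrix file: need a header row and at least one data row",
      call. = FALSE
    )
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 2) {
    stop("malformed header: no array identifiers found", call. = FALSE)
  }
  arr_ids <- header[-1]
  n <- length(arr_ids)
  body <- cells[-1]
  widths <- lengths(body)
  if (any(widths != n + 1)) {
    stop(sprintf(
      "ragged row: line %d has %d cells, expected %d",
      which(widths != n + 1)[1] + 1L, widths[widths != n + 1][1], n + 1L
    ), call. = FALSE)
  }
  qry_ids <- vapply(body, `[`, character(1), 1L)
  raw <- t(vapply(body, function(r) r[-1], character(n)))
  if (n == 1) raw <- matrix(vapply(body, `[`, character(1), 2L), ncol = 1)
  raw[raw == missing_token] <- NA_character_
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- is.na(vals) & !is.na(raw)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "unparseable cell '%s' at query '%s', array '%s'",
      raw[bad][1], qry_ids[ij[1]], arr_ids[ij[2]]
    ), call. = FALSE)
  }
  if (validate_nonnegative) {
    fitness_matrix(vals, query_ids = qry_ids, array_ids = arr_ids, name = name)
  } else {
    score_matrix(vals, query_ids = qry_ids, array_ids = arr_ids, name = name)
  }
}

#' Write a fitness or score matrix as tab-delimited text
#'
#' Values are printed with 6 significant digits; missing cells are written as
#' `missing_token`. `read_fitness_matrix()` on the result reproduces the
#' identifiers, ordering, values (to the printed precision) and missingness.
#'
#' @param m A `fitness_matrix` or `score_matrix`.
#' @param path Output file path.
#' @param missing_token Token written for missing cells (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, missing_token = "NA") {
  v <- unclass(m)
  txt <- matrix(sprintf("%.6g", v), nrow(v), ncol(v))
  txt[is.na(v)] <- missing_token
  lines <- c(
    paste(c("id", colnames(v)), collapse = "\t"),
    vapply(
      seq_len(nrow(v)),
      function(i) paste(c(rownames(v)[i], txt[i, ]), collapse = "\t"),
      character(1)
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction edge list (BioGRID-style tab format)
#'
#' Reads a tab-delimited file with a header row and returns one record per
#' retained edge. Default column names follow the BioGRID TAB 2.0 dialect;
#' arbitrary column names can be supplied for other sources.
#'
#' @param path Path to the tab-delimited edge file.
#' @param category_column Name of the column holding the experimental-system
#'   category (e.g. "Positive Genetic").
#' @param id_columns Character vector of length 2 naming the two interactor
#'   identifier columns.
#' @param organism_filter Optional value; when given, only rows whose
#'   `organism_column` equals it (as text) are kept.
#' @param organism_column Column consulted by `organism_filter`.
#'
#' @return A tibble with columns `gene_a`, `gene_b`, `category`, `source`.
#'   Self pairs are retained here and filtered where reference classes are
#'   built.
#' @export
read_edge_list <- function(path,
                           category_column = "Experimental System",
                           id_columns = c(
                             "Systematic Name Interactor A",
                             "Systematic Name Interactor B"
                           ),
                           organism_filter = NULL,
                           organism_column = "Organism Interactor A") {
  df <- utils::read.delim(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    quote = "", comment.char = ""
  )
  need <- c(id_columns, category_column)
  if (!is.null(organism_filter)) need <- c(need, organism_column)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "edge file lacks required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  if (!is.null(organism_filter)) {
    df <- df[as.character(df[[organism_column]]) == as.character(organism_filter), ,
      drop = FALSE
    ]
  }
  tibble::tibble(
    gene_a = as.character(df[[id_columns[1]]]),
    gene_b = as.character(df[[id_columns[2]]]),
    category = as.character(df[[category_column]]),
    source = basename(path)
  )
}
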