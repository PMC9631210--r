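#' Write / read a labeled dense matrix as TSV
#'
#' Matrices travel as UTF-8 tab-delimited text with a header row of
#' column identifiers and a first column of row identifiers. Values are
#' written with 17 significant digits so a write/read round trip is
#' bit-exact for doubles. Writing refuses non-finite entries.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @param expected_ids optional identifier vector; reading fails if the
#'   row labels do not match it (alignment guard).
#' @param check_symmetric validate symmetry on read (for similarity
#'   matrices).
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns a numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) {
    stop_ldapred("refusing to write non-finite matrix entries", "io_error")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_ldapred("matrix must carry row and column identifiers", "io_error")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con, useBytes = TRUE)
  body <- apply(m, 1, function(r) paste(formatC(r, digits = 17, format = "g"),
                                        collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, expected_ids = NULL, check_symmetric = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                          fileEncoding = "UTF-8")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (!is.null(expected_ids) && !identical(rownames(m), as.character(expected_ids))) {
    stop_ldapred("matrix row labels do not match the expected identifiers",
                 "alignment_error")
  }
  if (check_symmetric) {
    if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-9) {
      stop_ldapred("matrix read from file is not symmetric", "alignment_error")
    }
  }
  m
}

#' Read a disease ontology edge list
#'
#' Two-column tab-delimited file `child<TAB>parent`; `#` comments and
#' blank lines ignored; identifiers are opaque, case-sensitive strings.
#' @param path file path.
#' @return data frame with columns `child`, `parent`.
#' @export
read_ontology <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(data.frame(child = character(), parent = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 2)) {
    stop_ldapred(paste0("malformed ontology line in ", path), "parse_error")
  }
  data.frame(child = vapply(parts, `[[`, "", 1),
             parent = vapply(parts, `[[`, "", 2))
}

#' @rdname read_ontology
#' @param edges data frame with columns `child`, `parent`.
#' @export
write_ontology <- function(edges, path) {
  writeLines(paste(edges$child, edges$parent, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}
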