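#' Construct a lncRNA-disease association matrix
#'
#' The association matrix is the central data object: a binary
#' `nl x nd` matrix whose rows are lncRNAs, columns are diseases, and
#' `A[l, d] = 1` records an experimentally supported association.
#' Unknown or non-existent pairs are 0 and act as (weak) negatives.
#'
#' @param values binary matrix, `nl x nd`.
#' @param lncrna_ids,disease_ids unique identifier vectors; taken from
#'   `dimnames(values)` when omitted.
#' @return a matrix of class `"assoc_matrix"` with identifier dimnames.
#' @examples
#' a <- association_matrix(matrix(c(1, 0, 0, 1, 1, 0), 2, 3),
#'                         c("l1", "l2"), c("d1", "d2", "d3"))
#' dim(a)
#' @export
association_matrix <- function(values, lncrna_ids = rownames(values),
                               disease_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(lncrna_ids) || is.null(disease_ids)) {
    stop_ldapred("lncRNA and disease identifiers are required", "input_error")
  }
  if (nrow(values) < 1 || ncol(values) < 1) {
    stop_ldapred("association matrix must be at least 1 x 1", "input_error")
  }
  if (anyDuplicated(lncrna_ids) || anyDuplicated(disease_ids)) {
    stop_ldapred("identifiers must be unique", "input_error")
  }
  if (!all(values %in% c(0, 1))) {
    stop_ldapred("association entries must be 0 or 1", "input_error")
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(lncrna_ids), as.character(disease_ids))
  class(values) <- c("assoc_matrix", class(matrix()))
  values
}

#' Build an association matrix from (lncRNA, disease) pairs
#'
#' @param pairs two-column data frame or matrix of identifiers, one known
#'   association per row.
#' @param lncrna_ids,disease_ids optional full registries (so nodes with
#'   zero associations can still be represented); defaults to
#'   first-appearance order of the pairs.
#' @return an [association_matrix()].
#' @export
association_from_pairs <- function(pairs, lncrna_ids = NULL, disease_ids = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2 || nrow(pairs) < 1) {
    stop_ldapred("pairs must have at least one row and two columns", "input_error")
  }
  l <- as.character(pairs[[1]]); d <- as.character(pairs[[2]])
  lncrna_ids <- lncrna_ids %||% unique(l)
  disease_ids <- disease_ids %||% unique(d)
  bad_l <- setdiff(l, lncrna_ids); bad_d <- setdiff(d, disease_ids)
  if (length(bad_l) || length(bad_d)) {
    stop_ldapred("pairs contain identifiers outside the registries", "input_error")
  }
  if (anyDuplicated(paste(l, d, sep = "\r"))) {
    warning("duplicated association pair(s) collapsed to a single entry")
  }
  m <- matrix(0, length(lncrna_ids), length(disease_ids),
              dimnames = list(lncrna_ids, disease_ids))
  m[cbind(match(l, lncrna_ids), match(d, disease_ids))] <- 1
  association_matrix(m)
}

#' Read known associations from a two-column TSV file
#'
#' Expects UTF-8 tab-delimited lines `lncrna_id<TAB>disease_id`; lines
#' starting with `#` and blank lines are ignored. Identifier registries
#' follow first appearance; duplicated pairs collapse to a single 1 with
#' a warning.
#'
#' @param path file path.
#' @return an [association_matrix()].
#' @export
read_associations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (!length(lines)) {
    stop_ldapred(paste0("no association records in ", path), "parse_error")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad)) {
    stop_ldapred(sprintf("malformed line %d in %s (expected 2 tab-separated fields)",
                         which(keep)[bad[1]], path), "parse_error")
  }
  pairs <- data.frame(l = vapply(parts, `[[`, "", 1),
                      d = vapply(parts, `[[`, "", 2))
  association_from_pairs(pairs)
}

#' Write associations as a two-column TSV file
#' @param assoc an [association_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  idx <- which(assoc == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- paste(rownames(assoc)[idx[, 1]], colnames(assoc)[idx[, 2]], sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("lncRNA-disease association matrix: %d lncRNAs x %d diseases, %d known associations\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}
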