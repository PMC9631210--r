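#' Similarity matrix container
#'
#' Thin wrapper tagging a square numeric matrix with its kind. Kinds
#' `"semantic"`, `"functional"` and `"gaussian"` are validated to be
#' symmetric; `"integrated"` disease similarity may exceed 1 because the
#' fusion rule adds the semantic and Gaussian entries, so only symmetry
#' and non-negativity are enforced there.
#'
#' @param values square numeric matrix with identifier dimnames.
#' @param kind one of `"semantic"`, `"functional"`, `"gaussian"`,
#'   `"integrated"`.
#' @return matrix of class `"similarity_matrix"` with a `kind` attribute.
#' @export
similarity_matrix <- function(values, kind) {
  kind <- match.arg(kind, c("semantic", "functional", "gaussian", "integrated"))
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop_ldapred("similarity matrix must be square", "input_error")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("n", seq_len(nrow(values)))
  }
  if (nrow(values) > 1 && max(abs(values - t(values))) > 1e-9) {
    stop_ldapred("similarity matrix must be symmetric (tol 1e-9)", "input_error")
  }
  if (kind == "integrated" && any(values < 0)) {
    stop_ldapred("integrated similarity must be non-negative", "input_error")
  }
  structure(values, kind = kind,
            class = c("similarity_matrix", class(matrix())))
}

sim_kind <- function(x) attr(x, "kind")

#' lncRNA functional similarity by best-match averaging
#'
#' Two lncRNAs are functionally similar when the diseases they associate
#' with are semantically similar. For lncRNAs `li` (disease set `D1`,
#' size m) and `lj` (disease set `D2`, size n), every disease in `D1` is
#' matched to its most semantically similar disease in `D2` and vice
#' versa; the match scores are summed and divided by `m + n`.
#'
#' lncRNAs without any known association get a zero row/column (the
#' Gaussian kernel later fills these via the integration rule); their ids
#' are recorded in the `"no_association"` attribute.
#'
#' @param assoc an [association_matrix()].
#' @param ds semantic similarity matrix covering all diseases of `assoc`.
#' @return symmetric similarity matrix of kind `"functional"`; diagonal 1
#'   for every lncRNA with at least one association.
#' @export
lncrna_functional_similarity <- function(assoc, ds) {
  if (!all(colnames(assoc) %in% rownames(ds))) {
    stop_ldapred("semantic similarity does not cover all diseases",
                 "alignment_error")
  }
  ds <- ds[colnames(assoc), colnames(assoc), drop = FALSE]
  nl <- nrow(assoc)
  sets <- lapply(seq_len(nl), function(i) which(assoc[i, ] == 1))
  out <- matrix(0, nl, nl, dimnames = list(rownames(assoc), rownames(assoc)))
  for (i in seq_len(nl)) {
    D1 <- sets[[i]]
    if (!length(D1)) next
    for (j in i:nl) {
      D2 <- sets[[j]]
      if (!length(D2)) next
      sub <- ds[D1, D2, drop = FALSE]
      out[i, j] <- out[j, i] <-
        (sum(apply(sub, 1, max)) + sum(apply(sub, 2, max))) /
        (length(D1) + length(D2))
    }
  }
  res <- similarity_matrix(out, kind = "functional")
  attr(res, "no_association") <-
    rownames(assoc)[vapply(sets, length, 1L) == 0]
  res
}

#' Gaussian interaction-profile kernel similarity
#'
#' Each node is represented by its binary interaction profile (its row
#' or column of the association matrix). The kernel bandwidth is
#' normalized by the mean squared profile norm, and the similarity of two
#' nodes is `exp(-bandwidth * ||p_i - p_j||^2)`, giving entries in
#' `(0, 1]` with unit diagonal.
#'
#' @param profiles numeric matrix, one profile per row, with row
#'   identifiers.
#' @return symmetric similarity matrix of kind `"gaussian"`, plus a
#'   `"bandwidth"` attribute.
#' @examples
#' p <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
#'             dimnames = list(c("d1", "d2"), NULL))
#' gaussian_profile_kernel(p)["d1", "d2"]  # exp(-2)
#' @export
gaussian_profile_kernel <- function(profiles) {
  profiles <- as.matrix(profiles)
  norms2 <- rowSums(profiles^2)
  if (all(norms2 == 0)) {
    stop_ldapred("all interaction profiles are zero; bandwidth undefined",
                 "input_error")
  }
  bw <- 1 / mean(norms2)
  # ||pi - pj||^2 = |pi|^2 + |pj|^2 - 2 pi.pj
  g <- tcrossprod(profiles)
  d2 <- outer(norms2, norms2, "+") - 2 * g
  d2[d2 < 0] <- 0
  k <- exp(-bw * d2)
  diag(k) <- 1
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("n", seq_len(nrow(profiles)))
  }
  dimnames(k) <- list(rownames(profiles), rownames(profiles))
  res <- similarity_matrix(k, kind = "gaussian")
  attr(res, "bandwidth") <- bw
  res
}

#' @rdname gaussian_profile_kernel
#' @param assoc an [association_matrix()].
#' @param side `"disease"` uses columns of `assoc` as profiles,
#'   `"lncrna"` uses rows.
#' @export
gip_similarity <- function(assoc, side = c("disease", "lncrna")) {
  side <- match.arg(side)
  profiles <- if (side == "disease") t(unclass(assoc)) else unclass(assoc)
  gaussian_profile_kernel(profiles)
}

#' Fuse semantic and Gaussian disease similarity
#'
#' Where the semantic similarity is non-zero the two sources are added
#' (entries may exceed 1); where it is zero the Gaussian kernel fills the
#' gap. Set `average = TRUE` to average instead of add in the non-zero
#' branch (off by default).
#'
#' @param ds semantic disease similarity.
#' @param gd Gaussian disease similarity with identical identifiers.
#' @param average average instead of add where `ds != 0`.
#' @return similarity matrix of kind `"integrated"`.
#' @export
integrate_disease_similarity <- function(ds, gd, average = FALSE) {
  check_same_ids(ds, gd)
  fused <- ifelse(ds != 0,
                  if (average) (ds + gd) / 2 else ds + gd,
                  gd)
  similarity_matrix(fused, kind = "integrated")
}

#' Fuse functional and Gaussian lncRNA similarity
#'
#' Pass-through fusion: the functional similarity is kept wherever it is
#' non-zero and the Gaussian kernel only fills zero entries (no addition,
#' unlike the disease-side rule).
#'
#' @param fs functional lncRNA similarity.
#' @param gl Gaussian lncRNA similarity with identical identifiers.
#' @return similarity matrix of kind `"integrated"`.
#' @export
integrate_lncrna_similarity <- function(fs, gl) {
  check_same_ids(fs, gl)
  fused <- ifelse(fs != 0, fs, gl)
  similarity_matrix(fused, kind = "integrated")
}

check_same_ids <- function(a, b) {
  if (!identical(dim(a), dim(b)) || !identical(rownames(a), rownames(b))) {
    stop_ldapred("similarity matrices are not aligned on the same identifiers",
                 "alignment_error")
  }
  invisible(TRUE)
}

#' Assemble the heterogeneous node feature matrix
#'
#' Stacks the integrated similarities block-anti-diagonally:
#' `X = [[0 (nd x nl), DS_I], [FS_I, 0 (nl x nd)]]`, shape
#' `(nd + nl) x (nl + nd)`. Row `i` of `X` is the raw feature vector of
#' node `i`; diseases come first, then lncRNAs.
#'
#' @param ds_i integrated disease similarity (`nd x nd`).
#' @param fs_i integrated lncRNA similarity (`nl x nl`).
#' @return numeric matrix of class `"hetero_features"` with attributes
#'   `nd`, `nl`, `disease_ids`, `lncrna_ids`.
#' @export
assemble_feature_matrix <- function(ds_i, fs_i) {
  nd <- nrow(ds_i); nl <- nrow(fs_i)
  top <- cbind(matrix(0, nd, nl), unclass(ds_i))
  bottom <- cbind(unclass(fs_i), matrix(0, nl, nd))
  x <- rbind(top, bottom)
  rownames(x) <- c(rownames(ds_i), rownames(fs_i))
  colnames(x) <- c(rownames(fs_i), rownames(ds_i))
  structure(x, nd = nd, nl = nl,
            disease_ids = rownames(ds_i), lncrna_ids = rownames(fs_i),
            class = c("hetero_features", class(matrix())))
}
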