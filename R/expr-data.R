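#' Coerce a tidy expression table to a numeric matrix
#'
#' Expression data in pairomics is a data frame with one identifier column
#' (default: the first, conventionally named `gene`) and one numeric column
#' per sample. This helper converts that representation to a base matrix with
#' gene identifiers as row names, validating the container invariants on the
#' way: unique gene and sample identifiers, numeric values, and (optionally)
#' a minimum of 2 genes x 2 samples.
#'
#' @param x A data frame (gene column + sample columns) or a numeric matrix
#'   with gene row names.
#' @param gene_col Name or index of the identifier column when `x` is a data
#'   frame. Defaults to the first column.
#' @param min_dim Require at least 2 genes and 2 samples (the container
#'   invariant). Set `FALSE` for single-feature extractions.
#' @return A numeric matrix, genes in rows.
#' @export
as_expr_matrix <- function(x, gene_col = 1L, min_dim = TRUE) {
  if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) abort("expression matrix must have gene row names")
  } else if (is.data.frame(x)) {
    if (is.numeric(gene_col)) gene_col <- names(x)[gene_col]
    if (!gene_col %in% names(x)) {
      abort(sprintf("gene column '%s' not found", gene_col))
    }
    genes <- as.character(x[[gene_col]])
    vals <- x[setdiff(names(x), gene_col)]
    bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
    if (length(bad)) {
      abort(sprintf("non-numeric sample column(s): %s", paste(bad, collapse = ", ")))
    }
    m <- as.matrix(vals)
    rownames(m) <- genes
  } else {
    abort("`x` must be a data frame or a numeric matrix")
  }
  if (!is.numeric(m)) abort("expression values must be numeric")
  if (anyDuplicated(rownames(m))) abort("duplicated gene identifiers")
  if (anyDuplicated(colnames(m))) abort("duplicated sample identifiers")
  if (min_dim && (nrow(m) < 2L || ncol(m) < 2L)) {
    abort("expression data needs at least 2 genes and 2 samples")
  }
  if (any(is.infinite(m))) abort("non-finite expression values (use NA for missing)")
  m
}

#' Convert a gene-by-sample matrix back to a tibble
#'
#' @param m Numeric matrix with gene row names.
#' @param gene_col Name for the identifier column.
#' @return A tibble with the identifier column first.
#' @export
as_expr_tbl <- function(m, gene_col = "gene") {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(!!gene_col := rownames(m)), out)
  out
}

# Validate sample metadata and align it to a set of matrix samples.
# Returns tibble(sample, group) restricted to `samples`, erroring on an
# empty intersection or conflicting duplicate assignments.
align_meta <- function(meta, samples) {
  if (!is.data.frame(meta) || ncol(meta) < 2L) {
    abort("`meta` must be a data frame with sample and group columns")
  }
  meta <- tibble(sample = as.character(meta[[1]]), group = as.character(meta[[2]]))
  meta <- dplyr::distinct(meta)
  if (anyDuplicated(meta$sample)) {
    abort("sample(s) assigned to more than one group in `meta`")
  }
  keep <- meta$sample %in% samples
  if (!any(keep)) abort("no overlap between `meta` samples and matrix samples")
  meta[keep, ]
}

# Two group labels -> named list of sample id vectors, with n >= `min_n` each.
split_two_groups <- function(meta, group, reference, min_n = 2L) {
  if (is.null(group) || is.null(reference)) {
    grps <- unique(meta$group)
    if (length(grps) != 2L) {
      abort("`meta` must contain exactly 2 groups unless `group`/`reference` are given")
    }
    group <- group %||% grps[1]
    reference <- reference %||% setdiff(grps, group)
  }
  for (g in c(group, reference)) {
    if (!g %in% meta$group) abort(sprintf("group '%s' not present in `meta`", g))
  }
  out <- list(
    group = meta$sample[meta$group == group],
    reference = meta$sample[meta$group == reference]
  )
  ns <- lengths(out)
  if (any(ns < min_n)) {
    abort(sprintf("each group needs n >= %d samples (got %d vs %d)", min_n, ns[1], ns[2]))
  }
  names(out) <- c(group, reference)
  out
}
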