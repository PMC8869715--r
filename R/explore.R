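#' Log2-transform a linear-scale expression table
#'
#' Applies `log2(v + pseudocount)` to every value. Inputs must be
#' non-negative: the caller declares the matrix to be on a linear scale
#' (e.g. FPKM), and negative values indicate it already is not.
#'
#' @param x Expression table (gene column + sample columns) or matrix.
#' @param pseudocount Non-negative offset added before the log (default 1).
#' @param gene_col Identifier column, see [as_expr_matrix()].
#' @return A tibble of the same shape on the log2 scale.
#' @export
log2_transform <- function(x, pseudocount = 1, gene_col = 1L) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0) {
    abort("`pseudocount` must be a single non-negative number")
  }
  m <- as_expr_matrix(x, gene_col)
  if (any(m < 0, na.rm = TRUE)) {
    abort("negative values: data are not on a linear scale")
  }
  as_expr_tbl(log2(m + pseudocount))
}

#' Z-normalize each gene row
#'
#' Centers and scales every row to mean 0 and sample standard deviation 1
#' (n - 1 denominator). Rows that are constant (zero SD) map to all zeros
#' rather than NaN. Missing values are ignored when computing the row
#' statistics and propagated in the output.
#'
#' @inheritParams log2_transform
#' @return A tibble of row z-scores.
#' @export
z_normalize_rows <- function(x, gene_col = 1L) {
  m <- as_expr_matrix(x, gene_col)
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, sd, na.rm = TRUE)
  z <- (m - mu) / ifelse(s > 0, s, Inf) # constant rows -> 0
  z[is.na(z) & !is.na(m)] <- 0
  as_expr_tbl(z)
}

#' Rank genes by variability
#'
#' Orders genes by raw median absolute deviation (no consistency constant) or
#' by sample variance, descending, and returns the `top_n` most variable.
#' Ties are broken by gene identifier so the ranking is deterministic.
#'
#' @inheritParams log2_transform
#' @param method `"mad"` (default) or `"variance"`.
#' @param top_n How many genes to keep; must not exceed the number of genes.
#' @return A tibble with columns `gene`, `statistic`, `rank`.
#' @export
rank_variable_genes <- function(x, method = c("mad", "variance"), top_n = 100L,
                                gene_col = 1L) {
  method <- match.arg(method)
  m <- as_expr_matrix(x, gene_col)
  if (top_n < 1 || top_n > nrow(m)) {
    abort(sprintf("`top_n` must be in [1, %d]", nrow(m)))
  }
  stat <- switch(method,
    mad = apply(m, 1, function(v) median(abs(v - median(v, na.rm = TRUE)), na.rm = TRUE)),
    variance = apply(m, 1, var, na.rm = TRUE)
  )
  ord <- order(-stat, rownames(m))
  out <- tibble(gene = rownames(m)[ord], statistic = unname(stat[ord]),
                rank = seq_len(nrow(m)))
  out[seq_len(top_n), ]
}

#' Compare one gene's expression between two sample groups
#'
#' Summarizes one gene per group (n, median, quartiles) and tests for a
#' two-sided difference by Wilcoxon rank-sum (default; exact when the
#' combined n is at most 12 and there are no ties, normal approximation with
#' tie and continuity correction otherwise) or Welch's t-test.
#'
#' @param x Expression table or matrix.
#' @param meta Sample metadata (`sample`, `group`).
#' @param gene Gene identifier present in `x`.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @param group,reference Group labels; may be omitted when `meta` contains
#'   exactly two groups.
#' @param log2 If `TRUE`, values are log2-transformed (with `pseudocount`)
#'   before summarizing and testing; use when `x` is on a linear scale.
#' @param pseudocount Offset for the optional log2 transform.
#' @param gene_col Identifier column of `x`.
#' @return A `group_comparison` object; see [tidy.group_comparison()].
#' @export
compare_groups <- function(x, meta, gene, test = c("wilcoxon", "t"),
                           group = NULL, reference = NULL,
                           log2 = FALSE, pseudocount = 1, gene_col = 1L) {
  test <- match.arg(test)
  m <- as_expr_matrix(x, gene_col, min_dim = FALSE)
  if (!gene %in% rownames(m)) abort(sprintf("gene '%s' not in matrix", gene))
  meta <- align_meta(meta, colnames(m))
  grp <- split_two_groups(meta, group, reference)
  vals <- m[gene, ]
  if (log2) {
    if (any(vals < 0, na.rm = TRUE)) abort("negative values cannot be log2-transformed")
    vals <- base::log2(vals + pseudocount)
  }
  va <- vals[grp[[1]]]
  vb <- vals[grp[[2]]]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) < 2 || length(vb) < 2) abort("each group needs >= 2 non-missing values")
  ht <- two_group_test(va, vb, test)
  summ <- purrr::map_dfr(list(va, vb), function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(n = length(v), median = q[2], q1 = q[1], q3 = q[3])
  })
  summ <- dplyr::bind_cols(tibble(group = names(grp)), summ)
  structure(
    list(feature = gene, summary = summ, method = ht$method,
         statistic = ht$statistic, p_value = ht$p_value),
    class = "group_comparison"
  )
}

# Shared two-sided two-group test used for expression rows and ssGSEA scores.
two_group_test <- function(va, vb, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (test == "wilcoxon") {
    ties <- anyDuplicated(c(va, vb)) > 0
    exact <- (length(va) + length(vb)) <= 12 && !ties
    ht <- suppressWarnings(wilcox.test(va, vb, exact = exact, correct = TRUE))
    list(method = if (exact) "wilcoxon_exact" else "wilcoxon_approx",
         statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    ht <- t.test(va, vb)
    list(method = "welch_t", statistic = unname(ht$statistic), p_value = ht$p.value)
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison for '%s' (%s): statistic = %.4g, p = %.4g\n",
              x$feature, x$method, x$statistic, x$p_value))
  print(x$summary)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return `tidy()`: the per-group summary tibble; `glance()`: a one-row
#'   tibble with the test statistic and p-value.
#' @exportS3Method generics::tidy
#' @export
tidy.group_comparison <- function(x, ...) x$summary

#' @rdname tidy.group_comparison
#' @exportS3Method generics::glance
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(feature = x$feature, method = x$method,
         statistic = x$statistic, p_value = x$p_value)
}
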