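#' Single-sample GSEA scores
#'
#' Rank-based per-sample enrichment: within each sample, genes are ranked by
#' expression (average ranks on ties, so scores are invariant under any
#' strictly increasing transform of the sample). Walking the genes in
#' descending expression order (ties broken lexicographically), the score of
#' a set is the sum over all positions of the difference between the
#' weighted in-set ECDF, with weights \eqn{rank^{\alpha}}, and the unweighted
#' out-of-set ECDF. With `normalize = TRUE` all scores are divided by the
#' range (max - min) over the whole score matrix.
#'
#' @param x Expression table or matrix.
#' @param sets Gene-set collection (long tibble or named list).
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Divide the score matrix by its range (default `FALSE`).
#' @param gene_col Identifier column of `x`.
#' @return A tibble with a `set` column and one numeric column per sample
#'   (the same shape as an expression table, so downstream tools accept it),
#'   with `alpha` and `normalized` recorded as attributes.
#' @export
ssgsea_scores <- function(x, sets, alpha = 0.25, normalize = FALSE, gene_col = 1L) {
  m <- as_expr_matrix(x, gene_col)
  if (anyNA(m)) abort("ssGSEA requires complete expression values")
  genes <- rownames(m)
  lst <- as_gene_set_list(sets)
  in_matrix <- lapply(lst, intersect, genes)
  none <- lengths(in_matrix) == 0
  if (any(none)) {
    warn(sprintf("skipping %d set(s) with no gene in the matrix: %s",
                 sum(none), paste(names(lst)[none], collapse = ", ")))
    in_matrix <- in_matrix[!none]
  }
  if (!length(in_matrix)) abort("no gene set intersects the matrix")
  single <- lengths(in_matrix) == 1
  if (any(single)) {
    warn(sprintf("set(s) with a single gene in the matrix: %s",
                 paste(names(in_matrix)[single], collapse = ", ")))
  }
  N <- nrow(m)
  hit_mat <- vapply(in_matrix, function(g) genes %in% g, logical(N))
  scores <- apply(m, 2, function(v) {
    r <- rank(v, ties.method = "average")    # N = most expressed
    ord <- order(-v, genes)                  # walk order, deterministic
    w <- r[ord]^alpha
    out_step <- 1 / (N - colSums(hit_mat))
    vapply(seq_len(ncol(hit_mat)), function(j) {
      hit <- hit_mat[ord, j]
      k <- sum(hit)
      p_in <- cumsum(w * hit) / sum(w[hit])
      if (k == N) return(sum(p_in))
      p_out <- cumsum(!hit) * out_step[j]
      sum(p_in - p_out)
    }, 0)
  })
  scores <- matrix(scores, nrow = ncol(hit_mat),
                   dimnames = list(colnames(hit_mat), colnames(m)))
  if (normalize) scores <- scores / (max(scores) - min(scores))
  out <- as_expr_tbl(scores, gene_col = "set")
  attr(out, "alpha") <- alpha
  attr(out, "normalized") <- normalize
  out
}

#' Compare ssGSEA scores of one set between two groups
#'
#' Applies the same two-group comparison used for single genes (see
#' [compare_groups()]) to one row of an ssGSEA score matrix.
#'
#' @param scores Score table from [ssgsea_scores()].
#' @param meta Sample metadata (`sample`, `group`).
#' @param set Gene-set name (a row of `scores`).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @param group,reference Optional group labels.
#' @return A `group_comparison` object.
#' @export
ssgsea_group_compare <- function(scores, meta, set, test = c("wilcoxon", "t"),
                                 group = NULL, reference = NULL) {
  test <- match.arg(test)
  m <- as_expr_matrix(scores, gene_col = 1L, min_dim = FALSE)
  if (!set %in% rownames(m)) abort(sprintf("set '%s' not in score matrix", set))
  compare_groups(scores, meta, set, test = test, group = group,
                 reference = reference, log2 = FALSE)
}

#' Boxplot of ssGSEA scores by group
#'
#' @inheritParams ssgsea_group_compare
#' @return A ggplot.
#' @export
plot_ssgsea_box <- function(scores, meta, set, group = NULL, reference = NULL) {
  m <- as_expr_matrix(scores, gene_col = 1L, min_dim = FALSE)
  if (!set %in% rownames(m)) abort(sprintf("set '%s' not in score matrix", set))
  meta <- align_meta(meta, colnames(m))
  df <- tibble(sample = meta$sample, group = meta$group,
               score = m[set, meta$sample])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(title = set, x = NULL, y = "ssGSEA score") +
    ggplot2::theme_minimal()
}
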