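#' Merge one feature from each of two matrices across shared samples
#'
#' Pairs, sample by sample, a feature row of one matrix (gene expression or
#' ssGSEA scores) with a feature row of another, for scatter-style comparison
#' (e.g. a gene's RNA vs protein abundance). Only samples present in both
#' matrices are kept; fewer than 2 shared samples is an error.
#'
#' @param a,b Expression or ssGSEA score tables (identifier column first).
#' @param feature_a,feature_b Row identifiers in `a` and `b`.
#' @param meta Optional sample metadata; when given, a `group` column is
#'   attached (samples without metadata get `NA`).
#' @return A tibble with one row per shared sample: `sample`, `value_a`,
#'   `value_b`, and `group` when `meta` is supplied.
#' @export
merge_features <- function(a, b, feature_a, feature_b, meta = NULL) {
  ma <- as_expr_matrix(a, min_dim = FALSE)
  mb <- as_expr_matrix(b, min_dim = FALSE)
  if (!feature_a %in% rownames(ma)) abort(sprintf("feature '%s' not in `a`", feature_a))
  if (!feature_b %in% rownames(mb)) abort(sprintf("feature '%s' not in `b`", feature_b))
  shared <- intersect(colnames(ma), colnames(mb))
  if (length(shared) < 2) abort("need at least 2 shared samples")
  out <- tibble(sample = shared,
                value_a = ma[feature_a, shared],
                value_b = mb[feature_b, shared])
  if (!is.null(meta)) {
    meta <- tibble(sample = as.character(meta[[1]]), group = as.character(meta[[2]]))
    out <- dplyr::left_join(out, dplyr::distinct(meta), by = "sample")
  }
  out
}

#' Rank genes by correlation with a target profile
#'
#' Correlates every gene of a matrix with a target per-sample profile (a gene
#' row, a protein row, or an ssGSEA score row) over their shared samples and
#' returns the genes sorted by coefficient from lowest to highest. Pairs with
#' missing values are dropped per gene; a constant target has no defined
#' correlation and is an error.
#'
#' @param x Expression table or matrix.
#' @param target Named numeric vector of per-sample values (names = samples).
#' @param method `"spearman"` (default), `"pearson"` or `"kendall"`.
#' @param gene_col Identifier column of `x`.
#' @return A tibble (`gene`, `correlation`, `rank`), ascending in
#'   `correlation`; `rank` 1 is the most negative.
#' @export
correlation_rank <- function(x, target, method = c("spearman", "pearson", "kendall"),
                             gene_col = 1L) {
  method <- match.arg(method)
  m <- as_expr_matrix(x, gene_col)
  if (is.null(names(target))) abort("`target` must be named by sample")
  shared <- intersect(colnames(m), names(target))
  if (length(shared) < 3) abort("need at least 3 shared samples")
  tv <- target[shared]
  if (sd(tv, na.rm = TRUE) == 0 || all(is.na(tv))) abort("constant target: correlation undefined")
  co <- suppressWarnings(
    apply(m[, shared, drop = FALSE], 1, cor, y = tv,
          method = method, use = "pairwise.complete.obs")
  )
  ord <- order(co, rownames(m), na.last = TRUE)
  tibble(gene = rownames(m)[ord], correlation = unname(co[ord]),
         rank = seq_along(co))
}

#' Pair two differential-expression contrasts gene by gene
#'
#' Inner-joins two DE results (e.g. transcriptome and proteome, both oriented
#' as the same group-vs-reference contrast) on gene, computes the per-gene
#' log2FC difference `delta = log2FC_a - log2FC_b`, and labels each gene's
#' quadrant from the two classified directions: `concordant_up`,
#' `concordant_down`, `discordant`, or `ns` when either side is not called.
#'
#' @param de_a,de_b `de_fit` objects or tidy DE tables with `log2FC` and
#'   `direction` columns, classified with the same cutoffs and orientation.
#' @return A tibble with one row per shared gene: `gene`, `log2FC_a`,
#'   `log2FC_b`, `delta`, `abs_delta`, `direction_a`, `direction_b`,
#'   `concordance`.
#' @export
compare_log2fc <- function(de_a, de_b) {
  ta <- de_table(de_a); tb <- de_table(de_b)
  out <- dplyr::inner_join(
    dplyr::select(ta, "gene", log2FC_a = "log2FC", direction_a = "direction"),
    dplyr::select(tb, "gene", log2FC_b = "log2FC", direction_b = "direction"),
    by = "gene"
  )
  if (nrow(out) == 0) abort("no genes shared between the two contrasts")
  out$delta <- out$log2FC_a - out$log2FC_b
  out$abs_delta <- abs(out$delta)
  out$concordance <- dplyr::case_when(
    out$direction_a == "up" & out$direction_b == "up" ~ "concordant_up",
    out$direction_a == "down" & out$direction_b == "down" ~ "concordant_down",
    out$direction_a %in% c("up", "down") & out$direction_b %in% c("up", "down") ~ "discordant",
    TRUE ~ "ns"
  )
  dplyr::select(out, "gene", "log2FC_a", "log2FC_b", "delta", "abs_delta",
                "direction_a", "direction_b", "concordance")
}

de_table <- function(de) {
  tab <- if (inherits(de, "de_fit")) de$table else as_tibble(de)
  need <- c("gene", "log2FC")
  if (!all(need %in% names(tab))) abort("DE table needs `gene` and `log2FC` columns")
  if (!"direction" %in% names(tab)) tab$direction <- NA_character_
  tab
}

#' Derive reciprocal gene-set signatures from two DE contrasts
#'
#' Re-classifies both contrasts at the given cutoffs and extracts the four
#' differential signatures (up and down per matrix) used by the reciprocal
#' enrichment workflow. Empty signatures are recorded and excluded from the
#' returned collection (downstream enrichment skips them).
#'
#' @inheritParams compare_log2fc
#' @param lfc_cutoff,p_cutoff,use_adjusted Thresholds, see [classify_de()].
#' @param labels Length-2 labels naming the two matrices (default
#'   `c("A", "B")`); sets are named `<label>_up` / `<label>_down`.
#' @return A gene-set tibble (`set`, `description`, `gene`) ready for
#'   [write_gmt()], [gsea_significance()] or [ssgsea_scores()], with an
#'   `empty_sets` attribute listing signatures that had no gene.
#' @export
derive_signatures <- function(de_a, de_b, lfc_cutoff = 1, p_cutoff = 0.05,
                              use_adjusted = TRUE, labels = c("A", "B")) {
  if (length(labels) != 2 || anyDuplicated(labels)) abort("`labels` must be 2 distinct labels")
  ta <- classify_de(de_table(de_a), lfc_cutoff, p_cutoff, use_adjusted)
  tb <- classify_de(de_table(de_b), lfc_cutoff, p_cutoff, use_adjusted)
  sigs <- list(
    ta$gene[ta$direction == "up"], ta$gene[ta$direction == "down"],
    tb$gene[tb$direction == "up"], tb$gene[tb$direction == "down"]
  )
  names(sigs) <- paste(rep(labels, each = 2), c("up", "down"), sep = "_")
  empty <- names(sigs)[lengths(sigs) == 0]
  if (length(empty)) {
    warn(sprintf("empty signature(s): %s", paste(empty, collapse = ", ")))
    sigs <- sigs[lengths(sigs) > 0]
  }
  desc <- sprintf("derived DE signature (|log2FC| >= %g, %s p <= %g)",
                  lfc_cutoff, if (use_adjusted) "adjusted" else "nominal", p_cutoff)
  out <- gene_sets_tbl(sigs, description = rep(desc, length(sigs)))
  attr(out, "empty_sets") <- empty
  attr(out, "thresholds") <- list(lfc_cutoff = lfc_cutoff, p_cutoff = p_cutoff,
                                  use_adjusted = use_adjusted)
  out
}

#' Reciprocal GSEA between two omics matrices
#'
#' Connectivity-map-inspired consistency check: differential signatures
#' derived from matrix A are tested by GSEA in matrix B, and B's signatures
#' are tested in A. Concordant datasets yield positive enrichment of the
#' `up` signatures (and negative of the `down`) on the reciprocal side.
#'
#' @param x_a,meta_a,x_b,meta_b The two matrices with their sample metadata.
#' @param signatures Derived signature collection from [derive_signatures()]
#'   (set names must carry the `labels` prefixes).
#' @param group,reference Contrast labels, identical orientation on both
#'   sides.
#' @param labels The two matrix labels used when deriving the signatures.
#' @inheritParams gsea_significance
#' @return A tibble with one row per (signature, target matrix): `source`,
#'   `target`, `set`, `size`, `es`, `nes`, `p_value`, `fdr_q`.
#' @export
reciprocal_gsea <- function(x_a, meta_a, x_b, meta_b, signatures,
                            group = NULL, reference = NULL, n_perm = 1000,
                            mode = "auto", weight = 1, seed,
                            labels = c("A", "B")) {
  if (missing(seed)) abort("`seed` is required")
  lst <- as_gene_set_list(signatures)
  from_a <- grepl(paste0("^", labels[1], "_"), names(lst))
  sets_a <- lst[from_a]   # derived from A -> tested in B
  sets_b <- lst[!from_a]  # derived from B -> tested in A
  run <- function(x, meta, sets, src, tgt, seed) {
    if (!length(sets)) return(NULL)
    res <- gsea_significance(x, meta, sets, group, reference, n_perm = n_perm,
                             mode = mode, weight = weight, seed = seed)
    dplyr::bind_cols(tibble(source = src, target = tgt),
                     dplyr::select(tidy(res), -"leading_edge"))
  }
  out <- dplyr::bind_rows(
    run(x_b, meta_b, sets_a, labels[1], labels[2], seed),
    run(x_a, meta_a, sets_b, labels[2], labels[1], seed + 1L)
  )
  if (is.null(out) || nrow(out) == 0) abort("no non-empty signature to test")
  out
}

#' Reciprocal ssGSEA between two omics matrices
#'
#' Scores each matrix's derived signatures on the *other* matrix by ssGSEA
#' and compares the scores between the contrast groups.
#'
#' @inheritParams reciprocal_gsea
#' @param alpha,normalize ssGSEA parameters, see [ssgsea_scores()].
#' @param test Group-comparison test (`"wilcoxon"` or `"t"`).
#' @return A list with `scores_in_a`, `scores_in_b` (ssGSEA tables; `NULL`
#'   when a side has no signature) and `comparisons`, a tibble of per-set
#'   group tests on the reciprocal side.
#' @export
reciprocal_ssgsea <- function(x_a, meta_a, x_b, meta_b, signatures,
                              group = NULL, reference = NULL,
                              alpha = 0.25, normalize = FALSE,
                              test = "wilcoxon", labels = c("A", "B")) {
  lst <- as_gene_set_list(signatures)
  from_a <- grepl(paste0("^", labels[1], "_"), names(lst))
  score_side <- function(x, meta, sets, src, tgt) {
    if (!length(sets)) return(list(scores = NULL, comp = NULL))
    scores <- ssgsea_scores(x, gene_sets_tbl(sets), alpha = alpha, normalize = normalize)
    comp <- purrr::map_dfr(scores$set, function(s) {
      gc <- ssgsea_group_compare(scores, meta, s, test = test,
                                 group = group, reference = reference)
      dplyr::bind_cols(tibble(source = src, target = tgt, set = s),
                       dplyr::select(glance(gc), -"feature"))
    })
    list(scores = scores, comp = comp)
  }
  in_b <- score_side(x_b, meta_b, lst[from_a], labels[1], labels[2])
  in_a <- score_side(x_a, meta_a, lst[!from_a], labels[2], labels[1])
  comparisons <- dplyr::bind_rows(in_b$comp, in_a$comp)
  if (is.null(comparisons) || nrow(comparisons) == 0) {
    abort("no non-empty signature to score")
  }
  list(scores_in_a = in_a$scores, scores_in_b = in_b$scores,
       comparisons = comparisons)
}
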