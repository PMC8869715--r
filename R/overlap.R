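#' Venn counts of differential genes between two contrasts
#'
#' Counts, for one direction, the genes called only in contrast A, only in
#' contrast B, and in both.
#'
#' @inheritParams compare_log2fc
#' @param direction `"up"` or `"down"`.
#' @return A one-row tibble: `direction`, `a_only`, `b_only`, `both`, and the
#'   shared genes as a list-column.
#' @export
venn_overlap <- function(de_a, de_b, direction = c("up", "down")) {
  direction <- match.arg(direction)
  ta <- de_table(de_a); tb <- de_table(de_b)
  ga <- ta$gene[ta$direction %in% direction]
  gb <- tb$gene[tb$direction %in% direction]
  shared <- sort(intersect(ga, gb))
  tibble(direction = direction,
         a_only = length(setdiff(ga, gb)),
         b_only = length(setdiff(gb, ga)),
         both = length(shared),
         genes_both = list(shared))
}

#' Overlap concordance statistics for two gene sets
#'
#' Partitions a declared universe by membership in two sets into the 2x2
#' counts (a = both, b = A only, c = B only, d = neither) and reports
#' Fisher's exact test (one-sided enrichment by default), the sample odds
#' ratio ad/bc, Cohen's kappa
#' \deqn{\kappa = (p_o - p_e)/(1 - p_e), \quad p_o = (a+d)/N, \quad
#'   p_e = ((a+b)(a+c) + (c+d)(b+d))/N^2,}
#' and the Jaccard index a/(a+b+c). Kappa is undefined (returned as `NA`)
#' when the expected agreement is 1, i.e. both sets empty or both equal to
#' the universe; Jaccard is `NA` when both sets are empty.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of at least 2 identifiers.
#' @param alternative Fisher alternative (default `"greater"`, enrichment).
#' @return A one-row tibble: `n_both`, `n_a_only`, `n_b_only`, `n_neither`,
#'   `universe_size`, `odds_ratio`, `fisher_p`, `kappa`, `jaccard`.
#' @export
overlap_stats <- function(set_a, set_b, universe, alternative = "greater") {
  universe <- unique(as.character(universe))
  if (length(universe) < 2) abort("universe needs at least 2 identifiers")
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("both sets must be subsets of the universe")
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
  c_ <- sum(!in_a & in_b); d <- sum(!in_a & !in_b)
  N <- length(universe)
  p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                   alternative = alternative)$p.value
  or <- (a * d) / (b * c_) # sample odds ratio; Inf/NaN on zero margins
  po <- (a + d) / N
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / N^2
  kappa <- if (pe >= 1) NA_real_ else (po - pe) / (1 - pe)
  jaccard <- if (a + b + c_ > 0) a / (a + b + c_) else NA_real_
  tibble(n_both = a, n_a_only = b, n_b_only = c_, n_neither = d,
         universe_size = N, odds_ratio = or, fisher_p = p,
         kappa = kappa, jaccard = jaccard)
}

#' Scan a query gene set against a pathway collection
#'
#' Computes [overlap_stats()] of a query set (typically the DE genes of one
#' omics) against a reference set (typically the other omics' DE genes) and
#' against every pathway of a collection, over a declared universe
#' (recommended: genes measured in both matrices). Pathways are intersected
#' with the universe first. The table is sorted by Fisher p, so a
#' cross-omics overlap that beats every curated pathway ranks first.
#'
#' @param query Character vector, subset of `universe`.
#' @param collection Gene-set collection (long tibble or named list).
#' @param universe Declared gene universe.
#' @param reference_set The reference gene set to include in the scan.
#' @param reference_name Row label for the reference set.
#' @return A tibble with `|collection| + 1` rows: `set` plus the
#'   [overlap_stats()] columns, ascending in `fisher_p` (ties: larger overlap
#'   first, then name).
#' @export
pathway_overlap_scan <- function(query, collection, universe, reference_set,
                                 reference_name = "reference") {
  lst <- as_gene_set_list(collection)
  if (!length(lst)) abort("empty collection")
  universe <- unique(as.character(universe))
  sets <- c(setNames(list(intersect(unique(as.character(reference_set)), universe)),
                     reference_name),
            lapply(lst, intersect, universe))
  rows <- purrr::map_dfr(names(sets), function(nm) {
    dplyr::bind_cols(tibble(set = nm),
                     overlap_stats(query, sets[[nm]], universe))
  })
  dplyr::arrange(rows, .data$fisher_p, dplyr::desc(.data$n_both), .data$set)
}
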