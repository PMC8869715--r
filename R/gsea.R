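#' Signal-to-noise phenotype ranking
#'
#' Ranks every gene by the signal-to-noise ratio between two sample groups,
#' \deqn{s2n_g = (\mu_{group} - \mu_{ref}) / (\sigma_{group} + \sigma_{ref}),}
#' where each group's standard deviation is floored at
#' \eqn{\max(0.2 |\mu|, 0.2)} for that group (the Broad GSEA convention,
#' which keeps low-variance genes from dominating the ranking). Genes are
#' returned in descending score order with ties broken lexicographically by
#' identifier. Genes with missing values in either group are dropped.
#'
#' @param x Expression table or matrix (log2-scale values).
#' @param meta Sample metadata (`sample`, `group`).
#' @param group,reference Group labels of the contrast.
#' @param gene_col Identifier column of `x`.
#' @return A tibble (`gene`, `score`) in ranking order, with the contrasted
#'   groups recorded as attributes.
#' @export
signal_to_noise <- function(x, meta, group = NULL, reference = NULL, gene_col = 1L) {
  m <- as_expr_matrix(x, gene_col)
  meta <- align_meta(meta, colnames(m))
  grp <- split_two_groups(meta, group, reference)
  if (any(lengths(grp) < 3)) {
    warn("signal-to-noise with a group of n < 3 is unstable")
  }
  m1 <- m[, grp[[1]], drop = FALSE]
  m2 <- m[, grp[[2]], drop = FALSE]
  complete <- !apply(is.na(m1), 1, any) & !apply(is.na(m2), 1, any)
  if (!any(complete)) abort("no gene has complete data in both groups")
  s <- s2n_stat(m1[complete, , drop = FALSE], m2[complete, , drop = FALSE])
  ord <- order(-s, names(s))
  out <- tibble(gene = names(s)[ord], score = unname(s[ord]))
  attr(out, "group") <- names(grp)[1]
  attr(out, "reference") <- names(grp)[2]
  out
}

# signal-to-noise with the sigma floor, rowwise over two matrices
s2n_stat <- function(m1, m2) {
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  s1 <- floor_sd(apply(m1, 1, sd), mu1)
  s2 <- floor_sd(apply(m2, 1, sd), mu2)
  (mu1 - mu2) / (s1 + s2)
}

floor_sd <- function(s, mu) pmax(s, 0.2 * abs(mu), 0.2)

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: hit genes advance the running sum by
#' \eqn{|r|^{p} / \sum_{hits} |r|^{p}}, misses retreat by \eqn{1/(N - N_h)}.
#' The enrichment score is the signed maximum deviation of the running sum
#' from zero; when the positive and negative extrema tie in magnitude the
#' positive one is taken. A set covering the whole list has no miss steps and
#' scores 1 by convention. If all hit scores are exactly zero under `weight
#' > 0`, hits fall back to equal increments.
#'
#' @param ranked Ranked list: a tibble (`gene`, `score`) as returned by
#'   [signal_to_noise()], or a named numeric vector sorted in ranking order.
#' @param gene_set Character vector of member genes (filtered to the ranked
#'   genes first; an empty intersection is an error).
#' @param weight Exponent p on |score| for hit increments (default 1, the
#'   classic GSEA weighting; 0 gives the unweighted KS statistic).
#' @param running_sum Also return the full running sum and leading edge.
#' @return The enrichment score (numeric in \[-1, 1\]), or, when
#'   `running_sum = TRUE`, a list with `es`, a `running_sum` tibble
#'   (`position`, `gene`, `hit`, `running_sum`) and the `leading_edge`
#'   members (hits at or before the positive extremum; hits from the
#'   negative extremum onward for negative scores).
#' @export
gsea_es <- function(ranked, gene_set, weight = 1, running_sum = FALSE) {
  if (is.data.frame(ranked)) {
    scores <- setNames(ranked$score, ranked$gene)
  } else {
    scores <- ranked
  }
  if (anyDuplicated(names(scores))) abort("duplicated genes in ranked list")
  genes <- names(scores)
  N <- length(scores)
  hit <- genes %in% gene_set
  k <- sum(hit)
  if (k == 0) abort("gene set does not intersect the ranked list")
  pos <- which(hit)
  w <- abs(scores[pos])^weight
  if (!running_sum) {
    return(es_from_positions(pos, w, N))
  }
  if (k == N) {
    rs <- cumsum(w / sum(w))
    es <- 1
    lead <- genes
  } else {
    if (sum(w) == 0) w <- rep(1, k)
    inc <- rep(-1 / (N - k), N)
    inc[pos] <- w / sum(w)
    rs <- cumsum(inc)
    mx <- max(rs); mn <- min(rs)
    es <- if (mx >= -mn - 1e-12) mx else mn
    lead <- if (es >= 0) {
      genes[pos[pos <= which.max(rs)]]
    } else {
      genes[pos[pos >= which.min(rs)]]
    }
  }
  list(
    es = es,
    running_sum = tibble(position = seq_len(N), gene = genes,
                         hit = hit, running_sum = unname(rs)),
    leading_edge = lead
  )
}

# ES from sorted hit positions and their weights, visiting only the hit
# points (the running sum is piecewise linear between hits).
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  if (k == N) return(1)
  if (sum(w) == 0) w <- rep(1, k)
  whit <- cumsum(w) / sum(w)
  drop <- (pos - seq_len(k)) / (N - k)
  rs_after <- whit - drop            # running sum just after each hit
  rs_before <- c(0, whit[-k]) - drop # just before each hit
  mx <- max(rs_after)
  mn <- min(rs_before, 0)
  # equal-magnitude extrema resolve to the positive one; the 1e-12 slack
  # keeps the choice stable across algebraically equivalent computations
  if (mx >= -mn - 1e-12) mx else mn
}

#' GSEA with permutation significance
#'
#' Ranks genes by signal-to-noise for the declared contrast, computes the
#' weighted-KS enrichment score of every gene set, and assesses significance
#' against a permutation null: phenotype relabelings when the design has at
#' least 7 samples (below that the mode auto-switches, with a warning, to
#' random same-size gene sets). NES divides each score by the mean |null ES|
#' of matching sign; the nominal p is the sign-matched one-sided permutation
#' fraction with +1 smoothing in numerator and denominator; the FDR q follows
#' the sign-stratified NES-ratio procedure of desktop GSEA (with a
#' monotonicity pass within each sign stratum).
#'
#' @inheritParams signal_to_noise
#' @param sets Gene-set collection (long tibble or named list). Sets with no
#'   gene in the ranked list are skipped with a warning.
#' @param n_perm Number of permutations (>= 10).
#' @param mode `"auto"` (default), `"phenotype"` or `"gene_set"`.
#' @param weight Hit-increment exponent, as in [gsea_es()].
#' @param seed Integer seed; required, and recorded in the result.
#' @return A `gsea_result` object; `tidy()` gives one row per set (`set`,
#'   `size`, `es`, `nes`, `p_value`, `fdr_q`, `leading_edge` list-column),
#'   sorted by NES descending.
#' @export
gsea_significance <- function(x, meta, sets, group = NULL, reference = NULL,
                              n_perm = 1000, mode = c("auto", "phenotype", "gene_set"),
                              weight = 1, seed, gene_col = 1L) {
  mode <- match.arg(mode)
  if (missing(seed)) abort("`seed` is required for reproducible permutations")
  if (n_perm < 10) abort("`n_perm` must be at least 10")
  m <- as_expr_matrix(x, gene_col)
  meta <- align_meta(meta, colnames(m))
  grp <- split_two_groups(meta, group, reference)
  n1 <- length(grp[[1]]); n2 <- length(grp[[2]])
  if (mode != "gene_set" && n1 + n2 < 7) {
    if (mode == "phenotype") {
      warn("fewer than 7 samples: switching to gene_set permutation mode")
    } else {
      warn("fewer than 7 samples: using gene_set permutation mode")
    }
    mode <- "gene_set"
  }
  if (mode == "auto") mode <- "phenotype"

  ranked <- signal_to_noise(x, meta, names(grp)[1], names(grp)[2], gene_col = gene_col)
  genes <- ranked$gene
  N <- length(genes)
  lst <- as_gene_set_list(sets)
  lst <- lapply(lst, intersect, genes)
  empty <- lengths(lst) == 0
  if (any(empty)) {
    warn(sprintf("skipping %d set(s) with no gene in the ranked list: %s",
                 sum(empty), paste(names(lst)[empty], collapse = ", ")))
    lst <- lst[!empty]
  }
  if (!length(lst)) abort("no gene set intersects the ranked list")

  # observed ES + leading edge
  obs <- lapply(lst, function(g) gsea_es(ranked, g, weight, running_sum = TRUE))
  es <- vapply(obs, `[[`, 0, "es")
  lead <- lapply(obs, `[[`, "leading_edge")
  sizes <- lengths(lst)

  null_es <- withr::with_seed(seed, {
    if (mode == "phenotype") {
      Xsub <- m[, c(grp[[1]], grp[[2]]), drop = FALSE]
      complete <- !apply(is.na(Xsub), 1, any)
      Xsub <- Xsub[complete, , drop = FALSE]
      ind <- replicate(n_perm, sample(c(rep(1, n1), rep(0, n2))))
      null_es_phenotype(Xsub, ind, n1, n2, lst, weight)
    } else {
      r_obs <- setNames(ranked$score, ranked$gene)
      null_es_geneset(r_obs, sizes, n_perm, weight)
    }
  })

  # sign-matched normalization and nominal p
  nes <- numeric(length(es)); pval <- numeric(length(es))
  null_nes <- null_es
  for (i in seq_along(es)) {
    nul <- null_es[i, ]
    pos_mean <- mean(nul[nul > 0])
    neg_mean <- mean(abs(nul[nul < 0]))
    null_nes[i, ] <- ifelse(nul > 0, nul / pos_mean,
                            ifelse(nul < 0, nul / neg_mean, 0))
    if (es[i] >= 0) {
      nes[i] <- if (is.finite(pos_mean)) es[i] / pos_mean else NA_real_
      pval[i] <- (1 + sum(nul >= es[i])) / (1 + sum(nul >= 0))
    } else {
      nes[i] <- if (is.finite(neg_mean)) es[i] / neg_mean else NA_real_
      pval[i] <- (1 + sum(nul <= es[i])) / (1 + sum(nul < 0))
    }
  }
  fdr <- gsea_fdr(nes, null_nes)

  tab <- tibble(set = names(lst), size = unname(sizes), es = unname(es),
                nes = unname(nes), p_value = unname(pval), fdr_q = unname(fdr),
                leading_edge = unname(lead))
  tab <- dplyr::arrange(tab, dplyr::desc(.data$nes))
  structure(
    list(table = tab, n_perm = n_perm, mode = mode, weight = weight,
         seed = seed, group = names(grp)[1], reference = names(grp)[2]),
    class = "gsea_result"
  )
}

# Null ES matrix (sets x perms) from phenotype relabelings. X: genes x
# samples (first n1 columns = group under the observed labels), ind: 0/1
# indicator matrix (samples x perms) of which samples play "group".
null_es_phenotype <- function(X, ind, n1, n2, lst, weight) {
  genes <- rownames(X)
  sum1 <- X %*% ind
  mu1 <- sum1 / n1
  mu2 <- (rowSums(X) - sum1) / n2
  X2 <- X^2
  ss1 <- X2 %*% ind
  v1 <- (ss1 - n1 * mu1^2) / (n1 - 1)
  v2 <- ((rowSums(X2) - ss1) - n2 * mu2^2) / (n2 - 1)
  s1 <- floor_sd(sqrt(pmax(v1, 0)), mu1)
  s2 <- floor_sd(sqrt(pmax(v2, 0)), mu2)
  s2n <- (mu1 - mu2) / (s1 + s2)
  set_idx <- lapply(lst, function(g) match(intersect(g, genes), genes))
  if (any(lengths(set_idx) == 0)) {
    abort("a gene set lost all members after dropping incomplete genes")
  }
  N <- nrow(X)
  out <- matrix(NA_real_, length(lst), ncol(ind),
                dimnames = list(names(lst), NULL))
  pos_of <- integer(N)
  for (p in seq_len(ncol(ind))) {
    s <- s2n[, p]
    ord <- order(-s, genes)
    pos_of[ord] <- seq_len(N)
    sa <- abs(s)^weight
    for (j in seq_along(set_idx)) {
      idx <- set_idx[[j]]
      posi <- sort.int(pos_of[idx])
      out[j, p] <- es_from_positions(posi, sa[ord[posi]], N)
    }
  }
  out
}

# Null ES matrix from random same-size gene sets on the observed ranking.
null_es_geneset <- function(r_obs, sizes, n_perm, weight) {
  N <- length(r_obs)
  sa <- abs(r_obs)^weight
  out <- matrix(NA_real_, length(sizes), n_perm,
                dimnames = list(names(sizes), NULL))
  for (p in seq_len(n_perm)) {
    for (j in seq_along(sizes)) {
      posi <- sort.int(sample.int(N, sizes[j]))
      out[j, p] <- es_from_positions(posi, sa[posi], N)
    }
  }
  out
}

# Sign-stratified NES-ratio FDR (desktop-GSEA style), with a cummin pass so
# q is monotone in |NES| within each sign stratum.
gsea_fdr <- function(nes, null_nes) {
  pool <- as.vector(null_nes)
  pool <- pool[is.finite(pool)]
  q <- rep(NA_real_, length(nes))
  pos_pool <- pool[pool >= 0]; neg_pool <- pool[pool < 0]
  obs_pos <- nes[!is.na(nes) & nes >= 0]; obs_neg <- nes[!is.na(nes) & nes < 0]
  for (i in seq_along(nes)) {
    if (is.na(nes[i])) next
    if (nes[i] >= 0) {
      num <- if (length(pos_pool)) mean(pos_pool >= nes[i]) else 0
      den <- mean(obs_pos >= nes[i])
    } else {
      num <- if (length(neg_pool)) mean(neg_pool <= nes[i]) else 0
      den <- mean(obs_neg <= nes[i])
    }
    q[i] <- min(1, num / den)
  }
  # enforce monotonicity: more extreme NES never has larger q
  for (sgn in c(1, -1)) {
    sel <- which(!is.na(nes) & (if (sgn > 0) nes >= 0 else nes < 0))
    if (length(sel) > 1) {
      ord <- sel[order(-sgn * nes[sel])] # most extreme first
      q[ord] <- cummin(q[ord])
    }
  }
  q
}

#' Pre-compute a GSEA summary table for a collection
#'
#' Runs [gsea_significance()] over a collection and returns (optionally
#' writing to TSV) one row per set, sorted by NES descending, with the
#' leading edge collapsed to a comma-separated field. Re-running with the
#' same seed reproduces the file byte for byte.
#'
#' @inheritParams gsea_significance
#' @param path Optional output TSV path.
#' @return The summary tibble (invisibly when `path` is given).
#' @export
precompute_summary_table <- function(x, meta, sets, group = NULL, reference = NULL,
                                     n_perm = 1000, mode = "auto", weight = 1,
                                     seed, path = NULL, gene_col = 1L) {
  res <- gsea_significance(x, meta, sets, group, reference, n_perm = n_perm,
                           mode = mode, weight = weight, seed = seed,
                           gene_col = gene_col)
  tab <- res$table
  tab$leading_edge <- vapply(tab$leading_edge, paste, "", collapse = ",")
  if (!is.null(path)) {
    readr::write_tsv(tab, path, progress = FALSE)
    return(invisible(tab))
  }
  tab
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: %s vs %s, %d set(s), %d %s permutations (seed %s)\n",
              x$group, x$reference, nrow(x$table), x$n_perm, x$mode,
              format(x$seed)))
  print(dplyr::select(x$table, -"leading_edge"))
  invisible(x)
}

#' Tidy a GSEA result
#'
#' @param x A `gsea_result` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.gsea_result <- function(x, ...) x$table

#' @rdname tidy.gsea_result
#' @exportS3Method generics::glance
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(group = x$group, reference = x$reference, n_sets = nrow(x$table),
         n_perm = x$n_perm, mode = x$mode, weight = x$weight, seed = x$seed)
}

#' NES dot plot of a GSEA result
#'
#' @param object A `gsea_result`.
#' @param fdr_cutoff Sets at or below this FDR are highlighted.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.gsea_result <- function(object, fdr_cutoff = 0.25, ...) {
  tab <- object$table
  tab$set <- factor(tab$set, levels = rev(tab$set))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$nes, y = .data$set,
                                    colour = .data$fdr_q <= fdr_cutoff,
                                    size = .data$size)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey50"),
                                 name = sprintf("FDR <= %g", fdr_cutoff)) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Running-sum enrichment plot
#'
#' @param ranked Ranked list as in [gsea_es()].
#' @param gene_set Member genes.
#' @param weight Hit-increment exponent.
#' @return A ggplot of the running sum with hit positions marked.
#' @export
plot_running_sum <- function(ranked, gene_set, weight = 1) {
  res <- gsea_es(ranked, gene_set, weight, running_sum = TRUE)
  rs <- res$running_sum
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_rug(data = rs[rs$hit, ], sides = "b") +
    ggplot2::labs(x = "rank in ordered list", y = "running enrichment score",
                  title = sprintf("ES = %.3f", res$es)) +
    ggplot2::theme_minimal()
}
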