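#' Empirical-Bayes moderated-t differential expression
#'
#' Two-group differential expression on log2-scale values with per-gene
#' variance shrinkage (Smyth 2004). For gene g with pooled variance
#' \eqn{s_g^2} on \eqn{d_g = n_1 + n_2 - 2} degrees of freedom, the posterior
#' variance is
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' with prior degrees of freedom \eqn{d_0} and prior variance \eqn{s_0^2}
#' estimated by moments matching on the scaled-F distribution of the
#' \eqn{s_g^2} (on the log scale, via the trigamma inverse). The moderated
#' statistic is \eqn{\tilde{t}_g = \mathrm{log2FC}_g /
#' (\tilde{s}_g \sqrt{1/n_1 + 1/n_2})}, referred to a t distribution with
#' \eqn{d_0 + d_g} degrees of freedom, and BH-adjusted across genes.
#'
#' The moments estimate of \eqn{d_0} is capped at `1e6`; `prior_df` may be
#' forced, with `0` recovering the ordinary pooled two-sample t and `Inf`
#' collapsing every posterior variance to \eqn{s_0^2} (normal reference
#' distribution). log2FC is always group minus reference. Genes with missing
#' values in either group are dropped from the contrast and listed in the
#' result's `dropped_genes`.
#'
#' @param x Expression table or matrix, values on the log2 scale.
#' @param meta Sample metadata (`sample`, `group`).
#' @param group,reference Group labels defining the contrast.
#' @param prior_df Optional forced prior degrees of freedom (`NULL` =
#'   estimate by moments).
#' @param lfc_cutoff,p_cutoff,use_adjusted Classification thresholds passed
#'   to [classify_de()] (defaults: |log2FC| >= 1 and adjusted p < 0.05).
#' @param gene_col Identifier column of `x`.
#' @return A `de_fit` object. `tidy()` gives the per-gene table (`gene`,
#'   `log2FC`, `mean_expression`, `t`, `p_value`, `p_adjusted`, `direction`);
#'   `glance()` gives the prior estimates and contrast metadata. The pooled
#'   and posterior per-gene variances are kept as `s2_pooled` /
#'   `s2_posterior` for shrinkage diagnostics.
#' @export
moderated_t_de <- function(x, meta, group = NULL, reference = NULL,
                           prior_df = NULL, lfc_cutoff = 1, p_cutoff = 0.05,
                           use_adjusted = TRUE, gene_col = 1L) {
  m <- as_expr_matrix(x, gene_col)
  meta <- align_meta(meta, colnames(m))
  grp <- split_two_groups(meta, group, reference)
  m1 <- m[, grp[[1]], drop = FALSE]
  m2 <- m[, grp[[2]], drop = FALSE]
  complete <- !apply(is.na(m1), 1, any) & !apply(is.na(m2), 1, any)
  dropped <- rownames(m)[!complete]
  if (!any(complete)) abort("no gene has complete data in both groups")
  m1 <- m1[complete, , drop = FALSE]
  m2 <- m2[complete, , drop = FALSE]
  n1 <- ncol(m1); n2 <- ncol(m2)
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  dg <- n1 + n2 - 2
  s2 <- (rowSums((m1 - mu1)^2) + rowSums((m2 - mu2)^2)) / dg
  prior <- fit_scaled_f_moments(s2, dg)
  d0 <- prior_df %||% prior$d0
  if (length(d0) != 1 || is.na(d0) || d0 < 0) abort("`prior_df` must be a single number >= 0")
  s02 <- prior$s02
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s02 + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  }
  lfc <- mu1 - mu2
  tstat <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df = df_total)
  tab <- tibble(
    gene = rownames(m1),
    log2FC = unname(lfc),
    mean_expression = unname((rowSums(m1) + rowSums(m2)) / (n1 + n2)),
    t = unname(tstat),
    p_value = unname(p),
    p_adjusted = bh_adjust(unname(p)),
    direction = NA_character_
  )
  fit <- structure(
    list(table = tab, prior_df = d0, prior_df_estimated = prior$d0,
         prior_var = s02, df_residual = dg,
         s2_pooled = setNames(unname(s2), rownames(m1)),
         s2_posterior = setNames(unname(s2_post), rownames(m1)),
         group = names(grp)[1], reference = names(grp)[2],
         n_group = n1, n_reference = n2, dropped_genes = dropped,
         lfc_cutoff = lfc_cutoff, p_cutoff = p_cutoff,
         use_adjusted = use_adjusted),
    class = "de_fit"
  )
  classify_de(fit, lfc_cutoff, p_cutoff, use_adjusted)
}

# Moments-matching estimator of the scaled-F prior (d0, s0^2) for pooled
# variances s2 on df1 residual df. Estimation uses log(s2) of the strictly
# positive variances; d0 is capped at 1e6 for numerical stability.
fit_scaled_f_moments <- function(s2, df1, cap = 1e6) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) abort("need at least 2 genes with positive variance to estimate the prior")
  e <- log(s2[ok]) - digamma(df1 / 2) + log(df1 / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df1 / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- cap
  } else {
    d0 <- min(2 * trigamma_inverse(evar), cap)
  }
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton inversion of the trigamma function (x such that trigamma(x) = y).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Classify genes as up, down or not significant
#'
#' A gene is `up` when log2FC >= `lfc_cutoff` and the p criterion holds,
#' `down` when log2FC <= -`lfc_cutoff` with the p criterion, otherwise `ns`.
#' The default fold-change line is 1 log2 unit in either direction.
#'
#' @param de A `de_fit` or a tidy DE table with `log2FC` and p-value columns.
#' @param lfc_cutoff Non-negative log2 fold-change threshold (default 1).
#' @param p_cutoff Significance threshold in (0, 1] (default 0.05).
#' @param use_adjusted Apply `p_cutoff` to BH-adjusted (default) or nominal p.
#' @return Same type as `de`, with `direction` filled in.
#' @export
classify_de <- function(de, lfc_cutoff = 1, p_cutoff = 0.05, use_adjusted = TRUE) {
  if (!is.numeric(lfc_cutoff) || lfc_cutoff < 0) abort("`lfc_cutoff` must be >= 0")
  if (!is.numeric(p_cutoff) || p_cutoff <= 0 || p_cutoff > 1) abort("`p_cutoff` must be in (0, 1]")
  tab <- if (inherits(de, "de_fit")) de$table else as_tibble(de)
  pcol <- if (use_adjusted) tab$p_adjusted else tab$p_value
  sig <- pcol <= p_cutoff
  tab$direction <- dplyr::case_when(
    sig & tab$log2FC >= lfc_cutoff & (lfc_cutoff > 0 | tab$log2FC > 0) ~ "up",
    sig & tab$log2FC <= -lfc_cutoff & (lfc_cutoff > 0 | tab$log2FC < 0) ~ "down",
    TRUE ~ "ns"
  )
  if (inherits(de, "de_fit")) {
    de$table <- tab
    de$lfc_cutoff <- lfc_cutoff
    de$p_cutoff <- p_cutoff
    de$use_adjusted <- use_adjusted
    de
  } else {
    tab
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: the step-up
#' FDR adjustment, monotone in p-value rank with q >= p elementwise.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of BH q-values.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Over-representation analysis of a DE gene list
#'
#' One-sided Fisher's exact (hypergeometric) enrichment of a differential
#' gene list against each set of a collection, with membership restricted to
#' the declared universe and BH adjustment across the tested sets. Sets with
#' no member in the universe are skipped with a warning.
#'
#' @param de_genes Character vector of differential genes (must be a subset
#'   of `universe`).
#' @param universe Character vector of all assayed genes.
#' @param sets Gene-set collection (long tibble or named list).
#' @return A tibble with one row per tested set: overlap and expected counts,
#'   set size in the universe, Fisher `p_value`, BH `p_adjusted`, and the
#'   overlapping genes as a list-column, sorted by p.
#' @export
ora_enrich <- function(de_genes, universe, sets) {
  universe <- unique(as.character(universe))
  if (!length(universe)) abort("empty universe")
  de_genes <- unique(as.character(de_genes))
  if (!all(de_genes %in% universe)) abort("`de_genes` must be a subset of `universe`")
  lst <- as_gene_set_list(sets)
  memb <- lapply(lst, intersect, universe)
  empty <- lengths(memb) == 0
  if (any(empty)) {
    warn(sprintf("skipping %d set(s) disjoint from the universe: %s",
                 sum(empty), paste(names(lst)[empty], collapse = ", ")))
    memb <- memb[!empty]
  }
  if (!length(memb)) abort("no gene set intersects the universe")
  N <- length(universe); n <- length(de_genes)
  rows <- purrr::map_dfr(names(memb), function(s) {
    K <- length(memb[[s]])
    hits <- intersect(de_genes, memb[[s]])
    a <- length(hits)
    tibble(set = s, overlap = a, set_size = K, expected = n * K / N,
           p_value = phyper(a - 1, K, N - K, n, lower.tail = FALSE),
           genes = list(sort(hits)))
  })
  rows$p_adjusted <- bh_adjust(rows$p_value)
  dplyr::arrange(rows, .data$p_value, dplyr::desc(.data$overlap), .data$set)
}

#' @export
print.de_fit <- function(x, ...) {
  n_up <- sum(x$table$direction == "up")
  n_dn <- sum(x$table$direction == "down")
  cat(sprintf("Moderated-t differential expression: %s vs %s (n = %d vs %d)\n",
              x$group, x$reference, x$n_group, x$n_reference))
  cat(sprintf("  %d genes tested (%d dropped for missing values)\n",
              nrow(x$table), length(x$dropped_genes)))
  cat(sprintf("  prior df = %.4g, prior variance = %.4g\n", x$prior_df, x$prior_var))
  cat(sprintf("  %d up / %d down at |log2FC| >= %g, %s p <= %g\n", n_up, n_dn,
              x$lfc_cutoff, if (x$use_adjusted) "adjusted" else "nominal", x$p_cutoff))
  invisible(x)
}

#' Tidy a moderated-t fit
#'
#' @param x A `de_fit` object.
#' @param ... Unused.
#' @return `tidy()`: the per-gene result tibble; `glance()`: a one-row tibble
#'   with the contrast, sample sizes and empirical-Bayes prior estimates.
#' @exportS3Method generics::tidy
#' @export
tidy.de_fit <- function(x, ...) x$table

#' @rdname tidy.de_fit
#' @exportS3Method generics::glance
#' @export
glance.de_fit <- function(x, ...) {
  tibble(group = x$group, reference = x$reference,
         n_group = x$n_group, n_reference = x$n_reference,
         n_genes = nrow(x$table), n_dropped = length(x$dropped_genes),
         prior_df = x$prior_df, prior_var = x$prior_var,
         df_residual = x$df_residual,
         n_up = sum(x$table$direction == "up"),
         n_down = sum(x$table$direction == "down"))
}
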