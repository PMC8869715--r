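#' Hierarchical clustering of samples or genes
#'
#' Agglomerative clustering over the chosen axis using `stats::hclust`.
#' Supported linkages are `ward` (Ward's minimum variance on Euclidean
#' distances, `ward.D2`), `average`, `complete`, and `centroid`; `ward`
#' refuses non-Euclidean metrics. Centroid linkage is run on squared
#' Euclidean distances as it requires, with merge heights reported back on
#' the distance scale. The caller is expected to have applied any
#' transformation (the standard pipeline selects top variable genes, log2
#' transforms, then row z-normalizes before clustering).
#'
#' Matrices with missing values are refused unless `pairwise_complete = TRUE`,
#' which falls back to `dist`'s proportionally rescaled pairwise-complete
#' distances.
#'
#' @inheritParams log2_transform
#' @param method Linkage: `"ward"`, `"average"`, `"complete"` or `"centroid"`.
#' @param distance Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param axis Cluster `"samples"` (columns, default) or `"genes"` (rows).
#' @param pairwise_complete Allow missing values via pairwise-complete
#'   distances.
#' @return A `hier_clust` object wrapping the `hclust` fit, with the leaf
#'   order, linkage and metric recorded. See [tidy.hier_clust()],
#'   [as_newick()], and [autoplot.hier_clust()].
#' @export
hierarchical_cluster <- function(x, method = c("ward", "average", "complete", "centroid"),
                                 distance = "euclidean",
                                 axis = c("samples", "genes"),
                                 pairwise_complete = FALSE, gene_col = 1L) {
  method <- match.arg(method)
  axis <- match.arg(axis)
  m <- as_expr_matrix(x, gene_col)
  if (axis == "samples") m <- t(m)
  if (nrow(m) < 2L) abort("need at least 2 items on the clustered axis")
  if (anyNA(m) && !pairwise_complete) {
    abort("missing values: set `pairwise_complete = TRUE` or impute first")
  }
  if (method == "ward" && distance != "euclidean") {
    abort("ward linkage requires the euclidean metric")
  }
  d <- dist(m, method = distance)
  if (anyNA(d)) abort("distance undefined for at least one pair (all-missing overlap)")
  if (method == "centroid") {
    hc <- hclust(d^2, method = "centroid")
    hc$height <- sqrt(pmax(hc$height, 0))
  } else {
    hc <- hclust(d, method = switch(method, ward = "ward.D2", method))
  }
  structure(
    list(hclust = hc, order = hc$labels[hc$order], axis = axis,
         method = method, distance = distance, n = nrow(m)),
    class = "hier_clust"
  )
}

#' @export
print.hier_clust <- function(x, ...) {
  cat(sprintf("Hierarchical clustering of %d %s (%s linkage, %s distance)\n",
              x$n, x$axis, x$method, x$distance))
  cat("leaf order:", paste(head(x$order, 8), collapse = ", "),
      if (x$n > 8) "..." else "", "\n")
  invisible(x)
}

#' Tidy a hierarchical clustering
#'
#' `tidy()` returns one row per merge (children encoded as in
#' [stats::hclust()]: negative = leaf index, positive = earlier merge) with
#' its height; `glance()` returns a one-row summary.
#'
#' @param x A `hier_clust` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.hier_clust <- function(x, ...) {
  hc <- x$hclust
  tibble(merge = seq_along(hc$height),
         child1 = hc$merge[, 1], child2 = hc$merge[, 2],
         height = hc$height)
}

#' @rdname tidy.hier_clust
#' @exportS3Method generics::glance
#' @export
glance.hier_clust <- function(x, ...) {
  tibble(n_leaves = x$n, n_merges = length(x$hclust$height),
         method = x$method, distance = x$distance, axis = x$axis,
         max_height = max(x$hclust$height))
}

#' Serialize a dendrogram to newick
#'
#' @param x A `hier_clust` object.
#' @param path Optional file to write to; otherwise the newick string is
#'   returned.
#' @export
as_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "hier_clust"))
  phy <- ape::as.phylo(x$hclust)
  if (is.null(path)) ape::write.tree(phy) else ape::write.tree(phy, file = path)
}

# x/y segment coordinates for a ggplot dendrogram, computed from the
# merge table (leaves at integer x in leaf order, height on y).
hclust_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  xpos <- numeric(n - 1)
  segs <- vector("list", n - 1)
  child_xy <- function(ch) {
    if (ch < 0) c(leaf_x[-ch], 0) else c(xpos[ch], hc$height[ch])
  }
  for (i in seq_len(n - 1)) {
    a <- child_xy(hc$merge[i, 1])
    b <- child_xy(hc$merge[i, 2])
    xpos[i] <- (a[1] + b[1]) / 2
    h <- hc$height[i]
    segs[[i]] <- tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], h), yend = c(h, h, h)
    )
  }
  dplyr::bind_rows(segs)
}

#' Plot a dendrogram
#'
#' @param object A `hier_clust` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.hier_clust <- function(object, ...) {
  hc <- object$hclust
  segs <- hclust_segments(hc)
  labs <- tibble(x = seq_along(hc$order), label = hc$labels[hc$order])
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = sprintf("height (%s, %s)", object$method, object$distance)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}
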