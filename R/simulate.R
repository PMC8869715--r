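#' Simulate paired omics matrices with planted differential structure
#'
#' Generates two gene-by-sample matrices (think transcriptome and proteome
#' of the same experiment) on the log2 scale, with Gaussian noise around
#' per-gene baselines drawn uniformly from \[2, 10\] log2 units. A chosen
#' number of genes is shifted by `+effect_size` (up) or `-effect_size`
#' (down) in the treated group of each matrix. The default design mirrors a
#' knockdown experiment with 6 treated (`shRNA`) and 4 control (`scramble`)
#' samples per matrix.
#'
#' Cross-omics concordance is tunable: a fraction `concordance` of matrix A's
#' differential genes (per direction) carries the identical shift in matrix
#' B; the remaining differential genes of B are re-drawn independently from
#' genes unaffected in A. The full ground truth is returned for parameter-
#' recovery testing.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_group,n_reference Samples in the treated and control groups of
#'   each matrix (defaults 6 and 4).
#' @param n_de_up,n_de_down Planted up-/downregulated genes per matrix
#'   (defaults 100 and 60).
#' @param effect_size Shift in log2 units (default 2).
#' @param noise_sd Gaussian noise SD in log2 units (default 1).
#' @param concordance Fraction of A's differential genes shared (with
#'   direction) by B, in \[0, 1\] (default 1).
#' @param seed Integer seed; the output is byte-identical for a fixed seed.
#' @return A list: `expr_a`, `meta_a`, `expr_b`, `meta_b` (tibbles in the
#'   package's expression/metadata shapes) and `truth`, a tibble with per-
#'   gene `direction_a`, `direction_b` (`up`/`down`/`null`) and a
#'   `concordant` flag.
#' @export
simulate_paired_omics <- function(n_genes = 2000, n_group = 6, n_reference = 4,
                                  n_de_up = 100, n_de_down = 60,
                                  effect_size = 2, noise_sd = 1,
                                  concordance = 1, seed) {
  if (missing(seed)) abort("`seed` is required")
  stopifnot(n_genes >= 4, n_group >= 2, n_reference >= 2,
            n_de_up >= 0, n_de_down >= 0, noise_sd >= 0,
            effect_size >= 0, concordance >= 0, concordance <= 1)
  n_de <- n_de_up + n_de_down
  if (n_de > n_genes) abort("n_de_up + n_de_down exceeds n_genes")
  if (2 * n_de > n_genes && concordance < 1) {
    abort("not enough null genes to re-draw independent DE genes for matrix B")
  }
  genes <- sprintf("g%05d", seq_len(n_genes))
  n_s <- n_group + n_reference
  grp_vec <- rep(c("shRNA", "scramble"), c(n_group, n_reference))

  withr::with_seed(seed, {
    de_a <- sample(genes, n_de)
    dir_a_de <- rep(c("up", "down"), c(n_de_up, n_de_down))
    # per-direction concordant subsets keep the directional counts balanced
    conc <- c(
      if (n_de_up > 0) sample(de_a[dir_a_de == "up"], round(concordance * n_de_up)),
      if (n_de_down > 0) sample(de_a[dir_a_de == "down"], round(concordance * n_de_down))
    )
    dir_a <- setNames(rep("null", n_genes), genes)
    dir_a[de_a] <- dir_a_de
    dir_b <- setNames(rep("null", n_genes), genes)
    dir_b[conc] <- dir_a[conc]
    n_need_up <- n_de_up - sum(dir_b == "up")
    n_need_dn <- n_de_down - sum(dir_b == "down")
    if (n_need_up + n_need_dn > 0) {
      pool <- genes[dir_a == "null" & dir_b == "null"]
      extra <- sample(pool, n_need_up + n_need_dn)
      dir_b[extra] <- rep(c("up", "down"), c(n_need_up, n_need_dn))
    }
    make_matrix <- function(dirs, prefix) {
      base <- runif(n_genes, 2, 10)
      m <- base + matrix(rnorm(n_genes * n_s, 0, noise_sd), n_genes, n_s)
      shift <- ifelse(dirs == "up", effect_size,
                      ifelse(dirs == "down", -effect_size, 0))
      m[, seq_len(n_group)] <- m[, seq_len(n_group)] + shift
      dimnames(m) <- list(genes, paste0(prefix, "_s", seq_len(n_s)))
      m
    }
    ma <- make_matrix(dir_a, "rna")
    mb <- make_matrix(dir_b, "prot")
    truth <- tibble(gene = genes,
                    direction_a = unname(dir_a),
                    direction_b = unname(dir_b),
                    concordant = genes %in% conc)
    list(
      expr_a = as_expr_tbl(ma),
      meta_a = tibble(sample = colnames(ma), group = grp_vec),
      expr_b = as_expr_tbl(mb),
      meta_b = tibble(sample = colnames(mb), group = grp_vec),
      truth = truth
    )
  })
}

#' Simulate a random GMT-style gene-set collection
#'
#' Draws random sets from a gene pool, optionally embedding a known
#' ("planted") set for positive-control enrichment tests.
#'
#' @param n_sets Number of random sets (0 allowed only with a planted set).
#' @param genes Gene pool to draw from.
#' @param set_size Length-2 range of set sizes (inclusive).
#' @param planted Optional character vector included verbatim as a set.
#' @param planted_name Name of the planted set (default `"PLANTED"`).
#' @param seed Integer seed.
#' @return A gene-set tibble (`set`, `description`, `gene`).
#' @export
simulate_gene_sets <- function(n_sets, genes, set_size = c(10, 50),
                               planted = NULL, planted_name = "PLANTED", seed) {
  if (missing(seed)) abort("`seed` is required")
  if (n_sets < 1 && is.null(planted)) abort("nothing to generate: n_sets = 0 and no planted set")
  if (max(set_size) > length(genes)) abort("set size exceeds the gene pool")
  withr::with_seed(seed, {
    lst <- list()
    if (n_sets > 0) {
      sizes <- sample(seq(set_size[1], set_size[2]), n_sets, replace = TRUE)
      lst <- lapply(sizes, function(k) sample(genes, k))
      names(lst) <- sprintf("RANDOM_%03d", seq_len(n_sets))
    }
    if (!is.null(planted)) {
      lst <- c(setNames(list(unique(as.character(planted))), planted_name), lst)
    }
    gene_sets_tbl(lst, description = rep("synthetic", length(lst)))
  })
}
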