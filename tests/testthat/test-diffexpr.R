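sim_de_matrix <- function(seed = 3, n_genes = 50, n1 = 6, n2 = 4, effect = 2,
                          n_de = 5) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  m <- matrix(rnorm(n_genes * (n1 + n2), 5, 1), n_genes,
              dimnames = list(genes, paste0("s", seq_len(n1 + n2))))
  # heterogeneous variances so the prior df is finite and shrinkage matters
  m <- 5 + (m - 5) * runif(n_genes, 0.3, 3)
  m[seq_len(n_de), seq_len(n1)] <- m[seq_len(n_de), seq_len(n1)] + effect
  list(x = as_expr_tbl(m),
       meta = meta_fixture(colnames(m), rep(c("kd", "ctl"), c(n1, n2))))
}

test_that("forcing prior df to 0 reproduces the ordinary pooled t", {
  d <- sim_de_matrix()
  fit <- moderated_t_de(d$x, d$meta, "kd", "ctl", prior_df = 0)
  m <- as_expr_matrix(d$x)
  ref_t <- oracle_pooled_t(m[, 1:6], m[, 7:10])
  expect_lt(max(abs(tidy(fit)$t - ref_t[tidy(fit)$gene])), 1e-10)
  expect_equal(fit$s2_posterior, fit$s2_pooled)
})

test_that("infinite prior df collapses every posterior variance to the prior", {
  d <- sim_de_matrix()
  fit <- moderated_t_de(d$x, d$meta, "kd", "ctl", prior_df = Inf)
  rel <- abs(fit$s2_posterior - fit$prior_var) / fit$prior_var
  expect_lt(max(rel), 1e-12)
  # reference distribution becomes normal
  expect_equal(tidy(fit)$p_value,
               2 * pnorm(-abs(tidy(fit)$t)))
})

test_that("moderated t matches a step-by-step transcription of the estimators", {
  d <- sim_de_matrix(seed = 9)
  fit <- moderated_t_de(d$x, d$meta, "kd", "ctl")
  m <- as_expr_matrix(d$x)
  ref <- oracle_moderated_t(m[, 1:6], m[, 7:10])
  expect_lt(abs(fit$prior_df - ref$d0) / ref$d0, 1e-8)
  expect_lt(abs(fit$prior_var - ref$s02) / ref$s02, 1e-8)
  tab <- tidy(fit)
  expect_lt(max(abs(tab$t - ref$t[tab$gene])), 1e-10)
  expect_lt(max(abs(tab$p_value - ref$p[tab$gene])), 1e-10)
})

test_that("moderated t agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  d <- sim_de_matrix(seed = 21, n_genes = 200)
  fit <- moderated_t_de(d$x, d$meta, "kd", "ctl")
  m <- as_expr_matrix(d$x)
  design <- cbind(intercept = 1, kd = rep(c(1, 0), c(6, 4)))
  lf <- limma::eBayes(limma::lmFit(m, design))
  tab <- tidy(fit)
  expect_equal(tab$log2FC, unname(lf$coefficients[tab$gene, "kd"]), tolerance = 1e-10)
  expect_equal(fit$prior_df, lf$df.prior, tolerance = 1e-4)
  expect_equal(tab$t, unname(lf$t[tab$gene, "kd"]), tolerance = 1e-6)
  expect_equal(tab$p_value, unname(lf$p.value[tab$gene, "kd"]), tolerance = 1e-6)
})

test_that("swapping group and reference negates log2FC and t, keeps p", {
  d <- sim_de_matrix(seed = 5)
  f1 <- moderated_t_de(d$x, d$meta, "kd", "ctl")
  f2 <- moderated_t_de(d$x, d$meta, "ctl", "kd")
  expect_equal(tidy(f1)$log2FC, -tidy(f2)$log2FC)
  expect_equal(tidy(f1)$t, -tidy(f2)$t)
  expect_equal(tidy(f1)$p_value, tidy(f2)$p_value)
})

test_that("adding a constant to one gene shifts its mean but not t or p", {
  d <- sim_de_matrix(seed = 6)
  x2 <- d$x
  x2[x2$gene == "g001", -1] <- x2[x2$gene == "g001", -1] + 7
  f1 <- moderated_t_de(d$x, d$meta, "kd", "ctl")
  f2 <- moderated_t_de(x2, d$meta, "kd", "ctl")
  i <- which(tidy(f1)$gene == "g001")
  expect_equal(tidy(f2)$t[i], tidy(f1)$t[i], tolerance = 1e-12)
  expect_equal(tidy(f2)$p_value[i], tidy(f1)$p_value[i], tolerance = 1e-12)
  expect_equal(tidy(f2)$mean_expression[i], tidy(f1)$mean_expression[i] + 7)
})

test_that("constant genes and missing values are handled explicitly", {
  d <- sim_de_matrix(seed = 8, n_genes = 30)
  m <- as_expr_matrix(d$x)
  m["g001", ] <- 3           # constant everywhere: moderated variance keeps t finite
  m["g002", 2] <- NA         # missing in the kd group: dropped and reported
  fit <- moderated_t_de(as_expr_tbl(m), d$meta, "kd", "ctl")
  expect_false("g002" %in% tidy(fit)$gene)
  expect_equal(fit$dropped_genes, "g002")
  expect_true(is.finite(tidy(fit)$t[tidy(fit)$gene == "g001"]))
  small <- meta_fixture(paste0("s", 1:10), c("kd", rep("ctl", 9)))
  expect_error(moderated_t_de(d$x, small, "kd", "ctl"), "n >= 2")
})

test_that("classify_de applies fold-change and p thresholds", {
  tab <- tibble::tibble(gene = c("a", "b", "c", "d"),
                        log2FC = c(1.5, 0, -2, 0.5),
                        p_value = c(0.001, 0.5, 0.01, 0.001),
                        p_adjusted = c(0.01, 0.9, 0.04, 0.02))
  out <- classify_de(tab, lfc_cutoff = 1, p_cutoff = 0.05, use_adjusted = TRUE)
  expect_equal(out$direction, c("up", "ns", "down", "ns"))
  degen <- classify_de(tab, lfc_cutoff = 0, p_cutoff = 1)
  expect_equal(degen$direction, c("up", "ns", "down", "up"))
  expect_error(classify_de(tab, lfc_cutoff = -1), "lfc_cutoff")
})

test_that("bh_adjust is the BH step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(4)
  p <- runif(100)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("ORA matches the exhaustive hypergeometric tail", {
  universe <- sprintf("u%02d", 1:40)
  sets <- list(S1 = universe[1:10], S2 = universe[31:40], FAR = c("x1", "x2"))
  de <- universe[1:8]
  expect_warning(res <- ora_enrich(de, universe, sets), "disjoint")
  s1 <- res[res$set == "S1", ]
  expect_equal(s1$overlap, 8L)
  expect_equal(s1$p_value, oracle_hyper_tail(8, 10, 8, 40), tolerance = 1e-12)
  # de list = universe forces full overlap and p = 1
  res_all <- suppressWarnings(ora_enrich(universe, universe, sets["S1"]))
  expect_equal(res_all$overlap, 10L)
  expect_equal(res_all$p_value, 1)
  expect_error(ora_enrich(c(de, "zz"), universe, sets), "subset")
})

test_that("DE recovery: FDR controlled at the study design, power grows with effect", {
  res <- sapply(1:8, function(s) {
    sim <- simulate_paired_omics(n_genes = 800, n_de_up = 48, n_de_down = 32,
                                 effect_size = 2, noise_sd = 1, seed = 100 + s)
    fit <- moderated_t_de(sim$expr_a, sim$meta_a, "shRNA", "scramble")
    tab <- tidy(fit)
    called <- tab$gene[tab$p_adjusted <= 0.05]
    truth <- sim$truth$gene[sim$truth$direction_a != "null"]
    c(fdr = if (length(called)) mean(!called %in% truth) else 0,
      sens = mean(truth %in% called))
  })
  expect_lte(median(res["fdr", ]), 0.10)
  expect_gt(median(res["sens", ]), 0.3)

  strong <- sapply(1:4, function(s) {
    sim <- simulate_paired_omics(n_genes = 800, n_de_up = 48, n_de_down = 32,
                                 effect_size = 4, noise_sd = 1, seed = 200 + s)
    fit <- moderated_t_de(sim$expr_a, sim$meta_a, "shRNA", "scramble")
    tab <- tidy(fit)
    truth <- sim$truth$gene[sim$truth$direction_a != "null"]
    mean(truth %in% tab$gene[tab$p_adjusted <= 0.05])
  })
  expect_gte(median(strong), 0.95)
})
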