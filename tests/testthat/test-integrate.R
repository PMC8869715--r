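test_that("merge_features pairs shared samples and rejects disjoint ones", {
  sim <- tiny_sim(seed = 4)
  # same matrix, same feature: diagonal pairs
  g <- sim$truth$gene[1]
  mf <- merge_features(sim$expr_a, sim$expr_a, g, g, meta = sim$meta_a)
  expect_equal(mf$value_a, mf$value_b)
  expect_equal(cor(mf$value_a, mf$value_b), 1)
  expect_true(all(c("sample", "group") %in% names(mf)))
  # rna vs protein rows share no sample names here
  expect_error(merge_features(sim$expr_a, sim$expr_b, g, g), "shared samples")
  expect_error(merge_features(sim$expr_a, sim$expr_a, "zz", g), "not in")
})

test_that("correlation_rank sorts ascending with self-correlation last", {
  sim <- tiny_sim(seed = 6)
  m <- as_expr_matrix(sim$expr_a)
  target <- m["g00010", ]
  cr <- correlation_rank(sim$expr_a, target, method = "spearman")
  expect_equal(cr$gene[nrow(cr)], "g00010")
  expect_equal(cr$correlation[nrow(cr)], 1)
  expect_true(!is.unsorted(cr$correlation))
  crn <- correlation_rank(sim$expr_a, -target, method = "spearman")
  expect_equal(crn$correlation[crn$gene == "g00010"], -1)
  expect_error(correlation_rank(sim$expr_a, setNames(rep(1, 10), names(target))),
               "constant target")
})

test_that("spearman equals pearson on ranks", {
  set.seed(2)
  v <- setNames(rnorm(6), paste0("s", 1:6))
  m <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("g", 1:5), names(v)))
  cr <- correlation_rank(as_expr_tbl(m), v, method = "spearman")
  ref <- apply(m, 1, function(row) cor(rank(row), rank(v)))
  expect_equal(setNames(cr$correlation, cr$gene)[names(ref)], ref,
               tolerance = 1e-12)
})

test_that("compare_log2fc computes deltas and quadrant labels", {
  de <- tibble::tibble(gene = c("a", "b", "c"),
                       log2FC = c(2, -2, 0.2),
                       p_value = c(0.001, 0.001, 0.8),
                       p_adjusted = c(0.01, 0.01, 0.9))
  de <- classify_de(de)
  same <- compare_log2fc(de, de)
  expect_equal(same$delta, rep(0, 3))
  expect_equal(same$concordance, c("concordant_up", "concordant_down", "ns"))
  flipped <- de
  flipped$log2FC <- -flipped$log2FC
  flipped <- classify_de(flipped)
  pc <- compare_log2fc(de, flipped)
  expect_equal(pc$delta[pc$gene == "a"], 4)
  expect_equal(pc$concordance[pc$gene == "a"], "discordant")
  # antisymmetry of the delta
  pc_rev <- compare_log2fc(flipped, de)
  expect_equal(pc$delta, -pc_rev$delta)
  # join is the gene intersection
  expect_equal(nrow(compare_log2fc(de, de[1:2, ])), 2L)
  expect_error(compare_log2fc(de, dplyr::mutate(de, gene = paste0("x", gene))),
               "shared")
})

test_that("derive_signatures builds the four reciprocal sets and round-trips GMT", {
  de_a <- tibble::tibble(gene = paste0("g", 1:6),
                         log2FC = c(2, 3, 1.5, -2, -3, 0),
                         p_value = rep(0.001, 6), p_adjusted = rep(0.01, 6))
  de_b <- tibble::tibble(gene = paste0("g", 1:6),
                         log2FC = c(2, 0, 0, 0, 0, 0),
                         p_value = rep(0.001, 6), p_adjusted = rep(0.01, 6))
  expect_warning(sigs <- derive_signatures(de_a, de_b), "empty signature.*B_down")
  expect_equal(sort(unique(sigs$set)), c("A_down", "A_up", "B_up"))
  expect_equal(sum(sigs$set == "A_up"), 3L)
  expect_equal(sum(sigs$set == "A_down"), 2L)
  expect_equal(sum(sigs$set == "B_up"), 1L)
  expect_equal(attr(sigs, "empty_sets"), "B_down")
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sigs, f)
  expect_equal(read_gmt(f)[c("set", "gene")], sigs[c("set", "gene")],
               ignore_attr = TRUE)
  # degenerate cutoffs assign every nonzero-FC gene a direction
  all_sig <- derive_signatures(de_a, de_a, lfc_cutoff = 0, p_cutoff = 1)
  expect_setequal(all_sig$gene[startsWith(all_sig$set, "A")], paste0("g", 1:5))
})

test_that("self-reciprocal GSEA enriches a matrix's own up signature", {
  sim <- tiny_sim(seed = 8)
  de_a <- moderated_t_de(sim$expr_a, sim$meta_a, "shRNA", "scramble")
  sigs <- derive_signatures(de_a, de_a, labels = c("A", "B"))
  rg <- reciprocal_gsea(sim$expr_a, sim$meta_a, sim$expr_a, sim$meta_a, sigs,
                        "shRNA", "scramble", n_perm = 100, seed = 31)
  expect_gt(rg$es[rg$set == "A_up"], 0)
  expect_lt(rg$es[rg$set == "A_down"], 0)
  expect_equal(nrow(rg), 4L)
  expect_setequal(rg$target[rg$source == "A"], "B")
})

test_that("reciprocal ssGSEA separates groups on concordant data", {
  sim <- simulate_paired_omics(n_genes = 500, n_de_up = 40, n_de_down = 30,
                               effect_size = 3, concordance = 1, seed = 99)
  de_a <- moderated_t_de(sim$expr_a, sim$meta_a, "shRNA", "scramble")
  de_b <- moderated_t_de(sim$expr_b, sim$meta_b, "shRNA", "scramble")
  sigs <- derive_signatures(de_a, de_b)
  rs <- reciprocal_ssgsea(sim$expr_a, sim$meta_a, sim$expr_b, sim$meta_b, sigs,
                          "shRNA", "scramble")
  comp <- rs$comparisons
  expect_lt(comp$p_value[comp$set == "A_up" & comp$target == "B"], 0.05)
  expect_s3_class(rs$scores_in_b, "tbl_df")
})

test_that("venn_overlap counts directional overlaps", {
  de_a <- classify_de(tibble::tibble(gene = c("g1", "g2", "g3"),
                                     log2FC = c(2, 2, 2),
                                     p_value = 0.001, p_adjusted = 0.01))
  de_b <- classify_de(tibble::tibble(gene = c("g2", "g3", "g4"),
                                     log2FC = c(2, 2, 2),
                                     p_value = 0.001, p_adjusted = 0.01))
  v <- venn_overlap(de_a, de_b, "up")
  expect_equal(unlist(v[c("a_only", "b_only", "both")]),
               c(a_only = 1L, b_only = 1L, both = 2L))
  expect_equal(v$genes_both[[1]], c("g2", "g3"))
  expect_equal(v$a_only + v$b_only + v$both,
               length(union(c("g1", "g2", "g3"), c("g2", "g3", "g4"))))
  same <- venn_overlap(de_a, de_a, "up")
  expect_equal(same$a_only + same$b_only, 0L)
})

test_that("overlap_stats: closed forms, symmetry, degenerate cases", {
  universe <- sprintf("u%03d", 1:100)
  set_a <- universe[1:15]
  set_b <- universe[c(1:10, 16:20)]
  # a = 10, b = 5, c = 5, d = 80
  os <- overlap_stats(set_a, set_b, universe)
  expect_equal(unlist(os[c("n_both", "n_a_only", "n_b_only", "n_neither")]),
               c(n_both = 10L, n_a_only = 5L, n_b_only = 5L, n_neither = 80L))
  expect_equal(os$jaccard, 0.5)
  po <- 0.90; pe <- (15 * 15 + 85 * 85) / 1e4
  expect_equal(os$kappa, (po - pe) / (1 - pe), tolerance = 1e-14)
  expect_equal(os$fisher_p, oracle_hyper_tail(10, 15, 15, 100), tolerance = 1e-14)
  # symmetric in the two sets
  os2 <- overlap_stats(set_b, set_a, universe)
  expect_equal(os2[c("fisher_p", "kappa", "jaccard")],
               os[c("fisher_p", "kappa", "jaccard")])
  # identical, disjoint, undefined-kappa cases
  expect_equal(overlap_stats(set_a, set_a, universe)$kappa, 1)
  expect_equal(overlap_stats(set_a, set_a, universe)$jaccard, 1)
  expect_equal(overlap_stats(universe[1:5], universe[6:10], universe)$jaccard, 0)
  und <- overlap_stats(character(0), character(0), universe)
  expect_true(is.na(und$kappa))
  expect_error(overlap_stats(c(set_a, "zz"), set_b, universe), "subsets")
})

test_that("pathway_overlap_scan ranks the matching reference first", {
  universe <- sprintf("u%03d", 1:200)
  query <- universe[1:30]
  reference <- universe[5:32]
  coll <- simulate_gene_sets(6, genes = universe, set_size = c(15, 40), seed = 3)
  scan <- pathway_overlap_scan(query, coll, universe, reference,
                               reference_name = "other_omics")
  expect_equal(nrow(scan), 7L)
  expect_equal(scan$set[1], "other_omics")
  expect_equal(scan$n_both[1], length(intersect(query, reference)))
  expect_true(!is.unsorted(scan$fisher_p))
  # a collection containing the query itself maximizes the overlap count
  coll2 <- dplyr::bind_rows(coll,
                            tibble::tibble(set = "SELF", description = "q", gene = query))
  scan2 <- pathway_overlap_scan(query, coll2, universe, reference)
  expect_equal(scan2$set[1], "SELF")
  expect_equal(scan2$n_both[1], 30L)
  expect_error(pathway_overlap_scan(query, coll[0, ], universe, reference), "empty")
})

test_that("minimum Fisher p over random sets behaves like a minimum of uniforms", {
  universe <- sprintf("u%03d", 1:400)
  k <- 5
  mins <- sapply(1:60, function(s) {
    coll <- simulate_gene_sets(k, genes = universe, set_size = c(40, 60),
                               seed = 1000 + s)
    query <- withr::with_seed(2000 + s, sample(universe, 50))
    lst <- as.list(split(coll$gene, coll$set))
    min(sapply(lst, function(g) overlap_stats(query, g, universe)$fisher_p))
  })
  # Beta(1, k) CDF transform of the minimum should look uniform; the Fisher p
  # is discrete and conservative, so allow a generous KS threshold
  u <- 1 - (1 - mins)^k
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.001)
})
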