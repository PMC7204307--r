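ranked_fixture <- function(genes, metric) {
  structure(data.frame(gene = genes, metric = metric,
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

test_that("signal-to-noise metric and ordering are as defined", {
  # two groups of 3 with known means/sds
  x <- rbind(gUp = c(2, 2, 2, 0, 0, 0),
             gFlat = c(1, 2, 3, 1, 2, 3),
             gDown = c(0, 0, 0, 2, 2, 2))
  x["gUp", 1:3] <- c(1.5, 2, 2.5)    # meanA 2, sdA 0.5
  x["gUp", 4:6] <- c(-0.5, 0, 0.5)   # meanB 0, sdB 0.5
  colnames(x) <- paste0("s", 1:6)
  ct <- group_contrast(paste0("s", 1:3), paste0("s", 4:6))
  rl <- signal2noise_ranking(x, ct, sd_floor_frac = 0.2)
  # sdA floored at 0.2*|2| = 0.5 (tie), so metric = 2 / (0.5 + 0.5)
  expect_equal(rl$metric[rl$gene == "gUp"], 2.0)
  expect_equal(rl$metric[rl$gene == "gFlat"], 0)
  expect_equal(rl$gene[1], "gUp")
  expect_equal(rl$gene[nrow(rl)], "gDown")
  # ties broken lexicographically
  xt <- rbind(b = c(1, 2, 3, 1, 2, 3), a = c(1, 2, 3, 1, 2, 3))
  colnames(xt) <- paste0("s", 1:6)
  rlt <- signal2noise_ranking(xt, ct)
  expect_equal(rlt$gene, c("a", "b"))
  expect_error(signal2noise_ranking(x[, 1:5], group_contrast(
    paste0("s", 1:2), paste0("s", 3:5))), "at least 3")
})

test_that("ranking equals brute-force recomputation on random data", {
  set.seed(14)
  x <- matrix(rnorm(60 * 10, 5), 60, 10,
              dimnames = list(sprintf("g%02d", 1:60), paste0("s", 1:10)))
  ct <- group_contrast(paste0("s", 1:5), paste0("s", 6:10))
  rl <- signal2noise_ranking(x, ct)
  manual <- vapply(rownames(x), function(g) {
    a <- x[g, 1:5]
    b <- x[g, 6:10]
    sa <- max(sd(a), 0.2 * abs(mean(a)), 1e-8)
    sb <- max(sd(b), 0.2 * abs(mean(b)), 1e-8)
    (mean(a) - mean(b)) / (sa + sb)
  }, numeric(1))
  expect_equal(setNames(rl$metric, rl$gene),
               manual[order(-manual, names(manual))])
})

test_that("running sum walks the hand-computed path", {
  rl <- ranked_fixture(c("a", "b", "c", "d"), c(3, 2, 1, 0))
  top <- enrichment_score(rl, "a")
  expect_equal(top$running, c(1, 2 / 3, 1 / 3, 0))
  expect_equal(top$es, 1)
  bottom <- enrichment_score(rl, "d")
  expect_equal(bottom$es, -1)
  expect_equal(bottom$running, c(-1 / 3, -2 / 3, -1, 0))
  expect_error(enrichment_score(rl, "zz"), "does not intersect")
  expect_error(enrichment_score(rl, c("a", "b", "c", "d")), "entire")
})

test_that("reversing the list negates the equal-weight ES", {
  set.seed(15)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    genes <- sprintf("g%02d", seq_len(n))
    metric <- sort(rnorm(n), decreasing = TRUE)
    set_genes <- sample(genes, sample(2:(n - 2), 1))
    fwd <- enrichment_score(ranked_fixture(genes, metric), set_genes)
    rev <- enrichment_score(ranked_fixture(rev(genes), rev(metric)),
                            set_genes)
    expect_equal(rev$es, -fwd$es, tolerance = 1e-12)
  }
})

test_that("ES equals the exhaustive max-deviation oracle", {
  set.seed(16)
  for (rep in 1:50) {
    n <- sample(5:50, 1)
    genes <- sprintf("g%02d", seq_len(n))
    metric <- sort(rnorm(n), decreasing = TRUE)
    k <- sample(seq_len(n - 1), 1)
    set_genes <- sample(genes, k)
    es <- enrichment_score(ranked_fixture(genes, metric), set_genes)$es
    expect_equal(es, oracle_es(genes, set_genes), tolerance = 1e-12)
  }
})

test_that("equal-weight ES agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  for (rep in 1:10) {
    n <- 40
    genes <- sprintf("g%02d", seq_len(n))
    metric <- sort(rnorm(n), decreasing = TRUE)
    set_genes <- sample(genes, 8)
    ours <- enrichment_score(ranked_fixture(genes, metric), set_genes)$es
    theirs <- fgsea::calcGseaStat(setNames(metric, genes),
                                  which(genes %in% set_genes),
                                  gseaParam = 0)
    expect_equal(ours, theirs, tolerance = 1e-8)
  }
})

test_that("permutation p-values are deterministic and floor at 1/(n+1)", {
  set.seed(18)
  n <- 100
  genes <- sprintf("g%03d", seq_len(n))
  metric <- sort(rnorm(n, sd = 2), decreasing = TRUE)
  rl <- ranked_fixture(genes, metric)
  top10 <- genes[1:10]
  res <- random_geneset_pvalue(rl, top10, n_perm = 199, seed = 4)
  expect_equal(res$es, 1)  # contiguous top block under equal weights
  expect_equal(res$p, 1 / 200)
  res2 <- random_geneset_pvalue(rl, top10, n_perm = 199, seed = 4)
  expect_identical(res$p, res2$p)
  expect_identical(res$null_es, res2$null_es)
  expect_warning(random_geneset_pvalue(rl, top10, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("leading edge is the members at or before the peak", {
  rl <- ranked_fixture(sprintf("g%02d", 1:20),
                       seq(2, -2, length.out = 20))
  # contiguous top set: leading edge = whole set
  res <- enrichment_score(rl, sprintf("g%02d", 1:5))
  expect_identical(leading_edge(res, rl), sprintf("g%02d", 1:5))
  # one member above the peak, one far below: only the first survives
  res2 <- enrichment_score(rl, c("g01", "g20"))
  le2 <- leading_edge(res2, rl)
  expect_identical(le2, "g01")
  # containment always
  set.seed(19)
  for (rep in 1:10) {
    set_genes <- sample(rl$gene, 6)
    r <- enrichment_score(rl, set_genes)
    expect_true(all(leading_edge(r, rl) %in% set_genes))
  }
})

test_that("distillation intersects the top leading edge with the mask", {
  le <- top19_leading_edge_synthetic()
  mask <- mitosis_regulators_synthetic()
  expect_length(le, 19)
  distilled <- distill_signature(le, mask, k_max = 19, name = "PC-CIN")
  expect_setequal(distilled$genes,
                  c("PBK", "CEP55", "UBE2C", "MELK", "TPX2", "PTTG1",
                    "CDCA3"))
  # rank order preserved
  expect_identical(distilled$genes, le[le %in% mask])
  # mask superset leaves the top k unchanged
  all_in <- distill_signature(le, le, k_max = 5)
  expect_identical(all_in$genes, le[1:5])
  expect_error(distill_signature(le, c("NOPE"), k_max = 19), "larger k_max")
})

test_that("planted signature enriches with small p in the cohort", {
  cfg <- simulation_config(n_samples_per_group = 15,
                           group_cin_means = c("M0-NM" = 0.2,
                                               "M1-poly" = 1.2),
                           n_genes = 300, n_signature_genes = 30,
                           arms = 4, cin_effect = 1, seed = 41)
  coh <- generate_cohort(cfg)
  nrm <- tmm_normalize(filter_low_counts(coh$expression))
  ann <- coh$annotations
  ct <- group_contrast(ann$sample[ann$group == "M1-poly"],
                       ann$sample[ann$group == "M0-NM"],
                       "M1-poly", "M0-NM")
  rl <- signal2noise_ranking(nrm$log2, ct)
  res <- random_geneset_pvalue(rl, gene_signature("planted",
                                                  coh$truth$gene_id),
                               n_perm = 500, seed = 6)
  expect_gt(res$es, 0)
  expect_lte(res$p, 0.01)
  le <- leading_edge(res, rl)
  expect_gt(length(le), 0)
  expect_true(all(le %in% coh$truth$gene_id))
})
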