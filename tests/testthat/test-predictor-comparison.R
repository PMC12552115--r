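make_gene_datasets <- function(n_genes = 3, n_individuals = 500,
                               variants_per_gene = 40, seed = 50,
                               directions = rep("case", n_genes), ...) {
  cfg <- sim_config(n_individuals = n_individuals,
                    n_variants = n_genes * variants_per_gene,
                    n_genes = n_genes, seed = seed, ...)
  sim <- simulate_cohort(cfg)
  genes <- unique(sim$variants$gene)
  datasets <- lapply(seq_along(genes), function(k) {
    keep <- sim$variants$gene == genes[k]
    list(pair = gene_phenotype_pair(genes[k], direction = directions[k]),
         profiles = gene_profiles(sim$genotypes[, keep, drop = FALSE],
                                  sim$variants[keep, , drop = FALSE],
                                  names(cfg$panel_spec)),
         cohort = sim$cohort)
  })
  list(datasets = datasets, sim = sim, cfg = cfg)
}

test_that("protective-gene flip is an involution and identity for case genes", {
  coh <- null_cohort(100)
  prot <- gene_phenotype_pair("G", direction = "control")
  case <- gene_phenotype_pair("G", direction = "case")
  expect_identical(flip_protective(coh, case), coh)
  expect_identical(flip_protective(flip_protective(coh, prot), prot), coh)
  expect_equal(flip_protective(coh, prot)$phenotype, 1L - coh$phenotype)
})

test_that("flipping the phenotype direction negates the gene's SLPs", {
  x <- make_gene_datasets(n_genes = 1, seed = 51)
  d <- x$datasets[[1]]
  as_case <- predictor_slp(d$profiles,
                           flip_protective(d$cohort, d$pair),
                           "informative")
  prot <- gene_phenotype_pair(d$pair$gene, direction = "control")
  as_control <- predictor_slp(d$profiles,
                              flip_protective(d$cohort, prot),
                              "informative")
  expect_equal(as_control$slp, -as_case$slp, tolerance = 1e-6)
})

test_that("comparison matrix rows, means and ordering are consistent", {
  x <- make_gene_datasets(n_genes = 3, seed = 52)
  cmp <- run_comparison(x$datasets, names(x$cfg$panel_spec))
  expect_s3_class(cmp, "slp_comparison")
  expect_equal(dim(cmp$slp), c(3, 3))
  expect_equal(cmp$mean_slp, rowMeans(cmp$slp), tolerance = 1e-9)
  # independent recomputation of one row mean
  expect_equal(unname(cmp$mean_slp[1]), mean(cmp$slp[1, ]))
  expect_true(!is.unsorted(rev(cmp$mean_slp)))   # descending order
  df <- as.data.frame(cmp)
  expect_equal(df$mean_slp, unname(cmp$mean_slp))
})

test_that("identical predictor columns give identical SLP rows", {
  x <- make_gene_datasets(n_genes = 2, seed = 53)
  datasets <- lapply(x$datasets, function(d) {
    d$profiles$copy <- d$profiles$informative
    d
  })
  cmp <- run_comparison(datasets, c("informative", "copy"),
                        sort_rows = FALSE)
  expect_equal(unname(cmp$slp["informative", ]), unname(cmp$slp["copy", ]))
})

test_that("an informative predictor outranks a noise predictor over genes", {
  x <- make_gene_datasets(n_genes = 6, n_individuals = 1000, seed = 54,
                          effect_size = 0.5)
  cmp <- run_comparison(x$datasets, c("informative", "noise"))
  expect_gt(cmp$mean_slp["informative"], cmp$mean_slp["noise"])
})

test_that("correlation matrix is symmetric, unit-diagonal and matches brute force", {
  set.seed(55)
  k <- 5; m <- 50
  scores <- matrix(rnorm(m * k), m, dimnames = list(NULL, paste0("p", 1:k)))
  scores[sample(length(scores), 40)] <- NA     # injected missingness
  v <- data.frame(variant_id = sprintf("1:%d:A:T", 1:m),
                  consequence = "missense_variant", scores)
  cm <- score_correlation_matrix(v, paste0("p", 1:k))
  expect_equal(cm, t(cm), ignore_attr = TRUE)
  expect_equal(unname(diag(cm)), rep(1, k))
  expect_true(all(abs(cm[!is.na(cm)]) <= 1 + 1e-12))
  oracle <- cor_oracle(as.matrix(v[paste0("p", 1:k)]))
  expect_equal(cm, oracle, ignore_attr = TRUE)
})

test_that("correlation restricts to missense and masks sparse pairs", {
  v <- data.frame(variant_id = sprintf("1:%d:A:T", 1:8),
                  consequence = c(rep("missense_variant", 6), "stop_gained",
                                  "synonymous_variant"),
                  a = c(1, 2, 3, 4, 5, 6, 100, -100),
                  b = c(2, 1, 4, 3, 6, 5, 100, -100),
                  c = c(1, 2, NA, NA, NA, NA, 1, 2))
  cm <- score_correlation_matrix(v, c("a", "b", "c"))
  expect_equal(attr(cm, "n_variants"), 6)      # non-missense dropped
  expect_true(is.na(cm["a", "c"]))             # only 2 complete pairs
  expect_equal(cm["a", "b"], cor(v$a[1:6], v$b[1:6]))
  # a duplicated column correlates perfectly
  v$dup <- v$a
  cm2 <- score_correlation_matrix(v, c("a", "dup"))
  expect_equal(cm2["a", "dup"], 1)
})

test_that("relative SLP scales each gene by its best positive SLP", {
  m <- matrix(c(4, 2, -1,
                10, 5, 2.5,
                -1, -2, -3), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("g1", "g2", "g3")))
  rel <- relative_slp(m)
  expect_equal(unname(rel$relative[, "g1"]), c(1, 0.5, -0.25))
  expect_true(rel$negative["p3", "g1"])
  expect_equal(rel$no_positive, "g3")
  expect_true(all(is.na(rel$relative[, "g3"])))
  # invariant to positive rescaling of a column
  m2 <- m; m2[, "g1"] <- 5 * m[, "g1"]
  expect_equal(relative_slp(m2)$relative[, "g1"], rel$relative[, "g1"])
  # the column maximum maps to exactly 1
  expect_equal(max(rel$relative[, "g2"]), 1)
})

test_that("published reference table reproduces its printed row averages", {
  ref <- slp_reference()
  expect_equal(dim(ref$slp), c(11, 18))
  recomputed <- rowMeans(ref$slp)
  expect_equal(round(unname(recomputed), 2),
               unname(ref$printed_average), tolerance = 1e-12)
  expect_length(ref$pairs, 18)
  expect_s3_class(ref$pairs[[1]], "gene_phenotype_pair")
})
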