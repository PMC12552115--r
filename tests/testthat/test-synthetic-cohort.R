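test_that("configuration validation names the offending field", {
  expect_error(sim_config(0, 10), "n_individuals")
  expect_error(sim_config(10, 10, maf_max = 0.6), "maf_max")
  expect_error(sim_config(10, 10, category_probs = c(0.5, 0.5, 0.5)),
               "category_probs")
  expect_error(sim_config(10, 10, panel_spec = c(a = 0.5, a = 0.2)),
               "panel_spec")
  expect_error(sim_config(10, 10, panel_spec = c(a = 1.5)), "panel_spec")
  expect_error(sim_config(10, 10, target_prevalence = 1.2),
               "target_prevalence")
})

test_that("simulated MAFs respect the configured maximum", {
  cfg <- sim_config(1000, 500, maf_max = 0.01, seed = 2)
  v <- simulate_variants(cfg)
  expect_equal(nrow(v), 500)
  expect_true(all(v$maf > 0 & v$maf <= 0.01))
  expect_true(all(v$truth >= 0 & v$truth <= 1))
})

test_that("degenerate category distribution flags every variant LOF", {
  cfg <- sim_config(100, 200, category_probs = c(1, 0, 0), seed = 3)
  v <- simulate_variants(cfg)
  expect_true(all(v$is_lof == 1L))
  expect_true(all(v$consequence %in%
    c("stop_gained", "frameshift_variant", "splice_acceptor_variant",
      "splice_donor_variant")))
})

test_that("empirical mean MAF matches the truncated log-uniform analytic mean", {
  cfg <- sim_config(10000, 10000, seed = 4)
  v <- simulate_variants(cfg)
  a <- 1 / (2 * cfg$n_individuals); b <- cfg$maf_max
  analytic_mean <- (b - a) / log(b / a)
  analytic_var <- (b^2 - a^2) / (2 * log(b / a)) - analytic_mean^2
  mc_se <- sqrt(analytic_var / nrow(v))
  expect_lt(abs(mean(v$maf) - analytic_mean), 3 * mc_se)
})

test_that("panel informativeness controls rank correlation with the truth", {
  cfg <- sim_config(1000, 10000, seed = 5,
                    category_probs = c(0, 1, 0),  # all protein-altering
                    panel_spec = c(perfect = 1, pure_noise = 0))
  v <- simulate_variants(cfg)
  v <- simulate_predictor_panel(v, cfg$panel_spec, cfg$seed)
  expect_equal(cor(v$perfect, v$truth, method = "spearman"), 1)
  expect_lt(abs(cor(v$pure_noise, v$truth, method = "spearman")), 0.05)
})

test_that("scores attach only to protein-altering variants by default", {
  cfg <- sim_config(500, 400, seed = 6)
  v <- simulate_variants(cfg)
  v <- simulate_predictor_panel(v, c(p = 0.5), cfg$seed)
  expect_true(all(is.na(v$p[v$is_protein_altering == 0L])))
  expect_true(all(!is.na(v$p[v$is_protein_altering == 1L])))
  v2 <- simulate_predictor_panel(simulate_variants(cfg), c(p = 0.5),
                                 cfg$seed, attach_to = "all")
  expect_true(all(!is.na(v2$p)))
})

test_that("panel generation is deterministic given the seed stream", {
  cfg <- sim_config(100, 300, seed = 8)
  v <- simulate_variants(cfg)
  a <- simulate_predictor_panel(v, c(first = 0.4), seed = 8)
  b <- simulate_predictor_panel(v, c(renamed = 0.4), seed = 8)
  expect_identical(a$first, b$renamed)
  expect_error(simulate_predictor_panel(v, c(x = 0.1, x = 0.2), 1),
               "duplicate")
})

test_that("genotypes are Binomial(2, MAF) with the right frequencies", {
  v <- data.frame(variant_id = c("1:1:A:T", "1:2:C:G"),
                  maf = c(0.005, 0))
  g <- simulate_genotypes(v, 20000, seed = 9)
  expect_true(all(g[, 2] == 0))                       # MAF 0 column
  af <- mean(g[, 1]) / 2
  se <- sqrt(0.005 * 0.995 / (2 * 20000))
  expect_lt(abs(af - 0.005), 4 * se)
  expect_identical(g, simulate_genotypes(v, 20000, seed = 9))
})

test_that("null phenotype prevalence is calibrated to the target", {
  for (n in c(2000, 20000)) {
    cfg <- sim_config(n, 50, effect_size = 0, target_prevalence = 0.2,
                      seed = 10)
    sim <- simulate_cohort(cfg)
    se <- sqrt(0.2 * 0.8 / n)
    expect_lt(abs(mean(sim$cohort$phenotype) - 0.2), 4 * se)
  }
})

test_that("a strong burden effect makes cases carry more true burden", {
  cfg <- sim_config(4000, 100, effect_size = 1, seed = 12)
  sim <- simulate_cohort(cfg)
  tb <- attr(sim$cohort, "true_burden")
  y <- sim$cohort$phenotype
  expect_gt(mean(tb[y == 1]), mean(tb[y == 0]))
})

test_that("unreachable target prevalence errors with attained bounds", {
  # a huge negative sex effect pins ~half the cohort near risk 0, so no
  # intercept can push the expected prevalence to 0.99
  cfg <- sim_config(200, 20, effect_size = 0, target_prevalence = 0.99,
                    covariate_effects = c(-200, rep(0, 20)), seed = 13)
  v <- simulate_variants(cfg)
  g <- simulate_genotypes(v, cfg$n_individuals, cfg$seed)
  expect_error(simulate_phenotype(g, v, cfg), "unreachable")
})

test_that("the full generator is bit-reproducible from the master seed", {
  cfg <- sim_config(300, 60, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$genotypes, b$genotypes)
  expect_equal(a$cohort, b$cohort)
})
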