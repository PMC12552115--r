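# Shared fixture builders and independent oracles for the test suite.

# small complete cohort for fast end-to-end checks
small_sim <- function(n_individuals = 500, n_variants = 40, seed = 7,
                      ...) {
  cfg <- sim_config(n_individuals = n_individuals, n_variants = n_variants,
                    seed = seed, ...)
  c(simulate_cohort(cfg), list(config = cfg))
}

# independent triple-loop burden oracle (deliberately naive)
burden_oracle <- function(genotypes, variants, score_name, config) {
  n <- nrow(genotypes)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(nrow(variants))) {
      g <- genotypes[i, j]
      if (is.na(g)) g <- 0
      s <- variants[[score_name]][j]
      if (is.na(s)) s <- 0
      w <- frequency_weight(variants$maf[j], config)
      acc <- acc + g * w * s
    }
    out[i] <- acc
  }
  out
}

# independent pairwise-complete correlation oracle
cor_oracle <- function(scores, method = "pearson") {
  k <- ncol(scores)
  m <- matrix(NA_real_, k, k, dimnames = list(colnames(scores),
                                              colnames(scores)))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    ok <- !is.na(scores[, a]) & !is.na(scores[, b])
    if (sum(ok) >= 3)
      m[a, b] <- cor(scores[ok, a], scores[ok, b], method = method)
  }
  diag(m) <- 1
  m
}

# cohort with externally fixed covariates and an independent Bernoulli
# phenotype (null model), for calibration-style tests
null_cohort <- function(n, prevalence = 0.2) {
  data.frame(individual_id = sprintf("I%06d", seq_len(n)),
             phenotype = rbinom(n, 1, prevalence),
             sex = rbinom(n, 1, 0.5),
             matrix(rnorm(n * 20), n, dimnames = list(NULL, paste0("PC", 1:20))),
             stringsAsFactors = FALSE)
}
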