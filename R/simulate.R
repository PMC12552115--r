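# Synthetic cohort generator: variants, predictor panels, genotypes,
# covariates and phenotypes with the statistical structure the burden
# analysis assumes, so the pipeline is testable without restricted data.
#
# All distributional choices are artifact decisions (the analysis itself was
# designed for real exome data); they are documented in the methods vignette.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort generator. One master
#' `seed` drives all components; per-component streams (variants, panel,
#' genotypes, covariates, phenotype) are derived deterministically from it
#' (`seed * 7 + k` modulo 2^31 - 1 for component index k), so identical
#' configurations yield bit-identical outputs and components can be
#' regenerated independently.
#'
#' @param n_individuals number of individuals.
#' @param n_variants total number of variants across genes.
#' @param n_genes number of genes; variants are split evenly.
#' @param maf_law distribution of minor allele frequencies: `"loguniform"`
#'   (default; log-uniform on `[1/(2 n_individuals), maf_max]`, mimicking a
#'   rare-variant site-frequency spectrum) or `"uniform"` on `(0, maf_max]`.
#' @param maf_max upper bound of simulated MAFs (default 0.01, the
#'   rare-variant threshold).
#' @param category_probs probabilities for (LOF, protein-altering, excluded)
#'   category assignment; must sum to 1. Default `c(0.1, 0.6, 0.3)`.
#' @param panel_spec named numeric vector: one predictor per entry, value the
#'   informativeness `lambda` in [0, 1] (rank correlation strength between
#'   the score and the latent true pathogenicity).
#' @param effect_size log-odds of case status per unit of frequency-weighted
#'   true-pathogenicity burden (default 0.3).
#' @param target_prevalence desired expected case proportion (default 0.2).
#' @param covariate_effects log-odds for sex and each PC; a single 0 recycles
#'   to all 21 covariates.
#' @param weight_config [weight_config()] used for the true burden entering
#'   the phenotype model.
#' @param seed master integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals, n_variants, n_genes = 1L,
                       maf_law = c("loguniform", "uniform"), maf_max = 0.01,
                       category_probs = c(lof = 0.1, protein_altering = 0.6,
                                          excluded = 0.3),
                       panel_spec = c(informative = 0.9, weak = 0.3,
                                      noise = 0),
                       effect_size = 0.3, target_prevalence = 0.2,
                       covariate_effects = 0,
                       weight_config = slpburden::weight_config(),
                       seed = 1L) {
  maf_law <- match.arg(maf_law)
  if (!(is.numeric(n_individuals) && length(n_individuals) == 1L &&
        n_individuals >= 1))
    stop("invalid configuration field: n_individuals")
  if (!(is.numeric(n_variants) && length(n_variants) == 1L && n_variants >= 1))
    stop("invalid configuration field: n_variants")
  if (!(is.numeric(maf_max) && length(maf_max) == 1L && maf_max > 0 &&
        maf_max <= 0.5))
    stop("invalid configuration field: maf_max")
  if (length(category_probs) != 3L || any(category_probs < 0) ||
      abs(sum(category_probs) - 1) > 1e-12)
    stop("invalid configuration field: category_probs (must sum to 1)")
  if (is.null(names(panel_spec)) || anyDuplicated(names(panel_spec)))
    stop("invalid configuration field: panel_spec ",
         "(predictor names must be unique)")
  if (any(panel_spec < 0 | panel_spec > 1))
    stop("invalid configuration field: panel_spec (lambda must be in [0,1])")
  if (!(target_prevalence > 0 && target_prevalence < 1))
    stop("invalid configuration field: target_prevalence")
  if (!length(covariate_effects) %in% c(1L, 21L))
    stop("invalid configuration field: covariate_effects ",
         "(length 1 or 21: sex then 20 PCs)")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants), n_genes = as.integer(n_genes),
    maf_law = maf_law, maf_max = maf_max,
    category_probs = category_probs, panel_spec = panel_spec,
    effect_size = effect_size, target_prevalence = target_prevalence,
    covariate_effects = rep_len(covariate_effects, 21L),
    weight_config = weight_config, seed = as.integer(seed)),
    class = "sim_config")
}

# deterministic per-component substream seeds: variants=1, panel=2,
# genotypes=3, covariates=4, phenotype=5
.component_seed <- function(seed, component) {
  k <- c(variants = 1, panel = 2, genotypes = 3, covariates = 4,
         phenotype = 5)[[component]]
  as.integer((as.numeric(seed) * 7 + k) %% (2^31 - 1))
}

#' Simulate an annotated variant table
#'
#' Draws `n_variants` rare variants: MAF from the configured law truncated at
#' `maf_max`, a consequence term implying exactly one of the LOF /
#' protein-altering / excluded categories, a gene assignment, and a latent
#' true pathogenicity in [0, 1] (Uniform) that downstream predictor scores
#' and the phenotype model are built from.
#'
#' @param config a [sim_config()].
#' @return data.frame of variant records: `variant_id` (chrom:pos:ref:alt,
#'   1-based), `gene`, `consequence`, `maf`, `is_lof`,
#'   `is_protein_altering`, `truth`.
#' @export
simulate_variants <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_variants
  set.seed(.component_seed(config$seed, "variants"))
  maf <- switch(config$maf_law,
    loguniform = {
      # lower bound: the minimum observable allele frequency, clamped so
      # tiny test cohorts (2n < 1/maf_max) stay inside (0, maf_max]
      a <- min(1 / (2 * config$n_individuals), config$maf_max)
      exp(stats::runif(n, log(a), log(config$maf_max)))
    },
    uniform = stats::runif(n, 0, config$maf_max))
  maf <- pmin(maf, config$maf_max)
  cat_idx <- sample.int(3L, n, replace = TRUE, prob = config$category_probs)
  consequence <- character(n)
  consequence[cat_idx == 1L] <- sample(.lof_terms, sum(cat_idx == 1L),
                                       replace = TRUE)
  consequence[cat_idx == 2L] <- sample(.pa_terms, sum(cat_idx == 2L),
                                       replace = TRUE,
                                       prob = c(0.05, 0.85, 0.05, 0.05))
  consequence[cat_idx == 3L] <- "synonymous_variant"
  gene <- sprintf("G%03d", 1L + (seq_len(n) - 1L) %% config$n_genes)
  pos <- sort(sample.int(5e7, n))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  flags <- assign_categories(consequence)
  data.frame(
    variant_id = sprintf("1:%d:%s:%s", pos, ref, alt),
    gene = gene, consequence = consequence, maf = maf,
    is_lof = flags$is_lof, is_protein_altering = flags$is_protein_altering,
    truth = stats::runif(n), stringsAsFactors = FALSE)
}

#' Attach a panel of synthetic predictor scores
#'
#' For each panel entry `(name, lambda)` the score is the quantile rank (in
#' (0, 1]) of `lambda * truth + (1 - lambda) * noise` with independent
#' Uniform(0,1) noise: `lambda = 1` reproduces the truth ordering exactly,
#' `lambda = 0` is pure noise. By default scores are attached only to
#' protein-altering variants (mirroring missense-specific predictors; LOF
#' and excluded variants get `NA`).
#'
#' @param variants variant table from [simulate_variants()] (needs `truth`).
#' @param panel_spec named numeric vector of informativeness values in [0,1].
#' @param seed integer seed for the panel noise stream.
#' @param attach_to which variants receive scores: `"protein_altering"`
#'   (default), `"coding"` (LOF and protein-altering) or `"all"`.
#' @return `variants` with one additional score column per panel entry.
#' @export
simulate_predictor_panel <- function(variants, panel_spec, seed,
                                     attach_to = c("protein_altering",
                                                   "coding", "all")) {
  attach_to <- match.arg(attach_to)
  stopifnot(is.data.frame(variants), "truth" %in% names(variants))
  if (is.null(names(panel_spec)) || anyDuplicated(names(panel_spec)))
    stop("duplicate or missing predictor names in panel_spec")
  keep <- switch(attach_to,
    protein_altering = variants$is_protein_altering == 1L,
    coding = variants$is_lof == 1L | variants$is_protein_altering == 1L,
    all = rep(TRUE, nrow(variants)))
  for (i in seq_along(panel_spec)) {
    lambda <- panel_spec[[i]]
    set.seed(.component_seed(seed, "panel") + i)
    noise <- stats::runif(nrow(variants))
    raw <- lambda * variants$truth + (1 - lambda) * noise
    col <- rep(NA_real_, nrow(variants))
    if (any(keep)) col[keep] <- rank_transform(raw[keep])
    variants[[names(panel_spec)[i]]] <- col
  }
  variants
}

#' Simulate a genotype dosage matrix
#'
#' Each entry is an independent Binomial(2, MAF_j) ALT-allele count:
#' Hardy-Weinberg genotypes at linkage equilibrium, with no missingness.
#'
#' @param variants variant table with `maf` (and `variant_id` for column
#'   names).
#' @param n_individuals number of rows.
#' @param seed integer seed for the genotype stream.
#' @return integer matrix, individuals x variants, entries in \{0, 1, 2\},
#'   with individual ids `I000001, ...` as rownames.
#' @export
simulate_genotypes <- function(variants, n_individuals, seed) {
  stopifnot(is.data.frame(variants), "maf" %in% names(variants),
            n_individuals >= 1)
  set.seed(.component_seed(seed, "genotypes"))
  n <- as.integer(n_individuals); m <- nrow(variants)
  g <- matrix(stats::rbinom(n * m, 2L, rep(variants$maf, each = n)),
              nrow = n, ncol = m)
  rownames(g) <- sprintf("I%06d", seq_len(n))
  colnames(g) <- if ("variant_id" %in% names(variants))
    variants$variant_id else sprintf("V%06d", seq_len(m))
  g
}

#' Simulate covariates and a binary phenotype under a logistic burden model
#'
#' Covariates are sex ~ Bernoulli(0.5) and 20 standard-normal principal
#' components. The linear predictor is
#' `alpha + effect_size * true_burden + covariate effects`, where
#' `true_burden` is the frequency-weighted burden of the latent true
#' pathogenicity over the individual's LOF and protein-altering variants
#' (same weighting rules as the analysis). The intercept `alpha` is found by
#' root-finding so that the expected prevalence over the simulated cohort
#' equals `target_prevalence` to within 1e-6; the phenotype is then drawn
#' Bernoulli(logistic(linear predictor)).
#'
#' @param genotypes matrix from [simulate_genotypes()].
#' @param variants variant table with `truth`, `maf` and category flags.
#' @param config a [sim_config()].
#' @return cohort data.frame: `individual_id`, `phenotype` (0/1), `sex`
#'   (0/1), `PC1` ... `PC20`; attribute `"true_burden"` holds the latent
#'   burden vector and `"alpha"` the calibrated intercept.
#' @export
simulate_phenotype <- function(genotypes, variants, config) {
  stopifnot(inherits(config, "sim_config"), is.matrix(genotypes),
            all(c("truth", "maf") %in% names(variants)))
  n <- nrow(genotypes)
  set.seed(.component_seed(config$seed, "covariates"))
  sex <- stats::rbinom(n, 1L, 0.5)
  pcs <- matrix(stats::rnorm(n * 20L), nrow = n,
                dimnames = list(NULL, paste0("PC", 1:20)))

  qualifying <- variants$is_lof == 1L | variants$is_protein_altering == 1L
  v <- variants[qualifying, , drop = FALSE]
  g <- genotypes[, qualifying, drop = FALSE]
  true_burden <- if (ncol(g))
    as.numeric(individual_burden(g, v, "truth", config$weight_config))
  else rep(0, n)

  ce <- config$covariate_effects
  eta0 <- config$effect_size * true_burden + ce[1L] * sex +
    as.numeric(pcs %*% ce[-1L])
  f <- function(alpha) mean(stats::plogis(alpha + eta0)) -
    config$target_prevalence
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf(
      "target prevalence %.4g unreachable: attainable range [%.4g, %.4g]",
      config$target_prevalence, config$target_prevalence + f(lo),
      config$target_prevalence + f(hi)))
  alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-9)$root

  set.seed(.component_seed(config$seed, "phenotype"))
  phenotype <- stats::rbinom(n, 1L, stats::plogis(alpha + eta0))
  out <- data.frame(individual_id = rownames(genotypes),
                    phenotype = phenotype, sex = sex,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pcs))
  attr(out, "true_burden") <- true_burden
  attr(out, "alpha") <- alpha
  out
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running all four generator stages with streams derived
#' from the master seed.
#'
#' @param config a [sim_config()].
#' @return list with `variants` (scores attached), `genotypes` and `cohort`.
#' @export
simulate_cohort <- function(config) {
  variants <- simulate_variants(config)
  variants <- simulate_predictor_panel(variants, config$panel_spec,
                                       config$seed)
  genotypes <- simulate_genotypes(variants, config$n_individuals,
                                  config$seed)
  cohort <- simulate_phenotype(genotypes, variants, config)
  list(variants = variants, genotypes = genotypes, cohort = cohort)
}
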