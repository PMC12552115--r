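# Allele-frequency weights and per-individual weighted burden scores.

#' Weight configuration for frequency-based variant weighting
#'
#' Rarer variants receive higher weights. The default curve interpolates
#' linearly from `w_max` at MAF = 0 down to 1 at MAF = `f_max` (the rare
#' variant threshold). Alternative curves: `"step"` gives `w_max` for
#' MAF <= `f_max`/10 and 1 above; `"logistic"` is a smooth sigmoid in
#' log10(MAF) centred at `f_max`/10.
#'
#' @param w_max maximum weight, attained at MAF = 0 (default 10, must be >= 1).
#' @param f_max frequency at which the weight reaches 1 (default 0.01); also
#'   the largest admissible MAF.
#' @param form one of `"linear"`, `"step"`, `"logistic"`.
#' @return An object of class `weight_config`.
#' @export
weight_config <- function(w_max = 10, f_max = 0.01,
                          form = c("linear", "step", "logistic")) {
  form <- match.arg(form)
  stopifnot(is.numeric(w_max), length(w_max) == 1L, w_max >= 1,
            is.numeric(f_max), length(f_max) == 1L, f_max > 0, f_max <= 0.5)
  structure(list(w_max = w_max, f_max = f_max, form = form),
            class = "weight_config")
}

#' @export
print.weight_config <- function(x, ...) {
  cat(sprintf("Frequency weight: %s, w_max = %g, f_max = %g\n",
              x$form, x$w_max, x$f_max))
  invisible(x)
}

#' Allele-frequency weight for a rare variant
#'
#' @param maf numeric vector of minor allele frequencies in `[0, f_max]`.
#'   A MAF above `f_max` is an error (such variants should already have been
#'   removed by [filter_rare()]).
#' @param config a [weight_config()].
#' @return weights in `[1, w_max]`, non-increasing in `maf`.
#' @examples
#' frequency_weight(c(0, 0.005, 0.01), weight_config())  # 10, 5.5, 1
#' @export
frequency_weight <- function(maf, config = weight_config()) {
  stopifnot(inherits(config, "weight_config"), is.numeric(maf))
  if (any(is.na(maf))) stop("missing maf")
  if (any(maf < 0)) stop("negative maf")
  if (any(maf > config$f_max))
    stop(sprintf("maf above f_max = %g: should have been filtered out",
                 config$f_max))
  switch(config$form,
    linear = 1 + (config$w_max - 1) * (1 - maf / config$f_max),
    step = ifelse(maf <= config$f_max / 10, config$w_max, 1),
    logistic = {
      # sigmoid in log10(maf), centred one decade below f_max; maf = 0 is
      # mapped to the asymptote w_max
      centre <- log10(config$f_max / 10)
      s <- ifelse(maf == 0, config$w_max,
                  1 + (config$w_max - 1) / (1 + exp(4 * (log10(maf) - centre))))
      s
    })
}

.check_geno_variants <- function(genotypes, variants) {
  stopifnot(is.matrix(genotypes), is.data.frame(variants))
  if (ncol(genotypes) != nrow(variants))
    stop(sprintf("dimension mismatch: %d genotype columns vs %d variants",
                 ncol(genotypes), nrow(variants)))
  if (!is.null(colnames(genotypes)) && "variant_id" %in% names(variants) &&
      !identical(colnames(genotypes), as.character(variants$variant_id)))
    stop("genotype column names do not match variant_id order")
}

#' Per-individual weighted burden for one score
#'
#' Computes, for every individual, the gene burden
#' `sum_j dosage_ij * w(maf_j) * score_j` over the variants of one gene,
#' where `dosage` is the ALT allele count (0/1/2), `w` the frequency weight
#' and `score_j` the named per-variant score. A variant lacking the score
#' contributes 0; missing genotypes are treated as homozygous reference
#' (dosage 0) and tallied in the `"n_missing_genotypes"` attribute.
#'
#' @param genotypes integer matrix, individuals x variants, entries 0/1/2 or
#'   `NA`.
#' @param variants data.frame of the same gene's variants (already
#'   MAF-filtered), with columns `maf` and `score_name`.
#' @param score_name column of `variants` holding the per-variant score; may
#'   be a predictor score column or a category indicator (`is_lof`,
#'   `is_protein_altering`).
#' @param config a [weight_config()].
#' @return numeric vector of burdens, one per row of `genotypes`, named by
#'   rownames; attributes `"n_missing_genotypes"` and `"n_missing_scores"`.
#' @export
individual_burden <- function(genotypes, variants, score_name,
                              config = weight_config()) {
  .check_geno_variants(genotypes, variants)
  if (!score_name %in% names(variants))
    stop("unknown score column: ", score_name)
  score <- as.numeric(variants[[score_name]])
  n_missing_scores <- sum(is.na(score))
  score[is.na(score)] <- 0
  w <- frequency_weight(variants$maf, config)
  g <- genotypes
  n_missing_geno <- sum(is.na(g))
  g[is.na(g)] <- 0L
  burden <- as.numeric(g %*% (w * score))
  names(burden) <- rownames(genotypes)
  attr(burden, "n_missing_genotypes") <- n_missing_geno
  attr(burden, "n_missing_scores") <- n_missing_scores
  burden
}

#' Per-individual burden profiles for one gene
#'
#' Computes, for each individual, the LOF burden (per-variant score =
#' `is_lof`), the protein-altering burden (score = `is_protein_altering`) and
#' one burden per requested predictor, all weighted by allele frequency.
#'
#' @inheritParams individual_burden
#' @param predictor_names character vector of predictor score columns in
#'   `variants`.
#' @return data.frame with columns `individual_id`, `lof_burden`,
#'   `protein_altering_burden`, then one column per predictor; attribute
#'   `"weight_config"` records the weighting used.
#' @export
gene_profiles <- function(genotypes, variants, predictor_names = character(),
                          config = weight_config()) {
  .check_geno_variants(genotypes, variants)
  stopifnot(all(c("is_lof", "is_protein_altering", "maf") %in% names(variants)))
  unknown <- setdiff(predictor_names, names(variants))
  if (length(unknown))
    stop("unknown predictor name(s): ", paste(unknown, collapse = ", "))
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("I%06d", seq_len(nrow(genotypes)))
  out <- data.frame(
    individual_id = ids,
    lof_burden = as.numeric(
      individual_burden(genotypes, variants, "is_lof", config)),
    protein_altering_burden = as.numeric(
      individual_burden(genotypes, variants, "is_protein_altering", config)),
    stringsAsFactors = FALSE)
  for (p in predictor_names)
    out[[p]] <- as.numeric(individual_burden(genotypes, variants, p, config))
  attr(out, "weight_config") <- config
  out
}
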