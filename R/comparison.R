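# Multi-gene, multi-predictor comparison: protective-gene flip, SLP matrix
# with per-predictor means, relative SLP scaling, score correlation matrix.

#' Gene-phenotype pair descriptor
#'
#' Describes one gene-phenotype analysis unit and whether damaging rare
#' variants in the gene associate with case or with control status. For
#' protective genes (direction `"control"`), the analysis phenotype is
#' recoded as "being a control" so that damaging burden associates
#' positively, making SLPs comparable across genes.
#'
#' @param gene gene symbol.
#' @param phenotype_name label of the clinical phenotype.
#' @param direction `"case"` or `"control"`.
#' @return An object of class `gene_phenotype_pair`.
#' @export
gene_phenotype_pair <- function(gene, phenotype_name = NA_character_,
                                direction = c("case", "control")) {
  direction <- match.arg(direction)
  structure(list(gene = gene, phenotype_name = phenotype_name,
                 direction = direction), class = "gene_phenotype_pair")
}

#' Recode the phenotype of a protective gene
#'
#' For a pair with direction `"control"` the binary outcome is complemented
#' (cases become controls and vice versa); for direction `"case"` the cohort
#' is returned unchanged. Applying the flip twice restores the original
#' outcome.
#'
#' @param cohort cohort data.frame with a 0/1 `phenotype` column.
#' @param pair a [gene_phenotype_pair()].
#' @return The cohort, with `phenotype` complemented if the pair is
#'   protective.
#' @export
flip_protective <- function(cohort, pair) {
  stopifnot(is.data.frame(cohort), "phenotype" %in% names(cohort),
            inherits(pair, "gene_phenotype_pair"))
  if (pair$direction == "control")
    cohort$phenotype <- 1L - cohort$phenotype
  cohort
}

#' Run the full predictor-by-gene SLP comparison
#'
#' For every gene dataset, applies the protective-gene flip and computes one
#' SLP per predictor, assembling the predictor x gene SLP matrix and the
#' per-predictor mean SLP across genes — the primary benchmarking summary.
#'
#' @param gene_datasets list; each element a list with components `pair`
#'   (a [gene_phenotype_pair()]), `profiles` (from [gene_profiles()]) and
#'   `cohort`.
#' @param predictor_names predictors to test; must be burden columns in every
#'   `profiles` table.
#' @param sort_rows order rows by descending mean SLP (default `TRUE`).
#' @param ... passed to [predictor_slp()].
#' @return An object of class `slp_comparison`: list with `slp` (matrix,
#'   predictors x genes), `mean_slp` (named per-predictor means), `details`
#'   (long data.frame of all fits), `failed` (gene labels whose association
#'   errored; their columns are `NA`, not dropped).
#' @export
run_comparison <- function(gene_datasets, predictor_names,
                           sort_rows = TRUE, ...) {
  stopifnot(is.list(gene_datasets), length(gene_datasets) > 0,
            length(predictor_names) > 0)
  genes <- vapply(gene_datasets, function(d) d$pair$gene, character(1))
  slp <- matrix(NA_real_, nrow = length(predictor_names),
                ncol = length(genes),
                dimnames = list(predictor_names, genes))
  details <- list(); failed <- character()
  for (j in seq_along(gene_datasets)) {
    d <- gene_datasets[[j]]
    coh <- flip_protective(d$cohort, d$pair)
    for (p in predictor_names) {
      fit <- tryCatch(
        predictor_slp(d$profiles, coh, p, gene = d$pair$gene, ...),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failed <- union(failed, genes[j])
        warning(sprintf("association failed for gene %s, predictor %s: %s",
                        genes[j], p, conditionMessage(fit)))
        next
      }
      slp[p, j] <- fit$slp
      details[[length(details) + 1L]] <- as.data.frame(fit)
    }
  }
  mean_slp <- rowMeans(slp)
  if (sort_rows) {
    o <- order(mean_slp, decreasing = TRUE)
    slp <- slp[o, , drop = FALSE]
    mean_slp <- mean_slp[o]
  }
  structure(list(slp = slp, mean_slp = mean_slp,
                 details = do.call(rbind, details), failed = failed),
            class = "slp_comparison")
}

#' @export
print.slp_comparison <- function(x, digits = 2, ...) {
  cat(sprintf("SLP comparison: %d predictors x %d genes\n",
              nrow(x$slp), ncol(x$slp)))
  m <- cbind(x$slp, mean_SLP = x$mean_slp)
  print(round(m, digits))
  if (length(x$failed))
    cat("Failed genes (columns NA):", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.slp_comparison <- function(object, ...) {
  cat("Per-predictor mean SLP (descending):\n")
  print(round(sort(object$mean_slp, decreasing = TRUE), 3))
  invisible(object)
}

#' @export
as.data.frame.slp_comparison <- function(x, ...) {
  df <- as.data.frame(x$slp)
  df <- cbind(predictor = rownames(x$slp), df, mean_slp = x$mean_slp)
  rownames(df) <- NULL
  df
}

#' Dot-heatmap of relative SLPs
#'
#' Plots one dot per predictor x gene cell, with area proportional to the
#' cell's SLP relative to the best SLP attained for that gene; open (white)
#' circles mark negative SLPs.
#'
#' @param x an `slp_comparison`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.slp_comparison <- function(x, ...) {
  rel <- relative_slp(x)
  m <- rel$relative
  nr <- nrow(m); nc <- ncol(m)
  op <- graphics::par(mar = c(6, 10, 2, 1)); on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0.5, nc + 0.5), ylim = c(0.5, nr + 0.5),
                 xaxt = "n", yaxt = "n", xlab = "", ylab = "",
                 main = "Relative SLP by gene", ...)
  graphics::axis(1, at = seq_len(nc), labels = colnames(m), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(nr), labels = rev(rownames(m)), las = 1,
                 cex.axis = 0.8)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- m[i, j]
    if (is.na(v)) next
    r <- 0.45 * sqrt(abs(v))
    if (r == 0) next
    graphics::symbols(j, nr - i + 1, circles = r, inches = FALSE,
                      add = TRUE, bg = if (rel$negative[i, j]) "white" else "black")
  }
  invisible(x)
}

#' Predictor-score correlation matrix
#'
#' Pairwise correlations between predictor score columns across variants,
#' restricted by default to missense variants (the consequence on which all
#' predictors in a typical panel are defined). Pairs are computed over
#' variants where both scores are present (pairwise-complete); a pair with
#' fewer than 3 complete observations is reported as `NA`.
#'
#' @param variants variant table with a `consequence` column and one column
#'   per predictor.
#' @param predictor_names score columns to correlate.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param consequence restrict to variants whose consequence matches
#'   (default `"missense_variant"`); `NULL` uses all variants.
#' @return symmetric correlation matrix with unit diagonal; attributes
#'   `"method"`, `"n_variants"` and `"n_pairs"` (matrix of complete-pair
#'   counts).
#' @export
score_correlation_matrix <- function(variants, predictor_names,
                                     method = c("pearson", "spearman"),
                                     consequence = "missense_variant") {
  method <- match.arg(method)
  stopifnot(is.data.frame(variants), length(predictor_names) >= 2,
            all(predictor_names %in% names(variants)))
  if (!is.null(consequence)) {
    stopifnot("consequence" %in% names(variants))
    keep <- .canonical_consequence(variants$consequence) %in%
      .canonical_consequence(consequence)
    variants <- variants[keep, , drop = FALSE]
  }
  if (nrow(variants) < 2) stop("fewer than 2 variants after restriction")
  s <- as.matrix(variants[, predictor_names, drop = FALSE])
  storage.mode(s) <- "double"
  k <- length(predictor_names)
  cm <- suppressWarnings(
    stats::cor(s, use = "pairwise.complete.obs", method = method))
  present <- !is.na(s)
  n_pairs <- crossprod(present)
  cm[n_pairs < 3] <- NA_real_
  diag(cm) <- 1
  cm <- (cm + t(cm)) / 2   # enforce exact symmetry against float asymmetry
  attr(cm, "method") <- method
  attr(cm, "n_variants") <- nrow(variants)
  attr(cm, "n_pairs") <- n_pairs
  cm
}

#' Per-gene relative SLP scaling
#'
#' Scales each gene's column of the SLP matrix by the largest positive SLP
#' any predictor attained for that gene, so the best predictor maps to
#' exactly 1 and every cell lies in [-1, 1]. Negative SLPs keep their ratio
#' and are flagged. A gene whose column has no positive SLP is emitted as
#' all-`NA` and flagged.
#'
#' @param matrix an `slp_comparison` object or a plain numeric SLP matrix
#'   (predictors x genes).
#' @return list with `relative` (matrix in [-1, 1]), `negative` (logical
#'   matrix flagging negative SLPs) and `no_positive` (gene names with no
#'   positive SLP).
#' @export
relative_slp <- function(matrix) {
  m <- if (inherits(matrix, "slp_comparison")) matrix$slp else matrix
  stopifnot(is.matrix(m), is.numeric(m))
  col_max <- apply(m, 2, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v)) max(v) else NA_real_
  })
  no_positive <- colnames(m)[is.na(col_max)]
  rel <- sweep(m, 2, col_max, `/`)
  rel[, is.na(col_max)] <- NA_real_
  list(relative = rel, negative = !is.na(m) & m < 0,
       no_positive = no_positive %||% character())
}
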