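# Bundled reference results: the published SLP matrix for 11 predictors
# across 18 gene-phenotype pairs, used as the worked example for the
# comparison summaries.

#' Published reference SLP table
#'
#' Returns the bundled matrix of signed log10 p-values reported for 11
#' pathogenicity predictors (a DNA language model, AlphaMissense score and
#' category, and dbNSFP rank scores) across 18 gene-phenotype pairs from a
#' large biobank exome weighted-burden study, together with each row's
#' printed average. Recomputing the row means from the per-gene SLPs and
#' checking them against the printed averages is the package's worked
#' example of the [run_comparison()] mean-SLP summary.
#'
#' @return list with `slp` (numeric matrix, 11 predictors x 18 genes),
#'   `printed_average` (named numeric vector of the averages as printed) and
#'   `pairs` (list of [gene_phenotype_pair()] descriptors).
#' @examples
#' ref <- slp_reference()
#' rowMeans(ref$slp)["GPN-MSA"]  # reproduces the printed 2.05
#' @export
slp_reference <- function() {
  tab <- .read_tsv(system.file("extdata", "gene_slp_reference.tsv",
                               package = "slpburden", mustWork = TRUE))
  pred <- tab$predictor
  avg <- tab$printed_average
  m <- as.matrix(tab[, setdiff(names(tab), c("predictor", "printed_average")),
                     drop = FALSE])
  rownames(m) <- pred
  pairs <- read_pairs_tsv(system.file("extdata", "gene_phenotype_pairs.tsv",
                                      package = "slpburden", mustWork = TRUE))
  list(slp = m, printed_average = stats::setNames(avg, pred), pairs = pairs)
}
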