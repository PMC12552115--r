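# Consequence-category assignment, predictor-score transforms and the
# rare-variant MAF filter.

# Canonical Sequence Ontology terms per category, plus plain-text synonyms
# seen in the literature ("essential splice site" covers both splice
# acceptor and donor sites).
.lof_terms <- c("stop_gained", "frameshift_variant",
                "splice_acceptor_variant", "splice_donor_variant")
.pa_terms  <- c("protein_altering_variant", "missense_variant",
                "start_lost", "stop_lost")

.consequence_synonyms <- c(
  "stop gained"            = "stop_gained",
  "frameshift"             = "frameshift_variant",
  "essential splice site"  = "splice_acceptor_variant",
  "splice acceptor"        = "splice_acceptor_variant",
  "splice donor"           = "splice_donor_variant",
  "protein altering"       = "protein_altering_variant",
  "missense"               = "missense_variant",
  "start lost"             = "start_lost",
  "stop lost"              = "stop_lost",
  "synonymous"             = "synonymous_variant"
)

.canonical_consequence <- function(term) {
  term <- trimws(term)
  hit <- .consequence_synonyms[tolower(term)]
  ifelse(is.na(hit), term, unname(hit))
}

#' Assign loss-of-function / protein-altering category flags
#'
#' Classifies consequence terms into the two variant categories used by the
#' weighted burden analysis: loss of function (stop gained, frameshift,
#' essential splice site) and protein altering (protein altering, missense,
#' start lost, stop lost). Any other recognized term is excluded from the
#' analysis and receives `(0, 0)`. The categories are mutually exclusive.
#'
#' A variant annotated with several terms (e.g. one per transcript, separated
#' by `"&"` or `","`) is assigned its most severe category under the ordering
#' LOF > protein-altering > excluded.
#'
#' @param consequence character vector of consequence terms. Both Sequence
#'   Ontology strings (`"stop_gained"`) and plain-text names
#'   (`"essential splice site"`) are accepted.
#' @return A data.frame with integer columns `is_lof` and
#'   `is_protein_altering` (each 0/1, never both 1), one row per input, and
#'   an attribute `"unrecognized"` counting terms that were not recognized
#'   (these trigger a warning and are excluded).
#' @examples
#' assign_categories(c("stop_gained", "missense_variant", "synonymous_variant"))
#' @export
assign_categories <- function(consequence) {
  stopifnot(is.character(consequence))
  known <- c(.lof_terms, .pa_terms,
             "synonymous_variant", "intron_variant", "intergenic_variant",
             "5_prime_UTR_variant", "3_prime_UTR_variant",
             "upstream_gene_variant", "downstream_gene_variant",
             "splice_region_variant", "stop_retained_variant",
             "non_coding_transcript_exon_variant", "inframe_insertion",
             "inframe_deletion", "coding_sequence_variant")
  n_unrec <- 0L
  one <- function(terms) {
    terms <- .canonical_consequence(terms)
    unrec <- setdiff(terms, known)
    if (length(unrec)) n_unrec <<- n_unrec + length(unrec)
    if (any(terms %in% .lof_terms)) c(1L, 0L)
    else if (any(terms %in% .pa_terms)) c(0L, 1L)
    else c(0L, 0L)
  }
  parts <- strsplit(consequence, "[&,;]")
  flags <- vapply(parts, one, integer(2))
  if (n_unrec > 0)
    warning(sprintf("%d unrecognized consequence term(s); excluded", n_unrec))
  out <- data.frame(is_lof = flags[1L, ], is_protein_altering = flags[2L, ])
  attr(out, "unrecognized") <- n_unrec
  out
}

#' Orient a DNA language-model log-likelihood-ratio score
#'
#' DNA language-model deleteriousness scores of the GPN-MSA family are
#' distributed as the log likelihood ratio of the ALT versus the REF allele,
#' so low values indicate unlikely (deleterious) ALT alleles. This multiplies
#' the score by -1 so that, like every other predictor in the panel, a high
#' score indicates higher predicted pathogenicity.
#'
#' @param raw_score numeric vector of log-likelihood-ratio scores. `NA` is
#'   passed through (score absent); non-finite non-missing values are an
#'   error.
#' @return `-raw_score`.
#' @examples
#' transform_gpn_msa(-2.7)  # 2.7
#' @export
transform_gpn_msa <- function(raw_score) {
  stopifnot(is.numeric(raw_score))
  bad <- !is.na(raw_score) & !is.finite(raw_score)
  if (any(bad))
    stop("non-finite score(s) at position(s): ",
         paste(which(bad), collapse = ", "))
  -raw_score
}

#' Code AlphaMissense class labels as numeric scores
#'
#' Maps the three AlphaMissense classification labels to the numeric
#' prediction score used in burden aggregation: `likely_pathogenic` to 2,
#' `ambiguous` to 1, `likely_benign` to 0.
#'
#' @param label character vector of labels. `NA` passes through as `NA`.
#' @return integer vector of scores in \{0, 1, 2\}.
#' @examples
#' map_alphamissense_category(c("likely_pathogenic", "ambiguous", "likely_benign"))
#' @export
map_alphamissense_category <- function(label) {
  stopifnot(is.character(label) || all(is.na(label)))
  map <- c(likely_pathogenic = 2L, ambiguous = 1L, likely_benign = 0L)
  out <- map[label]
  bad <- is.na(out) & !is.na(label)
  if (any(bad))
    stop("unrecognized AlphaMissense label(s): ",
         paste(unique(label[bad]), collapse = ", "))
  unname(out)
}

#' Filter a variant table to rare variants
#'
#' Retains variants with minor allele frequency less than or equal to the
#' threshold (inclusive), preserving input order. The default threshold of
#' 0.01 is the conventional rare-variant cut-off for weighted burden tests.
#'
#' @param variants data.frame with a numeric `maf` column.
#' @param maf_threshold inclusive MAF cut-off (default 0.01).
#' @return The subset of rows with `maf <= maf_threshold`.
#' @examples
#' v <- data.frame(variant_id = c("a", "b", "c"), maf = c(0.005, 0.01, 0.02))
#' filter_rare(v)  # keeps a and b
#' @export
filter_rare <- function(variants, maf_threshold = 0.01) {
  stopifnot(is.data.frame(variants), "maf" %in% names(variants),
            is.numeric(maf_threshold), length(maf_threshold) == 1L,
            maf_threshold >= 0)
  miss <- is.na(variants$maf)
  if (any(miss)) {
    ids <- if ("variant_id" %in% names(variants))
      variants$variant_id[miss] else which(miss)
    stop("missing maf for variant(s): ", paste(ids, collapse = ", "))
  }
  variants[variants$maf <= maf_threshold, , drop = FALSE]
}

#' Quantile rank-transform of predictor scores
#'
#' Transforms scores to rank scores in (0, 1], the dbNSFP convention that
#' puts heterogeneous predictors on a common scale: each present value is
#' mapped to rank / (number present), with average ranks for ties. Missing
#' values stay missing.
#'
#' @param scores numeric vector, possibly with `NA`s.
#' @return numeric vector of the same length; present values in (0, 1].
#' @examples
#' rank_transform(c(3, 1, 2))  # 1, 1/3, 2/3
#' @export
rank_transform <- function(scores) {
  stopifnot(is.numeric(scores))
  n_present <- sum(!is.na(scores))
  if (n_present == 0L) stop("all scores are absent; nothing to rank")
  r <- rank(scores, ties.method = "average", na.last = "keep")
  r / n_present
}
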