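# Readers and writers for the pipeline's tabular formats, plus VCF genotype
# ingestion. All TSVs use "NA" as the sole absence token and carry an
# optional metadata header of "# key=value" comment lines.

.write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) {
    meta <- c(list(package = paste0("slpburden ",
                                    utils::packageVersion("slpburden"))),
              meta)
    for (k in names(meta))
      writeLines(sprintf("# %s=%s", k, paste(format(meta[[k]]),
                                             collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#", na.strings = "NA",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read and write the variant annotation table
#'
#' The annotation TSV has header columns `variant_id`, `gene`, `consequence`,
#' `maf`, then one column per predictor score; absences are encoded `NA`.
#' Category flag columns (`is_lof`, `is_protein_altering`) are written when
#' present and recomputed from `consequence` on read when absent.
#'
#' @param path file path.
#' @param variants variant data.frame.
#' @param meta optional named list written as `# key=value` header lines.
#' @return `read_variants_tsv`: the variant data.frame;
#'   `write_variants_tsv`: the path, invisibly.
#' @export
read_variants_tsv <- function(path) {
  v <- .read_tsv(path)
  need <- c("variant_id", "gene", "consequence", "maf")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop("variants TSV lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(c("is_lof", "is_protein_altering") %in% names(v))) {
    flags <- assign_categories(v$consequence)
    v$is_lof <- flags$is_lof
    v$is_protein_altering <- flags$is_protein_altering
  }
  v
}

#' @rdname read_variants_tsv
#' @export
write_variants_tsv <- function(variants, path, meta = NULL) {
  .write_tsv(variants, path, meta)
}

#' Read and write the cohort table
#'
#' Cohort TSV columns: `individual_id`, `phenotype` (0/1), `sex` (0/1),
#' `PC1` ... `PC20`.
#'
#' @param path file path.
#' @param cohort cohort data.frame.
#' @param meta optional metadata header list.
#' @export
read_cohort_tsv <- function(path) {
  coh <- .read_tsv(path)
  miss <- setdiff(c("individual_id", "phenotype", "sex"), names(coh))
  if (length(miss))
    stop("cohort TSV lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(coh$individual_id))
    stop("duplicate individual_ids in cohort TSV")
  if (!all(coh$phenotype %in% c(0, 1)))
    stop("phenotype must be 0/1")
  coh
}

#' @rdname read_cohort_tsv
#' @export
write_cohort_tsv <- function(cohort, path, meta = NULL) {
  .write_tsv(cohort, path, meta)
}

#' Read and write per-gene burden profile tables
#'
#' Burden profile TSV columns: `individual_id`, `lof_burden`,
#' `protein_altering_burden`, then one column per predictor.
#'
#' @param path file path.
#' @param profiles burden profile data.frame from [gene_profiles()].
#' @param meta optional metadata header list (the weight configuration is
#'   recorded automatically when present as an attribute).
#' @export
read_profiles_tsv <- function(path) {
  prof <- .read_tsv(path)
  miss <- setdiff(c("individual_id", "lof_burden", "protein_altering_burden"),
                  names(prof))
  if (length(miss))
    stop("profiles TSV lacks column(s): ", paste(miss, collapse = ", "))
  prof
}

#' @rdname read_profiles_tsv
#' @export
write_profiles_tsv <- function(profiles, path, meta = NULL) {
  wc <- attr(profiles, "weight_config")
  if (!is.null(wc))
    meta <- c(list(w_max = wc$w_max, f_max = wc$f_max,
                   weight_form = wc$form), meta)
  .write_tsv(profiles, path, meta)
}

#' Read a gene-phenotype pair list
#'
#' TSV with columns `gene`, `phenotype_name`, `direction` (case/control).
#'
#' @param path file path.
#' @return list of [gene_phenotype_pair()] objects.
#' @export
read_pairs_tsv <- function(path) {
  df <- .read_tsv(path)
  miss <- setdiff(c("gene", "direction"), names(df))
  if (length(miss))
    stop("pairs TSV lacks column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    gene_phenotype_pair(df$gene[i],
                        if ("phenotype_name" %in% names(df))
                          df$phenotype_name[i] else NA_character_,
                        df$direction[i]))
}

#' Read a genotype dosage matrix
#'
#' Two formats are supported. TSV: header row of variant_ids, first column
#' `individual_id`, cells the ALT allele count 0/1/2 or `NA`. VCF: genotypes
#' taken from the GT field (positions 1-based); multi-allelic records are
#' split into one bi-allelic row per ALT allele, with dosage the count of
#' that allele and variant_ids canonicalized as `chrom:pos:ref:alt`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`; default guessed from the extension.
#' @return integer matrix, individuals x variants, with dimnames.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  switch(format, tsv = .read_genotypes_tsv(path),
         vcf = .read_genotypes_vcf(path))
}

.read_genotypes_tsv <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "individual_id")
    stop("genotype TSV must start with an individual_id column")
  if (anyDuplicated(df$individual_id))
    stop("duplicate individual_ids in genotype TSV")
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  bad <- !is.na(g) & !(g %in% 0:2)
  if (any(bad)) {
    rows <- unique(which(bad, arr.ind = TRUE)[, 1])
    stop("genotype cells outside {0,1,2,NA} at data line(s): ",
         paste(utils::head(rows, 5), collapse = ", "))
  }
  rownames(g) <- df$individual_id
  g
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  if (anyDuplicated(samples)) stop("duplicate sample ids in VCF")
  cols <- list(); ids <- character()
  for (r in seq_len(nrow(gt))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    toks <- strsplit(gt[r, ], "[/|]")
    lens <- lengths(toks)
    malformed <- !is.na(gt[r, ]) & (lens < 1 | lens > 2 |
      vapply(toks, function(a) any(!a %in% c(".", as.character(0:9))),
             logical(1)))
    if (any(malformed))
      stop(sprintf("malformed GT at VCF record %d (%s:%s), sample(s) %s",
                   r, fix[r, "CHROM"], fix[r, "POS"],
                   paste(samples[malformed], collapse = ", ")))
    for (a in seq_along(alts)) {
      dose <- vapply(toks, function(al) {
        if (length(al) == 0 || any(al == ".") || anyNA(al))
          return(NA_integer_)
        sum(al == as.character(a))
      }, integer(1))
      dose[is.na(gt[r, ])] <- NA_integer_
      cols[[length(cols) + 1L]] <- dose
      ids <- c(ids, sprintf("%s:%s:%s:%s", fix[r, "CHROM"], fix[r, "POS"],
                            fix[r, "REF"], alts[a]))
    }
  }
  g <- do.call(cbind, cols)
  dimnames(g) <- list(samples, ids)
  g
}

#' Write a genotype dosage matrix
#'
#' `write_genotypes_tsv` writes the TSV dialect read by [read_genotypes()].
#' `write_genotypes_vcf` emits a minimal VCFv4.2 file with unphased GT
#' fields; dosage 1 is written `0/1`, 2 as `1/1`, `NA` as `./.`. Variant ids
#' must be in `chrom:pos:ref:alt` form.
#'
#' @param genotypes integer matrix, individuals x variants, with dimnames.
#' @param path output path.
#' @param meta optional metadata header list (TSV only).
#' @export
write_genotypes_tsv <- function(genotypes, path, meta = NULL) {
  df <- data.frame(individual_id = rownames(genotypes),
                   genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path, meta)
}

#' @rdname write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  ids <- colnames(genotypes)
  parts <- strsplit(ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 4))
    stop("variant ids must be chrom:pos:ref:alt to write VCF")
  gt_str <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L],
                   nrow = nrow(genotypes))
  gt_str[is.na(genotypes)] <- "./."
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=slpburden",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")), con)
  for (j in seq_along(ids)) {
    p <- parts[[j]]
    writeLines(paste(c(p[1], p[2], ids[j], p[3], p[4], ".", "PASS", ".",
                       "GT", gt_str[, j]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the comparison outputs
#'
#' Writes the SLP matrix (genes as columns, plus the per-predictor mean), a
#' correlation matrix, or the relative-SLP table, each as TSV with a
#' metadata header.
#'
#' @param comparison an `slp_comparison` object.
#' @param cormat a correlation matrix from [score_correlation_matrix()].
#' @param path output path.
#' @param meta optional extra metadata entries.
#' @export
write_comparison_tsv <- function(comparison, path, meta = NULL) {
  stopifnot(inherits(comparison, "slp_comparison"))
  .write_tsv(as.data.frame(comparison), path, meta)
}

#' @rdname write_comparison_tsv
#' @export
write_correlation_tsv <- function(cormat, path, meta = NULL) {
  meta <- c(list(method = attr(cormat, "method") %||% "pearson",
                 n_variants = attr(cormat, "n_variants") %||% NA), meta)
  df <- data.frame(predictor = rownames(cormat), as.data.frame(cormat),
                   check.names = FALSE)
  .write_tsv(df, path, meta)
}
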