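# Per-gene logistic association and the signed log10 p-value (SLP).

#' Fit a logistic regression by maximum likelihood
#'
#' Thin wrapper around the binomial IRLS fitter with the convergence policy
#' used throughout the package: tolerance 1e-8, at most 100 iterations, and
#' an explicit convergence flag instead of a warning. Exactly collinear
#' columns are dropped (their coefficients reported as `NA`) and flagged.
#'
#' @param outcome 0/1 vector with both classes present.
#' @param design numeric model matrix including an intercept column.
#' @return list with `coef`, `se` (named numeric vectors, `NA` for dropped
#'   columns), `converged` (logical), `rank_deficient` (logical) and
#'   `dropped` (names of dropped columns).
#' @export
fit_logistic <- function(outcome, design) {
  stopifnot(is.numeric(outcome) || is.logical(outcome))
  outcome <- as.numeric(outcome)
  stopifnot(all(outcome %in% c(0, 1)), is.matrix(design),
            nrow(design) == length(outcome))
  if (length(unique(outcome)) < 2L)
    stop("outcome has a single class; logistic model is not identifiable")
  fit <- suppressWarnings(
    stats::glm.fit(design, outcome, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  p <- ncol(design)
  coefs <- fit$coefficients
  dropped <- names(coefs)[is.na(coefs)]
  rank_deficient <- fit$rank < p
  se <- rep(NA_real_, p)
  names(se) <- colnames(design)
  # covariance of the estimated (non-aliased) coefficients from the final
  # weighted least-squares step; qr columns are pivoted
  R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov_ok <- chol2inv(R)
  se[fit$qr$pivot[seq_len(fit$rank)]] <- sqrt(diag(cov_ok))
  list(coef = coefs, se = se, converged = fit$converged,
       rank_deficient = rank_deficient, dropped = dropped)
}

#' Signed log10 p-value
#'
#' Converts a coefficient and its p-value into the SLP statistic:
#' `-log10(p)` signed by the coefficient, so positive SLP means the score is
#' positively associated with the phenotype. `beta = 0` (where the sign is
#' undefined) gives SLP 0. Magnitudes are capped at 323, the double-precision
#' p-value underflow floor, with a `"capped"` attribute.
#'
#' @param beta numeric coefficient(s).
#' @param p p-value(s) in (0, 1].
#' @return numeric SLP, same length as the inputs.
#' @examples
#' compute_slp(1.2, 0.01)   #  2
#' compute_slp(-0.4, 0.01)  # -2
#' @export
compute_slp <- function(beta, p) {
  stopifnot(is.numeric(beta), is.numeric(p))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p must lie in (0, 1]")
  slp <- sign(beta) * (-log10(p))
  capped <- abs(slp) > 323
  slp[capped] <- sign(slp[capped]) * 323
  if (any(capped)) attr(slp, "capped") <- which(capped)
  slp
}

#' Weighted burden association for one predictor in one gene
#'
#' Fits the per-gene logistic model
#' `outcome ~ intercept + 20 PCs + sex + lof_burden +
#' protein_altering_burden + predictor_burden`
#' and summarizes the Wald test on the predictor burden coefficient as a
#' signed log10 p-value. The p-value is the two-sided normal tail probability
#' of `z = beta / se`. A degenerate (constant) predictor burden yields SLP 0
#' with the `degenerate` flag set, without error; a non-converged fit yields
#' `NA` SLP unless `allow_nonconverged = TRUE`.
#'
#' @param profiles burden profile data.frame from [gene_profiles()]
#'   (`individual_id`, `lof_burden`, `protein_altering_burden`, predictor
#'   columns).
#' @param cohort cohort data.frame with `individual_id`, binary `phenotype`,
#'   `sex`, and principal-component columns `PC1` ... (20 by default).
#' @param predictor_name which predictor burden column to test.
#' @param gene gene label carried into the result.
#' @param n_pcs number of principal components expected in `cohort`.
#' @param allow_nonconverged report the last-iterate SLP even when the fit
#'   did not converge (default `FALSE`: SLP is `NA`).
#' @return An object of class `slp_fit`: list with `gene`, `predictor`,
#'   `beta`, `se`, `z`, `p`, `slp`, `converged`, `degenerate`, `n`, `n_cases`
#'   and the full coefficient table `coefficients`.
#' @export
predictor_slp <- function(profiles, cohort, predictor_name,
                          gene = attr(profiles, "gene") %||% NA_character_,
                          n_pcs = 20L, allow_nonconverged = FALSE) {
  stopifnot(is.data.frame(profiles), is.data.frame(cohort),
            "individual_id" %in% names(profiles),
            all(c("individual_id", "phenotype", "sex") %in% names(cohort)))
  if (!predictor_name %in% names(profiles))
    stop("unknown predictor burden column: ", predictor_name)
  pc_cols <- paste0("PC", seq_len(n_pcs))
  missing_pcs <- setdiff(pc_cols, names(cohort))
  if (length(missing_pcs))
    stop("cohort lacks principal components: ",
         paste(missing_pcs, collapse = ", "))
  common <- intersect(profiles$individual_id, cohort$individual_id)
  if (length(common) != nrow(profiles) || length(common) != nrow(cohort))
    stop(sprintf(
      "individual_id mismatch: %d in profiles, %d in cohort, %d shared",
      nrow(profiles), nrow(cohort), length(common)))
  prof <- profiles[match(common, profiles$individual_id), , drop = FALSE]
  coh <- cohort[match(common, cohort$individual_id), , drop = FALSE]

  x_pred <- prof[[predictor_name]]
  degenerate <- stats::var(x_pred) == 0 || !is.finite(stats::var(x_pred))
  res <- structure(list(
    gene = gene, predictor = predictor_name,
    beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
    slp = NA_real_, converged = NA, degenerate = degenerate,
    n = length(common), n_cases = sum(coh$phenotype == 1),
    coefficients = NULL), class = "slp_fit")
  if (degenerate) {
    res$slp <- 0
    res$converged <- TRUE
    return(res)
  }

  design <- cbind(`(Intercept)` = 1,
                  as.matrix(coh[, pc_cols, drop = FALSE]),
                  sex = coh$sex,
                  lof_burden = prof$lof_burden,
                  protein_altering_burden = prof$protein_altering_burden,
                  predictor_burden = x_pred)
  fit <- fit_logistic(coh$phenotype, design)
  beta <- unname(fit$coef["predictor_burden"])
  se <- unname(fit$se["predictor_burden"])
  res$converged <- fit$converged
  res$coefficients <- data.frame(term = names(fit$coef),
                                 estimate = unname(fit$coef),
                                 se = unname(fit$se))
  if (is.na(beta)) {         # aliased: predictor collinear with covariates
    res$degenerate <- TRUE
    res$slp <- 0
    return(res)
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  p <- max(p, .Machine$double.xmin)   # guard exact underflow to 0
  res$beta <- beta; res$se <- se; res$z <- z; res$p <- p
  if (fit$converged || allow_nonconverged)
    res$slp <- as.numeric(compute_slp(beta, p))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.slp_fit <- function(x, ...) {
  cat(sprintf("Weighted burden association (gene %s, predictor %s)\n",
              x$gene, x$predictor))
  cat(sprintf("  n = %d (%d cases)\n", x$n, x$n_cases))
  if (isTRUE(x$degenerate)) {
    cat("  degenerate predictor burden (constant); SLP = 0\n")
  } else {
    cat(sprintf("  beta = %.4g  se = %.4g  z = %.3f  p = %.3g  SLP = %.3f%s\n",
                x$beta, x$se, x$z, x$p, x$slp,
                if (!isTRUE(x$converged)) "  [NOT CONVERGED]" else ""))
  }
  invisible(x)
}

#' @export
summary.slp_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$coefficients)) {
    cat("\nFull coefficient table:\n")
    print(object$coefficients, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.slp_fit <- function(object, ...) {
  if (is.null(object$coefficients)) return(c(predictor_burden = object$beta))
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.slp_fit <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  m <- cbind(lower = object$beta - q * object$se,
             upper = object$beta + q * object$se)
  rownames(m) <- "predictor_burden"
  m
}

#' @export
as.data.frame.slp_fit <- function(x, ...) {
  data.frame(gene = x$gene, predictor = x$predictor, beta = x$beta,
             se = x$se, z = x$z, p = x$p, slp = x$slp,
             converged = x$converged, degenerate = x$degenerate,
             stringsAsFactors = FALSE)
}
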