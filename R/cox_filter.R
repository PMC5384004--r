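#' Cox-filter model for one gene
#'
#' Fits, for a single gene, the Cox proportional hazards model
#' \deqn{\lambda(t) = \lambda_0(t)\exp(\beta_1 I(SCC) + \beta_2 X +
#'   \beta_3 X \cdot I(SCC))}
#' by maximum partial likelihood (Efron handling of tied event times).
#' The subtype-specific effects are `beta_AC = beta2` (log hazard-rate
#' change per expression unit among AC patients) and
#' `beta_SCC = beta2 + beta3`; both are tested with two-sided Wald tests,
#' the SCC variance coming from
#' `var(b2) + var(b3) + 2 cov(b2, b3)`.
#'
#' Degenerate genes (no variation, separation, or any failure of the
#' Newton iterations) are not an error: they are returned with
#' `converged = FALSE` and `p_AC = p_SCC = 1`, so that a genome-wide scan
#' completes and such genes are never selected.
#'
#' @param x Numeric expression vector, one value per sample, aligned with
#'   `clinical` rows.
#' @param clinical Clinical `data.frame` (see [read_clinical()]).
#' @param eps Convergence tolerance on the relative change in the log
#'   partial likelihood.
#' @param iter_max Maximum Newton-Raphson iterations.
#' @return A one-row `data.frame` with columns `beta1`, `beta2`, `beta3`,
#'   `beta_AC`, `beta_SCC`, `se_AC`, `se_SCC`, `p_AC`, `p_SCC`,
#'   `converged`.
#' @seealso [cox_filter()] for the genome-wide scan with adjusted
#'   p-values.
#' @export
fit_gene_cox <- function(x, clinical, eps = 1e-9, iter_max = 50L) {
  clinical <- validate_clinical(clinical)
  if (length(x) != nrow(clinical))
    stop("expression vector length (", length(x),
         ") does not match number of clinical records (", nrow(clinical), ")")
  if (sum(clinical$event) == 0L)
    stop("all records are censored; the partial likelihood is undefined")
  out <- cox_filter_scan(matrix(x, nrow = 1L, dimnames = list("x", NULL)),
                         clinical, eps = eps, iter_max = iter_max)
  out$gene_id <- NULL
  out
}

# Genome-wide Cox-filter scan over the rows of a covariate matrix.
# Shared by the gene-level and set-level fitters: one three-column Cox
# model per row, Wald tests for the AC and SCC slopes.
#' @keywords internal
cox_filter_scan <- function(X, clinical, eps = 1e-9, iter_max = 50L) {
  stopifnot(is.matrix(X), ncol(X) == nrow(clinical))
  if (sum(clinical$event) < 1L)
    stop("all records are censored; the partial likelihood is undefined")
  scc <- as.numeric(clinical$subtype == "SCC")
  y <- survival::Surv(clinical$time, clinical$event)
  ctrl <- survival::coxph.control(eps = eps, iter.max = iter_max)
  rn <- as.character(seq_len(ncol(X)))
  p <- nrow(X)
  res <- data.frame(
    gene_id = if (is.null(rownames(X))) as.character(seq_len(p)) else rownames(X),
    beta1 = NA_real_, beta2 = NA_real_, beta3 = NA_real_,
    beta_AC = NA_real_, beta_SCC = NA_real_,
    se_AC = NA_real_, se_SCC = NA_real_,
    p_AC = 1, p_SCC = 1, converged = FALSE,
    stringsAsFactors = FALSE
  )
  for (g in seq_len(p)) {
    xg <- X[g, ]
    M <- cbind(scc = scc, x = xg, xscc = xg * scc)
    fit <- tryCatch(
      suppressWarnings(survival::coxph.fit(
        M, y, strata = NULL, offset = NULL, init = NULL,
        control = ctrl, weights = NULL, method = "efron", rownames = rn)),
      error = function(e) NULL)
    if (is.null(fit)) next
    b <- fit$coefficients
    V <- fit$var
    ok <- !anyNA(b) && all(is.finite(b)) && all(is.finite(V)) &&
      all(diag(V) > 0) && fit$iter < iter_max && max(abs(b)) < 15
    if (!ok) {
      res$beta1[g] <- unname(b[1L]); res$beta2[g] <- unname(b[2L])
      res$beta3[g] <- unname(b[3L])
      next
    }
    w <- test_subtype_effects(b[2L], b[3L], V[2:3, 2:3])
    res$beta1[g] <- unname(b[1L])
    res$beta2[g] <- unname(b[2L])
    res$beta3[g] <- unname(b[3L])
    res$beta_AC[g] <- unname(b[2L])
    res$beta_SCC[g] <- unname(b[2L] + b[3L])
    res$se_AC[g] <- w$se_AC
    res$se_SCC[g] <- w$se_SCC
    res$p_AC[g] <- w$p_AC
    res$p_SCC[g] <- w$p_SCC
    res$converged[g] <- TRUE
  }
  res
}

#' Genome-wide Cox-filter scan
#'
#' Applies [fit_gene_cox()] to every gene of an expression matrix and
#' appends multiplicity-adjusted p-values per subtype (`q_AC`, `q_SCC`)
#' computed over all genes in the scan.
#'
#' @param expr Genes-by-samples numeric matrix; columns aligned with
#'   `clinical` (use [align_cohort()] first when in doubt).
#' @param clinical Clinical `data.frame`.
#' @param adjust Multiple-testing procedure, `"BH"`
#'   (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @inheritParams fit_gene_cox
#' @return A `data.frame` of class `gene_cox_fits`, one row per gene,
#'   with the per-gene columns of [fit_gene_cox()] plus `q_AC`, `q_SCC`.
#' @examples
#' sc <- sim_scenario(n_AC = 40, n_SCC = 40, n_sets = 4, set_size = 5,
#'                    seed = 7)
#' d <- simulate_cohort(sc)
#' fits <- cox_filter(d$expr, d$clinical)
#' head(fits[order(fits$p_AC), c("gene_id", "beta_AC", "p_AC", "q_AC")])
#' @export
cox_filter <- function(expr, clinical, adjust = c("BH", "bonferroni"),
                       eps = 1e-9, iter_max = 50L) {
  adjust <- match.arg(adjust)
  aligned <- align_cohort(expr, clinical)
  res <- cox_filter_scan(aligned$expr, aligned$clinical,
                         eps = eps, iter_max = iter_max)
  res$q_AC <- adjust_bh(res$p_AC, method = adjust)
  res$q_SCC <- adjust_bh(res$p_SCC, method = adjust)
  class(res) <- c("gene_cox_fits", "data.frame")
  res
}

#' Subtype-specific Wald tests from a Cox-filter fit
#'
#' Given the gene (`beta2`) and interaction (`beta3`) coefficients and
#' their 2x2 covariance block, forms the AC effect `beta2` and the SCC
#' effect `beta2 + beta3` with standard errors and two-sided normal-tail
#' p-values.
#'
#' @param beta2,beta3 Coefficient estimates.
#' @param covariance Symmetric positive semi-definite 2x2 covariance
#'   matrix of `(beta2, beta3)`.
#' @return A list with `p_AC`, `p_SCC`, `se_AC`, `se_SCC`.
#' @export
test_subtype_effects <- function(beta2, beta3, covariance) {
  V <- as.matrix(covariance)
  if (!all(dim(V) == c(2L, 2L)))
    stop("covariance must be a 2x2 matrix")
  if (abs(V[1L, 2L] - V[2L, 1L]) > 1e-8 * (1 + max(abs(V))))
    stop("covariance matrix is not symmetric")
  v_AC <- V[1L, 1L]
  v_SCC <- V[1L, 1L] + V[2L, 2L] + 2 * V[1L, 2L]
  if (v_AC < 0 || V[2L, 2L] < 0 || v_SCC < 0)
    stop("negative variance; covariance matrix is not positive semi-definite")
  se_AC <- sqrt(v_AC)
  se_SCC <- sqrt(v_SCC)
  wald_p <- function(b, se) {
    if (se == 0) return(if (b == 0) 1 else 0)
    2 * stats::pnorm(-abs(b / se))
  }
  list(p_AC = wald_p(beta2, se_AC),
       p_SCC = wald_p(beta2 + beta3, se_SCC),
       se_AC = se_AC, se_SCC = se_SCC)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up adjustment (or Bonferroni), with domain
#' validation: inputs outside `[0, 1]` are an error rather than silently
#' propagated.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Write a per-gene Cox-filter results table as TSV
#'
#' @param fits `gene_cox_fits` data.frame from [cox_filter()].
#' @param path Output path.
#' @export
write_cox_fits <- function(fits, path) {
  cols <- c("gene_id", "beta_AC", "se_AC", "p_AC", "q_AC",
            "beta_SCC", "se_SCC", "p_SCC", "q_SCC", "converged")
  utils::write.table(as.data.frame(fits)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
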