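#' Set-level Cox-filter fits on sign-average profiles
#'
#' Refits the Cox-filter model with gene sets in place of genes: for each
#' set, the covariates are the subtype indicator, the sign-average risk
#' profile `Z` and their interaction, giving set-level `beta_AC` and
#' `beta_SCC` with Wald tests and per-subtype adjusted p-values.
#'
#' @param profile A `set_risk_profile` from [compute_set_profiles()].
#' @param clinical Clinical `data.frame` aligned with the profile rows.
#' @param adjust Multiple-testing procedure (see [adjust_bh()]).
#' @inheritParams fit_gene_cox
#' @return A `data.frame` of class `set_cox_fits`, one row per set, with
#'   column `set_name` plus the effect/test columns of [cox_filter()].
#' @export
fit_set_cox <- function(profile, clinical, adjust = c("BH", "bonferroni"),
                        eps = 1e-9, iter_max = 50L) {
  adjust <- match.arg(adjust)
  clinical <- validate_clinical(clinical)
  Z <- profile$Z
  stopifnot(nrow(Z) == nrow(clinical),
            identical(rownames(Z), clinical$sample_id))
  res <- cox_filter_scan(t(Z), clinical, eps = eps, iter_max = iter_max)
  names(res)[names(res) == "gene_id"] <- "set_name"
  res$q_AC <- adjust_bh(res$p_AC, method = adjust)
  res$q_SCC <- adjust_bh(res$p_SCC, method = adjust)
  class(res) <- c("set_cox_fits", "data.frame")
  res
}

# Scoring information frozen at selection time: for each kept set, the
# per-subtype sign vector over its considered genes and the set-level
# subtype slope.  Used to score held-out patients without re-estimation.
#' @keywords internal
freeze_scoring <- function(kept_sets, profile, setfits, subtype) {
  lapply(kept_sets, function(k) {
    grp <- profile$groupings[[k]][[subtype]]
    list(set_name = k,
         signs = stats::setNames(ifelse(grp$considered %in% grp$H, 1, -1),
                                 grp$considered),
         beta = setfits[[paste0("beta_", subtype)]][
           match(k, setfits$set_name)])
  })
}

#' @keywords internal
new_bilevel_selection <- function(direction, per_subtype) {
  structure(list(direction = direction, subtypes = per_subtype),
            class = "bilevel_selection")
}

#' Forward Cox-filter bi-level selection
#'
#' Sets first, genes second.  Per subtype: (1) sign-average profiles over
#' all set genes; (2) set-level Cox-filter fits with BH adjustment across
#' sets, keeping sets with adjusted p at most `alpha_set`; (3) among the
#' genes of the kept sets, gene-level p-values are re-adjusted within that
#' restricted family and genes with adjusted p at most `alpha_gene` are
#' selected (set `gene_family = "genomewide"` to reuse the genome-wide
#' q-values instead).
#'
#' @param expr Genes-by-samples expression matrix.
#' @param clinical Clinical `data.frame` aligned with `expr`.
#' @param sets Named list of gene sets.
#' @param fits Genome-wide `gene_cox_fits` from [cox_filter()].
#' @param alpha_set Cutoff on the set-level adjusted p-value.
#' @param alpha_gene Cutoff on the gene-level adjusted p-value.
#' @param gene_family Family for the step-2 gene-level adjustment:
#'   `"restricted"` (default, genes of the selected sets) or
#'   `"genomewide"`.
#' @param adjust Multiple-testing procedure (see [adjust_bh()]).
#' @return A `bilevel_selection`: per subtype, the selected set names,
#'   gene symbols, the cutoffs used and frozen scoring information for
#'   [predict_risk()].
#' @export
forward_select <- function(expr, clinical, sets, fits,
                           alpha_set = 0.05, alpha_gene = 0.05,
                           gene_family = c("restricted", "genomewide"),
                           adjust = "BH") {
  gene_family <- match.arg(gene_family)
  profile <- compute_set_profiles(expr, sets, fits, clinical)
  setfits <- fit_set_cox(profile, clinical, adjust = adjust)
  per <- lapply(c(AC = "AC", SCC = "SCC"), function(j) {
    q_set <- setfits[[paste0("q_", j)]]
    kept <- setfits$set_name[q_set <= alpha_set & setfits$converged]
    genes_pool <- intersect(unique(unlist(sets[kept])), fits$gene_id)
    if (length(genes_pool)) {
      if (gene_family == "restricted") {
        p <- fits[[paste0("p_", j)]][match(genes_pool, fits$gene_id)]
        q <- adjust_bh(p)
      } else {
        q <- fits[[paste0("q_", j)]][match(genes_pool, fits$gene_id)]
      }
      genes <- genes_pool[q <= alpha_gene]
    } else genes <- character(0)
    list(selected_sets = kept, selected_genes = genes,
         alpha_set = alpha_set, alpha_gene = alpha_gene,
         scoring = freeze_scoring(kept, profile, setfits, j))
  })
  new_bilevel_selection("forward", per)
}

#' Backward Cox-filter bi-level selection
#'
#' Genes first, sets second.  Per subtype: (1) candidate genes are those
#' with genome-wide adjusted p at most `alpha_gene`; (2) sign-average
#' profiles are rebuilt over the candidates only (sets without candidates
#' drop out); (3) set-level Cox-filter fits with BH adjustment keep sets
#' with adjusted p at most `alpha_set`; (4) the final genes are the
#' candidates contained in the kept sets.
#'
#' @inheritParams forward_select
#' @return A `bilevel_selection` (see [forward_select()]).
#' @export
backward_select <- function(expr, clinical, sets, fits,
                            alpha_gene = 0.05, alpha_set = 0.05,
                            adjust = "BH") {
  per <- lapply(c(AC = "AC", SCC = "SCC"), function(j) {
    q_gene <- fits[[paste0("q_", j)]]
    candidates <- fits$gene_id[q_gene <= alpha_gene & fits$converged]
    empty <- list(selected_sets = character(0),
                  selected_genes = character(0),
                  alpha_set = alpha_set, alpha_gene = alpha_gene,
                  candidates = candidates, scoring = list())
    if (!length(candidates)) return(empty)
    profile <- tryCatch(
      compute_set_profiles(expr, sets, fits, clinical,
                           gene_filter = candidates),
      error = function(e) NULL)
    if (is.null(profile)) return(empty)
    setfits <- fit_set_cox(profile, clinical, adjust = adjust)
    q_set <- setfits[[paste0("q_", j)]]
    kept <- setfits$set_name[q_set <= alpha_set & setfits$converged]
    genes <- intersect(candidates, unique(unlist(sets[kept])))
    list(selected_sets = kept, selected_genes = genes,
         alpha_set = alpha_set, alpha_gene = alpha_gene,
         candidates = candidates,
         scoring = freeze_scoring(kept, profile, setfits, j))
  })
  new_bilevel_selection("backward", per)
}

#' @export
print.bilevel_selection <- function(x, ...) {
  cat(x$direction, "Cox-filter selection\n")
  for (j in names(x$subtypes)) {
    s <- x$subtypes[[j]]
    cat(sprintf("  %s: %d gene set(s), %d gene(s)  [alpha_set=%g, alpha_gene=%g]\n",
                j, length(s$selected_sets), length(s$selected_genes),
                s$alpha_set, s$alpha_gene))
  }
  invisible(x)
}

#' Risk scores for new samples from a frozen selection
#'
#' Scores each patient as the sum over the selected sets of that
#' patient's subtype of `beta_set x Z`, where both the set-level slope
#' and the hazardous/preventive grouping are frozen from the data the
#' selection was made on (no re-estimation on the scored samples).
#' Patients of a subtype with an empty selection receive score 0, i.e. an
#' uninformative (random-guess) ranking.
#'
#' @param selection A `bilevel_selection`.
#' @param expr Genes-by-samples expression matrix for the samples to
#'   score.
#' @param clinical Clinical `data.frame` aligned with `expr`.
#' @return Numeric vector of risk scores, one per `expr` column (higher
#'   means worse prognosis).
#' @export
predict_risk <- function(selection, expr, clinical) {
  stopifnot(inherits(selection, "bilevel_selection"),
            ncol(expr) == nrow(clinical))
  scores <- numeric(ncol(expr))
  names(scores) <- colnames(expr)
  for (j in c("AC", "SCC")) {
    rows <- clinical$subtype == j
    if (!any(rows)) next
    for (item in selection$subtypes[[j]]$scoring) {
      genes <- intersect(names(item$signs), rownames(expr))
      if (!length(genes) || !is.finite(item$beta)) next
      s <- item$signs[genes]
      Z <- as.numeric(crossprod(expr[genes, rows, drop = FALSE], s)) /
        length(genes)
      scores[rows] <- scores[rows] + item$beta * Z
    }
  }
  scores
}
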