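#' Classify a gene set into hazardous and preventive groups
#'
#' For one subtype, genes whose estimated subtype-specific log hazard-rate
#' effect is positive (higher expression, higher hazard) form the
#' hazardous group `H`; the remainder (including an exact zero estimate,
#' a measure-zero tie resolved by convention) form the preventive group
#' `P`.  Genes without a converged Cox-filter fit, or absent from the fit
#' table, are dropped from consideration.
#'
#' @param fits `gene_cox_fits` table from [cox_filter()].
#' @param geneset Character vector of gene symbols (one gene set).
#' @param subtype `"AC"` or `"SCC"`.
#' @return A list of class `hazard_grouping` with components `H`, `P`,
#'   `considered` (`H` and `P` partition `considered`) and `subtype`.
#' @export
classify_hazard_groups <- function(fits, geneset, subtype = c("AC", "SCC")) {
  subtype <- match.arg(subtype)
  fits <- as.data.frame(fits)
  idx <- match(geneset, fits$gene_id)
  keep <- !is.na(idx)
  idx <- idx[keep]
  conv <- fits$converged[idx]
  considered <- geneset[keep][conv]
  beta <- fits[[paste0("beta_", subtype)]][idx][conv]
  structure(list(H = considered[beta > 0],
                 P = considered[beta <= 0],
                 considered = considered,
                 subtype = subtype),
            class = "hazard_grouping")
}

#' Sign-average risk summary of one patient over one gene set
#'
#' Computes
#' \deqn{Z = \left(\sum_{l \in H} X_{il} - \sum_{l \in P} X_{il}\right) /
#'   |considered|}
#' the signed average of the patient's expression over the genes under
#' consideration in the set.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param grouping A `hazard_grouping` from [classify_hazard_groups()].
#' @param sample Sample identifier (must be a column of `expr`).
#' @return A single numeric value.
#' @export
compute_sign_average <- function(expr, grouping, sample) {
  if (!sample %in% colnames(expr))
    stop("sample '", sample, "' not present in expression matrix")
  genes <- intersect(grouping$considered, rownames(expr))
  if (!length(genes)) stop("grouping considers no gene present in the data")
  s <- ifelse(genes %in% grouping$H, 1, -1)
  sum(s * expr[genes, sample]) / length(genes)
}

#' Samples-by-sets sign-average risk profiles
#'
#' Builds the matrix `Z` of sign averages for every patient and gene set.
#' Each patient's value uses the hazardous/preventive grouping of that
#' patient's own subtype.  In forward mode (`gene_filter = NULL`) all set
#' genes present in the data are considered; in backward mode
#' `gene_filter` restricts each set to pre-selected candidate genes.
#' Sets with no considered gene are absent from the profile (never
#' zero-filled).
#'
#' @param expr Genes-by-samples expression matrix.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param fits `gene_cox_fits` table from [cox_filter()].
#' @param clinical Clinical `data.frame` aligned with `expr` columns.
#' @param gene_filter Optional character vector of candidate genes; when
#'   given, each set's considered genes are its intersection with the
#'   filter.
#' @return A list of class `set_risk_profile` with components `Z`
#'   (samples x sets matrix), `groupings` (per set, a list with `AC` and
#'   `SCC` [classify_hazard_groups()] results), `n_considered` (per-set
#'   gene counts) and `sample_ids`.
#' @export
compute_set_profiles <- function(expr, sets, fits, clinical,
                                 gene_filter = NULL) {
  stopifnot(ncol(expr) == nrow(clinical))
  if (!length(sets)) stop("empty gene-set collection")
  groupings <- vector("list", length(sets))
  names(groupings) <- names(sets)
  keep <- logical(length(sets))
  for (k in seq_along(sets)) {
    genes <- sets[[k]]
    if (!is.null(gene_filter)) genes <- intersect(genes, gene_filter)
    genes <- intersect(genes, rownames(expr))
    gAC <- classify_hazard_groups(fits, genes, "AC")
    gSCC <- classify_hazard_groups(fits, genes, "SCC")
    if (length(gAC$considered) && length(gSCC$considered)) {
      keep[k] <- TRUE
      groupings[[k]] <- list(AC = gAC, SCC = gSCC)
    }
  }
  if (!any(keep))
    stop("no gene set has any considered gene; cannot build risk profiles")
  groupings <- groupings[keep]
  is_scc <- clinical$subtype == "SCC"
  Z <- matrix(NA_real_, nrow = ncol(expr), ncol = sum(keep),
              dimnames = list(colnames(expr), names(groupings)))
  for (k in seq_along(groupings)) {
    for (j in c("AC", "SCC")) {
      grp <- groupings[[k]][[j]]
      rows <- if (j == "SCC") is_scc else !is_scc
      if (!any(rows)) next
      s <- ifelse(grp$considered %in% grp$H, 1, -1)
      Xk <- expr[grp$considered, rows, drop = FALSE]
      Z[rows, k] <- as.numeric(crossprod(Xk, s)) / length(grp$considered)
    }
  }
  structure(list(Z = Z, groupings = groupings,
                 n_considered = vapply(groupings, function(g)
                   length(g$AC$considered), 0L),
                 sample_ids = colnames(expr)),
            class = "set_risk_profile")
}

#' @export
print.set_risk_profile <- function(x, ...) {
  cat("Sign-average risk profile: ", nrow(x$Z), " samples x ",
      ncol(x$Z), " gene sets\n", sep = "")
  invisible(x)
}

#' Export a risk profile as TSV (samples x sets)
#'
#' @param profile A `set_risk_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(sample_id = rownames(profile$Z), profile$Z,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
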