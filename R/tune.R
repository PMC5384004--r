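#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds, stratifying on the
#' subtype-by-event cross so that deaths and censorings of both subtypes
#' are spread evenly.  If any fold ends up without an event the
#' assignment is re-randomized (bounded retries) before failing.
#'
#' @param clinical Clinical `data.frame`.
#' @param k Number of folds.
#' @param seed Seed for the randomization.
#' @param max_retry Re-randomization attempts before a hard error.
#' @return Integer vector of fold ids (1..k), one per clinical row.
#' @export
make_folds <- function(clinical, k = 10L, seed = 1L, max_retry = 20L) {
  clinical <- validate_clinical(clinical)
  n <- nrow(clinical)
  if (n < k) stop("fewer samples (", n, ") than folds (", k, ")")
  strata <- interaction(clinical$subtype, clinical$event, drop = TRUE)
  for (attempt in seq_len(max_retry)) {
    folds <- withr_seed(seed + (attempt - 1L) * 1009L, {
      f <- integer(n)
      for (s in levels(strata)) {
        idx <- which(strata == s)
        f[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
      }
      f
    })
    fold_events <- tapply(clinical$event, factor(folds, levels = seq_len(k)),
                          sum, default = 0L)
    if (all(fold_events >= 1L)) return(folds)
  }
  stop("could not build ", k, " folds that all contain an event (",
       sum(clinical$event), " events in total)")
}

#' Cross-validated tuning of the two adjusted-p-value cutoffs
#'
#' Evaluates every pair `(alpha_gene, alpha_set)` over a grid (default
#' 0.01, 0.05, 0.1, 0.15, 0.2 for each, 25 pairs) by stratified k-fold
#' cross-validation: for each fold, the full selection procedure runs on
#' the training folds, held-out patients are scored with
#' [predict_risk()] (set-level slopes and hazard groupings frozen from
#' training), and the censoring-adjusted concordance is computed per
#' subtype on the validation fold with `tau` fixed at the 90th
#' percentile of the training follow-up times.  A fold on which the
#' selection is empty for a subtype contributes C = 0.5 (an empty
#' signature is a random guess).  Per subtype the pair with the maximal
#' mean held-out C is chosen; ties (within 1e-12) go to the smallest
#' `(alpha_set, alpha_gene)` lexicographically.
#'
#' @inheritParams forward_select
#' @param direction `"forward"` or `"backward"`.
#' @param grid Numeric vector of candidate cutoffs.
#' @param k_folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param tie_cutoffs Logical; when `TRUE` the two cutoffs are tied
#'   equal and only the diagonal of the grid is searched.
#' @return A list of class `tuning_result` with the per-pair per-subtype
#'   mean held-out C (`table`), the `chosen` pair per subtype, the fold
#'   assignment and the seed.
#' @export
tune_cutoffs_cv <- function(expr, clinical, sets,
                            direction = c("forward", "backward"),
                            grid = c(0.01, 0.05, 0.1, 0.15, 0.2),
                            k_folds = 10L, seed = 1L,
                            tie_cutoffs = FALSE) {
  direction <- match.arg(direction)
  aligned <- align_cohort(expr, clinical)
  expr <- aligned$expr
  clinical <- aligned$clinical
  folds <- make_folds(clinical, k_folds, seed)
  pairs <- if (tie_cutoffs) {
    data.frame(alpha_gene = grid, alpha_set = grid)
  } else {
    expand.grid(alpha_gene = grid, alpha_set = grid,
                KEEP.OUT.ATTRS = FALSE)
  }
  C <- array(NA_real_,
             dim = c(nrow(pairs), k_folds, 2L),
             dimnames = list(NULL, NULL, c("AC", "SCC")))
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    expr_tr <- expr[, tr, drop = FALSE]
    clin_tr <- clinical[tr, , drop = FALSE]
    expr_va <- expr[, !tr, drop = FALSE]
    clin_va <- clinical[!tr, , drop = FALSE]
    fits_tr <- cox_filter(expr_tr, clin_tr)
    tau_tr <- stats::quantile(clin_tr$time, 0.9, names = FALSE)
    for (p in seq_len(nrow(pairs))) {
      sel <- tryCatch({
        if (direction == "forward")
          forward_select(expr_tr, clin_tr, sets, fits_tr,
                         alpha_set = pairs$alpha_set[p],
                         alpha_gene = pairs$alpha_gene[p])
        else
          backward_select(expr_tr, clin_tr, sets, fits_tr,
                          alpha_gene = pairs$alpha_gene[p],
                          alpha_set = pairs$alpha_set[p])
      }, error = function(e) NULL)
      if (is.null(sel)) next
      sc <- predict_risk(sel, expr_va, clin_va)
      for (j in c("AC", "SCC")) {
        rows <- clin_va$subtype == j
        if (!any(rows)) next
        if (!length(sel$subtypes[[j]]$selected_sets)) {
          C[p, f, j] <- 0.5
          next
        }
        C[p, f, j] <- tryCatch(
          uno_c_statistic(clin_va$time[rows], clin_va$event[rows],
                          sc[rows], tau = min(tau_tr, max(clin_va$time[rows]))),
          error = function(e) NA_real_)
      }
    }
  }
  tab <- do.call(rbind, lapply(c("AC", "SCC"), function(j) {
    data.frame(direction = direction,
               alpha_gene = pairs$alpha_gene,
               alpha_set = pairs$alpha_set,
               subtype = j,
               mean_C = apply(C[, , j, drop = FALSE], 1L, mean, na.rm = TRUE),
               se_C = apply(C[, , j, drop = FALSE], 1L, function(v)
                 stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
               n_folds = apply(C[, , j, drop = FALSE], 1L,
                               function(v) sum(!is.na(v))))
  }))
  chosen <- lapply(c(AC = "AC", SCC = "SCC"), function(j) {
    tj <- tab[tab$subtype == j, ]
    best <- max(tj$mean_C, na.rm = TRUE)
    cand <- tj[tj$mean_C >= best - 1e-12 & !is.na(tj$mean_C), ]
    cand <- cand[order(cand$alpha_set, cand$alpha_gene), ]
    list(alpha_gene = cand$alpha_gene[1L], alpha_set = cand$alpha_set[1L],
         mean_C = cand$mean_C[1L])
  })
  structure(list(table = tab, chosen = chosen, direction = direction,
                 k_folds = k_folds, seed = seed, folds = folds),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("Cross-validated cutoff tuning (", x$direction, ", ", x$k_folds,
      " folds, seed ", x$seed, ")\n", sep = "")
  for (j in names(x$chosen))
    cat(sprintf("  %s: alpha_gene=%g, alpha_set=%g  (mean held-out C = %.3f)\n",
                j, x$chosen[[j]]$alpha_gene, x$chosen[[j]]$alpha_set,
                x$chosen[[j]]$mean_C))
  invisible(x)
}

#' Write a tuning table as TSV
#'
#' @param tuning A `tuning_result`.
#' @param path Output path.
#' @export
write_tuning <- function(tuning, path) {
  utils::write.table(tuning$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
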