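#' Censoring-adjusted concordance statistic
#'
#' Inverse-probability-of-censoring-weighted (IPCW) concordance over the
#' follow-up window `(0, tau)`.  A pair `(i, j)` is comparable when
#' subject `i` dies (`event = 1`) before `tau` and strictly before
#' `T_j`; it counts as concordant when the earlier failure carries the
#' higher risk score, tied scores contributing 1/2.  Each pair is
#' weighted by `1 / G(T_i-)^2`, where `G` is the Kaplan-Meier estimator
#' of the censoring survival distribution, floored at `weight_floor` to
#' bound the weights.  A value of 0.5 corresponds to a random-guess
#' score; 1 to perfect concordance.
#'
#' @param time Observed follow-up times.
#' @param event Event indicators (1 = death observed, 0 = censored).
#' @param score Risk scores, higher meaning worse prognosis.
#' @param tau Upper end of the evaluation window; defaults to the 90th
#'   percentile of the observed follow-up times.
#' @param weight_floor Lower bound applied to `G` before inverting
#'   (default 0.05).
#' @return A single numeric value in `[0, 1]`.
#' @export
uno_c_statistic <- function(time, event, score, tau = NULL,
                            weight_floor = 0.05) {
  stopifnot(length(time) == length(event), length(time) == length(score))
  if (any(!is.finite(score))) stop("risk scores must be finite")
  if (is.null(tau)) tau <- stats::quantile(time, 0.9, names = FALSE)
  if (tau <= 0) stop("tau must be positive")
  # Kaplan-Meier of the censoring distribution (censoring as the event)
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  # left-continuous G(t-): survival just before t
  G_minus <- function(t) {
    i <- findInterval(t, cfit$time, left.open = TRUE)
    c(1, cfit$surv)[i + 1L]
  }
  n <- length(time)
  anchors <- which(event == 1 & time < tau)
  if (!length(anchors)) stop("no comparable pairs: no event before tau")
  num <- 0
  den <- 0
  for (i in anchors) {
    later <- time > time[i]
    m <- sum(later)
    if (!m) next
    w <- 1 / max(G_minus(time[i]), weight_floor)^2
    conc <- sum(score[i] > score[later]) + 0.5 * sum(score[i] == score[later])
    num <- num + w * conc
    den <- den + w * m
  }
  if (den == 0) stop("no comparable pairs within (0, tau)")
  num / den
}

#' Bootstrap standard error of the concordance statistic
#'
#' Nonparametric bootstrap over samples: subjects are resampled with
#' replacement, the IPCW concordance recomputed on each resample (with
#' the censoring distribution re-estimated), and the standard deviation
#' across resamples reported.
#'
#' @inheritParams uno_c_statistic
#' @param n_boot Number of bootstrap resamples (default 200).
#' @param seed Seed for the resampling.
#' @return A list with `C` (point estimate) and `se`.
#' @export
uno_c_boot <- function(time, event, score, tau = NULL, weight_floor = 0.05,
                       n_boot = 200L, seed = 1L) {
  C <- uno_c_statistic(time, event, score, tau, weight_floor)
  n <- length(time)
  reps <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(uno_c_statistic(time[idx], event[idx], score[idx],
                               tau, weight_floor),
               error = function(e) NA_real_)
    }, 0)
  })
  list(C = C, se = stats::sd(reps, na.rm = TRUE))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards
#' @keywords internal
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @keywords internal
jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  if (!length(a) || !length(b)) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

#' Stability (Rand) index of repeated feature selections
#'
#' Mean pairwise Jaccard overlap of `k >= 2` feature lists (gene symbols
#' or gene-set names) obtained from repeated runs of a selection
#' procedure, e.g. the folds of a cross-validation.  Two empty lists
#' agree perfectly (1); an empty against a non-empty list scores 0.
#'
#' @param lists A list of `k >= 2` character vectors.
#' @return Mean pairwise Jaccard index in `[0, 1]`.
#' @export
rand_index <- function(lists) {
  k <- length(lists)
  if (k < 2L) stop("the stability index needs at least 2 lists")
  pairs <- utils::combn(k, 2L)
  mean(apply(pairs, 2L, function(ij)
    jaccard(lists[[ij[1L]]], lists[[ij[2L]]])))
}

#' Bootstrap standard error of the stability index
#'
#' Resamples the `k` lists with replacement and recomputes the mean
#' pairwise Jaccard on each resample.
#'
#' @inheritParams rand_index
#' @param n_boot Number of resamples (default 200).
#' @param seed Seed for the resampling.
#' @return A list with `rand` and `se`.
#' @export
rand_index_boot <- function(lists, n_boot = 200L, seed = 1L) {
  r <- rand_index(lists)
  k <- length(lists)
  reps <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(k, k, replace = TRUE)
      rand_index(lists[idx])
    }, 0)
  })
  list(rand = r, se = stats::sd(reps))
}

#' Selection stability across cross-validation folds
#'
#' Runs a selection procedure on each of the `k` leave-one-fold-out
#' training subsets and measures the agreement of the resulting gene
#' lists and gene-set lists with [rand_index()], per subtype.
#'
#' @param selector A function `(expr, clinical, sets, fits)` returning a
#'   [forward_select()]-style `bilevel_selection`; `fits` is the
#'   genome-wide Cox-filter scan of the training subset.
#' @param expr,clinical,sets As in [forward_select()].
#' @param k_folds Number of folds (default 10).
#' @param seed Seed for the stratified fold assignment.
#' @return A list per subtype with `rand_gene`, `rand_set`, and the
#'   per-fold `gene_lists` and `set_lists`.
#' @export
stability_over_folds <- function(selector, expr, clinical, sets,
                                 k_folds = 10L, seed = 1L) {
  aligned <- align_cohort(expr, clinical)
  folds <- make_folds(aligned$clinical, k_folds, seed)
  gene_lists <- list(AC = list(), SCC = list())
  set_lists <- list(AC = list(), SCC = list())
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    sel <- tryCatch({
      fits <- cox_filter(aligned$expr[, tr, drop = FALSE],
                         aligned$clinical[tr, , drop = FALSE])
      selector(aligned$expr[, tr, drop = FALSE],
               aligned$clinical[tr, , drop = FALSE], sets, fits)
    }, error = function(e) {
      warning("fold ", f, " failed and was excluded: ", conditionMessage(e))
      NULL
    })
    if (is.null(sel)) next
    for (j in c("AC", "SCC")) {
      gene_lists[[j]] <- c(gene_lists[[j]],
                           list(sel$subtypes[[j]]$selected_genes))
      set_lists[[j]] <- c(set_lists[[j]],
                          list(sel$subtypes[[j]]$selected_sets))
    }
  }
  lapply(list(AC = "AC", SCC = "SCC"), function(j)
    list(rand_gene = rand_index(gene_lists[[j]]),
         rand_set = rand_index(set_lists[[j]]),
         gene_lists = gene_lists[[j]],
         set_lists = set_lists[[j]]))
}
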