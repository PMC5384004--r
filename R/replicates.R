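#' Selector handles for the replicate harness
#'
#' Wrap the forward or backward procedure at fixed cutoffs into the
#' `(expr, clinical, sets, fits)` signature the replicate and stability
#' harnesses expect.
#'
#' @param alpha_gene,alpha_set Fixed adjusted-p-value cutoffs.
#' @return A selector function returning a `bilevel_selection`.
#' @name selectors
NULL

#' @rdname selectors
#' @export
make_forward_selector <- function(alpha_set = 0.05, alpha_gene = 0.05) {
  force(alpha_set); force(alpha_gene)
  function(expr, clinical, sets, fits)
    forward_select(expr, clinical, sets, fits,
                   alpha_set = alpha_set, alpha_gene = alpha_gene)
}

#' @rdname selectors
#' @export
make_backward_selector <- function(alpha_gene = 0.05, alpha_set = 0.05) {
  force(alpha_set); force(alpha_gene)
  function(expr, clinical, sets, fits)
    backward_select(expr, clinical, sets, fits,
                    alpha_gene = alpha_gene, alpha_set = alpha_set)
}

#' Run repeated simulations and summarise selection performance
#'
#' Draws `n_rep` independent datasets from a scenario, applies each
#' selection method to every replicate, and (optionally) scores an
#' independent same-scenario test cohort with the censoring-adjusted
#' concordance.  Aggregates, per method and subtype: mean selection
#' size, the percentage of replicates in which each planted causal gene
#' is selected, the mean test-set C with its standard error across
#' replicates, and the stability (Rand) index of the gene and set lists
#' across replicates.
#'
#' @param scenario A [sim_scenario()].
#' @param methods Named list of selector functions
#'   `(expr, clinical, sets, fits)` (see [make_forward_selector()]).
#' @param n_rep Number of replicates (default 50).
#' @param seed Base seed; replicate `r` uses `seed + r` for its training
#'   cohort and `seed + r + 500000` for its test cohort.
#' @param null Logical; when `TRUE` survival is generated with all
#'   causal effects zero (the random-guess reference), so any selection
#'   is a false positive.
#' @param test_cohort Logical; set `FALSE` to skip the test cohorts and
#'   the concordance summaries (faster).
#' @return A list of class `replicate_summary` with a `summary`
#'   data.frame (method x subtype rows), per-gene selection frequency
#'   columns, and the raw per-replicate selections.
#' @export
run_replicates <- function(scenario, methods, n_rep = 50L, seed = 1L,
                           null = FALSE, test_cohort = TRUE) {
  stopifnot(inherits(scenario, "sim_scenario"), length(methods) >= 1L)
  if (is.null(names(methods)) || any(!nzchar(names(methods))))
    stop("methods must be a named list")
  causal_genes <- scenario$causal$gene
  recs <- list()
  sel_store <- list()
  for (r in seq_len(n_rep)) {
    d <- simulate_cohort(scenario, null = null, seed = seed + r)
    test <- if (test_cohort)
      simulate_cohort(scenario, null = null, seed = seed + r + 500000L)
    fits <- cox_filter(d$expr, d$clinical)
    for (m in names(methods)) {
      sel <- tryCatch(methods[[m]](d$expr, d$clinical, d$sets, fits),
                      error = function(e) {
                        warning("method '", m, "' failed on replicate ", r,
                                ": ", conditionMessage(e))
                        NULL
                      })
      if (is.null(sel)) next
      test_scores <- if (test_cohort)
        predict_risk(sel, test$expr, test$clinical)
      for (j in c("AC", "SCC")) {
        sj <- sel$subtypes[[j]]
        Cj <- NA_real_
        if (test_cohort) {
          rows <- test$clinical$subtype == j
          if (!length(sj$selected_sets)) {
            Cj <- 0.5  # empty signature scores as a random guess
          } else {
            Cj <- tryCatch(
              uno_c_statistic(test$clinical$time[rows],
                              test$clinical$event[rows],
                              test_scores[rows]),
              error = function(e) NA_real_)
          }
        }
        recs[[length(recs) + 1L]] <- data.frame(
          method = m, subtype = j, replicate = r,
          size = length(sj$selected_genes), C = Cj,
          t(stats::setNames(as.numeric(causal_genes %in% sj$selected_genes),
                            causal_genes)),
          stringsAsFactors = FALSE, check.names = FALSE)
        sel_store[[m]][[j]]$genes[[r]] <- sj$selected_genes
        sel_store[[m]][[j]]$sets[[r]] <- sj$selected_sets
      }
    }
  }
  per_rep <- do.call(rbind, recs)
  summ <- do.call(rbind, lapply(names(methods), function(m) {
    do.call(rbind, lapply(c("AC", "SCC"), function(j) {
      pr <- per_rep[per_rep$method == m & per_rep$subtype == j, ,
                    drop = FALSE]
      if (!nrow(pr)) return(NULL)
      freq <- vapply(causal_genes, function(g) 100 * mean(pr[[g]]), 0)
      # replicates on which the method failed are excluded (left NULL)
      glists <- Filter(Negate(is.null), sel_store[[m]][[j]]$genes)
      slists <- Filter(Negate(is.null), sel_store[[m]][[j]]$sets)
      rand_g <- if (length(glists) >= 2L) rand_index_boot(glists) else
        list(rand = NA_real_, se = NA_real_)
      rand_s <- if (length(slists) >= 2L) rand_index_boot(slists) else
        list(rand = NA_real_, se = NA_real_)
      data.frame(method = m, subtype = j,
                 n_rep = nrow(pr),
                 mean_size = mean(pr$size),
                 t(freq),
                 mean_C = mean(pr$C, na.rm = TRUE),
                 se_C = stats::sd(pr$C, na.rm = TRUE) /
                   sqrt(max(1L, sum(!is.na(pr$C)))),
                 rand_gene = 100 * rand_g$rand,
                 rand_gene_se = 100 * rand_g$se,
                 rand_set = 100 * rand_s$rand,
                 rand_set_se = 100 * rand_s$se,
                 stringsAsFactors = FALSE, check.names = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, per_replicate = per_rep,
                 selections = sel_store, scenario = scenario,
                 n_rep = n_rep, seed = seed, null = null),
            class = "replicate_summary")
}

#' Replicates under the random-guess null
#'
#' Identical to [run_replicates()] except survival times are generated
#' with every causal effect set to zero, so no gene is truly associated
#' with survival and any selection is a false positive.
#'
#' @inheritParams run_replicates
#' @export
run_null_model <- function(scenario, methods, n_rep = 50L, seed = 1L,
                           test_cohort = FALSE) {
  run_replicates(scenario, methods, n_rep = n_rep, seed = seed,
                 null = TRUE, test_cohort = test_cohort)
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("Replicate summary (", x$n_rep, " replicates",
      if (x$null) ", null model" else "", ")\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write a replicate summary as TSV
#'
#' @param x A `replicate_summary`.
#' @param path Output path.
#' @export
write_replicate_summary <- function(x, path) {
  utils::write.table(x$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
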