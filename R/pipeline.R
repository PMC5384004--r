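#' Assemble a run configuration
#'
#' A run operates either on real data (paths to an expression table, a
#' clinical table and a GMT collection) or on a simulation scenario —
#' exactly one of the two.
#'
#' @param expr,clinical,gmt File paths for a real-data run.
#' @param scenario A [sim_scenario()] for a simulation run.
#' @param direction `"forward"` or `"backward"`.
#' @param alpha_gene,alpha_set Fixed cutoffs; ignored when `tune = TRUE`.
#' @param tune Logical; tune the cutoffs by cross-validation.
#' @param folds CV folds used for tuning and stability (default 10).
#' @param n_rep Replicates for a simulation run (default 50).
#' @param null Logical; simulate under the random-guess null.
#' @param seed Integer seed recorded in every output.
#' @param out_dir Output directory (created if absent).
#' @return A list of class `run_config`.
#' @export
run_config <- function(expr = NULL, clinical = NULL, gmt = NULL,
                       scenario = NULL,
                       direction = c("forward", "backward"),
                       alpha_gene = 0.05, alpha_set = 0.05,
                       tune = FALSE, folds = 10L, n_rep = 50L,
                       null = FALSE, seed = 1L, out_dir = ".") {
  direction <- match.arg(direction)
  real <- !is.null(expr) || !is.null(clinical) || !is.null(gmt)
  if (real == !is.null(scenario))
    stop("provide either real-data paths (expr, clinical, gmt) or a ",
         "scenario, not both")
  if (real && (is.null(expr) || is.null(clinical) || is.null(gmt)))
    stop("a real-data run needs all of expr, clinical and gmt")
  structure(list(expr = expr, clinical = clinical, gmt = gmt,
                 scenario = scenario, direction = direction,
                 alpha_gene = alpha_gene, alpha_set = alpha_set,
                 tune = tune, folds = as.integer(folds),
                 n_rep = as.integer(n_rep), null = null,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @keywords internal
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # the hash covers the semantic configuration, not where outputs land
  slim <- config[setdiff(names(config), c("scenario", "out_dir"))]
  if (!is.null(config$scenario))
    slim$scenario <- config$scenario[setdiff(names(config$scenario), "causal")]
  writeLines(jsonlite::toJSON(slim, auto_unbox = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a complete, reproducible analysis
#'
#' Orchestrates the package end to end.  For a real-data configuration:
#' read and align the inputs, scan all genes with the Cox-filter model,
#' (optionally) tune the two cutoffs by cross-validation, run the
#' requested bi-level selection, and measure selection stability over
#' folds.  For a simulation configuration: run the replicate harness
#' (under the null when requested).  All artifacts carry the seed and a
#' hash of the configuration; everything is deterministic given the
#' seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the files written (selection JSON,
#'   TSV tables, log).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  stamp <- list(package = "bilevelcox",
                version = as.character(utils::packageVersion("bilevelcox")),
                seed = config$seed, config_hash = hash)
  out <- list(log = log_path)
  logf("run start (seed ", config$seed, ", config ", hash, ")")
  t0 <- proc.time()[["elapsed"]]

  if (!is.null(config$scenario)) {
    logf("simulation run: ", config$n_rep, " replicates, direction ",
         config$direction, if (config$null) " (null model)" else "")
    selector <- if (config$direction == "forward")
      make_forward_selector(config$alpha_set, config$alpha_gene)
    else
      make_backward_selector(config$alpha_gene, config$alpha_set)
    methods <- stats::setNames(list(selector), config$direction)
    res <- run_replicates(config$scenario, methods, n_rep = config$n_rep,
                          seed = config$seed, null = config$null)
    out$summary <- file.path(config$out_dir, "replicate_summary.tsv")
    write_replicate_summary(res, out$summary)
    out$meta <- file.path(config$out_dir, "run.json")
    jsonlite::write_json(c(stamp, list(mode = "simulation",
                                       n_rep = config$n_rep,
                                       null = config$null)),
                         out$meta, auto_unbox = TRUE, pretty = TRUE)
  } else {
    logf("reading inputs")
    expr <- read_expression(config$expr)
    clinical <- read_clinical(config$clinical)
    sets <- read_gmt(config$gmt)
    aligned <- align_cohort(expr, clinical)
    logf("cohort: ", ncol(aligned$expr), " samples, ",
         nrow(aligned$expr), " genes, ", length(sets), " gene sets")
    fits <- cox_filter(aligned$expr, aligned$clinical)
    out$fits <- file.path(config$out_dir, "gene_cox_fits.tsv")
    write_cox_fits(fits, out$fits)
    alpha_gene <- config$alpha_gene
    alpha_set <- config$alpha_set
    chosen <- list(AC = list(alpha_gene = alpha_gene, alpha_set = alpha_set),
                   SCC = list(alpha_gene = alpha_gene, alpha_set = alpha_set))
    if (config$tune) {
      logf("tuning cutoffs (", config$folds, "-fold CV)")
      tuning <- tune_cutoffs_cv(aligned$expr, aligned$clinical, sets,
                                direction = config$direction,
                                k_folds = config$folds, seed = config$seed)
      chosen <- tuning$chosen
      out$tuning <- file.path(config$out_dir, "tuning.tsv")
      write_tuning(tuning, out$tuning)
    }
    # cutoffs may differ per subtype after tuning; select per subtype and
    # keep each subtype's own slice
    selection <- list(direction = config$direction)
    for (j in c("AC", "SCC")) {
      sel_j <- if (config$direction == "forward")
        forward_select(aligned$expr, aligned$clinical, sets, fits,
                       alpha_set = chosen[[j]]$alpha_set,
                       alpha_gene = chosen[[j]]$alpha_gene)
      else
        backward_select(aligned$expr, aligned$clinical, sets, fits,
                        alpha_gene = chosen[[j]]$alpha_gene,
                        alpha_set = chosen[[j]]$alpha_set)
      selection[[j]] <- list(
        alpha_gene = chosen[[j]]$alpha_gene,
        alpha_set = chosen[[j]]$alpha_set,
        sets = sel_j$subtypes[[j]]$selected_sets,
        genes = sel_j$subtypes[[j]]$selected_genes)
      logf(j, ": ", length(selection[[j]]$sets), " sets, ",
           length(selection[[j]]$genes), " genes")
    }
    out$selection <- file.path(config$out_dir, "selection.json")
    jsonlite::write_json(c(stamp, selection), out$selection,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  logf(sprintf("run complete in %.1f s", proc.time()[["elapsed"]] - t0))
  invisible(out)
}
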