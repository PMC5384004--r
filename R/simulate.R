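#' Define a simulation scenario
#'
#' Describes a synthetic two-subtype expression-plus-survival study:
#' block-correlated expression (genes partitioned into gene sets sharing
#' a latent factor), a small number of planted prognostic genes, and
#' Cox-exponential survival with a calibrated censoring fraction.
#'
#' The default causal structure plants 4 prognostic genes, three of them
#' (`COPA`, `ECE2`, `SMAD4`) in one gene set and the fourth (`ARRB1`) in
#' a different set.  Under `scenario = "exclusive"` the two subtypes
#' have disjoint prognostic genes (`ARRB1`, `ECE2` act in AC only;
#' `COPA`, `SMAD4` in SCC only); under `scenario = "shared"` all four
#' act identically in both subtypes.
#'
#' @param n_AC,n_SCC Cohort sizes per subtype (defaults 70 and 55, the
#'   sizes of a typical early-stage two-subtype RNA-seq cohort).
#' @param n_sets Number of gene sets / correlation blocks (default 100).
#' @param set_size Genes per set; a single integer or a vector of length
#'   `n_sets` (default 10).
#' @param rho Within-set correlation induced by the shared latent factor
#'   (default 0.5); must lie in `[0, 1)`.
#' @param scenario `"exclusive"` (subtype-specific prognostic genes) or
#'   `"shared"` (identical prognostic genes in both subtypes).
#' @param beta Magnitude of the causal log hazard-rate effects (default
#'   1.5, a strong effect; use 0.5 for a moderate one).
#' @param causal Optional `data.frame` overriding the default causal
#'   spec, with columns `gene`, `set_index`, `beta_AC`, `beta_SCC`.
#' @param lambda0 Exponential baseline hazard rate (default 0.1).
#' @param censor_target Expected fraction of censored records in
#'   `[0, 1)` (default 0.30).
#' @param seed Optional seed stored with the scenario; [simulate_cohort()]
#'   applies it.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_AC = 70L, n_SCC = 55L, n_sets = 100L,
                         set_size = 10L, rho = 0.5,
                         scenario = c("exclusive", "shared"),
                         beta = 1.5, causal = NULL, lambda0 = 0.1,
                         censor_target = 0.30, seed = NULL) {
  scenario <- match.arg(scenario)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (censor_target < 0 || censor_target >= 1)
    stop("censor_target must lie in [0, 1)")
  sizes <- rep_len(as.integer(set_size), n_sets)
  if (any(sizes < 1L)) stop("set sizes must be positive")
  if (is.null(causal)) {
    if (n_sets < 2L || sizes[1L] < 3L)
      stop("the default causal spec needs >= 2 sets and >= 3 genes in set 1")
    # signs are aligned for genes acting in the same subtype within the
    # same set: with block correlation, opposing signs inside a set would
    # cancel through the shared latent factor and erase the effect the
    # scenario is meant to plant
    causal <- switch(scenario,
      # disjoint prognostic genes: ARRB1, ECE2 drive AC; COPA, SMAD4 drive SCC
      exclusive = data.frame(
        gene = c("ARRB1", "ECE2", "COPA", "SMAD4"),
        set_index = c(2L, 1L, 1L, 1L),
        beta_AC = beta * c(1, -1, 0, 0),
        beta_SCC = beta * c(0, 0, 1, 1),
        stringsAsFactors = FALSE),
      # identical prognostic genes in both subtypes
      shared = data.frame(
        gene = c("ARRB1", "ECE2", "COPA", "SMAD4"),
        set_index = c(2L, 1L, 1L, 1L),
        beta_AC = beta * c(-1, 1, 1, 1),
        beta_SCC = beta * c(-1, 1, 1, 1),
        stringsAsFactors = FALSE))
  } else {
    need <- c("gene", "set_index", "beta_AC", "beta_SCC")
    if (!all(need %in% names(causal)))
      stop("causal spec needs columns: ", paste(need, collapse = ", "))
    if (any(causal$set_index > n_sets))
      stop("causal set_index exceeds n_sets")
  }
  structure(list(n_AC = as.integer(n_AC), n_SCC = as.integer(n_SCC),
                 n_sets = as.integer(n_sets), set_sizes = sizes,
                 rho = rho, scenario = scenario, causal = causal,
                 lambda0 = lambda0, censor_target = censor_target,
                 seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario (", x$scenario, "): ",
      x$n_AC, " AC + ", x$n_SCC, " SCC samples, ",
      sum(x$set_sizes), " genes in ", x$n_sets, " sets (rho = ", x$rho,
      "), ", nrow(x$causal), " causal genes, target censoring ",
      100 * x$censor_target, "%\n", sep = "")
  invisible(x)
}

#' Generate block-correlated expression and the gene-set collection
#'
#' Genes are partitioned into `n_sets` blocks; within a block every gene
#' is `sqrt(rho) * F + sqrt(1 - rho) * eps` with a shared standard
#' normal latent factor `F` per sample, so genes have mean 0, unit
#' variance and pairwise within-set correlation `rho`.  Causal genes are
#' renamed and placed per the scenario's causal spec.  Uses the current
#' RNG state; seed via [simulate_cohort()] or `set.seed()` for
#' reproducibility.
#'
#' @param scenario A `sim_scenario`.
#' @return A list with `expr` (genes x samples matrix), `sets` (named
#'   list, GMT-compatible), and `labels` (factor of subtypes per
#'   sample).
#' @export
generate_expression <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  n <- scenario$n_AC + scenario$n_SCC
  sizes <- scenario$set_sizes
  n_genes <- sum(sizes)
  set_id <- rep(seq_along(sizes), sizes)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  # rename the leading genes of each causal set to the causal symbols
  for (k in unique(scenario$causal$set_index)) {
    slots <- which(set_id == k)
    symbols <- scenario$causal$gene[scenario$causal$set_index == k]
    gene_ids[slots[seq_along(symbols)]] <- symbols
  }
  sample_ids <- c(sprintf("AC%03d", seq_len(scenario$n_AC)),
                  sprintf("SCC%03d", seq_len(scenario$n_SCC)))
  labels <- factor(rep(c("AC", "SCC"), c(scenario$n_AC, scenario$n_SCC)),
                   levels = c("AC", "SCC"))
  Fk <- matrix(stats::rnorm(scenario$n_sets * n), scenario$n_sets, n)
  eps <- matrix(stats::rnorm(n_genes * n), n_genes, n)
  x <- sqrt(scenario$rho) * Fk[set_id, , drop = FALSE] +
    sqrt(1 - scenario$rho) * eps
  dimnames(x) <- list(gene_ids, sample_ids)
  sets <- split(gene_ids, set_id)
  names(sets) <- sprintf("GS%04d", seq_along(sizes))
  attr(sets, "description") <- stats::setNames(
    sprintf("synthetic block %d", seq_along(sizes)), names(sets))
  list(expr = x, sets = sets, labels = labels)
}

# expected censoring fraction when censoring times are Exp(rate) and the
# event times are the simulated vector tt: P(C < T_i) = 1 - exp(-rate*T_i)
#' @keywords internal
expected_censoring <- function(rate, tt) mean(1 - exp(-rate * tt))

#' Calibrate the exponential censoring rate
#'
#' Root-finds the rate of an exponential censoring distribution so that
#' the expected fraction of censored records, given the simulated event
#' times, equals the target.
#'
#' @param tt Positive event times.
#' @param target Target censoring fraction in `[0, 1)`.
#' @return The censoring rate (0 when `target` is 0).
#' @export
calibrate_censoring <- function(tt, target) {
  if (target == 0) return(0)
  f <- function(log_rate) expected_censoring(exp(log_rate), tt) - target
  lo <- -25; hi <- 25
  if (f(lo) > 0 || f(hi) < 0)
    stop("censoring calibration failed to bracket the target (",
         "target = ", target, ", event-time range = [",
         signif(min(tt), 3), ", ", signif(max(tt), 3), "])")
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Simulate Cox-exponential survival for a generated cohort
#'
#' Event times are drawn by inverse transform from an exponential
#' baseline hazard scaled by the subtype-specific linear predictor:
#' `T = -log(U) / (lambda0 * exp(eta))` with
#' `eta_i = sum_g beta_subtype(i),g * X_ig` over the causal genes.
#' Censoring times are exponential with rate calibrated by root-finding
#' so the expected censoring fraction matches the scenario's target;
#' the observed time is `min(T, C)` and `event = 1` when the death is
#' observed.  Uses the current RNG state.
#'
#' @param expr Genes-by-samples expression matrix from
#'   [generate_expression()].
#' @param labels Subtype factor aligned with the columns of `expr`.
#' @param scenario A `sim_scenario`.
#' @param null Logical; when `TRUE` all causal effects are set to 0
#'   (survival independent of expression), the random-guess reference.
#' @return A clinical `data.frame` (`sample_id`, `time`, `event`,
#'   `subtype`) with the true linear predictor attached as attribute
#'   `linear_predictor`.
#' @export
simulate_survival <- function(expr, labels, scenario, null = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"),
            length(labels) == ncol(expr))
  n <- ncol(expr)
  eta <- numeric(n)
  if (!null) {
    for (r in seq_len(nrow(scenario$causal))) {
      g <- scenario$causal$gene[r]
      if (!g %in% rownames(expr))
        stop("causal gene '", g, "' absent from the generated expression")
      b <- ifelse(labels == "SCC", scenario$causal$beta_SCC[r],
                  scenario$causal$beta_AC[r])
      eta <- eta + b * expr[g, ]
    }
  }
  tt <- -log(stats::runif(n)) / (scenario$lambda0 * exp(eta))
  rate <- calibrate_censoring(tt, scenario$censor_target)
  cc <- if (rate == 0) rep(Inf, n) else stats::rexp(n, rate)
  clin <- data.frame(sample_id = colnames(expr),
                     time = pmin(tt, cc),
                     event = as.integer(tt <= cc),
                     subtype = labels,
                     stringsAsFactors = FALSE)
  clin <- validate_clinical(clin)
  attr(clin, "linear_predictor") <- stats::setNames(eta, colnames(expr))
  clin
}

#' Simulate a complete cohort (expression, gene sets, survival)
#'
#' Convenience wrapper seeding the RNG from the scenario (or the `seed`
#' argument) and chaining [generate_expression()] and
#' [simulate_survival()].
#'
#' @param scenario A `sim_scenario`.
#' @param null Logical; generate survival under the no-association null.
#' @param seed Optional seed overriding the scenario's.
#' @return A list with `expr`, `sets`, `clinical`, and `labels`.
#' @export
simulate_cohort <- function(scenario, null = FALSE, seed = NULL) {
  seed <- if (!is.null(seed)) seed else scenario$seed
  run <- function() {
    gen <- generate_expression(scenario)
    clin <- simulate_survival(gen$expr, gen$labels, scenario, null = null)
    list(expr = gen$expr, sets = gen$sets, clinical = clin,
         labels = gen$labels)
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}
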