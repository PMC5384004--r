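# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (and the survival package where the package
# itself relies on it): the partial likelihood, the censoring Kaplan-Meier
# and the pairwise concordance sums are written out from their definitions.

# Negative log partial likelihood of the three-covariate Cox-filter model,
# Efron handling of tied event times.
bf_neg_logpl <- function(beta, M, time, event) {
  eta <- as.numeric(M %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    d <- length(D)
    R <- which(time >= t)
    sR <- sum(exp(eta[R]))
    sD <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D]) - sum(log(sR - ((seq_len(d) - 1) / d) * sD))
  }
  -ll
}

# Brute-force maximizer: coarse multi-start grid, then quasi-Newton polish.
bf_cox_fit <- function(M, time, event) {
  starts <- as.matrix(expand.grid(b1 = c(-1, 0, 1), b2 = c(-2, 0, 2),
                                  b3 = c(-2, 0, 2)))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], bf_neg_logpl, M = M, time = time,
                   event = event, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  polish <- stats::optim(best$par, bf_neg_logpl, M = M, time = time,
                         event = event, method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-15))
  unname(polish$par)
}

# Hand product-limit estimate of the censoring survival G(t-) (strictly
# before t): censorings are the "events".
bf_G_minus <- function(t0, time, event) {
  g <- 1
  for (s in sort(unique(time))) {
    if (s >= t0) break
    n_s <- sum(time >= s)
    c_s <- sum(time == s & event == 0)
    g <- g * (1 - c_s / n_s)
  }
  g
}

# Brute-force pairwise IPCW concordance sum.
bf_uno_c <- function(time, event, score, tau, floor = 0.05) {
  num <- 0
  den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] >= tau) next
    w <- 1 / max(bf_G_minus(time[i], time, event), floor)^2
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      den <- den + w
      if (score[i] > score[j]) num <- num + w
      else if (score[i] == score[j]) num <- num + w / 2
    }
  }
  num / den
}

# Small aligned cohort for unit tests (no package simulation machinery).
toy_cohort <- function(n = 24, seed = 42, p_gene = 3) {
  set.seed(seed)
  subtype <- rep(c("AC", "SCC"), length.out = n)
  x <- matrix(rnorm(p_gene * n), p_gene, n,
              dimnames = list(paste0("g", seq_len(p_gene)),
                              paste0("s", seq_len(n))))
  eta <- 0.8 * x[1, ] * (subtype == "AC") - 0.8 * x[1, ] * (subtype == "SCC")
  time <- round(-log(runif(n)) / (0.2 * exp(eta)), 4)
  event <- rbinom(n, 1, 0.75)
  if (sum(event) < 4) event[seq_len(4)] <- 1L
  clinical <- data.frame(sample_id = colnames(x), time = time,
                         event = event, subtype = subtype,
                         stringsAsFactors = FALSE)
  list(expr = x, clinical = clinical)
}

# A compact scenario used wherever a full-size simulation is unnecessary.
small_scenario <- function(seed = NULL, ...) {
  args <- utils::modifyList(
    list(n_AC = 60L, n_SCC = 60L, n_sets = 8L, set_size = 5L,
         rho = 0.5, seed = seed),
    list(...))
  do.call(sim_scenario, args)
}
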