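test_that("per-gene fits match a brute-force partial-likelihood maximizer", {
  for (seed in c(5, 17, 29)) {
    tc <- toy_cohort(n = 26, seed = seed)
    cl <- tc$clinical
    x <- tc$expr[1, ]
    fit <- fit_gene_cox(x, cl)
    expect_true(fit$converged)
    M <- cbind(as.numeric(cl$subtype == "SCC"), x,
               x * as.numeric(cl$subtype == "SCC"))
    bf <- bf_cox_fit(M, cl$time, cl$event)
    expect_lt(max(abs(c(fit$beta1, fit$beta2, fit$beta3) - bf)), 1e-3)
  }
})

test_that("a stronger planted effect is recovered on a larger cohort", {
  # single causal gene, beta_AC = 1, beta_SCC = -1, exponential baseline
  set.seed(101)
  n <- 200
  subtype <- rep(c("AC", "SCC"), each = n / 2)
  x <- rnorm(n)
  eta <- ifelse(subtype == "AC", 1, -1) * x
  time <- -log(runif(n)) / (0.1 * exp(eta))
  cl <- data.frame(sample_id = paste0("s", 1:n), time = time,
                   event = rep(1L, n), subtype = subtype)
  fit <- fit_gene_cox(x, cl)
  M <- cbind(as.numeric(subtype == "SCC"), x,
             x * as.numeric(subtype == "SCC"))
  bf <- bf_cox_fit(M, cl$time, cl$event)
  expect_lt(max(abs(c(fit$beta1, fit$beta2, fit$beta3) - bf)), 1e-3)
  # beta_AC near 1, beta_SCC near -1 within sampling error
  expect_lt(abs(fit$beta_AC - 1), 0.35)
  expect_lt(abs(fit$beta_SCC + 1), 0.35)
  expect_equal(fit$beta_SCC, fit$beta2 + fit$beta3)
})

test_that("degenerate and invalid inputs follow the scan policy", {
  tc <- toy_cohort()
  fit <- fit_gene_cox(rep(2, nrow(tc$clinical)), tc$clinical)
  expect_false(fit$converged)
  expect_equal(fit$p_AC, 1)
  expect_equal(fit$p_SCC, 1)

  cl <- tc$clinical
  cl$event <- 0L
  expect_error(fit_gene_cox(tc$expr[1, ], cl), "censored")
  expect_error(fit_gene_cox(tc$expr[1, 1:5], tc$clinical), "length")
})

test_that("location shifts leave effects alone; scaling rescales betas only", {
  tc <- toy_cohort(n = 40, seed = 9)
  x <- tc$expr[1, ]
  f0 <- fit_gene_cox(x, tc$clinical)
  f_shift <- fit_gene_cox(x + 7.3, tc$clinical)
  expect_equal(f_shift$beta2, f0$beta2, tolerance = 1e-6)
  expect_equal(f_shift$beta3, f0$beta3, tolerance = 1e-6)
  expect_equal(f_shift$p_AC, f0$p_AC, tolerance = 1e-6)
  expect_equal(f_shift$p_SCC, f0$p_SCC, tolerance = 1e-6)

  f_scale <- fit_gene_cox(2.5 * x, tc$clinical)
  expect_equal(f_scale$beta2, f0$beta2 / 2.5, tolerance = 1e-6)
  expect_equal(f_scale$beta3, f0$beta3 / 2.5, tolerance = 1e-6)
  expect_equal(f_scale$p_AC, f0$p_AC, tolerance = 1e-5)
  expect_equal(f_scale$p_SCC, f0$p_SCC, tolerance = 1e-5)
})

test_that("subtype Wald construction follows the variance-of-sum identity", {
  w <- test_subtype_effects(0.3, -0.1,
                            matrix(c(0.04, 0.01, 0.01, 0.09), 2))
  expect_equal(w$se_SCC, sqrt(0.15), tolerance = 1e-12)
  expect_equal(w$se_AC, 0.2, tolerance = 1e-12)

  w0 <- test_subtype_effects(0, 0.5, diag(c(0.1, 0.1)))
  expect_equal(w0$p_AC, 1)

  # |z| = 1.959964 is the two-sided 5% point of the normal
  w5 <- test_subtype_effects(1.959964, -1.959964, diag(c(1, 1)))
  expect_equal(w5$p_AC, 0.05, tolerance = 1e-6)

  expect_error(test_subtype_effects(1, 1, matrix(c(-0.1, 0, 0, 1), 2)),
               "variance")
  expect_error(test_subtype_effects(1, 1, matrix(c(1, 0.5, 0, 1), 2)),
               "symmetric")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  p <- c(0.001, 0.2, 0.8)
  expect_true(all(adjust_bh(p) >= p))
  expect_equal(adjust_bh(p, method = "bonferroni"), pmin(1, 3 * p))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("null genes give uniform p-values with nominal type-I control", {
  # one cohort, survival independent of all genes
  set.seed(77)
  n <- 500
  n_genes <- 600
  subtype <- rep(c("AC", "SCC"), each = n / 2)
  cl <- data.frame(sample_id = paste0("s", 1:n),
                   time = rexp(n, 0.1), event = rbinom(n, 1, 0.7),
                   subtype = subtype)
  x <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("g%03d", 1:n_genes), cl$sample_id))
  fits <- cox_filter(x, cl)
  expect_true(all(fits$converged))
  # uniformity assessed at the designed replicate count (200 null genes);
  # the Wald p-value is asymptotic, so a mild finite-sample deviation is
  # detectable with many more replicates
  ks <- suppressWarnings(stats::ks.test(fits$p_AC[1:200], "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(fits$p_AC < 0.05) - 0.05), 0.02)
  expect_lt(abs(mean(fits$p_SCC < 0.05) - 0.05), 0.02)
  # BH q-values never fall below the raw p-values
  expect_true(all(fits$q_AC >= fits$p_AC))
})
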