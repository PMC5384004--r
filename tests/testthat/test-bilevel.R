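test_that("set-level fits agree with gene-level fits on a pseudo-gene", {
  sc <- small_scenario(seed = 31)
  d <- simulate_cohort(sc)
  fits <- cox_filter(d$expr, d$clinical)
  prof <- compute_set_profiles(d$expr, d$sets, fits, d$clinical)
  setfits <- fit_set_cox(prof, d$clinical)
  expect_s3_class(setfits, "set_cox_fits")
  # treating a set's Z column as a single-gene expression vector must give
  # the same model (identical covariates)
  k <- 3L
  g <- fit_gene_cox(prof$Z[, k], d$clinical)
  expect_equal(setfits$beta_AC[k], g$beta_AC, tolerance = 1e-10)
  expect_equal(setfits$p_SCC[k], g$p_SCC, tolerance = 1e-10)

  # constant Z column is a degenerate covariate
  prof0 <- prof
  prof0$Z[, 1] <- 1
  sf0 <- fit_set_cox(prof0, d$clinical)
  expect_false(sf0$converged[1])
  expect_equal(sf0$p_AC[1], 1)
})

test_that("forward selection output respects its structural contract", {
  sc <- small_scenario(seed = 33)
  d <- simulate_cohort(sc)
  fits <- cox_filter(d$expr, d$clinical)
  for (alpha in c(0.05, 0.2)) {
    sel <- forward_select(d$expr, d$clinical, d$sets, fits,
                          alpha_set = alpha, alpha_gene = alpha)
    for (j in c("AC", "SCC")) {
      sj <- sel$subtypes[[j]]
      pool <- unique(unlist(d$sets[sj$selected_sets]))
      expect_true(all(sj$selected_genes %in% pool))
    }
  }
  # a cutoff below any attainable adjusted p-value selects nothing
  sel0 <- forward_select(d$expr, d$clinical, d$sets, fits,
                         alpha_set = 1e-12, alpha_gene = 1e-12)
  expect_length(sel0$subtypes$AC$selected_sets, 0)
  expect_length(sel0$subtypes$AC$selected_genes, 0)
})

test_that("backward selection equals candidates intersected with kept sets", {
  sc <- small_scenario(seed = 35)
  d <- simulate_cohort(sc)
  fits <- cox_filter(d$expr, d$clinical)
  for (ag in c(0.05, 0.2)) {
    sel <- backward_select(d$expr, d$clinical, d$sets, fits,
                           alpha_gene = ag, alpha_set = 0.2)
    for (j in c("AC", "SCC")) {
      sj <- sel$subtypes[[j]]
      expect_setequal(
        sj$selected_genes,
        intersect(sj$candidates, unique(unlist(d$sets[sj$selected_sets]))))
    }
  }
  sel0 <- backward_select(d$expr, d$clinical, d$sets, fits,
                          alpha_gene = 1e-12, alpha_set = 0.2)
  expect_length(sel0$subtypes$SCC$selected_genes, 0)
})

test_that("relaxing the gene cutoff never shrinks the candidate pool", {
  sc <- small_scenario(seed = 37)
  d <- simulate_cohort(sc)
  fits <- cox_filter(d$expr, d$clinical)
  grid <- c(0.01, 0.05, 0.1, 0.15, 0.2)
  for (j in c("AC", "SCC")) {
    prev <- character(0)
    for (ag in grid) {
      sel <- backward_select(d$expr, d$clinical, d$sets, fits,
                             alpha_gene = ag, alpha_set = 0.2)
      cand <- sel$subtypes[[j]]$candidates
      expect_true(all(prev %in% cand))
      prev <- cand
    }
  }
})

test_that("with singleton sets and equal cutoffs both directions coincide", {
  sc <- small_scenario(seed = 39)
  d <- simulate_cohort(sc)
  singletons <- as.list(rownames(d$expr))
  names(singletons) <- paste0("single_", rownames(d$expr))
  fits <- cox_filter(d$expr, d$clinical)
  fw <- forward_select(d$expr, d$clinical, singletons, fits,
                       alpha_set = 0.1, alpha_gene = 0.1)
  bw <- backward_select(d$expr, d$clinical, singletons, fits,
                        alpha_gene = 0.1, alpha_set = 0.1)
  for (j in c("AC", "SCC")) {
    expect_setequal(fw$subtypes[[j]]$selected_genes,
                    bw$subtypes[[j]]$selected_genes)
    expect_setequal(fw$subtypes[[j]]$selected_sets,
                    bw$subtypes[[j]]$selected_sets)
    # both reduce to genome-wide per-gene thresholding
    expect_setequal(fw$subtypes[[j]]$selected_genes,
                    fits$gene_id[fits[[paste0("q_", j)]] <= 0.1 &
                                   fits$converged])
  }
})

test_that("selection is deterministic and risk scoring honors the freeze", {
  sc <- small_scenario(seed = 41)
  d <- simulate_cohort(sc)
  fits <- cox_filter(d$expr, d$clinical)
  s1 <- forward_select(d$expr, d$clinical, d$sets, fits, 0.1, 0.1)
  s2 <- forward_select(d$expr, d$clinical, d$sets, fits, 0.1, 0.1)
  expect_identical(s1$subtypes, s2$subtypes)

  # frozen scoring reproduces beta * Z on the training data itself
  sc_scores <- predict_risk(s1, d$expr, d$clinical)
  j <- "AC"
  rows <- d$clinical$subtype == j
  if (length(s1$subtypes[[j]]$scoring)) {
    manual <- rep(0, sum(rows))
    for (item in s1$subtypes[[j]]$scoring) {
      s <- item$signs
      z <- as.numeric(crossprod(d$expr[names(s), rows, drop = FALSE], s)) /
        length(s)
      manual <- manual + item$beta * z
    }
    expect_equal(unname(sc_scores[rows]), manual)
  }

  # an empty selection scores every patient 0 (uninformative)
  s0 <- forward_select(d$expr, d$clinical, d$sets, fits, 1e-12, 1e-12)
  expect_true(all(predict_risk(s0, d$expr, d$clinical) == 0))
})
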