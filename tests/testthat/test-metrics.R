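test_that("IPCW concordance matches the brute-force pairwise sum", {
  # fixed 5-subject toy
  time <- c(2, 4, 6, 8, 10)
  event <- c(1, 1, 0, 1, 1)
  score <- c(5, 4, 3, 2, 1)
  expect_equal(uno_c_statistic(time, event, score, tau = 10),
               bf_uno_c(time, event, score, tau = 10))
  expect_equal(uno_c_statistic(time, event, score, tau = 10), 1)

  # random instances with censoring and tied scores
  for (seed in c(3, 8, 15)) {
    set.seed(seed)
    n <- 40
    time <- round(rexp(n, 0.2), 2)
    event <- rbinom(n, 1, 0.6)
    score <- sample(seq_len(8), n, replace = TRUE)  # many ties
    tau <- quantile(time, 0.9, names = FALSE)
    expect_equal(uno_c_statistic(time, event, score, tau = tau),
                 bf_uno_c(time, event, score, tau = tau))
  }
})

test_that("concordance is 1 for a perfect score and symmetric under negation", {
  set.seed(5)
  n <- 60
  time <- rexp(n, 0.1)
  event <- rep(1L, n)
  score <- -time          # strictly decreasing in survival time
  tau <- max(time) + 1
  expect_equal(uno_c_statistic(time, event, score, tau = tau), 1)
  sc <- rnorm(n)
  expect_equal(uno_c_statistic(time, event, sc, tau = tau) +
                 uno_c_statistic(time, event, -sc, tau = tau), 1)
  # invariance under strictly increasing transforms
  expect_equal(uno_c_statistic(time, event, exp(sc / 3), tau = tau),
               uno_c_statistic(time, event, sc, tau = tau))
})

test_that("with no censoring the IPCW statistic equals Harrell's C", {
  for (seed in c(2, 9)) {
    set.seed(seed)
    n <- 50
    time <- rexp(n, 0.2)
    event <- rep(1L, n)
    score <- rnorm(n)
    h <- survival::concordance(survival::Surv(time, event) ~ score,
                               reverse = TRUE)$concordance
    expect_equal(uno_c_statistic(time, event, score, tau = max(time) + 1),
                 h, tolerance = 1e-12)
  }
})

test_that("concordance input contracts are enforced", {
  expect_error(uno_c_statistic(c(1, 2), c(1, 1), c(1, 2), tau = -1),
               "tau")
  expect_error(uno_c_statistic(c(1, 2), c(0, 0), c(1, 2), tau = 3),
               "comparable")
})

test_that("the stability index is the mean pairwise Jaccard", {
  expect_equal(rand_index(list(c("g1", "g2", "g3"), c("g2", "g3", "g4"))),
               0.5)
  same <- replicate(4, c("a", "b"), simplify = FALSE)
  expect_equal(rand_index(same), 1)
  disjoint <- list(c("a"), c("b"), c("c"))
  expect_equal(rand_index(disjoint), 0)
  expect_equal(rand_index(list(character(0), character(0))), 1)
  expect_equal(rand_index(list(character(0), "a")), 0)
  expect_error(rand_index(list("a")), "at least 2")

  # permutation invariance and bounds
  set.seed(10)
  lists <- replicate(5, sample(letters, sample(3:8, 1)), simplify = FALSE)
  r <- rand_index(lists)
  expect_equal(rand_index(rev(lists)), r)
  expect_gte(r, 0); expect_lte(r, 1)
})

test_that("random selections agree at the level an independent MC predicts", {
  # rand_index over random 10-subsets of 2000 genes, against a fresh
  # Monte-Carlo estimate of the expected pairwise Jaccard
  genes <- sprintf("g%04d", 1:2000)
  set.seed(11)
  lists <- replicate(40, sample(genes, 10), simplify = FALSE)
  obs <- rand_index(lists)
  mc <- replicate(2000, {
    a <- sample.int(2000, 10); b <- sample.int(2000, 10)
    length(intersect(a, b)) / length(union(a, b))
  })
  expect_lt(abs(obs - mean(mc)), 4 * stats::sd(mc) / sqrt(length(lists)))
})

test_that("stability over folds: constant selector agrees perfectly", {
  sc <- small_scenario(seed = 51)
  d <- simulate_cohort(sc)
  const_sel <- function(expr, clinical, sets, fits) {
    structure(list(direction = "forward",
                   subtypes = list(
                     AC = list(selected_sets = c("GS0001"),
                               selected_genes = c("COPA", "ECE2"),
                               scoring = list()),
                     SCC = list(selected_sets = c("GS0002"),
                                selected_genes = c("ARRB1"),
                                scoring = list()))),
              class = "bilevel_selection")
  }
  st <- stability_over_folds(const_sel, d$expr, d$clinical, d$sets,
                             k_folds = 5, seed = 2)
  expect_equal(st$AC$rand_gene, 1)
  expect_equal(st$AC$rand_set, 1)
  expect_equal(st$SCC$rand_gene, 1)
  expect_length(st$AC$gene_lists, 5)
})
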