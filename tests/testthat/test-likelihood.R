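test_that("node-local likelihoods match the closed forms", {
  eps <- 0.1; delta <- 0.2
  # single gene observed 1: the driver explains it
  expect_equal(node_local_likelihoods(1, 1, eps, delta),
               c(lambda = 1 - delta, gamma = eps))
  # two genes, both observed 0: a false negative on the (unidentified) driver
  expect_equal(node_local_likelihoods(c(0, 0), c(1, 1), eps, delta),
               c(lambda = delta * (1 - eps), gamma = (1 - eps)^2))
  # two genes, both observed 1: one is the driver, the other a false positive
  expect_equal(node_local_likelihoods(c(1, 1), c(1, 1), eps, delta),
               c(lambda = (1 - delta) * eps, gamma = eps^2))
  # unequal weights shift the mixture
  expect_equal(node_local_likelihoods(c(1, 0), c(3, 1), eps, delta),
               c(lambda = 0.75 * (1 - delta) * (1 - eps) + 0.25 * delta * eps,
                 gamma = eps * (1 - eps)))
  expect_error(node_local_likelihoods(c(1, 0), c(0, 0), eps, delta), "positive")
})

test_that("tumor likelihood handles pure-background and deterministic cases", {
  genes <- c("a", "b", "c")
  all_pass <- progression_model(list(character(0)), NA_integer_, NA_real_,
                                passengers = genes, genes = genes)
  expect_equal(tumor_log_likelihood(c(1, 0, 1), all_pass, eps = 0.1, delta = 0.3),
               2 * log(0.1) + log(0.9))
  # chain with f = 0.5 on both edges and (almost) no noise: only the state
  # "both fired" explains the row (1,1), with probability 0.25
  expect_equal(tumor_log_likelihood(c(1, 1), chain2(), eps = 1e-6, delta = 1e-6),
               log(0.25), tolerance = 1e-4)
  expect_error(tumor_log_likelihood(c(1, 1), chain3(), eps = .1, delta = .1),
               "3 genes")
})

test_that("dataset likelihood is the sum over independent tumors", {
  m <- vee_model()
  set.seed(11)
  B <- simulate_cohort(m, 6, 0.1, 0.1)
  alpha <- gene_rates(B)
  per_row <- vapply(seq_len(nrow(B)), function(i)
    tumor_log_likelihood(B[i, ], m, alpha, eps = 0.1, delta = 0.1), 0)
  expect_equal(dataset_log_likelihood(B, m, alpha, 0.1, 0.1), sum(per_row))
  # a duplicated tumor contributes exactly twice
  B2 <- rbind(B, B[3, , drop = FALSE])
  rownames(B2) <- paste0("t", 1:7)
  expect_equal(dataset_log_likelihood(B2, m, alpha, 0.1, 0.1),
               sum(per_row) + per_row[3])
  # single-row matrix equals the row likelihood
  B1 <- B[1, , drop = FALSE]
  expect_equal(dataset_log_likelihood(B1, m, alpha, 0.1, 0.1), per_row[1])
})

test_that("the DP equals brute-force marginalisation and is normalised", {
  set.seed(12)
  models <- list(vee_model(), bushy_model(), random_model(6), random_model(5))
  for (m in models) {
    N <- length(m$genes)
    alpha <- stats::setNames(stats::runif(N, 0.5, 2), m$genes)
    enum <- oracle_enumerate_states(m, alpha)
    rows <- all_rows(N)
    idx <- sample.int(nrow(rows), min(24, nrow(rows)))
    for (i in idx) {
      dp <- exp(tumor_log_likelihood(rows[i, ], m, alpha, eps = 0.07, delta = 0.12))
      expect_equal(dp, oracle_row_lik(rows[i, ], enum, 0.07, 0.12),
                   tolerance = 1e-10)
      expect_lte(dp, 1)
      expect_gt(dp, 0)
    }
  }
})

test_that("a noise-free row's likelihood approaches its generative probability", {
  m <- vee_model(f = c(0.7, 0.5))
  enum <- oracle_enumerate_states(m)
  # pick the state a, then c fired (a chosen within node 2 with prob 1/2)
  row <- c(a = 1, b = 0, c = 1, p1 = 0)
  i <- which(apply(enum$states, 1, function(s) all(s == row)))
  expect_equal(tumor_log_likelihood(row, m, eps = 1e-6, delta = 1e-6),
               log(enum$probs[i]), tolerance = 1e-4)
})
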