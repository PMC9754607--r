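test_that("minimum-error explanations match small-case enumeration", {
  # a row generated by the model needs no errors
  m <- vee_model()
  set.seed(21)
  for (i in 1:5) {
    r <- sample_tumor(m)
    t <- min_error_assignment(r, m)
    expect_equal(t$fp + t$fn, 0)
  }
  # passenger ones are always false positives
  single <- progression_model(list(character(0), "g"), c(NA, 1L), c(NA, .5),
                              passengers = "p", genes = c("g", "p"))
  t <- min_error_assignment(c(1, 1), single)
  expect_equal(t$fp, 1)
  expect_equal(t$fn, 0)
  # chain with row (0,1): one error either way; the tie-break avoids the FN
  t <- min_error_assignment(c(0, 1), chain2())
  expect_equal(t$fp + t$fn, 1)
  expect_equal(t$fn, 0)
})

test_that("min-error totals equal exhaustive minimisation on random models", {
  set.seed(22)
  for (i in 1:10) {
    m <- random_model(sample(3:7, 1))
    enum <- oracle_enumerate_states(m)
    rows <- all_rows(length(m$genes))
    for (j in sample.int(nrow(rows), min(12, nrow(rows)))) {
      mine <- min_error_assignment(rows[j, ], m)
      orac <- oracle_min_error(rows[j, ], enum)
      expect_equal(mine$fp + mine$fn, unname(orac["total"]))
      expect_equal(mine$fn, unname(orac["fn"]))
      # zero errors iff the row is a reachable noise-free vector
      reachable <- any(apply(enum$states, 1, function(s) all(s == rows[j, ])))
      expect_equal(mine$fp + mine$fn == 0, reachable)
    }
  }
})

test_that("empirical error rates follow the minimum-error tallies", {
  m <- vee_model()
  set.seed(23)
  B <- sample_tumors(m, 40)
  expect_equal(empirical_error_rates(B, m), c(eps = 1e-6, delta = 1e-6))
  # every tumor mutated in the driver and the passenger: all passenger ones
  # are FPs over the N - 1 true-zero positions per tumor, capped at 0.5
  single <- progression_model(list(character(0), "g"), c(NA, 1L), c(NA, .5),
                              passengers = "p", genes = c("g", "p"))
  Bones <- matrix(1L, 10, 2, dimnames = list(paste0("t", 1:10), c("g", "p")))
  expect_equal(empirical_error_rates(Bones, single), c(eps = 0.5, delta = 1e-6))
})

test_that("empirical rates are downward-biased but track the FP truth", {
  truth <- make_fixture("linear")
  set.seed(24)
  B <- simulate_cohort(truth, 500, 0.05, 0.05)
  ed <- empirical_error_rates(B, truth)
  expect_gte(ed[["eps"]], 0.3 * 0.05)
  expect_lte(ed[["eps"]], 1.2 * 0.05)
  # the minimum-error explanation reroutes most false negatives (an unseen
  # fired node costs nothing unless a descendant fired), so delta-hat only
  # admits an upper bracket
  expect_lte(ed[["delta"]], 1.2 * 0.05)
  expect_gt(ed[["delta"]], 1e-6)
})

test_that("fine-tuning never decreases the likelihood and leaves optima alone", {
  m <- chain2(f = c(0.7, 0.5))
  set.seed(25)
  B <- simulate_cohort(m, 80, 0.03, 0.03)
  alpha <- gene_rates(B)
  ll_at <- function(eps, delta) {
    mm <- m
    mm$f <- tomexo:::empirical_firing_probs(B, m, eps, delta)
    dataset_log_likelihood(B, mm, alpha, eps, delta)
  }
  # ascent contract from a far-off start
  ft <- finetune_error_rates(B, m, alpha, eps0 = 0.4, delta0 = 0.4)
  expect_gte(ft$log_lik, ll_at(0.4, 0.4))
  expect_gt(ft$log_lik, ll_at(0.4, 0.4))
  # starting at a grid-search optimum, the tuner barely moves
  grid <- seq(0.005, 0.2, by = 0.005)
  vals <- outer(grid, grid, Vectorize(ll_at))
  top <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  e0 <- grid[top[1]]; d0 <- grid[top[2]]
  ft2 <- finetune_error_rates(B, m, alpha, eps0 = e0, delta0 = d0)
  expect_lt(abs(ft2$eps - e0), 1e-2)
  expect_lt(abs(ft2$delta - d0), 1e-2)
  expect_gte(ft2$log_lik, max(vals))
})
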