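test_that("relation sets enumerate within-node pairs and ancestor pairs", {
  st <- star_tree(c("a", "b", "c"))
  rs <- relation_sets(st)
  expect_equal(nrow(rs$me_pairs), 0)
  expect_equal(nrow(rs$pr_pairs), 0)

  rs2 <- relation_sets(vee_model())   # root -> {a,b} -> {c}
  expect_equal(rs2$me_pairs, matrix(c("a", "b"), 1, 2,
                                    dimnames = list(NULL, c("g1", "g2"))))
  expect_setequal(paste(rs2$pr_pairs[, 1], rs2$pr_pairs[, 2]),
                  c("a c", "b c"))

  rs3 <- relation_sets(chain3())
  expect_equal(nrow(rs3$pr_pairs), 3)
})

test_that("F-scores reward exact recovery and zero the star tree", {
  truth <- vee_model()
  expect_equal(unname(f_scores(truth, truth)), c(1, 1, 1))
  star <- star_tree(truth$genes)
  expect_equal(unname(f_scores(star, truth)[["F_overall"]]), 0)
  # two empty relation sets agree perfectly
  expect_equal(unname(f_scores(star, star)), c(1, 1, 1))
  expect_error(f_scores(star_tree(c("x", "y")), truth), "universe")
})

test_that("partial recovery matches the hand-computed harmonic mean", {
  # truth: {a,b} -> {c,d}; prediction keeps the ME pairs but only half of
  # the four progression pairs
  truth <- progression_model(
    nodes = list(character(0), c("a", "b"), c("c", "d")),
    parent = c(NA, 1L, 2L), f = c(NA, .5, .5),
    passengers = c("e", "f"), genes = letters[1:6])
  pred <- progression_model(
    nodes = list(character(0), c("a", "b"), c("c", "d")),
    parent = c(NA, 1L, 1L), f = c(NA, .5, .5),
    passengers = c("e", "f"), genes = letters[1:6])
  # prediction implies no PR pairs at all -> F_PR = 0
  sc <- f_scores(pred, truth)
  expect_equal(unname(sc), c(1, 0, 0))
  # split {c,d} into two children of {a,b}: all four ancestor pairs are kept
  # but the (c,d) exclusivity pair is lost
  pred2 <- progression_model(
    nodes = list(character(0), c("a", "b"), "c", "d"),
    parent = c(NA, 1L, 2L, 2L), f = c(NA, .5, .5, .5),
    passengers = c("e", "f"), genes = letters[1:6])
  sc2 <- f_scores(pred2, truth)
  expect_equal(sc2[["F_ME"]], 2 * 1 * 0.5 / 1.5)   # keeps {a,b}, misses {c,d}
  expect_equal(sc2[["F_PR"]], 1)                   # all four ancestor pairs kept
  expect_equal(sc2[["F_overall"]],
               2 * sc2[["F_ME"]] * sc2[["F_PR"]] / (sc2[["F_ME"]] + sc2[["F_PR"]]))
})

make_B <- function(u, v, labels = c("u", "v")) {
  B <- cbind(as.integer(u), as.integer(v))
  dimnames(B) <- list(paste0("t", seq_len(nrow(B))), labels)
  B
}

test_that("progression score follows the conditional-rate contrast", {
  # 20 tumors: source in 10; target in 8 of those and 2 of the rest
  u <- rep(c(1, 0), each = 10)
  v <- c(rep(1, 8), 0, 0, 1, 1, rep(0, 8))
  B <- make_B(u, v)
  expect_equal(progression_score(B, "u", "v"), (0.8 - 0.2) / (0.8 + 0.2))
  # target only with source: perfect score
  expect_equal(progression_score(make_B(c(1, 1, 0, 0), c(1, 1, 0, 0)), "u", "v"), 1)
  # equal conditional rates: zero
  expect_equal(progression_score(make_B(c(1, 1, 0, 0), c(1, 0, 1, 0)), "u", "v"), 0)
  # degenerate conditioning
  expect_true(is.na(progression_score(make_B(c(1, 1, 1, 1), c(1, 0, 1, 0)), "u", "v")))
  expect_error(progression_score(B, character(0), "v"), "non-empty")
})

test_that("mutual-exclusivity score averages both directions", {
  # perfectly exclusive pair
  B <- make_B(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 0), c("g", "w"))
  expect_equal(mutual_exclusivity_score(B, "g", "w"), 1)
  expect_equal(mutual_exclusivity_score(B, "w", "g"), 1)
  # hand-computed asymmetric case: g in 10, w in 10, overlap 2, M = 40
  g <- c(rep(1, 10), rep(0, 30))
  w <- c(rep(1, 2), rep(0, 8), rep(1, 8), rep(0, 22))
  B2 <- make_B(g, w, c("g", "w"))
  d <- ((8 / 30 - 2 / 10) / (8 / 30 + 2 / 10))
  expect_equal(mutual_exclusivity_score(B2, "g", "w"), d)  # symmetric counts
  # single-gene node has no pairwise score
  expect_true(is.na(node_me_score(B2, "g")))
})

test_that("binomial tail p-values match direct summation", {
  # no co-occurrence: the upper tail covers everything
  B <- make_B(c(1, 1, 0, 0), c(0, 0, 1, 0))
  expect_equal(progression_pvalue(B, "u", "v"), 1)
  # all 10 source tumors carry the target at overall rate one half
  u <- rep(c(1, 0), each = 10)
  v <- c(rep(1, 10), rep(0, 10))
  expect_equal(progression_pvalue(make_B(u, v), "u", "v"), 0.5^10)
  # ME single-term case: no overlap at target rate one half
  g <- rep(c(1, 0), each = 10)
  w <- c(rep(0, 10), rep(1, 10))
  B3 <- make_B(g, w, c("g", "w"))
  expect_equal(tomexo:::me_pvalue_direction(B3, "g", "w"), 0.5^10)
  # random tables against the explicit sums
  set.seed(71)
  for (i in 1:25) {
    M <- sample(10:60, 1)
    u <- rbinom(M, 1, 0.5); v <- rbinom(M, 1, 0.4)
    if (sum(u) == 0 || sum(v) == 0) next
    B4 <- make_B(u, v)
    expect_equal(progression_pvalue(B4, "u", "v"),
                 oracle_upper_tail(sum(u & v), sum(u), mean(v)),
                 tolerance = 1e-12)
    expect_equal(tomexo:::me_pvalue_direction(B4, "u", "v"),
                 oracle_lower_tail(sum(u & v), sum(u), mean(v)),
                 tolerance = 1e-12)
    # symmetrised pair value
    expect_equal(mutual_exclusivity_pvalue(B4, "u", "v"),
                 mutual_exclusivity_pvalue(B4, "v", "u"))
    # the two directed progression scores share a sign
    s1 <- progression_score(B4, "u", "v"); s2 <- progression_score(B4, "v", "u")
    if (!is.na(s1) && !is.na(s2) && s1 != 0 && s2 != 0)
      expect_equal(sign(s1), sign(s2))
  }
})

test_that("score reports annotate edges and multi-gene nodes", {
  set.seed(72)
  truth <- vee_model(f = c(0.8, 0.6))
  B <- simulate_cohort(truth, 300, 0.02, 0.02)
  rep_ <- score_report(B, truth)
  expect_equal(nrow(rep_$edges), 1)         # {a,b} -> {c}
  expect_equal(nrow(rep_$nodes), 1)         # {a,b}
  expect_gt(rep_$edges$lambda_pr, 0.3)      # real progression signal
  expect_lt(rep_$edges$p_pr, 0.01)
  expect_gt(rep_$nodes$lambda_me, 0.3)      # real exclusivity signal
  expect_equal(rep_$n_tests, nrow(rep_$edges) + nrow(rep_$me_pairs))
})
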