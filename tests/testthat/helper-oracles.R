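# Independent brute-force oracles used to check the dynamic programs.
# These enumerate the generative process directly and never call the
# package's DP code paths.

# All noise-free tumor vectors a model can generate, with probabilities.
# Returns list(states = 0/1 matrix with one row per distinct vector in the
# model's canonical gene order, probs = exact state probabilities).
oracle_enumerate_states <- function(model, alpha = NULL) {
  N <- length(model$genes)
  V <- length(model$nodes)
  kids <- vector("list", V)
  if (V >= 2) for (v in 2:V) kids[[model$parent[v]]] <- c(kids[[model$parent[v]]], v)
  node_weights <- function(v) {
    g <- model$nodes[[v]]
    w <- if (is.null(alpha)) rep(1, length(g)) else alpha[g]
    w / sum(w)
  }
  combine <- function(opt_list) {
    mat <- matrix(0, 1, N); prob <- 1
    for (opt in opt_list) {
      n1 <- nrow(mat); n2 <- nrow(opt$mat)
      mat <- mat[rep(seq_len(n1), times = n2), , drop = FALSE] +
        opt$mat[rep(seq_len(n2), each = n1), , drop = FALSE]
      prob <- rep(prob, times = n2) * rep(opt$prob, each = n1)
    }
    list(mat = mat, prob = prob)
  }
  sub_opts <- function(v) {
    comb <- combine(lapply(kids[[v]], sub_opts))
    w <- node_weights(v)
    genes_idx <- match(model$nodes[[v]], model$genes)
    fired_mat <- NULL; fired_prob <- numeric(0)
    for (gi in seq_along(genes_idx)) {
      m <- comb$mat
      m[, genes_idx[gi]] <- m[, genes_idx[gi]] + 1
      fired_mat <- rbind(fired_mat, m)
      fired_prob <- c(fired_prob, model$f[v] * w[gi] * comb$prob)
    }
    list(mat = rbind(matrix(0, 1, N), fired_mat),
         prob = c(1 - model$f[v], fired_prob))
  }
  res <- combine(lapply(kids[[1]], sub_opts))
  key <- apply(res$mat, 1, paste, collapse = "")
  probs <- tapply(res$prob, key, sum)
  states <- do.call(rbind, lapply(names(probs), function(k)
    as.integer(strsplit(k, "")[[1]])))
  colnames(states) <- model$genes
  list(states = states, probs = as.numeric(probs))
}

# Brute-force marginal likelihood of one observed row: sum over the
# enumerated noise-free states of p(state) * p(row | state, eps, delta).
oracle_row_lik <- function(row, enum, eps, delta) {
  tot <- 0
  for (i in seq_len(nrow(enum$states))) {
    s <- enum$states[i, ]
    n_fp <- sum(row == 1 & s == 0)
    n_00 <- sum(row == 0 & s == 0)
    n_11 <- sum(row == 1 & s == 1)
    n_fn <- sum(row == 0 & s == 1)
    tot <- tot + enum$probs[i] *
      eps^n_fp * (1 - eps)^n_00 * (1 - delta)^n_11 * delta^n_fn
  }
  tot
}

# Brute-force minimum number of errors explaining a row, and the fp/fn split
# of the distinguished minimiser (fewest false negatives among minima).
oracle_min_error <- function(row, enum) {
  best <- c(total = Inf, fp = Inf, fn = Inf)
  for (i in seq_len(nrow(enum$states))) {
    s <- enum$states[i, ]
    fp <- sum(row == 1 & s == 0)
    fn <- sum(row == 0 & s == 1)
    if (fp + fn < best["total"] ||
        (fp + fn == best["total"] && fn < best["fn"])) {
      best <- c(total = fp + fn, fp = fp, fn = fn)
    }
  }
  best
}

all_rows <- function(N) {
  as.matrix(expand.grid(rep(list(0:1), N)))[, N:1, drop = FALSE]
}

# Direct-summation binomial tails (independent of stats::pbinom)
oracle_upper_tail <- function(k, n, p) {
  if (k > n) return(0)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}
oracle_lower_tail <- function(k, n, p) {
  sum(choose(n, 0:k) * p^(0:k) * (1 - p)^(n - (0:k)))
}
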