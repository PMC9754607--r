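# Empirical error-rate estimation: a post-order dynamic program finds, per
# tumor, the reachable noise-free vector that explains the observed row with
# the fewest false positives + false negatives. Summed tallies give fast
# plug-in estimates of (eps, delta) used inside every MCMC iteration; a final
# gradient ascent on the exact likelihood refines them for the selected model.

# Vectorised min-error DP over all tumors. Two states per node: "off" (all
# observed ones in the node are FPs) and "on" (one gene is the true driver:
# o-1 FPs when some 1 is observed, otherwise 1 FN). Ties in total cost prefer
# fewer false negatives; a remaining tie prefers "off" (fewer mutated nodes).
min_error_tallies_all <- function(B, model, arr = NULL) {
  if (is.null(arr))
    arr <- model_arrays(B, model, stats::setNames(rep(1, ncol(B)), colnames(B)))
  M <- arr$M; N <- arr$N; V <- arr$V
  pass_ones <- arr$pass_ones
  if (V == 1) {
    return(list(fp = pass_ones, fn = numeric(M),
                n_true_one = numeric(M), n_true_zero = rep(N, M)))
  }
  O <- arr$O
  cost_off <- fn_off <- non_off <- matrix(0, M, V)
  cost_on <- fn_on <- non_on <- matrix(0, M, V)
  kids <- arr$kids
  for (v in arr$po) {
    co <- O[, v]; fo <- rep(0, M); no <- rep(0, M)
    has1 <- O[, v] >= 1
    cn <- ifelse(has1, O[, v] - 1, 1)
    fnv <- as.numeric(!has1)
    nn <- rep(1, M)
    for (u in kids[[v]]) {
      don <- cost_on[, u]; doff <- cost_off[, u]
      sel <- don < doff | (don == doff & fn_on[, u] < fn_off[, u])
      cn <- cn + doff + sel * (don - doff)
      fnv <- fnv + fn_off[, u] + sel * (fn_on[, u] - fn_off[, u])
      nn <- nn + non_off[, u] + sel * (non_on[, u] - non_off[, u])
      co <- co + doff; fo <- fo + fn_off[, u]; no <- no + non_off[, u]
    }
    cost_off[, v] <- co; fn_off[, v] <- fo; non_off[, v] <- no
    cost_on[, v] <- cn; fn_on[, v] <- fnv; non_on[, v] <- nn
  }
  tot_cost <- pass_ones; tot_fn <- rep(0, M); tot_non <- rep(0, M)
  for (u in kids[[1]]) {
    don <- cost_on[, u]; doff <- cost_off[, u]
    sel <- don < doff | (don == doff & fn_on[, u] < fn_off[, u])
    tot_cost <- tot_cost + doff + sel * (don - doff)
    tot_fn <- tot_fn + fn_off[, u] + sel * (fn_on[, u] - fn_off[, u])
    tot_non <- tot_non + non_off[, u] + sel * (non_on[, u] - non_off[, u])
  }
  list(fp = tot_cost - tot_fn, fn = tot_fn,
       n_true_one = tot_non, n_true_zero = N - tot_non)
}

#' Minimum-error explanation of one tumor
#'
#' Over all noise-free vectors the model can generate, finds one that
#' minimises the number of false positives plus false negatives needed to
#' produce the observed row, by a single post-order traversal of the driver
#' tree. Ties in total error prefer fewer false negatives.
#'
#' @param row 0/1 vector in the model's canonical gene order.
#' @param model a `tomexo_model`.
#' @return a list with `fp`, `fn`, `n_true_one`, `n_true_zero`: the error
#'   counts of the minimising assignment and the implied numbers of true-one /
#'   true-zero positions in the explaining noise-free vector.
#' @export
min_error_assignment <- function(row, model) {
  B <- matrix(as.numeric(row), 1, length(row),
              dimnames = list("t1", model$genes))
  lapply(min_error_tallies_all(B, model), function(x) unname(x[1]))
}

#' Dataset error tally under a fixed structure
#'
#' Sums the per-tumor minimum-error tallies; the totals are the smallest
#' numbers of false positives and false negatives with which the whole matrix
#' can fully conform with the progression structure.
#'
#' @inheritParams empirical_error_rates
#' @return list with totals `fp`, `fn`, `n_true_one`, `n_true_zero`.
#' @export
error_tally <- function(B, model, arr = NULL) {
  t <- min_error_tallies_all(B, model, arr)
  list(fp = sum(t$fp), fn = sum(t$fn),
       n_true_one = sum(t$n_true_one), n_true_zero = sum(t$n_true_zero))
}

#' Empirical error-rate estimates
#'
#' Plug-in estimates from the minimum-error explanation of the data:
#' `eps = FP / #true-zero positions`, `delta = FN / #true-one positions`,
#' floored at 1e-6 and capped at 0.5. Because the explanation uses the fewest
#' errors consistent with the structure, both estimates are biased downward;
#' they are refined by [finetune_error_rates()] on the selected model.
#'
#' @param B binary mutation matrix.
#' @param model a `tomexo_model`.
#' @param arr optional precomputed count arrays (internal fast path).
#' @return named numeric `c(eps = ..., delta = ...)`.
#' @export
empirical_error_rates <- function(B, model, arr = NULL) {
  tl <- error_tally(B, model, arr)
  eps <- if (tl$n_true_zero > 0) tl$fp / tl$n_true_zero else ERR_FLOOR
  delta <- if (tl$n_true_one > 0) tl$fn / tl$n_true_one else ERR_FLOOR
  c(eps = clamp_error_rate(eps), delta = clamp_error_rate(delta))
}

#' Fine-tune error rates by gradient ascent
#'
#' Maximises the dataset log-likelihood over `(eps, delta)` for a fixed
#' structure. The rates are parameterised as `0.5 * plogis(x)` so the search
#' is unconstrained on the logit scale while the rates stay inside
#' `(0, 0.5)`; gradients are central finite differences and each step is
#' backtracked until the likelihood does not decrease, so the returned
#' likelihood is never below the starting one. Firing probabilities are
#' re-estimated empirically at every candidate `(eps, delta)` (the model class
#' ties them to the error rates), making the objective a profile likelihood.
#'
#' @param B binary mutation matrix.
#' @param model a `tomexo_model`.
#' @param alpha gene-rate weights.
#' @param eps0,delta0 starting values in (0, 0.5].
#' @param control list overriding `step` (initial step, 0.1), `max_iter`
#'   (200), `h` (finite-difference width, 1e-5) and `tol` (stop when the
#'   likelihood gain falls below it, 1e-8).
#' @return list with `eps`, `delta`, `log_lik`, `iterations`, and `model`
#'   (the input structure with firing probabilities refreshed at the tuned
#'   rates).
#' @export
finetune_error_rates <- function(B, model, alpha = gene_rates(B),
                                 eps0, delta0, control = list()) {
  ctl <- utils::modifyList(
    list(step = 0.1, max_iter = 200, h = 1e-5, tol = 1e-8), control)
  arr <- model_arrays(B, model, alpha)
  ind <- if (arr$V > 1) arr$O > 0 else matrix(FALSE, arr$M, 1)
  obj <- function(x) {
    eps <- max(0.5 * stats::plogis(x[1]), ERR_FLOOR)
    delta <- max(0.5 * stats::plogis(x[2]), ERR_FLOOR)
    f <- empirical_firing_probs(B, model, eps, delta, ind = ind)
    sum(loglik_from_arrays(arr, f, eps, delta))
  }
  to_x <- function(r) stats::qlogis(pmin(pmax(r, ERR_FLOOR), 0.5 - 1e-9) / 0.5)
  x <- c(to_x(eps0), to_x(delta0))
  cur <- obj(x)
  if (!is.finite(cur)) stop("non-finite likelihood at the starting error rates")
  # a start at the boundary has a vanishing logit-scale gradient; offer an
  # interior start as well and keep whichever scores higher
  x_int <- c(to_x(max(eps0, 0.005)), to_x(max(delta0, 0.005)))
  v_int <- obj(x_int)
  if (is.finite(v_int) && v_int > cur) { x <- x_int; cur <- v_int }
  iters <- 0L
  for (it in seq_len(ctl$max_iter)) {
    iters <- it
    g <- numeric(2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- ctl$h
      g[j] <- (obj(x + e) - obj(x - e)) / (2 * ctl$h)
    }
    t <- ctl$step
    improved <- FALSE
    while (t >= 1e-10) {
      cand <- x + t * g
      val <- obj(cand)
      if (is.finite(val) && val >= cur) {
        improved <- val - cur > ctl$tol
        x <- cand
        cur <- val
        break
      }
      t <- t / 2
    }
    if (!improved) break
  }
  eps <- 0.5 * stats::plogis(x[1]); delta <- 0.5 * stats::plogis(x[2])
  out_model <- model
  out_model$f <- empirical_firing_probs(B, model, eps, delta, ind = ind)
  list(eps = eps, delta = delta, log_lik = cur, iterations = iters,
       model = out_model)
}
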