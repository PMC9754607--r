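# Metropolis-Hastings sampler over progression models. The sampled space is
# the structure (topology + gene assignment) only: firing probabilities and
# the error rates (eps, delta) are deterministic functions of structure and
# data (empirical estimates), so every visited model carries them implicitly.

#' Build a sampler state for a structure
#'
#' Attaches to the structure its empirical error rates, empirical firing
#' probabilities, log-likelihood, log-prior and cached log-posterior.
#'
#' @param B binary mutation matrix.
#' @param model a `tomexo_model` (its `f` entries are replaced).
#' @param alpha gene-rate weights.
#' @param zeta prior strength.
#' @return list with `model`, `eps`, `delta`, `log_lik`, `log_prior`,
#'   `log_post`.
#' @export
mcmc_state <- function(B, model, alpha = gene_rates(B), zeta = 5) {
  arr <- model_arrays(B, model, alpha)
  ed <- empirical_error_rates(B, model, arr)
  ind <- if (arr$V > 1) arr$O > 0 else matrix(FALSE, arr$M, 1)
  model$f <- empirical_firing_probs(B, model, ed[["eps"]], ed[["delta"]], ind = ind)
  ll <- sum(loglik_from_arrays(arr, model$f, ed[["eps"]], ed[["delta"]]))
  lp <- log_prior(model, zeta)
  list(model = model, eps = ed[["eps"]], delta = ed[["delta"]],
       log_lik = ll, log_prior = lp, log_post = ll + lp)
}

#' One Metropolis-Hastings step
#'
#' Draws a structural proposal, recomputes the proposal's empirical firing
#' probabilities, error rates, likelihood and prior, and accepts with
#' probability `min(1, exp(delta log-posterior + log Hastings correction))`.
#' A proposal with non-finite posterior is rejected with a warning.
#'
#' @param state a state from [mcmc_state()].
#' @param B binary mutation matrix.
#' @param alpha gene-rate weights.
#' @param zeta prior strength.
#' @return list `(state, accepted, type)`.
#' @export
mh_step <- function(state, B, alpha = gene_rates(B), zeta = 5) {
  prop <- propose_move(state$model)
  cand <- mcmc_state(B, prop$model, alpha, zeta)
  if (!is.finite(cand$log_post)) {
    warning("proposal with non-finite posterior rejected")
    return(list(state = state, accepted = FALSE, type = prop$type))
  }
  log_acc <- (cand$log_post - state$log_post) + (prop$log_bwd - prop$log_fwd)
  if (is.nan(log_acc)) {
    warning("non-finite acceptance ratio; proposal rejected")
    return(list(state = state, accepted = FALSE, type = prop$type))
  }
  if (log(stats::runif(1)) < log_acc) {
    list(state = cand, accepted = TRUE, type = prop$type)
  } else {
    list(state = state, accepted = FALSE, type = prop$type)
  }
}

#' Run one MCMC chain
#'
#' Starts from the star tree (every gene in its own first-layer node, no
#' passengers), runs the requested number of Metropolis-Hastings iterations,
#' and tracks the maximum-posterior structure over all visited states
#' (including the initial one). Fully reproducible given `seed`.
#'
#' @param B binary mutation matrix.
#' @param iterations number of MH steps.
#' @param zeta prior strength (default 5).
#' @param seed integer seed for the chain; `NULL` uses the current RNG state.
#' @param alpha gene-rate weights.
#' @param init optional initial `tomexo_model` (defaults to the star tree).
#' @param record_every thinning interval of the posterior trace.
#' @param keep_states if `TRUE`, also record the visited structure at every
#'   iteration (used by the enumeration-based sampler diagnostics; memory
#'   heavy for long chains).
#' @return list with `best` (maximum-posterior state), `final`, `trace`
#'   (data.frame of iteration and log-posterior), `acceptance` (per-move-type
#'   proposal and acceptance counts), `iterations`, `seed`, and optionally
#'   `states`.
#' @export
run_chain <- function(B, iterations, zeta = 5, seed = NULL,
                      alpha = gene_rates(B), init = NULL,
                      record_every = 100L, keep_states = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- star_tree(colnames(B))
  state <- mcmc_state(B, init, alpha, zeta)
  best <- state
  proposed <- accepted <- stats::setNames(integer(length(MOVE_TYPES)), MOVE_TYPES)
  n_rec <- if (iterations > 0) floor(iterations / record_every) else 0
  trace_it <- integer(n_rec); trace_lp <- numeric(n_rec); ri <- 0L
  states <- if (keep_states) vector("list", iterations) else NULL
  if (iterations > 0) for (it in seq_len(iterations)) {
    step <- mh_step(state, B, alpha, zeta)
    state <- step$state
    proposed[step$type] <- proposed[step$type] + 1L
    if (step$accepted) accepted[step$type] <- accepted[step$type] + 1L
    if (state$log_post > best$log_post) best <- state
    if (it %% record_every == 0) {
      ri <- ri + 1L
      trace_it[ri] <- it; trace_lp[ri] <- state$log_post
    }
    if (keep_states) states[[it]] <- state$model
  }
  out <- list(
    best = best, final = state,
    trace = data.frame(iteration = trace_it[seq_len(ri)],
                       log_posterior = trace_lp[seq_len(ri)]),
    acceptance = data.frame(move = MOVE_TYPES, proposed = unname(proposed),
                            accepted = unname(accepted)),
    iterations = iterations, seed = seed
  )
  if (keep_states) out$states <- states
  out
}

#' Fit a progression model
#'
#' Runs independent MCMC chains (chain `i` is seeded with `seed + i - 1`),
#' selects the maximum-posterior structure over all chains, fine-tunes the
#' error rates on it by gradient ascent, and reports the model together with
#' its posterior ratio to the star tree and the minimum-error tally with which
#' the data conform to the structure.
#'
#' @param B binary mutation matrix.
#' @param chains number of independent chains (default 10).
#' @param iterations MH iterations per chain (default 1e5).
#' @param zeta prior strength (default 5).
#' @param seed master seed.
#' @param alpha gene-rate weights.
#' @param finetune run the gradient refinement of `(eps, delta)` (default
#'   `TRUE`).
#' @param record_every trace thinning interval.
#' @return an object of class `tomexo_fit`: the selected `model`, tuned
#'   `eps`/`delta`, `log_lik`/`log_prior`/`log_posterior`, the star-tree
#'   posterior, `log_posterior_ratio` and `per_tumor_ratio` against the star
#'   tree, the dataset `error_tally`, and per-chain diagnostics.
#' @export
fit <- function(B, chains = 10L, iterations = 100000L, zeta = 5, seed = 1L,
                alpha = gene_rates(B), finetune = TRUE, record_every = 100L) {
  stopifnot(chains >= 1, iterations >= 0)
  runs <- vector("list", chains)
  for (i in seq_len(chains)) {
    runs[[i]] <- run_chain(B, iterations, zeta = zeta, seed = seed + i - 1L,
                           alpha = alpha, record_every = record_every)
  }
  best_idx <- which.max(vapply(runs, function(r) r$best$log_post, 0))
  best <- runs[[best_idx]]$best
  if (finetune) {
    ft <- finetune_error_rates(B, best$model, alpha, best$eps, best$delta)
    model <- ft$model; eps <- ft$eps; delta <- ft$delta; ll <- ft$log_lik
  } else {
    model <- best$model; eps <- best$eps; delta <- best$delta; ll <- best$log_lik
  }
  lprior <- log_prior(model, zeta)
  lpost <- ll + lprior
  star <- mcmc_state(B, star_tree(colnames(B)), alpha, zeta)
  M <- nrow(B)
  structure(list(
    model = model, eps = eps, delta = delta,
    log_lik = ll, log_prior = lprior, log_posterior = lpost,
    star_log_posterior = star$log_post,
    log_posterior_ratio = lpost - star$log_post,
    per_tumor_ratio = exp((lpost - star$log_post) / M),
    error_tally = error_tally(B, model),
    chains = lapply(runs, function(r)
      list(best_log_post = r$best$log_post, trace = r$trace,
           acceptance = r$acceptance, seed = r$seed)),
    config = list(chains = chains, iterations = iterations, zeta = zeta,
                  seed = seed, finetune = finetune),
    n_tumors = M, n_genes = ncol(B)
  ), class = "tomexo_fit")
}

#' @export
print.tomexo_fit <- function(x, ...) {
  cat(sprintf("tomexo fit: %d tumors x %d genes, %d chain(s) x %d iteration(s)\n",
              x$n_tumors, x$n_genes, x$config$chains, x$config$iterations))
  cat(sprintf("log-posterior %.3f (star tree %.3f, per-tumor ratio %.3f)\n",
              x$log_posterior, x$star_log_posterior, x$per_tumor_ratio))
  cat(sprintf("error rates: eps = %.4f, delta = %.4f; minimal tally: %d FP, %d FN\n",
              x$eps, x$delta, x$error_tally$fp, x$error_tally$fn))
  print(x$model)
  invisible(x)
}
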