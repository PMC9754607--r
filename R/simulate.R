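# Generative process: top-down firing of driver nodes, one mutated gene per
# fired node, then independent false-positive / false-negative bit flips.

#' Sample noise-free tumors from a progression model
#'
#' Top-down traversal: the root is always active; a node may fire only if its
#' parent fired, with probability equal to its firing probability. Every
#' fired node puts a driver mutation in exactly one of its genes, chosen
#' categorically with probability proportional to the gene weights within the
#' node; all other positions, passengers included, stay 0.
#'
#' @param model a `tomexo_model`.
#' @param n number of tumors to draw.
#' @param alpha optional named gene weights; uniform within each node when
#'   `NULL`.
#' @return binary matrix `n x length(model$genes)` in canonical gene order.
#' @export
sample_tumors <- function(model, n, alpha = NULL) {
  N <- length(model$genes)
  V <- n_nodes(model)
  B <- matrix(0L, n, N, dimnames = list(paste0("t", seq_len(n)), model$genes))
  if (V == 1 || n == 0) return(B)
  depth_order <- order(vapply(2:V, function(v) {
    d <- 0L; u <- v
    while (!is.na(model$parent[u])) { d <- d + 1L; u <- model$parent[u] }
    d
  }, 1L))
  fired <- matrix(FALSE, n, V)
  fired[, 1] <- TRUE
  for (v in (2:V)[depth_order]) {
    fired[, v] <- fired[, model$parent[v]] & stats::runif(n) < model$f[v]
    hit <- which(fired[, v])
    if (!length(hit)) next
    genes <- model$nodes[[v]]
    w <- if (is.null(alpha)) rep(1, length(genes)) else alpha[genes]
    pick <- if (length(genes) == 1) rep(1L, length(hit)) else
      sample.int(length(genes), length(hit), replace = TRUE, prob = w)
    B[cbind(hit, match(genes, model$genes)[pick])] <- 1L
  }
  B
}

#' Sample one noise-free tumor vector
#'
#' @inheritParams sample_tumors
#' @return 0/1 vector in canonical gene order.
#' @export
sample_tumor <- function(model, alpha = NULL) {
  sample_tumors(model, 1L, alpha)[1, ]
}

#' Inject false positives and false negatives
#'
#' Independently flips every 0 to 1 with probability `eps` and every 1 to 0
#' with probability `delta`.
#'
#' @param Bstar binary matrix (noise-free).
#' @param eps,delta flip probabilities in \[0, 1).
#' @return binary matrix of the same shape and labels.
#' @export
inject_noise <- function(Bstar, eps, delta) {
  stopifnot(eps >= 0, eps < 1, delta >= 0, delta < 1)
  U <- matrix(stats::runif(length(Bstar)), nrow(Bstar))
  out <- ifelse(Bstar == 1, ifelse(U < delta, 0L, 1L), ifelse(U < eps, 1L, 0L))
  dimnames(out) <- dimnames(Bstar)
  out
}

#' Simulate an observed cohort
#'
#' [sample_tumors()] followed by [inject_noise()].
#'
#' @inheritParams sample_tumors
#' @inheritParams inject_noise
#' @return binary matrix `n x N` with tumor and gene labels.
#' @export
simulate_cohort <- function(model, n, eps, delta, alpha = NULL) {
  inject_noise(sample_tumors(model, n, alpha), eps, delta)
}

#' Benchmark progression-model fixtures
#'
#' The three topology families of the synthetic benchmark: `linear` — a chain
#' of multi-gene nodes (a pathway linear progression model); `single_seeded`
#' — one first-layer node from which all other nodes branch; `multi_seeded` —
#' several independent first-layer branches, each a chain. Gene counts and
#' firing probabilities are free parameters.
#'
#' @param family `"linear"`, `"single_seeded"` or `"multi_seeded"`.
#' @param n_nodes number of driver nodes (`linear`, `single_seeded`).
#' @param genes_per_node genes in every node.
#' @param f firing probabilities, recycled over nodes in construction order
#'   (defaults decay with depth).
#' @param n_passengers number of passenger genes appended to the universe.
#' @param branches number of first-layer branches (`multi_seeded`).
#' @param depth chain length of each branch (`multi_seeded`).
#' @return a validated `tomexo_model` with genes `g1, g2, ...` and passengers
#'   `p1, p2, ...`.
#' @export
make_fixture <- function(family = c("linear", "single_seeded", "multi_seeded"),
                         n_nodes = 3L, genes_per_node = 2L,
                         f = c(0.9, 0.7, 0.5), n_passengers = 2L,
                         branches = 3L, depth = 2L) {
  family <- match.arg(family)
  if (genes_per_node < 1 || n_passengers < 0) stop("invalid fixture parameters")
  total_nodes <- switch(family,
    linear = n_nodes,
    single_seeded = n_nodes,
    multi_seeded = branches * depth)
  if (total_nodes < 1) stop("fixture needs at least one driver node")
  parent <- switch(family,
    linear = c(NA_integer_, seq_len(n_nodes)),
    # seed node under the root, every other node under the seed
    single_seeded = c(NA_integer_, 1L, rep(2L, n_nodes - 1L)),
    multi_seeded = {
      p <- NA_integer_
      for (b in seq_len(branches)) {
        first <- 1L + (b - 1L) * depth + 1L
        p <- c(p, 1L, if (depth > 1) (first):(first + depth - 2L))
      }
      p
    })
  gene_labels <- paste0("g", seq_len(total_nodes * genes_per_node))
  nodes <- c(list(character(0)),
             split(gene_labels, rep(seq_len(total_nodes), each = genes_per_node)))
  fv <- c(NA_real_, rep_len(f, total_nodes))
  passengers <- if (n_passengers > 0) paste0("p", seq_len(n_passengers)) else character(0)
  progression_model(nodes = nodes, parent = parent, f = fv,
                    passengers = passengers,
                    genes = c(gene_labels, passengers))
}

#' Run a synthetic benchmark grid
#'
#' For every (noise level, cohort size) cell and replicate: simulate a cohort
#' from the fixture, fit a model by MCMC, and score the recovered structure
#' against the generative one. Equal false-positive and false-negative
#' probabilities are used, mirroring the benchmark design.
#'
#' @param family fixture family, see [make_fixture()].
#' @param noise_levels numeric vector of error probabilities
#'   (`eps = delta`).
#' @param tumor_counts integer vector of cohort sizes.
#' @param replicates datasets per cell.
#' @param chains,iterations,zeta MCMC configuration passed to [fit()].
#' @param seed master seed; each (cell, replicate) derives its own seed.
#' @param fixture optional `tomexo_model` overriding the default fixture.
#' @param ... further arguments to [make_fixture()].
#' @return data.frame with one row per replicate: `family`, `noise`, `n`,
#'   `replicate`, `seed`, `F_ME`, `F_PR`, `F_overall`.
#' @export
run_experiment_grid <- function(family = "linear",
                                noise_levels = c(0.001, 0.01, 0.05, 0.1),
                                tumor_counts = c(50, 100, 200, 500),
                                replicates = 10L, chains = 1L,
                                iterations = 20000L, zeta = 5, seed = 1L,
                                fixture = NULL, ...) {
  truth <- if (is.null(fixture)) make_fixture(family, ...) else fixture
  cells <- expand.grid(noise = noise_levels, n = tumor_counts,
                       replicate = seq_len(replicates))
  out <- cells
  out$family <- family
  out$seed <- NA_integer_
  out$F_ME <- out$F_PR <- out$F_overall <- NA_real_
  for (i in seq_len(nrow(cells))) {
    cell_seed <- as.integer(seed) + 7919L * (i - 1L)
    set.seed(cell_seed)
    B <- simulate_cohort(truth, cells$n[i], cells$noise[i], cells$noise[i])
    fit_i <- fit(B, chains = chains, iterations = iterations, zeta = zeta,
                 seed = cell_seed + 1L)
    sc <- f_scores(fit_i$model, truth)
    out$seed[i] <- cell_seed
    out$F_ME[i] <- sc["F_ME"]; out$F_PR[i] <- sc["F_PR"]
    out$F_overall[i] <- sc["F_overall"]
  }
  out[, c("family", "noise", "n", "replicate", "seed",
          "F_ME", "F_PR", "F_overall")]
}
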