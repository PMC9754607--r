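# Likelihood of the observed binary matrix given a progression model and
# global false-positive (eps) / false-negative (delta) rates. A single
# post-order traversal of the driver tree marginalises the latent node states,
# so the cost is linear in the number of nodes and, over the matrix, O(M*N).

# error rates are floored/capped before likelihood evaluation: the recursions
# need (0,1), and rates above 0.5 are unidentifiable relabelings
ERR_FLOOR <- 1e-6
ERR_CAP <- 0.5

clamp_error_rate <- function(x) pmin(pmax(x, ERR_FLOOR), ERR_CAP)

#' Node-local likelihoods of one node's observed bits
#'
#' For a single tumor and a single driver node, returns the probability of the
#' node's observed bits given the node's latent state. When the node is
#' mutated (state 1), exactly one gene carries the true driver mutation,
#' chosen with probability proportional to the gene weights; the driver gene
#' is observed 1 with probability `1 - delta`, every other bit is background
#' (1 with probability `eps`). When the node is not mutated (state 0) all bits
#' are background.
#'
#' @param bits 0/1 vector of observed bits for the node's genes.
#' @param weights positive gene-rate weights for the node's genes.
#' @param eps,delta error probabilities in (0,1).
#' @return named numeric `c(lambda = p(bits | state 1), gamma = p(bits | state 0))`.
#' @export
node_local_likelihoods <- function(bits, weights, eps, delta) {
  k <- length(bits)
  stopifnot(k >= 1, length(weights) == k)
  if (sum(weights) <= 0) stop("gene weights within a node must have positive sum")
  o <- sum(bits == 1)
  z <- k - o
  w1 <- sum(weights[bits == 1]) / sum(weights)
  lam <- 0
  if (o >= 1) lam <- lam + w1 * (1 - delta) * eps^(o - 1) * (1 - eps)^z
  if (z >= 1) lam <- lam + (1 - w1) * delta * eps^o * (1 - eps)^(z - 1)
  gam <- eps^o * (1 - eps)^z
  c(lambda = lam, gamma = gam)
}

# Per-node count arrays shared by the likelihood DP, the min-error DP and the
# firing-probability estimator: built once per candidate structure, so an MH
# step touches the M x N matrix a single time.
model_arrays <- function(B, model, alpha) {
  M <- nrow(B); N <- ncol(B)
  V <- n_nodes(model)
  pass_idx <- match(model$passengers, colnames(B))
  pass_ones <- if (length(pass_idx))
    rowSums(B[, pass_idx, drop = FALSE]) else numeric(M)
  kids <- model_children(model)
  po <- model_postorder(model)
  if (V == 1) {
    return(list(M = M, N = N, V = V, kids = kids, po = po,
                pass_ones = pass_ones, n_pass = length(pass_idx)))
  }
  W <- matrix(0, N, V)
  for (v in 2:V) W[match(model$nodes[[v]], colnames(B)), v] <- 1
  av <- unname(alpha[colnames(B)])
  O <- B %*% W                              # M x V counts of observed ones
  A1 <- B %*% (W * av)                      # alpha mass on observed-one genes
  suma <- as.numeric(crossprod(W, av))      # per-node total alpha
  ksz <- colSums(W)                         # node sizes
  list(M = M, N = N, V = V, kids = kids, po = po,
       pass_ones = pass_ones, n_pass = length(pass_idx),
       O = O, A1 = A1, suma = suma, ksz = ksz)
}

# likelihood DP given prepared arrays and firing probabilities
loglik_from_arrays <- function(arr, f, eps, delta) {
  le <- log(eps); l1e <- log1p(-eps)
  ld <- log(delta); l1d <- log1p(-delta)
  out <- arr$pass_ones * le + (arr$n_pass - arr$pass_ones) * l1e
  if (arr$V == 1) return(out)
  M <- arr$M; V <- arr$V
  O <- arr$O
  Z <- matrix(arr$ksz, M, V, byrow = TRUE) - O
  w1 <- sweep(arr$A1, 2, pmax(arr$suma, .Machine$double.xmin), "/")
  # log Lambda / log Gamma, nodes 2..V (log(0) = -Inf handles o=0 / z=0)
  t1 <- suppressWarnings(log(w1) + l1d + (O - 1) * le + Z * l1e)
  t2 <- suppressWarnings(log(1 - w1) + ld + O * le + (Z - 1) * l1e)
  logLam <- logaddexp(t1, t2)
  logGam <- O * le + Z * l1e
  logOmega <- matrix(0, M, V)
  logmix <- matrix(0, M, V)                 # log(f_c Psi_c + (1-f_c) Omega_c)
  for (v in arr$po) {
    accP <- logLam[, v]
    accO <- logGam[, v]
    for (cnode in arr$kids[[v]]) {
      accP <- accP + logmix[, cnode]
      accO <- accO + logOmega[, cnode]
    }
    logOmega[, v] <- accO
    logmix[, v] <- logaddexp(log(f[v]) + accP, log1p(-f[v]) + accO)
  }
  for (cnode in arr$kids[[1]]) out <- out + logmix[, cnode]
  out
}

# Per-tumor log-likelihood vector for the whole matrix; the workhorse behind
# tumor_log_likelihood / dataset_log_likelihood and every MH step.
tumor_log_likelihoods <- function(B, model, alpha = gene_rates(B),
                                  eps, delta, clamp = TRUE, arr = NULL) {
  if (clamp) { eps <- clamp_error_rate(eps); delta <- clamp_error_rate(delta) }
  if (!setequal(colnames(B), model$genes))
    stop("matrix gene labels do not match the model's gene universe")
  if (is.null(arr)) arr <- model_arrays(B, model, alpha)
  loglik_from_arrays(arr, model$f, eps, delta)
}

#' Log-likelihood of a single tumor
#'
#' Marginal probability of one observed tumor row under the progression model,
#' summing over every latent noise-free vector the model can generate. The
#' dynamic program visits each driver node once (post-order), combining each
#' child's "fired" and "not fired" branch likelihoods; passenger bits
#' contribute a pure background factor.
#'
#' @param row 0/1 vector, one entry per gene in the model's universe (in
#'   canonical gene order).
#' @param model a `tomexo_model`.
#' @param alpha named gene-rate weights (see [gene_rates()]); uniform rates
#'   are used when the data-derived default is unavailable.
#' @param eps,delta false-positive / false-negative probabilities.
#' @return the log marginal likelihood (a non-positive real).
#' @export
tumor_log_likelihood <- function(row, model, alpha = NULL, eps, delta) {
  if (length(row) != length(model$genes))
    stop(sprintf("row has %d bits but the model has %d genes",
                 length(row), length(model$genes)))
  B <- matrix(as.numeric(row), 1, length(row),
              dimnames = list("t1", model$genes))
  if (is.null(alpha)) alpha <- stats::setNames(rep(1, ncol(B)), colnames(B))
  as.numeric(tumor_log_likelihoods(B, model, alpha, eps, delta))
}

#' Log-likelihood of a mutation matrix
#'
#' Tumors are independent given the model, so the dataset log-likelihood is
#' the sum of per-tumor log-likelihoods; total cost O(M*N).
#'
#' @param B binary mutation matrix (tumors x genes, labelled).
#' @inheritParams tumor_log_likelihood
#' @return the dataset log-likelihood.
#' @export
dataset_log_likelihood <- function(B, model, alpha = gene_rates(B), eps, delta) {
  sum(tumor_log_likelihoods(B, model, alpha, eps, delta))
}
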