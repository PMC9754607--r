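#' Construct a progression model
#'
#' A progression model is a rooted driver tree whose non-root nodes hold
#' non-empty, pairwise-disjoint sets of driver genes, a firing probability on
#' the edge into every non-root node, and a set of passenger genes outside the
#' tree. Node 1 is always the root; it carries no genes and no firing
#' probability.
#'
#' @param nodes list of character vectors; `nodes[[1]]` must be the (empty)
#'   root gene set, every other entry a non-empty set of gene labels.
#' @param parent integer vector of parent indices; `parent[1]` is `NA`.
#' @param f numeric vector of firing probabilities in (0,1); `f[1]` is `NA`.
#' @param passengers character vector of gene labels outside the tree.
#' @param genes character vector: the full ordered gene universe (canonical
#'   column order of the mutation matrix).
#' @param validate if `TRUE` (default), stop on any invariant violation.
#' @return an object of class `tomexo_model`.
#' @seealso [validate_model()], [star_tree()]
#' @export
progression_model <- function(nodes, parent, f, passengers = character(0),
                              genes, validate = TRUE) {
  model <- structure(
    list(
      genes = as.character(genes),
      nodes = lapply(nodes, as.character),
      parent = as.integer(parent),
      f = as.numeric(f),
      passengers = as.character(passengers)
    ),
    class = "tomexo_model"
  )
  if (validate) {
    v <- validate_model(model, genes)
    if (length(v)) stop("invalid progression model: ", paste(v, collapse = "; "))
  }
  model
}

#' Star tree over a gene universe
#'
#' The MCMC initial state: every gene sits in its own single-gene node
#' ("simple node") attached directly to the root; no passengers.
#'
#' @param genes character vector of gene labels.
#' @param f firing probability assigned to every edge (placeholder; the
#'   sampler immediately replaces it with the empirical estimate).
#' @return a `tomexo_model`.
#' @export
star_tree <- function(genes, f = 0.5) {
  n <- length(genes)
  progression_model(
    nodes = c(list(character(0)), as.list(genes)),
    parent = c(NA_integer_, rep(1L, n)),
    f = c(NA_real_, rep(f, n)),
    passengers = character(0),
    genes = genes
  )
}

#' Validate a progression model against a gene universe
#'
#' Checks the structural invariants and returns a character vector of
#' violation descriptions (empty when the model is valid). Violations are
#' returned, never raised.
#'
#' @param model a `tomexo_model` (or a bare list with the same fields).
#' @param genes the gene universe the model must cover.
#' @return character vector of human-readable violations.
#' @export
validate_model <- function(model, genes = model$genes) {
  bad <- character(0)
  V <- length(model$nodes)
  if (V < 1) return("model has no root node")
  if (length(model$parent) != V || length(model$f) != V)
    bad <- c(bad, "parent/f length does not match the number of nodes")
  if (!is.na(model$parent[1]))
    bad <- c(bad, "root must have no parent")
  if (length(model$nodes[[1]]) != 0)
    bad <- c(bad, "root must carry no genes")
  if (V >= 2) {
    p <- model$parent[-1]
    if (anyNA(p) || any(p < 1 | p > V))
      bad <- c(bad, "non-root node with missing or out-of-range parent")
    else {
      # every node must reach the root by following parents (no cycles)
      for (v in 2:V) {
        seen <- logical(V)
        u <- v
        while (!is.na(model$parent[u])) {
          if (seen[u]) { bad <- c(bad, sprintf("cycle through node %d", v)); break }
          seen[u] <- TRUE
          u <- model$parent[u]
        }
        if (u != 1 && !seen[u]) bad <- c(bad, sprintf("node %d does not reach the root", v))
      }
    }
    empties <- which(vapply(model$nodes[-1], length, 1L) == 0)
    for (v in empties) bad <- c(bad, sprintf("empty node %d", v + 1L))
    fv <- model$f[-1]
    if (anyNA(fv) || any(fv <= 0 | fv >= 1))
      bad <- c(bad, "firing probabilities must lie strictly inside (0,1)")
  }
  driver <- unlist(model$nodes, use.names = FALSE)
  if (anyDuplicated(driver))
    bad <- c(bad, "overlapping gene sets: a gene appears in more than one node")
  all_genes <- c(driver, model$passengers)
  if (anyDuplicated(all_genes))
    bad <- c(bad, "a gene is both driver and passenger")
  if (!setequal(all_genes, genes))
    bad <- c(bad, "union of node gene sets and passengers does not equal the gene universe")
  bad
}

# ---- structural helpers (internal) -----------------------------------------

n_nodes <- function(model) length(model$nodes)

model_children <- function(model) {
  V <- n_nodes(model)
  kids <- vector("list", V)
  if (V >= 2) for (v in 2:V) kids[[model$parent[v]]] <- c(kids[[model$parent[v]]], v)
  kids
}

# node indices ordered so every child appears before its parent (reverse
# breadth-first order from the root; node indices need not be topologically
# sorted after structural moves)
model_postorder <- function(model) {
  V <- n_nodes(model)
  if (V == 1) return(integer(0))
  kids <- model_children(model)
  ord <- integer(V)
  ord[1] <- 1L
  head <- 1L; filled <- 1L
  while (head <= filled) {
    for (u in kids[[ord[head]]]) {
      filled <- filled + 1L
      ord[filled] <- u
    }
    head <- head + 1L
  }
  rev(ord[2:V])
}

# indices of v and all its descendants
subtree_nodes <- function(model, v) {
  V <- n_nodes(model)
  inset <- logical(V)
  inset[v] <- TRUE
  if (V >= 2) for (u in 2:V) {
    w <- u
    while (!is.na(model$parent[w]) && !inset[w]) w <- model$parent[w]
    if (inset[w]) inset[u] <- TRUE
  }
  which(inset)
}

is_leaf <- function(model, v) !(v %in% model$parent)

#' @export
print.tomexo_model <- function(x, ...) {
  V <- n_nodes(x)
  cat(sprintf("Progression model: %d driver node(s), %d gene(s), %d passenger(s)\n",
              V - 1L, length(x$genes), length(x$passengers)))
  if (V >= 2) {
    for (v in 2:V) {
      lab <- if (x$parent[v] == 1) "root" else paste(x$nodes[[x$parent[v]]], collapse = ",")
      cat(sprintf("  [%s] -> {%s}  f = %.3f\n", lab,
                  paste(x$nodes[[v]], collapse = ","), x$f[v]))
    }
  }
  if (length(x$passengers))
    cat("  passengers: {", paste(x$passengers, collapse = ","), "}\n", sep = "")
  invisible(x)
}

# ---- gene rates ------------------------------------------------------------

#' Per-gene mutation-rate weights
#'
#' Categorical weights for which gene of a mutated node receives the driver
#' mutation: the number of tumors carrying the gene plus a pseudocount of one,
#' so never-mutated genes keep positive weight. Weights are normalised within
#' each node at evaluation time.
#'
#' @param B binary mutation matrix (tumors x genes).
#' @return named numeric vector of weights, one per column of `B`.
#' @export
gene_rates <- function(B) {
  w <- colSums(B) + 1
  names(w) <- colnames(B)
  w
}

# ---- empirical firing probabilities ----------------------------------------

F_MIN <- 1e-6

#' Empirical firing probability of one edge
#'
#' Maximum-likelihood estimate of the firing probability on the edge into node
#' `v` under observation error: with `X` the number of tumors carrying a
#' mutation in any gene of the parent node (`X = M` for first-layer nodes) and
#' `Y` the number carrying a mutation in both the parent and `v`, the estimate
#' is `max{(Y - eps * X) / ((1 - eps - delta) * X), 0}`, clamped into
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param B binary mutation matrix.
#' @param model a `tomexo_model`.
#' @param v node index (2..V).
#' @param eps,delta false-positive / false-negative probabilities,
#'   `eps + delta < 1`.
#' @return estimated firing probability in (0,1).
#' @export
estimate_firing_probability <- function(B, model, v, eps = 0, delta = 0) {
  idx <- match(model$nodes[[v]], colnames(B))
  ind_v <- rowSums(B[, idx, drop = FALSE]) > 0
  u <- model$parent[v]
  if (u == 1L) {
    X <- nrow(B)
    Y <- sum(ind_v)
  } else {
    idx_u <- match(model$nodes[[u]], colnames(B))
    ind_u <- rowSums(B[, idx_u, drop = FALSE]) > 0
    X <- sum(ind_u)
    Y <- sum(ind_u & ind_v)
  }
  if (X == 0) {
    warning("no tumor carries the parent node; returning the minimum firing probability")
    return(F_MIN)
  }
  denom <- max(1 - eps - delta, F_MIN)
  fhat <- max((Y - eps * X) / (denom * X), 0)
  min(max(fhat, F_MIN), 1 - F_MIN)
}

# All edges at once; used inside the sampler. `ind` is the tumors x nodes
# node-observation indicator (any gene of the node observed mutated).
empirical_firing_probs <- function(B, model, eps, delta, ind = NULL) {
  V <- n_nodes(model)
  f <- rep(NA_real_, V)
  if (V == 1) return(f)
  if (is.null(ind)) ind <- node_indicator(B, model)
  M <- nrow(B)
  denom <- max(1 - eps - delta, F_MIN)
  for (v in 2:V) {
    u <- model$parent[v]
    if (u == 1L) {
      X <- M
      Y <- sum(ind[, v])
    } else {
      X <- sum(ind[, u])
      Y <- sum(ind[, u] & ind[, v])
    }
    if (X == 0) {
      f[v] <- F_MIN
    } else {
      f[v] <- min(max((Y - eps * X) / (denom * X), 0), 1 - F_MIN)
      f[v] <- max(f[v], F_MIN)
    }
  }
  f
}

# tumors x nodes logical matrix: node observed mutated (OR over its genes)
node_indicator <- function(B, model) {
  V <- n_nodes(model)
  ind <- matrix(FALSE, nrow(B), V)
  if (V >= 2) for (v in 2:V) {
    idx <- match(model$nodes[[v]], colnames(B))
    ind[, v] <- rowSums(B[, idx, drop = FALSE]) > 0
  }
  ind
}
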