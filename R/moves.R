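# Structural MCMC moves. Every move type is paired with an inverse type; a
# proposal carries the log forward and backward probabilities of the specific
# (type, inner choices) pair, including the uniform choice among the move
# types applicable to each endpoint, so the Metropolis-Hastings correction is
# exact for each reversible kernel pair.
#
# Inner randomness is uniform over the applicable choices; the subset drawn by
# the attach moves takes a size uniform on 1..min(4, available) and then a
# uniform subset of that size.

ATTACH_MAX <- 4L

sample1 <- function(x) x[sample.int(length(x), 1L)]

# uniform non-empty proper subset of 1..k (logical), by rejection
sample_proper_subset <- function(k) {
  repeat {
    s <- stats::runif(k) < 0.5
    if (any(s) && !all(s)) return(s)
  }
}

leaf_nodes <- function(model) {
  V <- n_nodes(model)
  if (V < 2) return(integer(0))
  setdiff(2:V, model$parent[-1])
}

# childless single-gene nodes in the first layer ("simple nodes")
childless_simple_nodes <- function(model) {
  lv <- leaf_nodes(model)
  lv[model$parent[lv] == 1L & vapply(model$nodes[lv], length, 1L) == 1L]
}

node_sizes <- function(model) vapply(model$nodes, length, 1L)

# genes removable one-at-a-time: those living in nodes with >= 2 genes;
# returns a 2-column matrix (node index, position within node)
removable_genes <- function(model) {
  out <- NULL
  sz <- node_sizes(model)
  for (v in which(sz >= 2)) {
    if (v == 1) next
    out <- rbind(out, cbind(v, seq_len(sz[v])))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

sibling_leaf_pairs <- function(model) {
  lv <- leaf_nodes(model)
  out <- NULL
  for (p in unique(model$parent[lv])) {
    sibs <- lv[model$parent[lv] == p]
    if (length(sibs) >= 2) {
      cmb <- utils::combn(sibs, 2)
      out <- cbind(out, cmb)
    }
  }
  if (is.null(out)) matrix(integer(0), 2, 0) else out
}

spr_candidates <- function(model) {
  V <- n_nodes(model)
  if (V < 3) return(integer(0))
  size <- rep(1L, V)
  for (v in model_postorder(model))
    size[model$parent[v]] <- size[model$parent[v]] + size[v]
  # targets for v: nodes outside its subtree, minus the current parent
  cand <- 2:V
  cand[(V - size[cand] - 1L) >= 1L]
}

# ---- structural edit helpers -----------------------------------------------

drop_nodes <- function(model, vs) {
  V <- n_nodes(model)
  keep <- setdiff(seq_len(V), vs)
  map <- integer(V)
  map[keep] <- seq_along(keep)
  model$nodes <- model$nodes[keep]
  model$f <- model$f[keep]
  model$parent <- map[model$parent[keep]]
  model
}

add_node <- function(model, genes, parent_idx, f = 0.5) {
  model$nodes <- c(model$nodes, list(as.character(genes)))
  model$parent <- c(model$parent, as.integer(parent_idx))
  model$f <- c(model$f, f)
  model
}

# ---- move applicability ----------------------------------------------------

MOVE_TYPES <- c("vertical_merge", "vertical_split",
                "horizontal_merge", "horizontal_split",
                "attach_from_passengers", "detach_into_passengers",
                "attach_from_simple", "detach_into_simple",
                "p2d", "d2p", "s2d", "d2s",
                "gene_swap", "spr")

applicable_moves <- function(model) {
  V <- n_nodes(model)
  sz <- node_sizes(model)
  lv <- leaf_nodes(model)
  cs <- childless_simple_nodes(model)
  nP <- length(model$passengers)
  small_leaves <- lv[sz[lv] <= ATTACH_MAX]
  multi_gene <- any(sz[-1] >= 2)
  ok <- c(
    vertical_merge = any(model$parent[lv] != 1L),
    vertical_split = multi_gene,
    horizontal_merge = anyDuplicated(model$parent[lv]) > 0,
    horizontal_split = any(sz[lv] >= 2),
    attach_from_passengers = nP >= 1,
    detach_into_passengers = length(small_leaves) >= 1,
    attach_from_simple = length(cs) >= 1,
    detach_into_simple = length(small_leaves) >= 1,
    p2d = nP >= 1 && V >= 2,
    d2p = multi_gene,
    s2d = length(cs) >= 1 && V >= 3,
    d2s = multi_gene,
    gene_swap = V >= 3 && any(model$parent[-1] != 1L),
    spr = length(spr_candidates(model)) >= 1
  )
  names(ok)[ok]
}

# ---- individual proposals --------------------------------------------------
# each returns list(model, log_inner_fwd, log_inner_bwd)

propose_vertical_merge <- function(model) {
  lv <- leaf_nodes(model)
  cand <- lv[model$parent[lv] != 1L]
  v <- sample1(cand)
  u <- model$parent[v]
  new <- model
  new$nodes[[u]] <- c(new$nodes[[u]], new$nodes[[v]])
  new <- drop_nodes(new, v)
  sz <- node_sizes(new)
  n_split <- sum(sz[-1] >= 2)
  k <- length(model$nodes[[u]]) + length(model$nodes[[v]])
  list(model = new,
       log_inner_fwd = -log(length(cand)),
       log_inner_bwd = -log(n_split) - log(2^k - 2))
}

propose_vertical_split <- function(model) {
  sz <- node_sizes(model)
  cand <- setdiff(which(sz >= 2), 1L)
  u <- sample1(cand)
  k <- sz[u]
  s <- sample_proper_subset(k)
  new <- model
  moved <- new$nodes[[u]][s]
  new$nodes[[u]] <- new$nodes[[u]][!s]
  new <- add_node(new, moved, u)
  lv2 <- leaf_nodes(new)
  n_merge <- length(lv2[new$parent[lv2] != 1L])
  list(model = new,
       log_inner_fwd = -log(length(cand)) - log(2^k - 2),
       log_inner_bwd = -log(n_merge))
}

propose_horizontal_merge <- function(model) {
  prs <- sibling_leaf_pairs(model)
  j <- sample.int(ncol(prs), 1L)
  v <- prs[1, j]; w <- prs[2, j]
  new <- model
  new$nodes[[v]] <- c(new$nodes[[v]], new$nodes[[w]])
  new <- drop_nodes(new, w)
  sz2 <- node_sizes(new)
  lv2 <- leaf_nodes(new)
  n_split <- length(lv2[sz2[lv2] >= 2])
  k <- length(model$nodes[[v]]) + length(model$nodes[[w]])
  list(model = new,
       log_inner_fwd = -log(ncol(prs)),
       log_inner_bwd = -log(n_split) - log((2^k - 2) / 2))
}

propose_horizontal_split <- function(model) {
  sz <- node_sizes(model)
  lv <- leaf_nodes(model)
  cand <- lv[sz[lv] >= 2]
  v <- sample1(cand)
  k <- sz[v]
  s <- sample_proper_subset(k)
  new <- model
  moved <- new$nodes[[v]][s]
  new$nodes[[v]] <- new$nodes[[v]][!s]
  new <- add_node(new, moved, new$parent[v])
  n_pairs <- ncol(sibling_leaf_pairs(new))
  list(model = new,
       log_inner_fwd = -log(length(cand)) - log((2^k - 2) / 2),
       log_inner_bwd = -log(n_pairs))
}

propose_attach_from_passengers <- function(model) {
  nP <- length(model$passengers)
  V <- n_nodes(model)
  smax <- min(ATTACH_MAX, nP)
  s <- sample.int(smax, 1L)
  genes <- model$passengers[sample.int(nP, s)]
  target <- sample.int(V, 1L)
  new <- model
  new$passengers <- setdiff(new$passengers, genes)
  new <- add_node(new, genes, target)
  sz2 <- node_sizes(new)
  lv2 <- leaf_nodes(new)
  n_detach <- length(lv2[sz2[lv2] <= ATTACH_MAX])
  list(model = new,
       log_inner_fwd = -log(smax) - lchoose(nP, s) - log(V),
       log_inner_bwd = -log(n_detach))
}

propose_detach_into_passengers <- function(model) {
  sz <- node_sizes(model)
  lv <- leaf_nodes(model)
  cand <- lv[sz[lv] <= ATTACH_MAX]
  v <- sample1(cand)
  s <- sz[v]
  new <- model
  new$passengers <- c(new$passengers, new$nodes[[v]])
  new <- drop_nodes(new, v)
  nP2 <- length(new$passengers)
  V2 <- n_nodes(new)
  list(model = new,
       log_inner_fwd = -log(length(cand)),
       log_inner_bwd = -log(min(ATTACH_MAX, nP2)) - lchoose(nP2, s) - log(V2))
}

propose_attach_from_simple <- function(model) {
  cs <- childless_simple_nodes(model)
  V <- n_nodes(model)
  smax <- min(ATTACH_MAX, length(cs))
  s <- sample.int(smax, 1L)
  chosen <- cs[sample.int(length(cs), s)]
  genes <- unlist(model$nodes[chosen], use.names = FALSE)
  target_pool <- setdiff(seq_len(V), chosen)
  target <- sample1(target_pool)
  keepmap <- integer(V)
  keepmap[setdiff(seq_len(V), chosen)] <- seq_along(setdiff(seq_len(V), chosen))
  new <- drop_nodes(model, chosen)
  new <- add_node(new, genes, keepmap[target])
  sz2 <- node_sizes(new)
  lv2 <- leaf_nodes(new)
  n_detach <- length(lv2[sz2[lv2] <= ATTACH_MAX])
  list(model = new,
       log_inner_fwd = -log(smax) - lchoose(length(cs), s) - log(length(target_pool)),
       log_inner_bwd = -log(n_detach))
}

propose_detach_into_simple <- function(model) {
  sz <- node_sizes(model)
  lv <- leaf_nodes(model)
  cand <- lv[sz[lv] <= ATTACH_MAX]
  v <- sample1(cand)
  genes <- model$nodes[[v]]
  s <- length(genes)
  new <- drop_nodes(model, v)
  for (g in genes) new <- add_node(new, g, 1L)
  cs2 <- childless_simple_nodes(new)
  V2 <- n_nodes(new)
  list(model = new,
       log_inner_fwd = -log(length(cand)),
       log_inner_bwd = -log(min(ATTACH_MAX, length(cs2))) -
         lchoose(length(cs2), s) - log(V2 - s))
}

propose_p2d <- function(model) {
  nP <- length(model$passengers)
  V <- n_nodes(model)
  g <- sample1(model$passengers)
  v <- if (V == 2) 2L else sample1(2:V)
  new <- model
  new$passengers <- setdiff(new$passengers, g)
  new$nodes[[v]] <- c(new$nodes[[v]], g)
  n_elig <- nrow(removable_genes(new))
  list(model = new,
       log_inner_fwd = -log(nP) - log(V - 1),
       log_inner_bwd = -log(n_elig))
}

propose_d2p <- function(model) {
  elig <- removable_genes(model)
  j <- sample.int(nrow(elig), 1L)
  v <- elig[j, 1]; pos <- elig[j, 2]
  g <- model$nodes[[v]][pos]
  new <- model
  new$nodes[[v]] <- new$nodes[[v]][-pos]
  new$passengers <- c(new$passengers, g)
  V <- n_nodes(new)
  list(model = new,
       log_inner_fwd = -log(nrow(elig)),
       log_inner_bwd = -log(length(new$passengers)) - log(V - 1))
}

propose_s2d <- function(model) {
  cs <- childless_simple_nodes(model)
  V <- n_nodes(model)
  v <- sample1(cs)
  target_pool <- setdiff(2:V, v)
  target <- sample1(target_pool)
  g <- model$nodes[[v]][1]
  new <- model
  new$nodes[[target]] <- c(new$nodes[[target]], g)
  new <- drop_nodes(new, v)
  n_elig <- nrow(removable_genes(new))
  list(model = new,
       log_inner_fwd = -log(length(cs)) - log(length(target_pool)),
       log_inner_bwd = -log(n_elig))
}

propose_d2s <- function(model) {
  elig <- removable_genes(model)
  j <- sample.int(nrow(elig), 1L)
  v <- elig[j, 1]; pos <- elig[j, 2]
  g <- model$nodes[[v]][pos]
  new <- model
  new$nodes[[v]] <- new$nodes[[v]][-pos]
  new <- add_node(new, g, 1L)
  cs2 <- childless_simple_nodes(new)
  V2 <- n_nodes(new)
  list(model = new,
       log_inner_fwd = -log(nrow(elig)),
       log_inner_bwd = -log(length(cs2)) - log(V2 - 2))
}

propose_gene_swap <- function(model) {
  V <- n_nodes(model)
  cand <- which(model$parent[-1] != 1L) + 1L
  v <- sample1(cand)
  u <- model$parent[v]
  new <- model
  tmp <- new$nodes[[u]]
  new$nodes[[u]] <- new$nodes[[v]]
  new$nodes[[v]] <- tmp
  list(model = new,
       log_inner_fwd = -log(length(cand)),
       log_inner_bwd = -log(length(cand)))
}

propose_spr <- function(model) {
  V <- n_nodes(model)
  cand <- spr_candidates(model)
  v <- sample1(cand)
  sub <- subtree_nodes(model, v)
  targets <- setdiff(seq_len(V), c(sub, model$parent[v]))
  t <- sample1(targets)
  new <- model
  new$parent[v] <- t
  cand2 <- spr_candidates(new)
  n_targets2 <- V - length(sub) - 1L
  list(model = new,
       log_inner_fwd = -log(length(cand)) - log(length(targets)),
       log_inner_bwd = -log(length(cand2)) - log(n_targets2))
}

PROPOSERS <- list(
  vertical_merge = propose_vertical_merge,
  vertical_split = propose_vertical_split,
  horizontal_merge = propose_horizontal_merge,
  horizontal_split = propose_horizontal_split,
  attach_from_passengers = propose_attach_from_passengers,
  detach_into_passengers = propose_detach_into_passengers,
  attach_from_simple = propose_attach_from_simple,
  detach_into_simple = propose_detach_into_simple,
  p2d = propose_p2d,
  d2p = propose_d2p,
  s2d = propose_s2d,
  d2s = propose_d2s,
  gene_swap = propose_gene_swap,
  spr = propose_spr
)

INVERSE_TYPE <- c(
  vertical_merge = "vertical_split", vertical_split = "vertical_merge",
  horizontal_merge = "horizontal_split", horizontal_split = "horizontal_merge",
  attach_from_passengers = "detach_into_passengers",
  detach_into_passengers = "attach_from_passengers",
  attach_from_simple = "detach_into_simple",
  detach_into_simple = "attach_from_simple",
  p2d = "d2p", d2p = "p2d", s2d = "d2s", d2s = "s2d",
  gene_swap = "gene_swap", spr = "spr"
)

#' Propose a structural move
#'
#' Selects a move type uniformly among the types applicable to the current
#' structure, draws the move's inner choices uniformly, and returns the
#' proposed structure together with the exact forward and backward log
#' proposal probabilities (both including the type-selection factor), ready
#' for the Metropolis-Hastings ratio.
#'
#' @param model current `tomexo_model`.
#' @return list with `model` (proposed structure, firing probabilities not yet
#'   refreshed), `type`, `log_fwd`, `log_bwd`.
#' @export
propose_move <- function(model) {
  app <- applicable_moves(model)
  if (!length(app)) stop("no applicable structural move (degenerate model)")
  type <- sample1(app)
  prop <- PROPOSERS[[type]](model)
  app2 <- applicable_moves(prop$model)
  inv <- INVERSE_TYPE[[type]]
  if (!(inv %in% app2))
    stop(sprintf("internal error: inverse move %s not applicable after %s", inv, type))
  list(model = prop$model, type = type,
       log_fwd = -log(length(app)) + prop$log_inner_fwd,
       log_bwd = -log(length(app2)) + prop$log_inner_bwd)
}
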