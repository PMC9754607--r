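#' Number of distinct noise-free tumor vectors of a model
#'
#' Counts the support of the generative process: a node contributes one "not
#' fired" state plus, when fired, one choice of driver gene combined with any
#' state of each child subtree. The post-order recursion is
#' `c(v) = 1 + |D_v| * prod_{u in children(v)} c(u)` for driver nodes and
#' `|S| = prod_{u in children(root)} c(u)` at the root; passengers are always
#' zero in the noise-free matrix and contribute no states. This cardinality
#' defines the structure prior, see [log_prior()].
#'
#' Counts grow multiplicatively with the tree, so the computation uses exact
#' arbitrary-precision integer arithmetic throughout.
#'
#' @param model a `tomexo_model`.
#' @return the exact count as a `tomexo_count` object; coerce with
#'   `as.numeric()` (exact up to 2^53) or `as.character()`.
#' @export
count_noise_free_states <- function(model) {
  V <- n_nodes(model)
  kids <- model_children(model)
  cnt <- vector("list", V)
  for (v in model_postorder(model)) {
    acc <- big_from_int(length(model$nodes[[v]]))
    for (u in kids[[v]]) acc <- big_mul(acc, cnt[[u]])
    cnt[[v]] <- big_add_small(acc, 1)
  }
  acc <- big_from_int(1)
  for (u in kids[[1]]) acc <- big_mul(acc, cnt[[u]])
  structure(list(digits = acc), class = "tomexo_count")
}

#' @export
as.numeric.tomexo_count <- function(x, ...) big_to_numeric(x$digits)

#' @export
as.character.tomexo_count <- function(x, ...) big_to_string(x$digits)

#' @export
print.tomexo_count <- function(x, ...) {
  cat(big_to_string(x$digits), "\n")
  invisible(x)
}

# log |S_{B*}(T)|, computed exactly in log space (no overflow for any tree)
log_count_states <- function(model) {
  V <- n_nodes(model)
  kids <- model_children(model)
  lg <- numeric(V)
  for (v in model_postorder(model)) {
    s <- log(length(model$nodes[[v]])) + sum(lg[kids[[v]]])
    lg[v] <- logaddexp(0, s)
  }
  sum(lg[kids[[1]]])
}

#' Log structure prior
#'
#' Unnormalised log prior `-zeta * log |S_B*(T)|`: models able to generate
#' many distinct noise-free tumor vectors are penalised, with `zeta`
#' controlling the strength. Only prior ratios are ever used, so the missing
#' normalising constant is irrelevant.
#'
#' @param model a `tomexo_model`.
#' @param zeta non-negative penalty exponent (default 5, the value used for
#'   all analyses).
#' @return log prior (a non-positive real).
#' @export
log_prior <- function(model, zeta = 5) {
  if (zeta < 0) stop("zeta must be non-negative")
  -zeta * log_count_states(model)
}
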