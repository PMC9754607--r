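# Model-vs-truth F-scores for synthetic benchmarks, and method-independent
# probabilistic-causation statistics (progression and mutual-exclusivity
# scores with binomial tail p-values) for fitted models on real data.

#' Relations implied by a progression model
#'
#' Mutual-exclusivity relations are unordered pairs of genes sharing a node;
#' progression relations are ordered pairs (g1, g2) where the node holding g1
#' is a strict ancestor of the node holding g2.
#'
#' @param model a `tomexo_model`.
#' @return list with `me_pairs` (2-column character matrix, rows sorted
#'   within pair) and `pr_pairs` (2-column character matrix, ancestor gene
#'   first).
#' @export
relation_sets <- function(model) {
  V <- n_nodes(model)
  me <- matrix(character(0), 0, 2)
  pr <- matrix(character(0), 0, 2)
  if (V >= 2) {
    for (v in 2:V) {
      g <- sort(model$nodes[[v]])
      if (length(g) >= 2) {
        cmb <- t(utils::combn(g, 2))
        me <- rbind(me, cmb)
      }
    }
    anc <- function(v) {
      out <- integer(0)
      u <- model$parent[v]
      while (!is.na(u) && u != 1L) { out <- c(out, u); u <- model$parent[u] }
      out
    }
    for (v in 2:V) {
      for (a in anc(v)) {
        pr <- rbind(pr, as.matrix(expand.grid(model$nodes[[a]], model$nodes[[v]],
                                              stringsAsFactors = FALSE)))
      }
    }
  }
  dimnames(me) <- list(NULL, c("g1", "g2"))
  dimnames(pr) <- list(NULL, c("ancestor", "descendant"))
  list(me_pairs = me, pr_pairs = pr)
}

pair_keys <- function(mat, ordered) {
  if (nrow(mat) == 0) return(character(0))
  if (!ordered) mat <- t(apply(mat, 1, sort))
  unique(paste(mat[, 1], mat[, 2], sep = "\r"))
}

f_component <- function(pred_keys, true_keys) {
  if (length(pred_keys) == 0 && length(true_keys) == 0) return(1)
  if (length(pred_keys) == 0 || length(true_keys) == 0) return(0)
  tp <- length(intersect(pred_keys, true_keys))
  prec <- tp / length(pred_keys)
  rec <- tp / length(true_keys)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' F-scores of a predicted model against the generative truth
#'
#' Precision and recall on the mutual-exclusivity and progression relation
#' sets give `F_ME` and `F_PR`; the overall score is their harmonic mean.
#' A relation set that is empty in the prediction but not in the truth (or
#' vice versa) scores 0; two empty sets score 1; a harmonic mean with any
#' zero component is 0 — so the star tree always scores `F_overall = 0`
#' against a non-trivial truth, and only the exact relation sets reach 1.
#'
#' @param predicted,truth `tomexo_model`s over the same gene universe.
#' @return named numeric `c(F_ME, F_PR, F_overall)`.
#' @export
f_scores <- function(predicted, truth) {
  if (!setequal(predicted$genes, truth$genes))
    stop("predicted and truth models have different gene universes")
  rp <- relation_sets(predicted)
  rt <- relation_sets(truth)
  f_me <- f_component(pair_keys(rp$me_pairs, FALSE), pair_keys(rt$me_pairs, FALSE))
  f_pr <- f_component(pair_keys(rp$pr_pairs, TRUE), pair_keys(rt$pr_pairs, TRUE))
  f_all <- if (f_me + f_pr == 0) 0 else 2 * f_me * f_pr / (f_me + f_pr)
  c(F_ME = f_me, F_PR = f_pr, F_overall = f_all)
}

gene_set_indicator <- function(B, genes) {
  idx <- match(genes, colnames(B))
  if (anyNA(idx)) stop("gene(s) not in the matrix: ",
                       paste(genes[is.na(idx)], collapse = ", "))
  rowSums(B[, idx, drop = FALSE]) > 0
}

#' Progression score between two gene sets
#'
#' Normalised difference of the target's mutation rate among tumors with and
#' without a mutation in the source set:
#' `(p(v|u) - p(v|not u)) / (p(v|u) + p(v|not u))`, in `[-1, 1]`. Positive
#' values mean the source promotes the target; comparing the two directions
#' indicates the more plausible causal orientation. A mutation in a gene set
#' means at least one of its genes is mutated.
#'
#' @param B binary mutation matrix.
#' @param source_genes,target_genes non-empty character vectors of gene
#'   labels.
#' @return the score, or `NA` when undefined (a conditioning group is empty
#'   or both conditional rates are zero).
#' @export
progression_score <- function(B, source_genes, target_genes) {
  if (!length(source_genes) || !length(target_genes))
    stop("source and target gene sets must be non-empty")
  u <- gene_set_indicator(B, source_genes)
  v <- gene_set_indicator(B, target_genes)
  if (!any(u) || all(u)) return(NA_real_)
  a <- mean(v[u]); b <- mean(v[!u])
  if (a + b == 0) return(NA_real_)
  (a - b) / (a + b)
}

me_direction <- function(B, g, w) {
  ig <- gene_set_indicator(B, g)
  iw <- gene_set_indicator(B, w)
  if (!any(iw) || all(iw)) return(NA_real_)
  a <- mean(ig[!iw]); b <- mean(ig[iw])
  if (a + b == 0) return(NA_real_)
  (a - b) / (a + b)
}

#' Mutual-exclusivity score of a gene pair
#'
#' Average of the exclusivity signal in both directions:
#' `0.5 * [ (p(g|not w) - p(g|w)) / (p(g|not w) + p(g|w)) + (symmetric) ]`,
#' in `[-1, 1]`; 1 means perfect exclusivity.
#'
#' @param B binary mutation matrix.
#' @param g,w gene labels.
#' @return the score, or `NA` when undefined.
#' @export
mutual_exclusivity_score <- function(B, g, w) {
  d1 <- me_direction(B, g, w)
  d2 <- me_direction(B, w, g)
  0.5 * (d1 + d2)
}

#' Mutual-exclusivity score of a node
#'
#' Mean pairwise [mutual_exclusivity_score()] over all unordered gene pairs
#' of the node; `NA` for single-gene nodes.
#'
#' @param B binary mutation matrix.
#' @param node_genes character vector of the node's genes.
#' @return mean score or `NA`.
#' @export
node_me_score <- function(B, node_genes) {
  if (length(node_genes) < 2) return(NA_real_)
  prs <- utils::combn(node_genes, 2)
  mean(apply(prs, 2, function(p) mutual_exclusivity_score(B, p[1], p[2])))
}

#' Progression p-value
#'
#' Upper binomial tail for the null that the target mutates independently at
#' its overall empirical rate: the probability of seeing at least the
#' observed number of co-mutated tumors among the source-mutated ones.
#'
#' @inheritParams progression_score
#' @return p-value in `[0, 1]`, or `NA` when no tumor carries the source.
#' @export
progression_pvalue <- function(B, source_genes, target_genes) {
  u <- gene_set_indicator(B, source_genes)
  v <- gene_set_indicator(B, target_genes)
  n_u <- sum(u)
  if (n_u == 0) return(NA_real_)
  n_uv <- sum(u & v)
  p_v <- mean(v)
  stats::pbinom(n_uv - 1, n_u, p_v, lower.tail = FALSE)
}

me_pvalue_direction <- function(B, g, w) {
  ig <- gene_set_indicator(B, g)
  iw <- gene_set_indicator(B, w)
  n_g <- sum(ig)
  if (n_g == 0) return(NA_real_)
  n_gw <- sum(ig & iw)
  stats::pbinom(n_gw, n_g, mean(iw))
}

#' Mutual-exclusivity p-value of a gene pair
#'
#' Lower binomial tail in each direction (probability of at most the observed
#' number of co-mutated tumors under independence), averaged over the two
#' directions.
#'
#' @inheritParams mutual_exclusivity_score
#' @return p-value or `NA`.
#' @export
mutual_exclusivity_pvalue <- function(B, g, w) {
  mean(c(me_pvalue_direction(B, g, w), me_pvalue_direction(B, w, g)))
}

#' Mutual-exclusivity p-value of a node
#'
#' Mean pairwise [mutual_exclusivity_pvalue()] over the node's gene pairs.
#'
#' @inheritParams node_me_score
#' @return mean p-value or `NA` for single-gene nodes.
#' @export
node_me_pvalue <- function(B, node_genes) {
  if (length(node_genes) < 2) return(NA_real_)
  prs <- utils::combn(node_genes, 2)
  mean(apply(prs, 2, function(p) mutual_exclusivity_pvalue(B, p[1], p[2])))
}

#' Score report for a fitted model
#'
#' Annotates every driver-to-driver edge with the progression score and its
#' binomial p-value, and every multi-gene node with the mutual-exclusivity
#' score and p-value (with the per-pair breakdown). No multiple-testing
#' correction is applied; `n_tests` is reported so users can adjust.
#'
#' @param B binary mutation matrix.
#' @param model a `tomexo_model` over the matrix genes.
#' @return object of class `tomexo_score_report`: data.frames `edges`,
#'   `nodes`, `me_pairs`, plus `n_tests`.
#' @export
score_report <- function(B, model) {
  V <- n_nodes(model)
  edges <- data.frame(parent = character(0), child = character(0),
                      lambda_pr = numeric(0), p_pr = numeric(0),
                      n_u = integer(0), n_uv = integer(0))
  nodes <- data.frame(node = character(0), lambda_me = numeric(0),
                      p_me = numeric(0))
  mep <- data.frame(g1 = character(0), g2 = character(0),
                    lambda_me = numeric(0), p_me = numeric(0))
  if (V >= 2) {
    for (v in 2:V) {
      u <- model$parent[v]
      if (u != 1L) {
        su <- model$nodes[[u]]; sv <- model$nodes[[v]]
        iu <- gene_set_indicator(B, su); iv <- gene_set_indicator(B, sv)
        edges <- rbind(edges, data.frame(
          parent = paste(su, collapse = ","),
          child = paste(sv, collapse = ","),
          lambda_pr = progression_score(B, su, sv),
          p_pr = progression_pvalue(B, su, sv),
          n_u = sum(iu), n_uv = sum(iu & iv)))
      }
      if (length(model$nodes[[v]]) >= 2) {
        nodes <- rbind(nodes, data.frame(
          node = paste(model$nodes[[v]], collapse = ","),
          lambda_me = node_me_score(B, model$nodes[[v]]),
          p_me = node_me_pvalue(B, model$nodes[[v]])))
        prs <- utils::combn(sort(model$nodes[[v]]), 2)
        for (j in seq_len(ncol(prs))) {
          mep <- rbind(mep, data.frame(
            g1 = prs[1, j], g2 = prs[2, j],
            lambda_me = mutual_exclusivity_score(B, prs[1, j], prs[2, j]),
            p_me = mutual_exclusivity_pvalue(B, prs[1, j], prs[2, j])))
        }
      }
    }
  }
  structure(list(edges = edges, nodes = nodes, me_pairs = mep,
                 n_tests = nrow(edges) + nrow(mep)),
            class = "tomexo_score_report")
}

#' @export
print.tomexo_score_report <- function(x, ...) {
  cat("Progression edges:\n"); print(x$edges)
  cat("Mutually exclusive nodes:\n"); print(x$nodes)
  invisible(x)
}
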