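# Shared model fixtures, built in code.

# chain root -> {g1} -> {g2}
chain2 <- function(f = c(0.5, 0.5)) {
  progression_model(
    nodes = list(character(0), "g1", "g2"),
    parent = c(NA, 1L, 2L), f = c(NA, f),
    genes = c("g1", "g2"))
}

# chain of three single-gene nodes
chain3 <- function(f = c(0.6, 0.5, 0.4)) {
  progression_model(
    nodes = list(character(0), "g1", "g2", "g3"),
    parent = c(NA, 1L, 2L, 3L), f = c(NA, f),
    genes = c("g1", "g2", "g3"))
}

# root -> {a,b} -> {c}, one passenger
vee_model <- function(f = c(0.7, 0.5)) {
  progression_model(
    nodes = list(character(0), c("a", "b"), "c"),
    parent = c(NA, 1L, 2L), f = c(NA, f),
    passengers = "p1",
    genes = c("a", "b", "c", "p1"))
}

# a broader 4-node tree over 7 genes with a passenger
bushy_model <- function() {
  progression_model(
    nodes = list(character(0), c("g1", "g2"), "g3", c("g4", "g5"), "g6"),
    parent = c(NA, 1L, 2L, 2L, 1L),
    f = c(NA, 0.8, 0.5, 0.6, 0.4),
    passengers = "p1",
    genes = c("g1", "g2", "g3", "g4", "g5", "g6", "p1"))
}

# random valid model over n_genes (drivers + passengers), for property tests
random_model <- function(n_genes, max_nodes = 4) {
  genes <- paste0("g", seq_len(n_genes))
  n_drivers <- sample.int(n_genes, 1)
  drivers <- sample(genes, n_drivers)
  n_nodes_d <- sample.int(min(max_nodes, n_drivers), 1)
  assign <- sort(sample.int(n_nodes_d, n_drivers, replace = TRUE))
  assign <- match(assign, unique(assign))        # 1..k contiguous
  k <- max(assign)
  nodes <- c(list(character(0)), split(drivers, assign))
  parent <- c(NA_integer_, vapply(seq_len(k), function(v)
    if (v == 1) 1L else sample.int(v, 1), 1L))   # parent among earlier nodes
  f <- c(NA, stats::runif(k, 0.2, 0.9))
  progression_model(nodes = nodes, parent = parent, f = f,
                    passengers = setdiff(genes, drivers), genes = genes)
}

# canonical structure key, invariant to node indexing and within-node gene
# order: nested parenthesisation from the root with sorted children, plus
# the sorted passenger set
model_key <- function(model) {
  kids <- tomexo:::model_children(model)
  rec <- function(v) {
    lab <- paste(sort(model$nodes[[v]]), collapse = ",")
    ch <- sort(vapply(kids[[v]], rec, ""))
    paste0("(", lab, if (length(ch)) paste0("|", paste(ch, collapse = ";")), ")")
  }
  paste0(rec(1), "P:", paste(sort(model$passengers), collapse = ","))
}

# every distinct structure over two genes (firing probabilities are
# placeholders; the sampler ties them to the data)
all_models_2genes <- function(genes = c("g1", "g2")) {
  g1 <- genes[1]; g2 <- genes[2]
  list(
    progression_model(list(character(0)), NA_integer_, NA_real_,
                      passengers = genes, genes = genes),
    progression_model(list(character(0), g1), c(NA, 1L), c(NA, .5),
                      passengers = g2, genes = genes),
    progression_model(list(character(0), g2), c(NA, 1L), c(NA, .5),
                      passengers = g1, genes = genes),
    star_tree(genes),
    progression_model(list(character(0), g1, g2), c(NA, 1L, 2L), c(NA, .5, .5),
                      genes = genes),
    progression_model(list(character(0), g2, g1), c(NA, 1L, 2L), c(NA, .5, .5),
                      genes = genes),
    progression_model(list(character(0), c(g1, g2)), c(NA, 1L), c(NA, .5),
                      genes = genes)
  )
}
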