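# Readers/writers: delimited mutation matrices, the JSON model schema, and
# Graphviz export of annotated progression models.

#' Read a binary mutation matrix from delimited text
#'
#' Comma or tab delimiter is auto-detected from the header line. The file
#' must have a header row of gene labels and a first column of tumor labels
#' (or the transpose, with `genes_in_rows = TRUE`). Any non-binary cell is
#' rejected with its row/column coordinates.
#'
#' @param path file path.
#' @param genes_in_rows set `TRUE` when genes are rows and tumors columns.
#' @return labelled binary matrix (tumors x genes).
#' @export
read_matrix <- function(path, genes_in_rows = FALSE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  B <- as.matrix(df)
  if (genes_in_rows) B <- t(B)
  if (anyDuplicated(rownames(B))) stop("duplicate tumor labels")
  if (anyDuplicated(colnames(B))) stop("duplicate gene labels")
  bad <- which(!(B %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(B)) + 1
    j <- ((bad[1] - 1) %/% nrow(B)) + 1
    stop(sprintf("non-binary entry '%s' at tumor '%s', gene '%s'",
                 B[bad[1]], rownames(B)[i], colnames(B)[j]))
  }
  storage.mode(B) <- "integer"
  B
}

#' Write a binary mutation matrix as delimited text
#'
#' @param B labelled binary matrix.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_matrix <- function(B, path, sep = "\t") {
  utils::write.table(B, path, sep = sep, quote = FALSE, col.names = NA)
}

#' Write a progression model to JSON
#'
#' Schema: `{nodes: [{id, parent, genes, f}], passengers, genes}`; the root
#' has id `"root"`, no genes and no `f`. Firing probabilities are written at
#' full precision so the round-trip is bit-exact.
#'
#' @param model a `tomexo_model`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  V <- n_nodes(model)
  ids <- c("root", if (V >= 2) paste0("n", 2:V))
  nodes <- lapply(seq_len(V), function(v) {
    if (v == 1) list(id = "root", genes = I(character(0)))
    else list(id = ids[v], parent = ids[model$parent[v]],
              genes = I(model$nodes[[v]]), f = model$f[v])
  })
  jsonlite::write_json(
    list(nodes = nodes, passengers = I(model$passengers), genes = I(model$genes)),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
}

#' Read a progression model from JSON
#'
#' Validates the schema written by [write_model()]; violations are reported
#' with the JSON path of the offending field.
#'
#' @param path file path.
#' @return a validated `tomexo_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$nodes) || is.null(doc$genes))
    stop("model JSON: missing $nodes or $genes")
  ids <- vapply(doc$nodes, function(n) n$id %||% NA_character_, "")
  if (anyNA(ids) || anyDuplicated(ids)) stop("model JSON: $nodes[*].id missing or duplicated")
  root_pos <- which(ids == "root")
  if (length(root_pos) != 1) stop("model JSON: exactly one node must have id 'root'")
  ord <- c(root_pos, setdiff(seq_along(ids), root_pos))
  ids <- ids[ord]
  docn <- doc$nodes[ord]
  V <- length(docn)
  nodes <- vector("list", V)
  parent <- rep(NA_integer_, V)
  f <- rep(NA_real_, V)
  nodes[[1]] <- character(0)
  if (V >= 2) for (v in 2:V) {
    n <- docn[[v]]
    loc <- sprintf("$nodes[id=%s]", ids[v])
    pid <- n$parent %||% NA_character_
    pidx <- match(pid, ids)
    if (is.na(pidx)) stop(sprintf("%s.parent: unknown node id '%s'", loc, pid))
    parent[v] <- pidx
    nodes[[v]] <- as.character(unlist(n$genes))
    fv <- n$f %||% NA_real_
    if (!is.numeric(fv) || is.na(fv) || fv <= 0 || fv >= 1)
      stop(sprintf("%s.f: firing probability must lie in (0,1)", loc))
    f[v] <- fv
  }
  progression_model(nodes = nodes, parent = parent, f = f,
                    passengers = as.character(unlist(doc$passengers)),
                    genes = as.character(unlist(doc$genes)))
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export a progression model as Graphviz DOT
#'
#' One box per driver node listing its genes, edges parent to child, and a
#' darker separate box for the passenger set. With a [score_report()], edges
#' are annotated with the progression score and p-value and multi-gene nodes
#' with the mutual-exclusivity score and p-value. Output is deterministic for
#' a fixed input.
#'
#' @param model a `tomexo_model`.
#' @param report optional `tomexo_score_report` for annotations.
#' @return a single DOT document as a character scalar.
#' @export
export_dot <- function(model, report = NULL) {
  V <- n_nodes(model)
  lines <- c("digraph progression {",
             "  node [shape=box, style=filled, fillcolor=white];",
             "  root [label=\"root\", shape=ellipse];")
  node_extra <- function(v) {
    if (is.null(report)) return("")
    key <- paste(model$nodes[[v]], collapse = ",")
    row <- report$nodes[report$nodes$node == key, ]
    if (nrow(row) == 0) return("")
    sprintf("\\nlambda_ME=%.2f p=%.2g", row$lambda_me[1], row$p_me[1])
  }
  edge_extra <- function(u, v) {
    if (is.null(report) || u == 1L) return("")
    ku <- paste(model$nodes[[u]], collapse = ",")
    kv <- paste(model$nodes[[v]], collapse = ",")
    row <- report$edges[report$edges$parent == ku & report$edges$child == kv, ]
    if (nrow(row) == 0) return("")
    sprintf(" [label=\"lambda_PR=%.2f p=%.2g\"]", row$lambda_pr[1], row$p_pr[1])
  }
  if (V >= 2) for (v in 2:V) {
    lab <- paste0(paste(model$nodes[[v]], collapse = "\\n"), node_extra(v))
    lines <- c(lines, sprintf("  n%d [label=%s];", v, dot_quote(lab)))
  }
  if (V >= 2) for (v in 2:V) {
    from <- if (model$parent[v] == 1L) "root" else sprintf("n%d", model$parent[v])
    lines <- c(lines, sprintf("  %s -> n%d [label=\"f=%.2f\"]%s;",
                              from, v, model$f[v], edge_extra(model$parent[v], v)))
  }
  if (length(model$passengers)) {
    lines <- c(lines, sprintf(
      "  passengers [label=%s, fillcolor=gray70];",
      dot_quote(paste0("passengers\\n", paste(model$passengers, collapse = "\\n")))))
  }
  paste(c(lines, "}"), collapse = "\n")
}
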