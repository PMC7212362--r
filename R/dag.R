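#' Construct a disease ancestor DAG
#'
#' A disease's semantic context is its set of ancestor terms `T(D)` (the
#' disease plus all its ancestors) and the parent-to-child edges `E(D)`
#' among them, as induced by a MeSH-style hierarchy. The structure must be
#' acyclic and every node must lie on a directed path down to the target
#' disease.
#'
#' @param target Disease identifier (must appear in `nodes`).
#' @param nodes Character vector of term ids, `T(D)`.
#' @param edges Two-column data frame or matrix of directed edges
#'   `(parent, child)`, `E(D)`. May have zero rows for a single-node DAG.
#' @return A list of class `"disease_dag"` with elements `target`, `nodes`,
#'   and `edges` (a two-column character matrix).
#' @export
disease_dag <- function(target, nodes, edges = NULL) {
  nodes <- unique(as.character(nodes))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L,
                    dimnames = list(NULL, c("parent", "child")))
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    colnames(edges) <- c("parent", "child")
    edges <- unique(edges)
  }
  if (!target %in% nodes) {
    mda_abort(sprintf("disease '%s': target absent from its node set", target))
  }
  missing_nodes <- setdiff(unique(c(edges)), nodes)
  nodes <- c(nodes, missing_nodes)
  dag <- structure(list(target = target, nodes = nodes, edges = edges),
                   class = "disease_dag")
  validate_dag(dag)
  dag
}

# Acyclicity plus target-reachability: every node must be the target or one
# of its ancestors, i.e. have a directed path to the target.
validate_dag <- function(dag) {
  if (nrow(dag$edges) == 0L) {
    if (length(dag$nodes) > 1L) {
      mda_abort(sprintf(
        "disease '%s': node(s) %s cannot reach the target", dag$target,
        paste(setdiff(dag$nodes, dag$target), collapse = ", ")))
    }
    return(invisible(TRUE))
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(dag$edges), directed = TRUE,
    vertices = data.frame(name = dag$nodes)
  )
  if (!igraph::is_dag(g)) {
    mda_abort(sprintf("disease '%s': cycle detected in its DAG", dag$target))
  }
  reach <- igraph::subcomponent(g, dag$target, mode = "in")
  unreachable <- setdiff(dag$nodes, names(reach))
  if (length(unreachable)) {
    mda_abort(sprintf("disease '%s': node(s) %s cannot reach the target",
                      dag$target, paste(unreachable, collapse = ", ")))
  }
  invisible(TRUE)
}

# Children of `node` inside the DAG.
dag_children <- function(dag, node) {
  dag$edges[dag$edges[, "parent"] == node, "child"]
}

#' Read a corpus of disease DAGs from a TSV edge list
#'
#' Each row holds `(target_disease, node, parent)`; an empty parent field
#' marks `node` as a root of that disease's DAG. All rows sharing a target
#' disease jointly define its node and edge sets. Lines starting with `#`
#' are comments.
#'
#' @param path Path to the TSV file.
#' @return A named list of [disease_dag()] objects, one per target disease.
#' @export
read_dag_file <- function(path) {
  lines <- read_tsv_lines(path)
  keep <- !startsWith(trimws(lines$text), "#") & nzchar(trimws(lines$text))
  text <- lines$text[keep]
  no <- lines$no[keep]
  if (!length(text)) {
    mda_abort("no DAG rows", class = "heatmda_parse_error")
  }
  fields <- strsplit(text, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad)) {
    mda_abort(sprintf("line %d: expected (target_disease, node, parent) fields",
                      no[bad[1L]]),
              class = "heatmda_parse_error")
  }
  tgt <- vapply(fields, `[[`, "", 1L)
  node <- vapply(fields, `[[`, "", 2L)
  parent <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "", "")
  out <- lapply(unique(tgt), function(d) {
    sel <- tgt == d
    has_parent <- nzchar(parent[sel])
    disease_dag(
      target = d,
      nodes = unique(c(node[sel], parent[sel][has_parent])),
      edges = cbind(parent = parent[sel][has_parent],
                    child = node[sel][has_parent])
    )
  })
  names(out) <- unique(tgt)
  out
}

#' Write a corpus of disease DAGs as a TSV edge list
#'
#' Inverse of [read_dag_file()].
#'
#' @param dags Named list of `"disease_dag"` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dag_file <- function(dags, path) {
  rows <- unlist(lapply(dags, function(dag) {
    parents <- lapply(dag$nodes, function(n) {
      dag$edges[dag$edges[, "child"] == n, "parent"]
    })
    unlist(lapply(seq_along(dag$nodes), function(i) {
      p <- parents[[i]]
      if (!length(p)) {
        sprintf("%s\t%s\t", dag$target, dag$nodes[i])
      } else {
        sprintf("%s\t%s\t%s", dag$target, dag$nodes[i], p)
      }
    }))
  }), use.names = FALSE)
  write_lines_checked(c("# target_disease\tnode\tparent", rows), path)
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag> '%s': %d terms, %d edges\n",
              x$target, length(x$nodes), nrow(x$edges)))
  invisible(x)
}
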