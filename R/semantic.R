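#' Model-1 semantic contributions of a disease's ancestor terms
#'
#' Under the decay model, the disease contributes 1 to its own semantic
#' value, and each ancestor term contributes `semantic_delta` times the
#' largest contribution among its children within the DAG, so contributions
#' shrink geometrically with distance from the disease. The disease's
#' semantic value is the sum of all contributions.
#'
#' @param dag A [disease_dag()].
#' @param semantic_delta Decay factor in `(0, 1)`; conventionally 0.5.
#' @return A list of class `"semantic_contributions"` with elements `model`
#'   (1), `per_node` (named numeric vector over `T(D)`), and `total`.
#' @examples
#' dag <- disease_dag("d1", c("d1", "r"), cbind("r", "d1"))
#' semantic_contributions_model1(dag, 0.5)
#' @export
semantic_contributions_model1 <- function(dag, semantic_delta = 0.5) {
  check_in_range(semantic_delta, "semantic_delta", 0, 1,
                 lo_open = TRUE, hi_open = TRUE)
  validate_dag(dag)
  memo <- new.env(parent = emptyenv())
  contrib <- function(node) {
    if (!is.null(memo[[node]])) return(memo[[node]])
    val <- if (node == dag$target) {
      1
    } else {
      kids <- dag_children(dag, node)
      semantic_delta * max(vapply(kids, contrib, 0))
    }
    memo[[node]] <- val
    val
  }
  per_node <- vapply(dag$nodes, contrib, 0)
  names(per_node) <- dag$nodes
  structure(list(model = 1L, per_node = per_node, total = sum(per_node)),
            class = "semantic_contributions")
}

#' Model-2 semantic contributions based on corpus frequency
#'
#' The information-content variant: a term's contribution to any disease
#' containing it is `-log` of the fraction of corpus DAGs whose node set
#' contains the term (natural logarithm). Rare, specific terms contribute
#' more; a term present in every DAG contributes zero.
#'
#' @param dag A [disease_dag()] belonging to `dag_corpus`.
#' @param dag_corpus Named list of all diseases' DAGs.
#' @return A `"semantic_contributions"` list (model 2).
#' @export
semantic_contributions_model2 <- function(dag, dag_corpus) {
  if (!length(dag_corpus)) {
    mda_abort("empty DAG corpus")
  }
  validate_dag(dag)
  n_dis <- length(dag_corpus)
  counts <- vapply(dag$nodes, function(term) {
    sum(vapply(dag_corpus, function(d) term %in% d$nodes, NA))
  }, 0L)
  per_node <- -log(counts / n_dis)
  names(per_node) <- dag$nodes
  structure(list(model = 2L, per_node = per_node, total = sum(per_node)),
            class = "semantic_contributions")
}

#' @export
print.semantic_contributions <- function(x, ...) {
  cat(sprintf("<semantic_contributions model %d> total = %g\n",
              x$model, x$total))
  print(x$per_node)
  invisible(x)
}

#' @export
tidy.semantic_contributions <- function(x, ...) {
  tibble(term = names(x$per_node), contribution = unname(x$per_node),
         model = x$model)
}

# Shared DAG-overlap similarity given precomputed contributions.
dag_overlap_similarity <- function(dags, contribs) {
  ids <- names(dags)
  n <- length(ids)
  per_node <- lapply(contribs, `[[`, "per_node")
  totals <- vapply(contribs, `[[`, 0, "total")
  values <- matrix(0, n, n, dimnames = list(ids, ids))
  zero_pairs <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      shared <- intersect(names(per_node[[i]]), names(per_node[[j]]))
      denom <- totals[i] + totals[j]
      if (denom == 0) {
        zero_pairs <- zero_pairs + 1L
        next
      }
      values[i, j] <- values[j, i] <-
        sum(per_node[[i]][shared] + per_node[[j]][shared]) / denom
    }
  }
  diag(values) <- ifelse(totals > 0, 1, 0)
  list(values = values, zero_pairs = zero_pairs)
}

#' Disease semantic similarity, model 1
#'
#' Two diseases are similar to the extent that they share ancestor terms,
#' each shared term weighted by its model-1 contribution to both diseases:
#' `SS1(i, j) = sum_t (D1_i(t) + D1_j(t)) / (DV1(i) + DV1(j))` over shared
#' terms `t`.
#'
#' @param dags Named list of [disease_dag()] objects.
#' @param semantic_delta Decay factor, see [semantic_contributions_model1()].
#' @return A `"sim_matrix"` with role `"SS1"` over the corpus diseases.
#' @export
semantic_similarity_model1 <- function(dags, semantic_delta = 0.5) {
  if (!length(dags)) mda_abort("empty DAG corpus")
  contribs <- lapply(dags, semantic_contributions_model1, semantic_delta)
  res <- dag_overlap_similarity(dags, contribs)
  similarity_matrix(res$values, role = "SS1")
}

#' Disease semantic similarity, model 2
#'
#' Mirror of [semantic_similarity_model1()] with frequency-based (model-2)
#' contributions. Pairs whose combined semantic value is zero (possible in a
#' degenerate corpus where every term occurs in every DAG) get similarity 0
#' with a warning.
#'
#' @param dags Named list of [disease_dag()] objects.
#' @return A `"sim_matrix"` with role `"SS2"`.
#' @export
semantic_similarity_model2 <- function(dags) {
  if (!length(dags)) mda_abort("empty DAG corpus")
  contribs <- lapply(dags, semantic_contributions_model2, dag_corpus = dags)
  res <- dag_overlap_similarity(dags, contribs)
  if (res$zero_pairs > 0L) {
    mda_warn(sprintf(
      "%d disease pair(s) have zero combined model-2 semantic value; similarity set to 0",
      res$zero_pairs))
  }
  similarity_matrix(res$values, role = "SS2", check_diagonal = FALSE)
}
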