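#' Similarity-augmented bipartite adjacency
#'
#' Adds weighted edges to the binary association matrix wherever a
#' sufficiently similar neighbour carries a known association. On the miRNA
#' side, cell `(i, j)` with no known association receives the largest
#' `SM(i, t)` over miRNAs `t` that are associated with disease `j` and
#' exceed the threshold; the disease side is the exact mirror using `SD`
#' over diseases associated with miRNA `i`. Known associations stay exactly
#' 1 and are never overwritten.
#'
#' @param A Binary association matrix (miRNAs x diseases) with dimnames.
#' @param sim `"sim_matrix"` over miRNAs (side `"mirna"`) or diseases
#'   (side `"disease"`); labels must match the corresponding axis of `A`.
#' @param threshold Strict similarity threshold in `[0, 1]` (delta for the
#'   miRNA side, eta for the disease side). At `threshold = 1` no similarity
#'   can qualify and the augmented matrix equals `A`.
#' @param side `"mirna"` (builds A') or `"disease"` (builds A'').
#' @param degree_mode `"binary"` (count nonzero incident edges) or
#'   `"weighted"` (sum incident weights).
#' @return An object of class `"augmented_adjacency"`: a list with `values`
#'   (n x q weighted matrix), `side`, `threshold`, `degree_mode`,
#'   `mirna_degrees`, and `disease_degrees`.
#' @export
augment_adjacency <- function(A, sim, threshold,
                              side = c("mirna", "disease"),
                              degree_mode = c("binary", "weighted")) {
  side <- match.arg(side)
  degree_mode <- match.arg(degree_mode)
  check_in_range(threshold, "threshold", 0, 1)
  if (side == "mirna") {
    check_same_labels(rownames(sim), rownames(A), "SM labels vs miRNA axis")
  } else {
    check_same_labels(rownames(sim), colnames(A), "SD labels vs disease axis")
  }
  S <- unclass_matrix(sim)
  S_thr <- S * (S > threshold)
  n <- nrow(A)
  q <- ncol(A)
  values <- matrix(0, n, q, dimnames = dimnames(A))
  if (side == "mirna") {
    # candidates for column j: miRNAs associated with disease j
    for (j in seq_len(q)) {
      t_idx <- which(A[, j] == 1L)
      if (length(t_idx)) {
        values[, j] <- apply(S_thr[, t_idx, drop = FALSE], 1L, max)
      }
    }
  } else {
    # candidates for row i: diseases associated with miRNA i
    for (i in seq_len(n)) {
      t_idx <- which(A[i, ] == 1L)
      if (length(t_idx)) {
        values[i, ] <- apply(S_thr[, t_idx, drop = FALSE], 1L, max)
      }
    }
  }
  values[A == 1L] <- 1
  degrees <- adjacency_degrees(values, degree_mode)
  structure(
    list(values = values,
         side = if (side == "mirna") "mirna_augmented" else "disease_augmented",
         threshold = threshold, degree_mode = degree_mode,
         mirna_degrees = degrees$mirna, disease_degrees = degrees$disease),
    class = "augmented_adjacency"
  )
}

adjacency_degrees <- function(values, degree_mode) {
  if (degree_mode == "binary") {
    list(mirna = rowSums(values > 0), disease = colSums(values > 0))
  } else {
    list(mirna = rowSums(values), disease = colSums(values))
  }
}

#' @export
print.augmented_adjacency <- function(x, ...) {
  cat(sprintf(
    "<augmented_adjacency %s> %d x %d, threshold %g, %d weighted edges (%s degrees)\n",
    x$side, nrow(x$values), ncol(x$values), x$threshold,
    sum(x$values > 0), x$degree_mode))
  invisible(x)
}
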