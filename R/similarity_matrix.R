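#' Construct a labelled similarity matrix
#'
#' All similarity matrices in the pipeline share one container: a symmetric
#' matrix with values in `[0, 1]`, identical row/column labels, a `role`
#' naming which similarity it holds, and a logical coverage mask marking the
#' pairs for which the role's primary source is defined (used by the fusion
#' rules to decide when to fall back to an interaction-profile kernel).
#'
#' @param values Square numeric matrix with identical row and column names.
#' @param role One of `"SS1"`, `"SS2"`, `"KD"`, `"KM"`, `"FS"`, `"SD"`,
#'   `"SM"`.
#' @param coverage Logical matrix of the same shape (default: all `TRUE`).
#' @param check_diagonal Should a unit diagonal be required on covered
#'   entries? Kernel and integrated similarities always have one; a
#'   functional-similarity matrix supplied by the user must too.
#' @return A numeric matrix of class `"sim_matrix"` with attributes `role`
#'   and `coverage`.
#' @export
similarity_matrix <- function(values,
                              role = c("FS", "SS1", "SS2", "KD", "KM", "SD", "SM"),
                              coverage = NULL,
                              check_diagonal = TRUE) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    mda_abort(sprintf("%s matrix must be square, got %d x %d",
                      role, nrow(values), ncol(values)),
              class = "heatmda_shape_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    mda_abort(sprintf("%s matrix must carry row and column labels", role),
              class = "heatmda_label_error")
  }
  if (!all(rownames(values) == colnames(values))) {
    mda_abort(sprintf("%s matrix row/column labels differ", role),
              class = "heatmda_label_error")
  }
  if (anyDuplicated(rownames(values))) {
    mda_abort(sprintf("%s matrix has duplicate labels", role),
              class = "heatmda_label_error")
  }
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8) {
    mda_abort(sprintf("%s matrix is asymmetric (max |S - t(S)| = %g)",
                      role, asym))
  }
  values[] <- (values + t(values)) / 2
  out_of_range <- max(c(0, -min(values), max(values) - 1))
  if (out_of_range > 1e-6) {
    mda_abort(sprintf("%s matrix has values outside [0, 1] by %g",
                      role, out_of_range))
  }
  if (out_of_range > 0) {
    mda_warn(sprintf("%s matrix values clipped to [0, 1] (by at most %g)",
                     role, out_of_range))
    values[] <- pmin(pmax(values, 0), 1)
  }
  if (is.null(coverage)) {
    coverage <- matrix(TRUE, nrow(values), ncol(values))
  }
  coverage <- as.matrix(coverage)
  storage.mode(coverage) <- "logical"
  stopifnot(dim(coverage) == dim(values))
  dimnames(coverage) <- dimnames(values)
  if (check_diagonal) {
    dbad <- which(coverage[cbind(seq_len(nrow(values)), seq_len(nrow(values)))] &
                    abs(diag(values) - 1) > 1e-8)
    if (length(dbad)) {
      mda_abort(sprintf("%s matrix diagonal is not 1 at '%s'",
                        role, rownames(values)[dbad[1L]]))
    }
  }
  structure(values, role = role, coverage = coverage,
            class = c("sim_matrix", class(matrix())))
}

sim_role <- function(x) attr(x, "role")
sim_coverage <- function(x) attr(x, "coverage")

#' Read a square similarity matrix from TSV
#'
#' The file holds a header row of labels, then one row per entity with its
#' label in the first column. Row and column label sets must match; values
#' must form a symmetric matrix in `[0, 1]` (tiny overshoots up to 1e-6 are
#' clipped with a warning).
#'
#' @param path Path to the TSV file.
#' @param role Role to assign (see [similarity_matrix()]).
#' @param coverage_path Optional path to a companion TSV of the same layout
#'   holding 0/1 coverage flags.
#' @return A `"sim_matrix"`.
#' @export
read_similarity_tsv <- function(path, role = "FS", coverage_path = NULL) {
  values <- read_square_tsv(path, what = "similarity")
  coverage <- NULL
  if (!is.null(coverage_path)) {
    coverage <- read_square_tsv(coverage_path, what = "coverage")
    check_same_labels(rownames(coverage), rownames(values),
                      "coverage vs similarity labels")
    coverage <- coverage > 0.5
  }
  similarity_matrix(values, role = role, coverage = coverage,
                    check_diagonal = FALSE)
}

read_square_tsv <- function(path, what) {
  if (!file.exists(path)) {
    mda_abort(sprintf("file not found: %s", path), class = "heatmda_io_error")
  }
  df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    mda_abort(sprintf("%s file %s contains non-numeric cells", what, path),
              class = "heatmda_parse_error")
  }
  if (nrow(m) != ncol(m)) {
    mda_abort(sprintf("%s file %s is not square (%d x %d)",
                      what, path, nrow(m), ncol(m)),
              class = "heatmda_shape_error")
  }
  if (!setequal(rownames(m), colnames(m)) ||
      !all(rownames(m) == colnames(m))) {
    mda_abort(sprintf("%s file %s: row and column labels differ", what, path),
              class = "heatmda_label_error")
  }
  m
}

#' Write a similarity matrix (and optionally its coverage mask) as TSV
#'
#' @param sim A `"sim_matrix"`.
#' @param path Output path for the values.
#' @param coverage_path Optional output path for the 0/1 coverage mask.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path, coverage_path = NULL) {
  write_square_tsv(unclass_matrix(sim), path)
  if (!is.null(coverage_path)) {
    write_square_tsv(sim_coverage(sim) + 0L, coverage_path)
  }
  invisible(path)
}

write_square_tsv <- function(m, path) {
  header <- paste(c("id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format_score(m[i, ])), collapse = "\t")
  }, "")
  write_lines_checked(c(header, rows), path)
}

unclass_matrix <- function(x) {
  attr(x, "role") <- NULL
  attr(x, "coverage") <- NULL
  class(x) <- NULL
  x
}

#' Similarity matrix as a tidy pair table
#'
#' @param x A `"sim_matrix"`.
#' @param ... Unused.
#' @return A tibble with one row per unordered pair (upper triangle,
#'   diagonal included): `id1`, `id2`, `similarity`, `covered`.
#' @export
tidy.sim_matrix <- function(x, ...) {
  idx <- which(upper.tri(x, diag = TRUE), arr.ind = TRUE)
  tibble(
    id1 = rownames(x)[idx[, 1L]],
    id2 = colnames(x)[idx[, 2L]],
    similarity = x[idx],
    covered = sim_coverage(x)[idx]
  )
}

#' Heat-map of a similarity matrix
#'
#' @param object A `"sim_matrix"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(
    id1 = factor(rownames(object), levels = rownames(object)),
    id2 = factor(colnames(object), levels = colnames(object))
  )
  df$similarity <- as.vector(t(unclass_matrix(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id2, y = .data$id1,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = sim_role(object)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("<sim_matrix role=%s> %d x %d, %.0f%% covered\n",
              sim_role(x), nrow(x), ncol(x), 100 * mean(sim_coverage(x))))
  invisible(x)
}
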