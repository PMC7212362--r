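#' Build a binary miRNA-disease association matrix from a pair list
#'
#' The association matrix `A` has one row per miRNA and one column per
#' disease, with `A[i, j] = 1` exactly when the pair was observed. Identifier
#' order follows first appearance in the pair list; duplicate pairs collapse
#' to a single cell with a warning.
#'
#' @param pairs A data frame whose first two columns are miRNA and disease
#'   identifiers (character).
#' @return A binary integer matrix of class `"assoc_matrix"` with miRNA ids
#'   as rownames and disease ids as colnames.
#' @examples
#' association_matrix(data.frame(
#'   mirna_id = c("m1", "m2", "m2", "m3"),
#'   disease_id = c("d1", "d1", "d2", "d2")
#' ))
#' @export
association_matrix <- function(pairs) {
  if (!is.data.frame(pairs) || ncol(pairs) < 2L) {
    mda_abort("`pairs` must be a data frame with at least two columns")
  }
  if (nrow(pairs) == 0L) {
    mda_abort("no associations", class = "heatmda_parse_error")
  }
  m <- as.character(pairs[[1L]])
  d <- as.character(pairs[[2L]])
  if (anyNA(m) || anyNA(d) || any(m == "") || any(d == "")) {
    mda_abort("association pairs contain empty identifiers",
              class = "heatmda_parse_error")
  }
  key <- paste(m, d, sep = "\r")
  if (anyDuplicated(key)) {
    mda_warn(sprintf("%d duplicate association pair(s) collapsed",
                     sum(duplicated(key))))
    keep <- !duplicated(key)
    m <- m[keep]
    d <- d[keep]
  }
  mirnas <- unique(m)
  diseases <- unique(d)
  A <- matrix(0L, nrow = length(mirnas), ncol = length(diseases),
              dimnames = list(mirnas, diseases))
  A[cbind(match(m, mirnas), match(d, diseases))] <- 1L
  structure(A, class = c("assoc_matrix", class(matrix())))
}

#' Read a miRNA-disease association list from a TSV file
#'
#' Expects two or more tab-separated columns (miRNA id, disease id); lines
#' starting with `#` are comments. See [association_matrix()] for the
#' resulting matrix conventions.
#'
#' @param path Path to the TSV file.
#' @return An `"assoc_matrix"` binary matrix.
#' @export
read_associations <- function(path) {
  lines <- read_tsv_lines(path)
  keep <- !startsWith(trimws(lines$text), "#") & nzchar(trimws(lines$text))
  lines$text <- lines$text[keep]
  lines$no <- lines$no[keep]
  if (!length(lines$text)) {
    mda_abort("no associations", class = "heatmda_parse_error")
  }
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad)) {
    mda_abort(sprintf("line %d: expected at least 2 tab-separated fields",
                      lines$no[bad[1L]]),
              class = "heatmda_parse_error")
  }
  association_matrix(data.frame(
    mirna_id = vapply(fields, `[[`, "", 1L),
    disease_id = vapply(fields, `[[`, "", 2L)
  ))
}

#' Write an association matrix as a TSV pair list
#'
#' Inverse of [read_associations()]: emits one `(mirna_id, disease_id)` row
#' per nonzero cell, in row-major matrix order so that a read/write cycle is
#' the identity.
#'
#' @param assoc An `"assoc_matrix"` (or any labelled binary matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  idx <- which(t(assoc) == 1L, arr.ind = TRUE)
  rows <- sprintf("%s\t%s", rownames(assoc)[idx[, 2L]],
                  colnames(assoc)[idx[, 1L]])
  write_lines_checked(c("# mirna_id\tdisease_id", rows), path)
}

#' Association matrix as a tidy pair list
#'
#' @param x An `"assoc_matrix"`.
#' @param ... Unused.
#' @return A tibble with columns `mirna_id` and `disease_id`, one row per
#'   known association.
#' @export
tidy.assoc_matrix <- function(x, ...) {
  idx <- which(x == 1L, arr.ind = TRUE)
  tibble(
    mirna_id = rownames(x)[idx[, 1L]],
    disease_id = colnames(x)[idx[, 2L]]
  ) |>
    dplyr::arrange(match(.data$disease_id, colnames(x)),
                   match(.data$mirna_id, rownames(x)))
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d miRNAs x %d diseases, %d known associations\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

# --- low-level text IO ------------------------------------------------------

read_tsv_lines <- function(path) {
  if (!file.exists(path)) {
    mda_abort(sprintf("file not found: %s", path), class = "heatmda_io_error")
  }
  text <- readLines(path, warn = FALSE)
  list(text = text, no = seq_along(text))
}

write_lines_checked <- function(lines, path) {
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    mda_abort(sprintf("cannot write to: %s", path), class = "heatmda_io_error")
  }
  invisible(path)
}
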