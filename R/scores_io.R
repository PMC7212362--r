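#' Write association scores as long-format TSV
#'
#' One row per (miRNA, disease) pair with columns `mirna_id`, `disease_id`,
#' `score`, `known_flag`, sorted by disease (matrix order) then descending
#' score, ties broken by miRNA id. Scores are printed with 12 significant
#' digits so a write/read/write cycle reproduces the file byte for byte.
#'
#' @param scores A `"score_matrix"` from [bhc_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  df <- tidy(scores)
  rows <- sprintf("%s\t%s\t%s\t%d", df$mirna_id, df$disease_id,
                  format_score(df$score), as.integer(df$known))
  write_lines_checked(c("# mirna_id\tdisease_id\tscore\tknown_flag", rows),
                      path)
}

#' Read long-format association scores
#'
#' Inverse of [write_scores_tsv()]; reconstructs the score and known
#' matrices with miRNA/disease order taken from first appearance in the
#' file.
#'
#' @param path Path to the TSV file.
#' @return A `"score_matrix"` (with a default [run_config()] attached).
#' @export
read_scores_tsv <- function(path) {
  lines <- read_tsv_lines(path)
  keep <- !startsWith(trimws(lines$text), "#") & nzchar(trimws(lines$text))
  text <- lines$text[keep]
  no <- lines$no[keep]
  if (!length(text)) {
    mda_abort("no score rows", class = "heatmda_parse_error")
  }
  fields <- strsplit(text, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 4L)
  if (length(bad)) {
    mda_abort(sprintf("line %d: expected 4 tab-separated fields", no[bad[1L]]),
              class = "heatmda_parse_error")
  }
  m <- vapply(fields, `[[`, "", 1L)
  d <- vapply(fields, `[[`, "", 2L)
  s <- as.numeric(vapply(fields, `[[`, "", 3L))
  k <- as.integer(vapply(fields, `[[`, "", 4L))
  if (anyNA(s) || anyNA(k)) {
    mda_abort("non-numeric score or known_flag cell",
              class = "heatmda_parse_error")
  }
  mirnas <- unique(m)
  diseases <- unique(d)
  scores <- matrix(NA_real_, length(mirnas), length(diseases),
                   dimnames = list(mirnas, diseases))
  known <- matrix(0L, length(mirnas), length(diseases),
                  dimnames = list(mirnas, diseases))
  idx <- cbind(match(m, mirnas), match(d, diseases))
  scores[idx] <- s
  known[idx] <- k
  if (anyNA(scores)) {
    mda_abort("score table does not cover the full miRNA x disease grid",
              class = "heatmda_parse_error")
  }
  structure(list(scores = scores,
                 known = structure(known, class = c("assoc_matrix",
                                                    class(matrix()))),
                 config = run_config()),
            class = "score_matrix")
}
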