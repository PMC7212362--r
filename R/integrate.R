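#' Integrated disease similarity
#'
#' Fuses the two semantic similarity models with the interaction-profile
#' kernel: where both diseases of a pair have semantic information (per the
#' semantic matrices' coverage masks), the integrated similarity is the
#' plain average `(SS1 + SS2) / 2`; elsewhere it falls back to the kernel
#' value `KD`.
#'
#' @param ss1,ss2 `"sim_matrix"` objects with roles `"SS1"`/`"SS2"`.
#' @param kd `"sim_matrix"` with role `"KD"`. All three must share the same
#'   ordered label set (expand semantic matrices first with
#'   [expand_similarity()] if they cover only a subset of diseases).
#' @return A `"sim_matrix"` with role `"SD"` covering every pair.
#' @export
integrate_disease_similarity <- function(ss1, ss2, kd) {
  check_same_labels(rownames(ss1), rownames(kd), "SS1 vs KD")
  check_same_labels(rownames(ss2), rownames(kd), "SS2 vs KD")
  semantic_cov <- sim_coverage(ss1) & sim_coverage(ss2)
  values <- ifelse(semantic_cov,
                   (unclass_matrix(ss1) + unclass_matrix(ss2)) / 2,
                   unclass_matrix(kd))
  diag(values) <- 1
  dimnames(values) <- dimnames(kd)
  similarity_matrix(values, role = "SD")
}

#' Integrated miRNA similarity
#'
#' Uses the precomputed functional similarity `FS` wherever it is defined
#' (per its coverage mask) and the interaction-profile kernel `KM`
#' elsewhere.
#'
#' @param fs `"sim_matrix"` with role `"FS"` (may be `NULL` to use the
#'   kernel everywhere).
#' @param km `"sim_matrix"` with role `"KM"`, same ordered labels as `fs`.
#' @return A `"sim_matrix"` with role `"SM"`.
#' @export
integrate_mirna_similarity <- function(fs, km) {
  if (is.null(fs)) {
    out <- unclass_matrix(km)
    return(similarity_matrix(out, role = "SM"))
  }
  check_same_labels(rownames(fs), rownames(km), "FS vs KM")
  values <- ifelse(sim_coverage(fs), unclass_matrix(fs), unclass_matrix(km))
  diag(values) <- 1
  dimnames(values) <- dimnames(km)
  similarity_matrix(values, role = "SM")
}

#' Expand a similarity matrix onto a larger label set
#'
#' Entries involving labels absent from `sim` are zero and marked uncovered,
#' so downstream fusion falls back to the kernel there.
#'
#' @param sim A `"sim_matrix"`, or `NULL` (treated as covering nothing).
#' @param labels Ordered character vector of the full label set.
#' @param role Role for the expanded matrix (defaults to `sim`'s role).
#' @return A `"sim_matrix"` over `labels`.
#' @export
expand_similarity <- function(sim, labels, role = NULL) {
  if (is.null(sim)) {
    values <- matrix(0, length(labels), length(labels),
                     dimnames = list(labels, labels))
    coverage <- matrix(FALSE, length(labels), length(labels))
    return(similarity_matrix(values, role = role %||% "FS",
                             coverage = coverage, check_diagonal = FALSE))
  }
  role <- role %||% sim_role(sim)
  known <- intersect(labels, rownames(sim))
  missing <- setdiff(rownames(sim), labels)
  if (length(missing)) {
    mda_abort(sprintf("similarity labels not in target set: %s",
                      paste(head(missing, 5L), collapse = ", ")),
              class = "heatmda_label_error")
  }
  n <- length(labels)
  values <- matrix(0, n, n, dimnames = list(labels, labels))
  coverage <- matrix(FALSE, n, n)
  idx <- match(known, labels)
  values[idx, idx] <- unclass_matrix(sim)[known, known]
  coverage[idx, idx] <- sim_coverage(sim)[known, known]
  similarity_matrix(values, role = role, coverage = coverage,
                    check_diagonal = FALSE)
}

#' Build every similarity matrix the predictor needs
#'
#' Convenience wrapper running the whole similarity stage: semantic models
#' over the DAG corpus, interaction-profile kernels from the association
#' matrix, and the two fusions. Diseases without a DAG and miRNA pairs
#' without functional-similarity coverage fall back to the kernels.
#'
#' @param A `"assoc_matrix"` binary association matrix.
#' @param fs Optional `"sim_matrix"` of miRNA functional similarity; its
#'   labels must be a subset of `rownames(A)`.
#' @param dags Optional named list of [disease_dag()] objects; names must be
#'   a subset of `colnames(A)`.
#' @param config A [run_config()].
#' @return A named list with elements `ss1`, `ss2`, `kd`, `km`, `sd`, `sm`
#'   (all `"sim_matrix"`; `ss1`/`ss2` are `NULL` when no DAGs are given).
#' @export
build_similarities <- function(A, fs = NULL, dags = NULL,
                               config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  kd <- gip_kernel(A, "diseases", config$gip_bandwidth_d)
  km <- gip_kernel(A, "mirnas", config$gip_bandwidth_m)
  ss1 <- ss2 <- NULL
  if (!is.null(dags) && length(dags)) {
    ss1 <- semantic_similarity_model1(dags, config$semantic_delta)
    ss2 <- semantic_similarity_model2(dags)
  }
  sd_mat <- integrate_disease_similarity(
    expand_similarity(ss1, colnames(A), role = "SS1"),
    expand_similarity(ss2, colnames(A), role = "SS2"),
    kd
  )
  sm_mat <- integrate_mirna_similarity(
    if (is.null(fs)) NULL else expand_similarity(fs, rownames(A)),
    km
  )
  list(ss1 = ss1, ss2 = ss2, kd = kd, km = km, sd = sd_mat, sm = sm_mat)
}
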