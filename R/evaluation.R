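#' ROC curve and AUC from pooled positive and candidate scores
#'
#' Sweeps every distinct score as a threshold; at each threshold the true
#' positive rate is the fraction of positives scoring at or above it, and
#' the false positive rate the fraction of candidates doing so. The
#' trapezoidal area under the resulting curve equals the Mann-Whitney
#' statistic with midrank (half-credit) tie handling.
#'
#' @param positive_scores Numeric scores of the held-out known associations.
#' @param candidate_scores Numeric scores of the unknown pairs.
#' @return A list with `roc_points` (tibble of `fpr`, `tpr`, from (0, 0) to
#'   (1, 1)) and `auc`.
#' @examples
#' auc_from_ranks(c(2), c(1, 3))$auc # 0.5
#' @export
auc_from_ranks <- function(positive_scores, candidate_scores) {
  if (!length(positive_scores) || !length(candidate_scores)) {
    mda_abort("positive and candidate score lists must both be nonempty")
  }
  thresholds <- sort(unique(c(positive_scores, candidate_scores)),
                     decreasing = TRUE)
  tpr <- vapply(thresholds, function(th) mean(positive_scores >= th), 0)
  fpr <- vapply(thresholds, function(th) mean(candidate_scores >= th), 0)
  roc <- tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc_points = roc, auc = auc)
}

# Per-positive placement among candidates: u in [0, 1] is the fraction of
# candidates scored strictly below, plus half the ties (the one-positive
# Mann-Whitney statistic); rank is the midrank position among candidates
# plus the positive itself (1 = best).
placement <- function(positive_score, candidate_scores) {
  below <- sum(candidate_scores < positive_score)
  ties <- sum(candidate_scores == positive_score)
  n <- length(candidate_scores)
  list(u = (below + 0.5 * ties) / n,
       rank = 1 + (n - below - ties) + 0.5 * ties)
}

# Step-function ROC from per-positive placements (each positive becomes a
# true positive once the false-positive rate passes 1 - u).
roc_from_placements <- function(u) {
  p <- sort(1 - u)
  steps <- tibble(fpr = unique(p),
                  tpr = cumsum(tabulate(match(p, unique(p)))) / length(p))
  dplyr::bind_rows(tibble(fpr = 0, tpr = 0), steps, tibble(fpr = 1, tpr = 1)) |>
    dplyr::distinct()
}

new_cv_result <- function(method, k, seed, test_ranks) {
  structure(
    list(method = method, k = k, seed = seed, test_ranks = test_ranks,
         roc_points = roc_from_placements(test_ranks$u),
         auc = mean(test_ranks$u)),
    class = "cv_result"
  )
}

# Shared fold engine: `folds` is a list of integer vectors of positive cell
# indices (into A) masked together. The semantic matrices and functional
# similarity do not derive from A, so they are computed once and shared by
# every fold; with `refit_similarity` only the kernels, the fusion, and the
# augmented networks are rebuilt from the masked training matrix.
run_cv_folds <- function(A, folds, fs, dags, config) {
  candidates <- which(A == 0L)
  side <- precompute_side_info(A, fs, dags, config)
  full_scores <- NULL
  if (!config$refit_similarity) {
    full_scores <- fold_model_scores(A, side, config)
  }
  rows <- lapply(folds, function(cells) {
    if (config$refit_similarity) {
      At <- A
      At[cells] <- 0L
      S <- fold_model_scores(At, side, config)
    } else {
      S <- full_scores
    }
    sc <- S[candidates]
    ij <- arrayInd(cells, dim(A))
    do.call(rbind, lapply(seq_along(cells), function(a) {
      pl <- placement(S[cells[a]], sc)
      data.frame(mirna_id = rownames(A)[ij[a, 1L]],
                 disease_id = colnames(A)[ij[a, 2L]],
                 rank = pl$rank, n_candidates = length(sc), u = pl$u)
    }))
  })
  as_tibble(do.call(rbind, rows))
}

# Fold-independent side information: semantic similarities over the DAG
# corpus and the functional similarity, both expanded onto A's label sets.
precompute_side_info <- function(A, fs, dags, config) {
  ss1 <- ss2 <- NULL
  if (!is.null(dags) && length(dags)) {
    ss1 <- semantic_similarity_model1(dags, config$semantic_delta)
    ss2 <- semantic_similarity_model2(dags)
  }
  list(
    ss1e = expand_similarity(ss1, colnames(A), role = "SS1"),
    ss2e = expand_similarity(ss2, colnames(A), role = "SS2"),
    fse = if (is.null(fs)) NULL else expand_similarity(fs, rownames(A))
  )
}

# Rebuild the data-dependent part of the model from a training matrix and
# score every pair.
fold_model_scores <- function(A_train, side, config) {
  kd <- gip_kernel(A_train, "diseases", config$gip_bandwidth_d)
  km <- gip_kernel(A_train, "mirnas", config$gip_bandwidth_m)
  sd_mat <- integrate_disease_similarity(side$ss1e, side$ss2e, kd)
  sm_mat <- integrate_mirna_similarity(side$fse, km)
  bhc_scores(A_train, sm_mat, sd_mat, config)$scores
}

#' Leave-one-out cross-validation of the predictor
#'
#' Each known association in turn is masked from the training matrix, the
#' model is rebuilt (see `refit_similarity` in [run_config()]), and the
#' held-out pair's score is ranked against every pair with no known
#' association in the full matrix (the global candidate set). The AUC is
#' the mean, over held-out pairs, of the fraction of candidates they
#' outscore (ties counted half), i.e. the pooled midrank Mann-Whitney
#' statistic.
#'
#' @param A `"assoc_matrix"` with at least two known associations.
#' @param fs Optional miRNA functional similarity (`"sim_matrix"`).
#' @param dags Optional named list of disease DAGs.
#' @param config A [run_config()].
#' @return A `"cv_result"`: method, per-pair `test_ranks` (tibble), pooled
#'   `roc_points`, and `auc`. See [tidy.cv_result()], [glance.cv_result()].
#' @export
loocv <- function(A, fs = NULL, dags = NULL, config = run_config()) {
  positives <- which(A == 1L)
  if (length(positives) < 2L) {
    mda_abort("leave-one-out needs at least two known associations")
  }
  folds <- as.list(positives)
  new_cv_result("loocv", k = length(positives), seed = config$seed,
                test_ranks = run_cv_folds(A, folds, fs, dags, config))
}

#' k-fold cross-validation of the predictor
#'
#' Known associations are randomly split into `k` near-equal disjoint
#' groups (reproducibly from `seed`); each group is masked in turn and its
#' pairs are ranked against the global candidate set, exactly as in
#' [loocv()]. Per-fold placements are pooled into one AUC.
#'
#' @param A `"assoc_matrix"`.
#' @param k Number of folds, between 2 and the number of known
#'   associations.
#' @param seed Integer seed for the partition (defaults to the config
#'   seed).
#' @param fs,dags,config As in [loocv()].
#' @return A `"cv_result"`.
#' @export
kfold_cv <- function(A, k, seed = NULL, fs = NULL, dags = NULL,
                     config = run_config()) {
  positives <- which(A == 1L)
  if (!is_scalar_number(k) || k != round(k) || k < 2L) {
    mda_abort("`k` must be an integer >= 2", class = "heatmda_config_error")
  }
  if (k > length(positives)) {
    mda_abort(sprintf("k = %d exceeds the %d known associations",
                      k, length(positives)),
              class = "heatmda_config_error")
  }
  seed <- as.integer(seed %||% config$seed)
  groups <- with_seed(seed, sample(rep(seq_len(k), length.out = length(positives))))
  folds <- lapply(seq_len(k), function(g) positives[groups == g])
  new_cv_result("kfold", k = as.integer(k), seed = seed,
                test_ranks = run_cv_folds(A, folds, fs, dags, config))
}

#' Top-k novel predictions for one disease
#'
#' Ranks the miRNAs with no known association to the disease by score,
#' descending, ties broken by miRNA id, and returns the first `k`. Known
#' associations are excluded from candidacy.
#'
#' @param scores A `"score_matrix"` from [bhc_scores()].
#' @param disease Disease identifier.
#' @param k Number of predictions (truncated to the candidate count).
#' @return A tibble with columns `rank`, `mirna_id`, `score`.
#' @export
top_k <- function(scores, disease, k = 50L) {
  if (!disease %in% colnames(scores$scores)) {
    mda_abort(sprintf("unknown disease id: '%s'", disease))
  }
  if (!is_scalar_number(k) || k < 1L) {
    mda_abort("`k` must be a positive integer", class = "heatmda_config_error")
  }
  cand <- which(scores$known[, disease] == 0L)
  s <- scores$scores[cand, disease]
  ids <- rownames(scores$scores)[cand]
  ord <- order(-s, ids)
  n <- min(as.integer(k), length(cand))
  tibble(rank = seq_len(n), mirna_id = ids[ord][seq_len(n)],
         score = unname(s[ord][seq_len(n)]))
}

#' Cross-validation test ranks as a tidy table
#'
#' @param x A `"cv_result"`.
#' @param ... Unused.
#' @return The per-held-out-pair tibble: `mirna_id`, `disease_id`, `rank`
#'   (midrank among candidates plus itself, 1 = best), `n_candidates`, and
#'   `u` (fraction of candidates outscored, ties half).
#' @export
tidy.cv_result <- function(x, ...) {
  x$test_ranks
}

#' One-row summary of a cross-validation run
#'
#' @param x A `"cv_result"`.
#' @param ... Unused.
#' @return A tibble with `method`, `k`, `seed`, `n_test`, `auc`.
#' @export
glance.cv_result <- function(x, ...) {
  tibble(method = x$method, k = x$k, seed = x$seed,
         n_test = nrow(x$test_ranks), auc = x$auc)
}

#' ROC curve of a cross-validation result
#'
#' @param object A `"cv_result"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$roc_points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s ROC (AUC = %.4f)", object$method, object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s%s> %d held-out pairs, AUC = %.4f\n",
              x$method, if (x$method == "kfold") sprintf(" k=%d", x$k) else "",
              nrow(x$test_ranks), x$auc))
  invisible(x)
}
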