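#' Run configuration for the heat-conduction pipeline
#'
#' Collects every tunable parameter of the prediction pipeline in one
#' validated list. Defaults follow the published calibration of the method:
#' miRNA-side augmentation threshold `delta = 0.29`, disease-side threshold
#' `eta = 0.13`, and degree-bias exponent `gamma = 0.001`, with a semantic
#' contribution factor of 0.5 and unit kernel bandwidth factors.
#'
#' @param delta Similarity threshold for miRNA-side network augmentation,
#'   in `[0, 1]`. A candidate edge (m_i, d_j) is added when some miRNA m_t
#'   associated with d_j has `SM(i, t) > delta`.
#' @param eta Similarity threshold for disease-side augmentation, in `[0, 1]`.
#' @param gamma Degree-bias exponent applied on the return pass of the
#'   conduction, `>= 0`. `gamma = 0` recovers plain heat conduction.
#' @param semantic_delta Per-generation decay factor for model-1 semantic
#'   contributions, in `(0, 1)`.
#' @param gip_bandwidth_d,gip_bandwidth_m Bandwidth factors (gamma'_d,
#'   gamma'_m) for the disease and miRNA Gaussian interaction-profile
#'   kernels; the effective bandwidth is the factor divided by the mean
#'   squared profile norm. Must be `> 0`.
#' @param degree_mode How node degrees of the augmented network are counted:
#'   `"binary"` (number of nonzero incident edges, the default) or
#'   `"weighted"` (sum of incident edge weights).
#' @param refit_similarity Logical; if `TRUE` (default) cross-validation
#'   folds recompute the interaction-profile kernels and the similarity
#'   fusion from the masked training matrix. If `FALSE`, folds reuse the
#'   full-data model (fast, but the held-out edge informs its own score).
#' @param seed Integer seed used wherever the pipeline needs randomness.
#'
#' @return A list of class `"run_config"`.
#' @examples
#' run_config()
#' run_config(gamma = 0, degree_mode = "weighted")
#' @export
run_config <- function(delta = 0.29,
                       eta = 0.13,
                       gamma = 0.001,
                       semantic_delta = 0.5,
                       gip_bandwidth_d = 1,
                       gip_bandwidth_m = 1,
                       degree_mode = c("binary", "weighted"),
                       refit_similarity = TRUE,
                       seed = 1L) {
  check_in_range(delta, "delta", 0, 1)
  check_in_range(eta, "eta", 0, 1)
  check_in_range(gamma, "gamma", 0, Inf)
  check_in_range(semantic_delta, "semantic_delta", 0, 1,
                 lo_open = TRUE, hi_open = TRUE)
  check_in_range(gip_bandwidth_d, "gip_bandwidth_d", 0, Inf, lo_open = TRUE)
  check_in_range(gip_bandwidth_m, "gip_bandwidth_m", 0, Inf, lo_open = TRUE)
  degree_mode <- match.arg(degree_mode)
  if (!is.logical(refit_similarity) || length(refit_similarity) != 1L ||
      is.na(refit_similarity)) {
    mda_abort("`refit_similarity` must be TRUE or FALSE",
              class = "heatmda_config_error")
  }
  if (!is_scalar_number(seed) || seed != round(seed)) {
    mda_abort("`seed` must be a single integer", class = "heatmda_config_error")
  }
  structure(
    list(
      delta = delta, eta = eta, gamma = gamma,
      semantic_delta = semantic_delta,
      gip_bandwidth_d = gip_bandwidth_d, gip_bandwidth_m = gip_bandwidth_m,
      degree_mode = degree_mode, refit_similarity = refit_similarity,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file is a flat key-value document whose keys are exactly the arguments
#' of [run_config()]. Unknown keys are rejected. Values passed through
#' `overrides` (for example parsed command-line flags) take precedence over
#' file values.
#'
#' @param path Path to a YAML file, or `NULL` for defaults only.
#' @param overrides Named list of values overriding the file.
#' @return A validated `"run_config"` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      mda_abort(sprintf("config file not found: %s", path),
                class = "heatmda_io_error")
    }
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals <- modifyList(vals, overrides)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    mda_abort(sprintf("unknown configuration key(s): %s",
                      paste(extra, collapse = ", ")),
              class = "heatmda_config_error")
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
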