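#' Forward heat conduction across the bipartite network
#'
#' Every node on the source axis starts with one unit of resource and
#' spreads it equally over its incident edges; a target node receives the
#' weighted sum of its neighbours' shares. Source nodes of degree zero hold
#' no edges and contribute nothing.
#'
#' @param adj An [augment_adjacency()] result.
#' @param from `"mirnas"` (resources flow miRNA -> disease) or `"diseases"`
#'   (disease -> miRNA).
#' @return A named numeric resource vector on the opposite axis, with
#'   attributes `axis` and `stage = "forward"`.
#' @export
forward_conduction <- function(adj, from = c("mirnas", "diseases")) {
  from <- match.arg(from)
  V <- adj$values
  if (from == "mirnas") {
    inv_deg <- safe_inverse(adj$mirna_degrees)
    out <- as.vector(crossprod(V, inv_deg))
    names(out) <- colnames(V)
    axis <- "diseases"
  } else {
    inv_deg <- safe_inverse(adj$disease_degrees)
    out <- as.vector(V %*% inv_deg)
    names(out) <- rownames(V)
    axis <- "mirnas"
  }
  structure(out, axis = axis, stage = "forward")
}

#' Biased back-conduction of resources
#'
#' Returns the forward-pass resources to the opposite axis, dividing each
#' source's resource by its degree and damping each receiving node by
#' `degree^(-gamma)`. The bias exponent `gamma` discounts high-degree
#' receivers, favouring unpopular nodes; `gamma = 0` is plain heat
#' conduction. Receivers of degree zero get 0.
#'
#' @param adj The same [augment_adjacency()] result used for the forward
#'   pass.
#' @param forward A resource vector produced by [forward_conduction()] on
#'   this adjacency.
#' @param gamma Bias exponent, `>= 0`.
#' @return A named resource vector on the axis opposite `forward`'s, with
#'   attribute `stage = "biased_back"`.
#' @export
biased_back_conduction <- function(adj, forward, gamma = 0.001) {
  if (!is_scalar_number(gamma) || gamma < 0) {
    mda_abort("`gamma` must be a single nonnegative number",
              class = "heatmda_config_error")
  }
  V <- adj$values
  from_axis <- attr(forward, "axis")
  if (is.null(from_axis)) {
    mda_abort("`forward` must come from forward_conduction()")
  }
  if (from_axis == "diseases") {
    check_same_labels(names(forward), colnames(V), "forward resources vs diseases")
    share <- forward * safe_inverse(adj$disease_degrees)
    raw <- as.vector(V %*% share)
    deg <- adj$mirna_degrees
    labels <- rownames(V)
    axis <- "mirnas"
  } else {
    check_same_labels(names(forward), rownames(V), "forward resources vs miRNAs")
    share <- forward * safe_inverse(adj$mirna_degrees)
    raw <- as.vector(crossprod(V, share))
    deg <- adj$disease_degrees
    labels <- colnames(V)
    axis <- "diseases"
  }
  out <- ifelse(deg > 0, deg^(-gamma) * raw, 0)
  names(out) <- labels
  structure(out, axis = axis, stage = "biased_back")
}

safe_inverse <- function(deg) {
  ifelse(deg > 0, 1 / deg, 0)
}

#' Biased heat-conduction association scores
#'
#' Runs the full two-pass pipeline. Pass one augments the association
#' matrix with miRNA-similarity edges (threshold `delta`), conducts one unit
#' of resource from every miRNA to the diseases, and returns it with degree
#' bias `gamma`, yielding per-miRNA resources `f'(m)`. Pass two mirrors this
#' on the disease side (threshold `eta`), yielding per-disease resources
#' `f''(d)`. The association score is the average
#' `S(i, j) = (f'(m_i) + f''(d_j)) / 2`.
#'
#' @param A `"assoc_matrix"` binary association matrix.
#' @param sm Integrated miRNA similarity (`"sim_matrix"`, labels =
#'   `rownames(A)`).
#' @param sd Integrated disease similarity (`"sim_matrix"`, labels =
#'   `colnames(A)`).
#' @param config A [run_config()].
#' @return An object of class `"score_matrix"`: list with `scores` (n x q),
#'   `known` (the input `A`), and `config`.
#' @examples
#' A <- association_matrix(data.frame(
#'   m = c("m1", "m2", "m2", "m3"), d = c("d1", "d1", "d2", "d2")))
#' sims <- build_similarities(A)
#' bhc_scores(A, sims$sm, sims$sd)
#' @export
bhc_scores <- function(A, sm, sd, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  a_prime <- augment_adjacency(A, sm, config$delta, side = "mirna",
                               degree_mode = config$degree_mode)
  f_d <- forward_conduction(a_prime, from = "mirnas")
  f_m_prime <- biased_back_conduction(a_prime, f_d, config$gamma)

  a_dprime <- augment_adjacency(A, sd, config$eta, side = "disease",
                                degree_mode = config$degree_mode)
  f_m_dprime <- forward_conduction(a_dprime, from = "diseases")
  f_d_dprime <- biased_back_conduction(a_dprime, f_m_dprime, config$gamma)

  scores <- outer(as.vector(f_m_prime), as.vector(f_d_dprime), `+`) / 2
  dimnames(scores) <- dimnames(A)
  structure(list(scores = scores, known = A, config = config),
            class = "score_matrix")
}

#' Association scores as a tidy table
#'
#' @param x A `"score_matrix"` from [bhc_scores()].
#' @param ... Unused.
#' @return A tibble with columns `mirna_id`, `disease_id`, `score`,
#'   `known` (logical), ordered by disease (matrix order) then descending
#'   score, ties broken by miRNA id.
#' @export
tidy.score_matrix <- function(x, ...) {
  tibble(
    mirna_id = rep(rownames(x$scores), times = ncol(x$scores)),
    disease_id = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores),
    known = as.vector(x$known == 1L)
  ) |>
    dplyr::arrange(match(.data$disease_id, colnames(x$scores)),
                   dplyr::desc(.data$score), .data$mirna_id)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d miRNAs x %d diseases (delta=%g, eta=%g, gamma=%g)\n",
              nrow(x$scores), ncol(x$scores),
              x$config$delta, x$config$eta, x$config$gamma))
  invisible(x)
}

#' Heat-map of association scores
#'
#' @param object A `"score_matrix"`.
#' @param ... Unused.
#' @return A ggplot object; known associations are outlined.
#' @export
autoplot.score_matrix <- function(object, ...) {
  df <- tidy(object)
  df$mirna_id <- factor(df$mirna_id, levels = rownames(object$scores))
  df$disease_id <- factor(df$disease_id, levels = colnames(object$scores))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$disease_id, y = .data$mirna_id,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$known, , drop = FALSE], fill = NA,
                       colour = "white", linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
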