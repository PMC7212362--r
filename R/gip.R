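#' Gaussian interaction-profile kernel similarity
#'
#' Each disease's interaction profile is its column of the binary
#' association matrix (which miRNAs it is associated with); each miRNA's
#' profile is its row. The kernel between two entities is
#' `exp(-gamma * ||IP(a) - IP(b)||^2)`, with the effective bandwidth
#' `gamma = bandwidth_prime / mean(||IP||^2)` normalised by the mean squared
#' profile norm over the axis's own entities.
#'
#' @param A Binary association matrix (miRNAs x diseases) with dimnames.
#' @param axis `"diseases"` (profiles are columns of `A`) or `"mirnas"`
#'   (profiles are rows).
#' @param bandwidth_prime Bandwidth factor gamma', `> 0`.
#' @return A `"sim_matrix"` with role `"KD"` (diseases) or `"KM"` (miRNAs).
#' @examples
#' A <- matrix(c(1, 1, 0, 1, 0, 1), nrow = 3,
#'             dimnames = list(c("m1", "m2", "m3"), c("d1", "d2")))
#' gip_kernel(A, "diseases") # K(d1, d2) = exp(-1)
#' @export
gip_kernel <- function(A, axis = c("diseases", "mirnas"), bandwidth_prime = 1) {
  axis <- match.arg(axis)
  check_in_range(bandwidth_prime, "bandwidth_prime", 0, Inf, lo_open = TRUE)
  if (sum(A) == 0) {
    mda_abort("empty interaction profile: the association matrix has no links")
  }
  profiles <- if (axis == "diseases") t(A) else A
  profiles <- unname(as.matrix(profiles)) * 1
  labels <- if (axis == "diseases") colnames(A) else rownames(A)
  sq <- rowSums(profiles^2)
  gamma <- bandwidth_prime / mean(sq)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0 # numerical guard
  K <- exp(-gamma * d2)
  diag(K) <- 1
  dimnames(K) <- list(labels, labels)
  similarity_matrix(K, role = if (axis == "diseases") "KD" else "KM")
}
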