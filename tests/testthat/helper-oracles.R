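# Independent oracles and fixture builders shared across tests. The oracles
# are deliberately written as plain loops over the defining formulas so they
# share no code with the package implementation.

toy_assoc <- function() {
  association_matrix(data.frame(
    mirna_id = c("m1", "m2", "m2", "m3"),
    disease_id = c("d1", "d1", "d2", "d2")
  ))
}

# Random symmetric similarity matrix in [0, 1] with unit diagonal.
rand_sim <- function(labels, role = "FS") {
  n <- length(labels)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  similarity_matrix(m, role = role)
}

rand_assoc <- function(n, q, p = 0.4) {
  A <- matrix(rbinom(n * q, 1L, p), n, q,
              dimnames = list(sprintf("m%d", seq_len(n)),
                              sprintf("d%d", seq_len(q))))
  structure(A, class = c("assoc_matrix", class(matrix())))
}

# Random chain DAG below a given root path; used for semantic properties.
rand_chain_dag <- function(target, depth, prefix = target) {
  anc <- if (depth > 0) sprintf("%s_a%d", prefix, seq_len(depth)) else character()
  nodes <- c(target, anc)
  edges <- if (length(nodes) > 1L) {
    cbind(parent = nodes[-1L], child = nodes[-length(nodes)])
  } else NULL
  disease_dag(target, nodes, edges)
}

# Naive loop implementation of the full scoring pipeline (augmentation,
# forward pass, biased return pass, score average).
oracle_bhc <- function(A, SM, SD, delta, eta, gamma, degree_mode = "binary") {
  n <- nrow(A); q <- ncol(A)
  deg <- function(v) if (degree_mode == "binary") sum(v > 0) else sum(v)

  A1 <- matrix(0, n, q)
  for (i in seq_len(n)) for (j in seq_len(q)) {
    if (A[i, j] == 1) A1[i, j] <- 1 else {
      best <- 0
      for (t in seq_len(n)) {
        if (A[t, j] == 1 && SM[i, t] > delta && SM[i, t] > best) best <- SM[i, t]
      }
      A1[i, j] <- best
    }
  }
  dm1 <- vapply(seq_len(n), function(i) deg(A1[i, ]), 0)
  dd1 <- vapply(seq_len(q), function(j) deg(A1[, j]), 0)
  fd <- numeric(q)
  for (j in seq_len(q)) for (i in seq_len(n)) {
    if (dm1[i] > 0) fd[j] <- fd[j] + A1[i, j] / dm1[i]
  }
  fm1 <- numeric(n)
  for (i in seq_len(n)) {
    if (dm1[i] == 0) next
    s <- 0
    for (j in seq_len(q)) if (dd1[j] > 0) s <- s + A1[i, j] * fd[j] / dd1[j]
    fm1[i] <- s / dm1[i]^gamma
  }

  A2 <- matrix(0, n, q)
  for (i in seq_len(n)) for (j in seq_len(q)) {
    if (A[i, j] == 1) A2[i, j] <- 1 else {
      best <- 0
      for (t in seq_len(q)) {
        if (A[i, t] == 1 && SD[j, t] > eta && SD[j, t] > best) best <- SD[j, t]
      }
      A2[i, j] <- best
    }
  }
  dm2 <- vapply(seq_len(n), function(i) deg(A2[i, ]), 0)
  dd2 <- vapply(seq_len(q), function(j) deg(A2[, j]), 0)
  fm2 <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(q)) {
    if (dd2[j] > 0) fm2[i] <- fm2[i] + A2[i, j] / dd2[j]
  }
  fd2 <- numeric(q)
  for (j in seq_len(q)) {
    if (dd2[j] == 0) next
    s <- 0
    for (i in seq_len(n)) if (dm2[i] > 0) s <- s + A2[i, j] * fm2[i] / dm2[i]
    fd2[j] <- s / dd2[j]^gamma
  }

  S <- matrix(0, n, q)
  for (i in seq_len(n)) for (j in seq_len(q)) S[i, j] <- (fm1[i] + fd2[j]) / 2
  S
}

# Exhaustive pairwise Mann-Whitney AUC with half-credit ties.
oracle_auc <- function(pos, cand) {
  wins <- 0
  for (p in pos) for (c in cand) {
    if (p > c) wins <- wins + 1 else if (p == c) wins <- wins + 0.5
  }
  wins / (length(pos) * length(cand))
}

# Pairwise-loop Gaussian interaction-profile kernel.
oracle_gip <- function(profiles, bandwidth_prime) {
  k <- nrow(profiles)
  gamma <- bandwidth_prime / mean(rowSums(profiles^2))
  K <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    K[i, j] <- exp(-gamma * sum((profiles[i, ] - profiles[j, ])^2))
  }
  K
}

# Strip sim_matrix attributes down to a plain numeric matrix.
strip_sim <- function(x) {
  matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
}

# Contiguous near-equal block assignment, mirroring the generator's rule.
block_ref <- function(n, b) sort(rep(seq_len(b), length.out = n))
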