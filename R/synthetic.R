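#' Specification for the block-structured synthetic benchmark
#'
#' The generator emulates the premise that functionally similar miRNAs
#' associate with semantically similar diseases: miRNAs and diseases are
#' partitioned into aligned blocks; associations are dense within aligned
#' blocks and sparse across; same-block diseases share DAG ancestors; and
#' functional similarity is high within miRNA blocks, low across, with
#' Gaussian noise.
#'
#' @param n_mirnas,n_diseases Numbers of miRNAs and diseases.
#' @param n_blocks Number of aligned blocks partitioning both axes
#'   (contiguous, sizes differing by at most one).
#' @param p_in,p_out Within-block and cross-block association
#'   probabilities; `0 <= p_out < p_in <= 1`.
#' @param fs_noise Standard deviation of the Gaussian perturbation on the
#'   block-derived functional similarity.
#' @param dag_depth Number of ancestor generations above each disease
#'   (including the shared root); at depth 1 every DAG is root -> disease.
#' @param dag_branching Number of alternative ancestor nodes per DAG level
#'   within a block.
#' @param fs_coverage Fraction of miRNA pairs whose functional similarity
#'   is marked as defined; the rest exercise the kernel fallback.
#' @param seed Integer seed; all generators are reproducible from it.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_mirnas = 60L, n_diseases = 40L, n_blocks = 4L,
                           p_in = 0.3, p_out = 0.02, fs_noise = 0.05,
                           dag_depth = 3L, dag_branching = 2L,
                           fs_coverage = 1, seed = 1L) {
  for (nm in c("n_mirnas", "n_diseases", "n_blocks", "dag_depth",
               "dag_branching")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v != round(v) || v < 1L) {
      mda_abort(sprintf("`%s` must be a positive integer", nm),
                class = "heatmda_config_error")
    }
  }
  check_in_range(p_in, "p_in", 0, 1)
  check_in_range(p_out, "p_out", 0, 1)
  if (p_out > p_in) {
    mda_abort("`p_out` must not exceed `p_in`", class = "heatmda_config_error")
  }
  check_in_range(fs_noise, "fs_noise", 0, Inf)
  check_in_range(fs_coverage, "fs_coverage", 0, 1)
  if (n_blocks > min(n_mirnas, n_diseases)) {
    mda_abort("`n_blocks` exceeds an axis length",
              class = "heatmda_config_error")
  }
  structure(
    list(n_mirnas = as.integer(n_mirnas), n_diseases = as.integer(n_diseases),
         n_blocks = as.integer(n_blocks), p_in = p_in, p_out = p_out,
         fs_noise = fs_noise, dag_depth = as.integer(dag_depth),
         dag_branching = as.integer(dag_branching),
         fs_coverage = fs_coverage, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Contiguous near-equal block labels for one axis.
block_labels <- function(n, n_blocks) {
  sort(rep(seq_len(n_blocks), length.out = n))
}

#' Generate a block-structured binary association matrix
#'
#' Cells within aligned (miRNA block, disease block) pairs are Bernoulli
#' `p_in`; all other cells Bernoulli `p_out`. Isolated rows or columns are
#' permitted.
#'
#' @param spec A [synthetic_spec()].
#' @return An `"assoc_matrix"` with ids `m01...` / `d01...` and a
#'   `blocks` attribute (list of per-axis block labels).
#' @export
gen_associations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mb <- block_labels(spec$n_mirnas, spec$n_blocks)
  db <- block_labels(spec$n_diseases, spec$n_blocks)
  prob <- ifelse(outer(mb, db, `==`), spec$p_in, spec$p_out)
  A <- with_seed(spec$seed, {
    matrix(rbinom(length(prob), 1L, prob), nrow = spec$n_mirnas)
  })
  dimnames(A) <- list(synth_ids("m", spec$n_mirnas),
                      synth_ids("d", spec$n_diseases))
  structure(A, blocks = list(mirna = mb, disease = db),
            class = c("assoc_matrix", class(matrix())))
}

synth_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(2L, nchar(n)), seq_len(n))
}

#' Generate a DAG corpus with shared within-block ancestry
#'
#' All diseases descend from one global root; each block adds its own
#' ancestor levels below it (`dag_depth - 1` levels, `dag_branching`
#' alternative nodes per level beyond the first), and each disease attaches
#' beneath a randomly chosen deepest-level node of its block. Same-block
#' diseases therefore share at least one non-root ancestor whenever
#' `dag_depth >= 2`; diseases in different blocks share only the root.
#'
#' @param spec A [synthetic_spec()].
#' @return A named list of [disease_dag()] objects, one per disease.
#' @export
gen_dag_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  db <- block_labels(spec$n_diseases, spec$n_blocks)
  ids <- synth_ids("d", spec$n_diseases)
  root <- "ROOT"
  with_seed(spec$seed + 1L, {
    # per-block ancestor scaffold: list of levels, each a character vector
    scaffolds <- lapply(seq_len(spec$n_blocks), function(b) {
      levels <- list()
      parents <- character()
      if (spec$dag_depth >= 2L) {
        levels[[1L]] <- sprintf("B%d_L1_1", b)
        parents[levels[[1L]]] <- root
        for (l in seq_len(spec$dag_depth - 2L)) {
          prev <- levels[[l]]
          nodes <- sprintf("B%d_L%d_%d", b, l + 1L, seq_len(spec$dag_branching))
          for (nd in nodes) parents[nd] <- prev[sample.int(length(prev), 1L)]
          levels[[l + 1L]] <- nodes
        }
      }
      list(levels = levels, parents = parents)
    })
    dags <- lapply(seq_len(spec$n_diseases), function(i) {
      b <- db[i]
      sc <- scaffolds[[b]]
      attach_to <- if (length(sc$levels)) {
        deepest <- sc$levels[[length(sc$levels)]]
        deepest[sample.int(length(deepest), 1L)]
      } else {
        root
      }
      # walk ancestor chain up to the root
      chain <- character()
      node <- attach_to
      while (node != root) {
        chain <- c(chain, node)
        node <- sc$parents[[node]]
      }
      nodes <- c(ids[i], chain, root)
      edges <- cbind(parent = nodes[-1L], child = nodes[-length(nodes)])
      disease_dag(ids[i], nodes, edges)
    })
    names(dags) <- ids
    dags
  })
}

#' Generate a noisy block-structured functional-similarity matrix
#'
#' Pairs within a miRNA block get base similarity 0.8, cross-block pairs
#' 0.1, perturbed by Gaussian noise (`fs_noise`), symmetrised, clipped to
#' `[0, 1]`, unit diagonal. A random fraction `1 - fs_coverage` of
#' off-diagonal pairs is marked uncovered to exercise the kernel fallback.
#'
#' @param spec A [synthetic_spec()].
#' @return A `"sim_matrix"` with role `"FS"`.
#' @export
gen_functional_similarity <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mb <- block_labels(spec$n_mirnas, spec$n_blocks)
  ids <- synth_ids("m", spec$n_mirnas)
  n <- spec$n_mirnas
  with_seed(spec$seed + 2L, {
    base <- ifelse(outer(mb, mb, `==`), 0.8, 0.1)
    noise <- matrix(rnorm(n * n, 0, spec$fs_noise), n, n)
    vals <- base + (noise + t(noise)) / 2
    vals <- pmin(pmax(vals, 0), 1)
    diag(vals) <- 1
    dimnames(vals) <- list(ids, ids)
    coverage <- matrix(TRUE, n, n)
    if (spec$fs_coverage < 1) {
      drop <- matrix(stats::runif(n * n) > spec$fs_coverage, n, n)
      drop[lower.tri(drop)] <- t(drop)[lower.tri(drop)]
      diag(drop) <- FALSE
      coverage[drop] <- FALSE
    }
    similarity_matrix(vals, role = "FS", coverage = coverage)
  })
}

#' Generate a complete synthetic dataset
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `assoc`, `dags`, `fs`, and `spec`.
#' @export
gen_dataset <- function(spec = synthetic_spec()) {
  list(assoc = gen_associations(spec), dags = gen_dag_corpus(spec),
       fs = gen_functional_similarity(spec), spec = spec)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `assoc.tsv`, `dags.tsv`, `fs.tsv`, `fs_coverage.tsv` and a
#' `manifest.yaml` recording the generating specification.
#'
#' @param data A list from [gen_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_associations(data$assoc, file.path(dir, "assoc.tsv"))
  write_dag_file(data$dags, file.path(dir, "dags.tsv"))
  write_similarity_tsv(data$fs, file.path(dir, "fs.tsv"),
                       file.path(dir, "fs_coverage.tsv"))
  yaml::write_yaml(unclass(data$spec), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
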