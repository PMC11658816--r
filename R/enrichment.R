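#' Cluster DMPs by non-negative matrix factorization of |r|
#'
#' Independent cross-validation of the hypergraph clustering. The DMP x CpG
#' correlation matrix is made non-negative via |r| (preserving magnitude
#' semantics), optionally restricted to the `max_cols` columns with the
#' smallest supplied p-values, and factorized as \eqn{V \approx W H} with
#' Lee-Seung multiplicative updates (Frobenius objective) from a seeded
#' uniform random start. Each DMP is assigned to its maximal basis
#' component. The objective is non-increasing across iterations; the trace
#' is returned for inspection.
#'
#' @param R DMP x CpG correlation matrix.
#' @param rank Number of components (>= 1); default 2 (coordinated vs not).
#' @param max_cols Column cap (default 100000).
#' @param p_for_ranking Optional p-value per column used to pick the
#'   `max_cols` retained columns (smallest first).
#' @param seed Integer seed for the random start.
#' @param max_iter,tol Convergence controls: stop when the relative
#'   objective change drops below `tol` or after `max_iter` iterations.
#' @return List with `assignment` (named integer per DMP), `W`, `H`,
#'   `objective` (per-iteration trace), `iterations`.
#' @export
nmf_cluster_dmps <- function(R, rank = 2, max_cols = 100000,
                             p_for_ranking = NULL, seed = 1,
                             max_iter = 500, tol = 1e-6) {
  if (rank < 1) .ec_stop("rank must be >= 1")
  if (rank > nrow(R)) .ec_stop("rank (%d) exceeds number of DMPs (%d)",
                               rank, nrow(R))
  V <- abs(R)
  if (ncol(V) > max_cols) {
    if (is.null(p_for_ranking)) {
      .ec_stop("p_for_ranking required to restrict %d columns to %d",
               ncol(V), max_cols)
    }
    keep <- order(p_for_ranking)[seq_len(max_cols)]
    V <- V[, keep, drop = FALSE]
  }
  n <- nrow(V); m <- ncol(V)
  eps <- .Machine$double.eps
  with_seed(sub_seed(seed, "nmf"), {
    W <- matrix(stats::runif(n * rank), n, rank)
    H <- matrix(stats::runif(rank * m), rank, m)
    obj <- numeric(0)
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      obj[it] <- sum((V - W %*% H)^2)
      if (it > 1 && abs(obj[it - 1] - obj[it]) <=
            tol * max(obj[it - 1], eps)) break
    }
    assignment <- apply(W, 1, which.max)
    names(assignment) <- rownames(R)
    list(assignment = assignment, W = W, H = H, objective = obj,
         iterations = length(obj))
  })
}

#' Best overlap between a hypergraph cluster and NMF clusters
#'
#' @param hypergraph_cluster Character vector of DMP ids (or a
#'   `central_cluster`).
#' @param nmf_assignment Named integer vector from [nmf_cluster_dmps()].
#' @return List with `best_cluster` (NMF component id), `jaccard`,
#'   `contingency` (2x2 in/out of each partition), and the per-component
#'   Jaccard vector.
#' @export
cluster_overlap <- function(hypergraph_cluster, nmf_assignment) {
  members <- if (inherits(hypergraph_cluster, "central_cluster")) {
    hypergraph_cluster$members
  } else as.character(hypergraph_cluster)
  ids <- names(nmf_assignment)
  jac <- vapply(sort(unique(nmf_assignment)), function(k) {
    set_k <- ids[nmf_assignment == k]
    compare_clusters(members, set_k)$jaccard
  }, numeric(1))
  names(jac) <- sort(unique(nmf_assignment))
  best <- as.integer(names(jac)[which.max(jac)])
  set_b <- ids[nmf_assignment == best]
  tab <- table(
    factor(ids %in% members, levels = c(TRUE, FALSE),
           labels = c("in_hypergraph", "out_hypergraph")),
    factor(ids %in% set_b, levels = c(TRUE, FALSE),
           labels = c("in_nmf", "out_nmf"))
  )
  list(best_cluster = best, jaccard = unname(max(jac)),
       contingency = tab, jaccard_by_cluster = jac)
}

#' Hypergeometric over-representation test over gene sets
#'
#' One-sided upper-tail hypergeometric p per set (probability of an overlap
#' at least as large, given the set size, query size and universe), with
#' Benjamini-Hochberg correction across sets.
#'
#' @param query_genes Character vector, a subset of `universe`.
#' @param gene_sets Named list of gene vectors; each set is intersected
#'   with the universe.
#' @param universe Character vector of all testable genes.
#' @return `data.frame` with `set_id`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`.
#' @export
hypergeometric_enrichment <- function(query_genes, gene_sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) .ec_stop("empty universe")
  query_genes <- unique(as.character(query_genes))
  if (!all(query_genes %in% universe)) {
    .ec_stop("query genes outside the universe: %s",
             paste(utils::head(setdiff(query_genes, universe), 3),
                   collapse = ", "))
  }
  nq <- length(query_genes)
  nu <- length(universe)
  rows <- lapply(names(gene_sets), function(sid) {
    set <- intersect(unique(gene_sets[[sid]]), universe)
    ov <- length(intersect(set, query_genes))
    p <- stats::phyper(ov - 1, length(set), nu - length(set), nq,
                       lower.tail = FALSE)
    data.frame(set_id = sid, overlap = ov, set_size = length(set),
               query_size = nq, universe_size = nu, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
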