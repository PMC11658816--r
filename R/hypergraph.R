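#' Bipartite DMP-by-CpG correlation matrix for one group
#'
#' Pearson (or Spearman) correlation, across one group's samples only,
#' between every DMP row and every background row (all probes not in
#' `dmp_ids`). Rows that are constant within the group yield undefined
#' correlations; these are set to 0 and counted in attribute
#' `"n_constant"`.
#'
#' @param dataset A [methylation_dataset()].
#' @param dmp_ids Probe ids used as hypergraph vertices.
#' @param group `"case"` or `"control"`; correlations use only that group's
#'   samples (at least 3 required).
#' @param background_ids Optional explicit background CpG ids; default all
#'   probes of the dataset not in `dmp_ids`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return DMPs x background correlation matrix with attribute `"group"`.
#' @export
bipartite_correlation <- function(dataset, dmp_ids,
                                  group = c("case", "control"),
                                  background_ids = NULL,
                                  method = c("pearson", "spearman")) {
  group <- match.arg(group)
  method <- match.arg(method)
  v <- group_values(dataset, group)
  if (ncol(v) < 3) .ec_stop("group '%s' has fewer than 3 samples", group)
  if (!all(dmp_ids %in% rownames(v))) .ec_stop("dmp_ids missing from dataset")
  if (is.null(background_ids)) {
    background_ids <- setdiff(rownames(v), dmp_ids)
  } else if (length(intersect(background_ids, dmp_ids)) > 0) {
    .ec_stop("background_ids must be disjoint from dmp_ids")
  }
  r <- suppressWarnings(stats::cor(t(v[dmp_ids, , drop = FALSE]),
                                   t(v[background_ids, , drop = FALSE]),
                                   method = method))
  n_const <- sum(!is.finite(r))
  if (n_const > 0) {
    message(sprintf("bipartite_correlation: %d undefined correlations set to 0 (constant rows)",
                    n_const))
    r[!is.finite(r)] <- 0
  }
  attr(r, "group") <- group
  r
}

#' Binarize a correlation matrix into a hypergraph incidence matrix
#'
#' The cut-off is the sample standard deviation (n-1 denominator) of all
#' |r| entries pooled; an entry is retained (1) iff its |r| strictly exceeds
#' the cut-off, so only the larger positive or negative correlations survive.
#'
#' @param R Correlation matrix from [bipartite_correlation()].
#' @return Integer 0/1 incidence matrix with attribute `"threshold"`.
#' @export
binarize_incidence <- function(R) {
  if (length(R) == 0) .ec_stop("empty correlation matrix")
  a <- abs(R)
  t0 <- stats::sd(a)
  if (!is.finite(t0) || t0 == 0) {
    .ec_stop("degenerate correlation structure: sd of |r| is 0")
  }
  M <- (a > t0) * 1L
  storage.mode(M) <- "integer"
  dimnames(M) <- dimnames(R)
  attr(M, "threshold") <- t0
  M
}

#' Hypergraph adjacency from an incidence matrix
#'
#' \eqn{A = M M^t}: the (i, j) entry counts the background CpG correlations
#' DMPs i and j share (the hyperedge dimension of the pair); the diagonal is
#' each DMP's incidence row sum.
#'
#' @param M Binary incidence matrix.
#' @return Symmetric integer adjacency matrix over the DMP ids.
#' @export
adjacency_from_incidence <- function(M) {
  if (!all(M %in% c(0L, 1L))) .ec_stop("incidence matrix must be binary")
  A <- tcrossprod(M)
  storage.mode(A) <- "integer"
  A
}

#' Extract the central coordinated cluster from a hypergraph adjacency
#'
#' Average-linkage hierarchical clustering of Euclidean distances between
#' adjacency rows. The tree is cut at the smallest number of clusters k
#' (scanning k = 2..`k_max`) at which some cluster of size >= `min_size`
#' exists; among the qualifying clusters at that cut, the one with the
#' largest mean internal off-diagonal edge dimension is selected. Stopping
#' at the shallowest qualifying cut keeps the full coordinated block
#' together instead of refining it into ever-tighter sub-blocks. The
#' selection is then trimmed: members whose mean edge dimension to the rest
#' of the cluster falls below `trim` times the cluster's mean internal
#' dimension are dropped iteratively (never below `min_size`), so loosely
#' attached vertices do not dilute a cluster whose defining property is
#' being connected by a large number of hyperedges. If every off-diagonal
#' entry is equal there is no structure to refine and the full vertex set
#' is returned.
#'
#' @param A Hypergraph adjacency matrix.
#' @param min_size Minimum cluster size (>= 2).
#' @param k_max Largest number of clusters scanned.
#' @param trim Relative connectivity floor for membership (0 disables
#'   trimming).
#' @return List of class `central_cluster`: `members`, `score` (mean
#'   internal edge dimension), `k` (cut used; `NA` for the degenerate case),
#'   `linkage`.
#' @export
extract_central_cluster <- function(A, min_size = 10, k_max = 10,
                                    trim = 0.9) {
  if (min_size < 2) .ec_stop("min_size must be >= 2")
  ids <- rownames(A)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
  off <- A[upper.tri(A)]
  if (length(unique(off)) == 1L) {
    return(structure(
      list(members = ids, score = mean(off), k = NA_integer_,
           linkage = "average"),
      class = "central_cluster"
    ))
  }
  hc <- stats::hclust(stats::dist(A), method = "average")
  k_max <- min(k_max, nrow(A) - 1L)
  for (k in 2:k_max) {
    cut <- stats::cutree(hc, k = k)
    best <- NULL
    for (cl in unique(cut)) {
      members <- which(cut == cl)
      if (length(members) < min_size) next
      sub <- A[members, members, drop = FALSE]
      score <- mean(sub[upper.tri(sub)])
      if (is.null(best) || score > best$score) {
        best <- list(members = ids[members], score = score, k = k)
      }
    }
    if (!is.null(best)) {
      members <- .trim_cluster(A, best$members, min_size, trim)
      sub <- A[members, members, drop = FALSE]
      return(structure(
        list(members = members, score = mean(sub[upper.tri(sub)]),
             k = best$k, linkage = "average"),
        class = "central_cluster"
      ))
    }
  }
  .ec_stop("no cluster of size >= %d found; try a smaller min_size",
           min_size)
}

# Internal: iteratively drop members connected to the rest of the cluster
# at less than `trim` times the mean internal edge dimension.
.trim_cluster <- function(A, members, min_size, trim) {
  if (trim <= 0) return(members)
  repeat {
    sub <- A[members, members, drop = FALSE]
    n <- length(members)
    if (n <= min_size) return(members)
    overall <- mean(sub[upper.tri(sub)])
    if (overall <= 0) return(members)
    per_member <- (rowSums(sub) - diag(sub)) / (n - 1)
    weak <- per_member < trim * overall
    if (!any(weak)) return(members)
    if (n - sum(weak) < min_size) {
      # keep the best-connected min_size members
      return(members[order(-per_member)[seq_len(min_size)]])
    }
    members <- members[!weak]
  }
}

#' @export
print.central_cluster <- function(x, ...) {
  cat(sprintf("central cluster: %d DMPs, mean edge dimension %.2f (k = %s)\n",
              length(x$members), x$score, as.character(x$k)))
  invisible(x)
}

#' Peripheral CpGs associated with most of the central cluster
#'
#' Returns the background CpG columns of the incidence matrix that are
#' connected to strictly more than `fraction` of the cluster's DMPs; with
#' the default 0.95 a CpG tied to exactly 95% of the cluster is excluded.
#'
#' @param M Incidence matrix.
#' @param cluster A `central_cluster` (or character vector of member ids).
#' @param fraction Strict lower bound on the connected fraction.
#' @return Character vector of peripheral CpG ids.
#' @export
refine_peripheral_cpgs <- function(M, cluster, fraction = 0.95) {
  members <- if (inherits(cluster, "central_cluster")) cluster$members
             else as.character(cluster)
  if (length(members) == 0) .ec_stop("empty cluster")
  if (!all(members %in% rownames(M))) {
    .ec_stop("cluster members missing from incidence matrix rows")
  }
  frac <- colSums(M[members, , drop = FALSE]) / length(members)
  colnames(M)[frac > fraction]
}

#' Overlap summary of two DMP (or CpG) sets
#'
#' @param set_a,set_b Character vectors.
#' @return List with `shared`, `unique_a`, `unique_b` (ids), their counts,
#'   and the Jaccard index.
#' @export
compare_clusters <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  shared <- intersect(set_a, set_b)
  un <- length(union(set_a, set_b))
  list(
    shared = shared,
    unique_a = setdiff(set_a, set_b),
    unique_b = setdiff(set_b, set_a),
    n_shared = length(shared),
    n_unique_a = length(set_a) - length(shared),
    n_unique_b = length(set_b) - length(shared),
    jaccard = if (un == 0) NA_real_ else length(shared) / un
  )
}

#' Compare the strength of retained correlations between two groups
#'
#' Collects |r| over the incidence-retained (DMP, CpG) pairs restricted to
#' each group's central cluster and reports the per-group medians, their
#' fold ratio (a over b), and a two-sided Wilcoxon rank-sum p-value.
#'
#' @param R_a,M_a,cluster_a Correlation matrix, incidence matrix and central
#'   cluster for group a (conventionally case).
#' @param R_b,M_b,cluster_b Same for group b (conventionally control).
#' @return List with `median_a`, `median_b`, `fold_ratio`, `wilcoxon_p`,
#'   `n_a`, `n_b`.
#' @export
peripheral_strength_comparison <- function(R_a, M_a, cluster_a,
                                           R_b, M_b, cluster_b) {
  pick <- function(R, M, cluster) {
    members <- if (inherits(cluster, "central_cluster")) cluster$members
               else as.character(cluster)
    keep <- M[members, , drop = FALSE] == 1L
    abs(R[members, , drop = FALSE])[keep]
  }
  va <- pick(R_a, M_a, cluster_a)
  vb <- pick(R_b, M_b, cluster_b)
  if (length(va) == 0 || length(vb) == 0) {
    .ec_stop("no incidence-retained pairs in one of the clusters")
  }
  list(
    median_a = stats::median(va),
    median_b = stats::median(vb),
    fold_ratio = stats::median(va) / stats::median(vb),
    wilcoxon_p = stats::wilcox.test(va, vb)$p.value,
    n_a = length(va), n_b = length(vb)
  )
}

#' Serialize a sparse binary or integer matrix as coordinate TSV
#'
#' Three columns (row id, column id, value); zeros are omitted.
#'
#' @param M Matrix with dimnames.
#' @param path File path.
#' @export
write_sparse_tsv <- function(M, path) {
  idx <- which(M != 0, arr.ind = TRUE)
  df <- data.frame(row = rownames(M)[idx[, 1]],
                   col = colnames(M)[idx[, 2]],
                   value = M[idx], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
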