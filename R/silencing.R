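#' Silence indirect associations in a correlation-like network
#'
#' Global silencing (Barzel & Barabasi): given an observed association
#' matrix G with unit diagonal, the direct-association scores are
#' \deqn{S = (G - I + D((G - I) G)) \, G^{-1}}
#' where \eqn{D(X)} zeroes the off-diagonal entries of X. Contributions of
#' indirect paths are suppressed: for a correlation chain, the silenced
#' score of the non-adjacent pair is far smaller than of the adjacent pairs.
#' When G is near-singular (reciprocal condition number below `rcond_tol`)
#' the Moore-Penrose generalized inverse is used and a message logged.
#'
#' @param G Square symmetric numeric matrix with unit diagonal.
#' @param rcond_tol Reciprocal-condition threshold below which the
#'   generalized inverse replaces `solve()`.
#' @return Direct-score matrix S (same dimnames as G; zero diagonal up to
#'   numerical error).
#' @export
silence_network <- function(G, rcond_tol = 1e-10) {
  if (!is.matrix(G) || nrow(G) != ncol(G)) .ec_stop("G must be square")
  if (max(abs(G - t(G))) > 1e-8) .ec_stop("G must be symmetric (within 1e-8)")
  if (max(abs(diag(G) - 1)) > 1e-8) .ec_stop("G must have unit diagonal")
  n <- nrow(G)
  I <- diag(n)
  X <- G - I
  D <- diag(diag(X %*% G), n)
  rc <- rcond(G)
  Ginv <- if (rc < rcond_tol) {
    message(sprintf("silence_network: G near-singular (rcond = %.3g); using generalized inverse",
                    rc))
    MASS::ginv(G)
  } else {
    solve(G)
  }
  S <- (X + D) %*% Ginv
  dimnames(S) <- dimnames(G)
  S
}

#' Z-score the silenced scores and threshold direct edges
#'
#' S is symmetrized (average with its transpose), its off-diagonal entries
#' are standardized (mean subtracted, sample SD divided), and unordered
#' pairs with |Z| above the threshold form the direct edge set.
#'
#' @param S Silenced score matrix from [silence_network()].
#' @param z_threshold Absolute Z cut-off for a direct edge (default 2).
#' @return List with `Z` (symmetric Z matrix, diagonal `NA`) and `edges`
#'   (`data.frame` of `probe_i`, `probe_j`, `z`, one row per unordered
#'   pair).
#' @export
direct_edge_zscores <- function(S, z_threshold = 2) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) .ec_stop("S must be square")
  Ssym <- (S + t(S)) / 2
  off <- Ssym[upper.tri(Ssym)]
  s0 <- stats::sd(off)
  if (!is.finite(s0) || s0 == 0) .ec_stop("off-diagonal SD is 0")
  Z <- (Ssym - mean(off)) / s0
  diag(Z) <- NA_real_
  ids <- rownames(S)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(S)))
  idx <- which(upper.tri(Z) & abs(Z) > z_threshold, arr.ind = TRUE)
  edges <- data.frame(
    probe_i = ids[idx[, 1]], probe_j = ids[idx[, 2]],
    z = Z[idx], stringsAsFactors = FALSE
  )
  list(Z = Z, edges = edges)
}

#' Classify direct edges as cis or trans by genomic distance
#'
#' cis iff both endpoints are on the same chromosome and strictly less than
#' `window` base pairs apart; 1,000,000 bp exactly is trans. Edges with an
#' endpoint missing coordinates are labelled `unknown` and reported.
#'
#' @param edges Edge `data.frame` with `probe_i`, `probe_j` columns.
#' @param annotation Probe annotation with `chromosome`, `position`.
#' @param window Distance bound in bp (default 1 Mb).
#' @return `edges` with added `distance` (NA across chromosomes) and
#'   `label` columns.
#' @export
classify_cis_trans <- function(edges, annotation, window = 1000000) {
  if (nrow(edges) == 0) {
    edges$distance <- numeric(0)
    edges$label <- character(0)
    return(edges)
  }
  i <- match(edges$probe_i, annotation$probe_id)
  j <- match(edges$probe_j, annotation$probe_id)
  chr_i <- annotation$chromosome[i]
  chr_j <- annotation$chromosome[j]
  pos_i <- annotation$position[i]
  pos_j <- annotation$position[j]
  same <- !is.na(chr_i) & !is.na(chr_j) & chr_i == chr_j
  dist <- ifelse(same, abs(pos_i - pos_j), NA_real_)
  label <- ifelse(same & dist < window, "cis", "trans")
  missing <- is.na(chr_i) | is.na(chr_j) | is.na(pos_i) | is.na(pos_j)
  if (any(missing)) {
    warning(sprintf("%d edge(s) with missing coordinates labelled unknown",
                    sum(missing)), call. = FALSE)
    label[missing] <- "unknown"
  }
  edges$distance <- dist
  edges$label <- label
  edges
}

#' Compare per-group direct edge sets
#'
#' Exact set arithmetic on unordered vertex pairs, a group-by-cis/trans
#' contingency table with a two-sided Fisher exact p, and a Wilcoxon
#' rank-sum test on the |Z| distributions.
#'
#' @param edges_case,edges_control Labelled edge tables from
#'   [classify_cis_trans()] (a `label` column is optional for the set
#'   arithmetic; required for the contingency test).
#' @return List with `shared`, `unique_case`, `unique_control` (pair keys),
#'   `contingency` (groups x cis/trans), `fisher_p`, `wilcoxon_p`.
#' @export
compare_group_edges <- function(edges_case, edges_control) {
  key_case <- if (nrow(edges_case)) .pair_key(edges_case$probe_i,
                                              edges_case$probe_j) else character(0)
  key_ctrl <- if (nrow(edges_control)) .pair_key(edges_control$probe_i,
                                                 edges_control$probe_j) else character(0)
  shared <- intersect(key_case, key_ctrl)

  tab <- matrix(0L, 2, 2,
                dimnames = list(c("case", "control"), c("cis", "trans")))
  if ("label" %in% names(edges_case)) {
    tab["case", "cis"] <- sum(edges_case$label == "cis")
    tab["case", "trans"] <- sum(edges_case$label == "trans")
  }
  if ("label" %in% names(edges_control)) {
    tab["control", "cis"] <- sum(edges_control$label == "cis")
    tab["control", "trans"] <- sum(edges_control$label == "trans")
  }
  fisher_p <- if (sum(tab) == 0) {
    warning("empty contingency table; Fisher p reported as 1", call. = FALSE)
    1
  } else {
    stats::fisher.test(tab)$p.value
  }
  wilcoxon_p <- if (nrow(edges_case) > 0 && nrow(edges_control) > 0) {
    suppressWarnings(
      stats::wilcox.test(abs(edges_case$z), abs(edges_control$z))$p.value
    )
  } else NA_real_
  list(
    shared = shared,
    unique_case = setdiff(key_case, key_ctrl),
    unique_control = setdiff(key_ctrl, key_case),
    contingency = tab, fisher_p = fisher_p, wilcoxon_p = wilcoxon_p
  )
}

#' Correlation-like association matrix from a hypergraph adjacency
#'
#' Alternative input for [silence_network()]: the integer adjacency is
#' normalized by its diagonal, \eqn{G_{ij} = A_{ij} / \sqrt{A_{ii} A_{jj}}},
#' giving a symmetric unit-diagonal association matrix (the cosine
#' similarity of incidence rows).
#'
#' @param A Hypergraph adjacency with a strictly positive diagonal.
#' @return Unit-diagonal numeric matrix.
#' @export
adjacency_correlation <- function(A) {
  d <- diag(A)
  if (any(d <= 0)) {
    .ec_stop("adjacency diagonal must be strictly positive (drop isolated vertices first)")
  }
  G <- A / sqrt(outer(d, d))
  diag(G) <- 1
  G
}

#' Per-group DMP correlation matrix for silencing
#'
#' Convenience builder of the matrix silencing operates on: the Pearson
#' correlation among central-cluster DMPs over one group's samples (unit
#' diagonal by construction).
#'
#' @param dataset A [methylation_dataset()].
#' @param members Central-cluster DMP ids.
#' @param group `"case"` or `"control"`.
#' @return Symmetric correlation matrix.
#' @export
cluster_correlation <- function(dataset, members,
                                group = c("case", "control")) {
  group <- match.arg(group)
  v <- group_values(dataset, group)
  r <- suppressWarnings(stats::cor(t(v[members, , drop = FALSE])))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}
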