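#' Edge-dimension distribution of a hypergraph cluster
#'
#' The hyperedge dimension of a DMP pair is the number of background CpG
#' correlations the pair shares (the off-diagonal adjacency entry). This
#' collects the dimensions of all member pairs and converts them to relative
#' frequencies over the distinct observed values.
#'
#' @param A Hypergraph adjacency matrix.
#' @param members Vertex ids (>= 2) to restrict to; default all.
#' @return Named numeric vector of frequencies (names = dimensions), which
#'   sums to 1.
#' @export
edge_dimension_distribution <- function(A, members = rownames(A)) {
  if (is.null(members)) members <- seq_len(nrow(A))
  if (length(members) < 2) .ec_stop("need at least two cluster members")
  sub <- A[members, members, drop = FALSE]
  d <- sub[upper.tri(sub)]
  tab <- table(d)
  stats::setNames(as.numeric(tab) / length(d), names(tab))
}

#' Shannon entropy of a discrete distribution, in bits
#'
#' \eqn{H = -\sum_v p_v \log_2 p_v}; zero-mass values contribute 0.
#'
#' @param dist Numeric vector of probabilities summing to 1 (within 1e-9).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(dist) {
  if (any(dist < 0)) .ec_stop("negative probability mass")
  if (abs(sum(dist) - 1) > 1e-9) {
    .ec_stop("distribution must sum to 1 (got %.6g)", sum(dist))
  }
  p <- dist[dist > 0]
  -sum(p * log2(p))
}

# Internal: entropy of a group-restricted hypergraph built from a vertex set
# against a background set. Returns NA if the binarization is degenerate.
.hypergraph_entropy <- function(values, vertex_ids, background_ids) {
  r <- suppressWarnings(stats::cor(t(values[vertex_ids, , drop = FALSE]),
                                   t(values[background_ids, , drop = FALSE])))
  r[!is.finite(r)] <- 0
  a <- abs(r)
  t0 <- stats::sd(a)
  if (!is.finite(t0) || t0 == 0) return(NA_real_)
  M <- (a > t0) * 1L
  A <- tcrossprod(M)
  d <- A[upper.tri(A)]
  tab <- tabulate(d + 1L)
  p <- tab[tab > 0] / length(d)
  -sum(p * log2(p))
}

#' Random-CpG null for central-cluster entropy
#'
#' Per iteration, `subset_size` background CpGs are drawn without
#' replacement and treated as pseudo-DMPs; the full hypergraph construction
#' (group-restricted correlation, SD-of-|r| binarization, adjacency) is run
#' and the Shannon entropy of all off-diagonal edge dimensions recorded.
#' The empirical p-value is one-sided toward low entropy (the direction of
#' interest: lower entropy means more ordered coordination), smoothed as
#' \eqn{(1 + \#\{H_{null} \le H_{obs}\}) / (1 + n_{iter})}.
#'
#' @param dataset A [methylation_dataset()].
#' @param group `"case"` or `"control"`.
#' @param background_ids Pool of non-DMP CpG ids to draw from.
#' @param observed Observed central-cluster entropy (bits).
#' @param subset_size Pseudo-DMPs per iteration (default 100).
#' @param n_iter Null iterations (default 1000).
#' @param seed Integer seed.
#' @param max_background Cap on the number of background CpGs each null
#'   hypergraph is correlated against (drawn once per iteration from the
#'   remaining pool); keeps repeated construction tractable.
#' @param two_sided If `TRUE`, doubles the smaller tail.
#' @return List of class `EntropyResult`: `entropy`, `n_edges`,
#'   `null_values`, `empirical_p`.
#' @export
central_cluster_entropy_null <- function(dataset, group, background_ids,
                                         observed, subset_size = 100,
                                         n_iter = 1000, seed = 1,
                                         max_background = 2000,
                                         two_sided = FALSE) {
  if (subset_size < 3) .ec_stop("subset_size must be >= 3")
  if (length(background_ids) < subset_size) {
    .ec_stop("background pool smaller than subset_size")
  }
  v <- group_values(dataset, group)
  null_values <- with_seed(sub_seed(seed, paste0("entropy_null_", group)), {
    vapply(seq_len(n_iter), function(i) {
      pseudo <- sample(background_ids, subset_size)
      rest <- setdiff(background_ids, pseudo)
      if (length(rest) > max_background) rest <- sample(rest, max_background)
      .hypergraph_entropy(v, pseudo, rest)
    }, numeric(1))
  })
  ok <- !is.na(null_values)
  lo <- (1 + sum(null_values[ok] <= observed)) / (1 + sum(ok))
  hi <- (1 + sum(null_values[ok] >= observed)) / (1 + sum(ok))
  p <- if (two_sided) min(1, 2 * min(lo, hi)) else lo
  structure(
    list(entropy = observed,
         n_edges = subset_size * (subset_size - 1) / 2,
         null_values = null_values, empirical_p = p),
    class = "EntropyResult"
  )
}

#' Bayesian bootstrap comparison of pathway hypergraph entropy
#'
#' For each gene set, the CpGs annotated to its genes are the hypergraph
#' vertices. Per group, `n_graphs` hypergraphs are built from bootstrap
#' subsamples (`boot_frac` of the mapped CpGs, without replacement) against
#' the background, and the Shannon entropy of each recorded. The posterior
#' difference is formed by `n_resample` bootstrap resamples of each group's
#' entropy list (difference of resample means, case minus control); the
#' equal-tailed credible interval at level `ci` is taken from its quantiles
#' and the pathway is significant iff the interval excludes 0.
#'
#' @param dataset_case,dataset_control Datasets for the two groups (may be
#'   the same object for self-calibration).
#' @param gene_sets Named list of gene symbol vectors (see [read_gmt()]).
#' @param annotation Probe annotation mapping probes to gene symbols.
#' @param background_ids Background CpG pool for the correlations.
#' @param n_graphs Hypergraphs per group per pathway (default 100).
#' @param n_resample Posterior resamples (default 10000).
#' @param ci Credible level (default 0.89).
#' @param boot_frac Fraction of mapped CpGs per bootstrap hypergraph.
#' @param min_cpgs Pathways mapping to fewer CpGs are skipped with a
#'   warning.
#' @param max_background Background cap per pathway (drawn once, seeded).
#' @param seed Integer seed.
#' @return `data.frame` with one row per retained pathway: `pathway_id`,
#'   `n_cpgs`, `mean_case`, `mean_control`, `delta` (posterior mean
#'   difference), `ci_low`, `ci_high`, `significant`. Entropy samples are
#'   attached as attribute `"entropy_samples"`.
#' @export
pathway_entropy_bayes <- function(dataset_case, dataset_control, gene_sets,
                                  annotation, background_ids,
                                  n_graphs = 100, n_resample = 10000,
                                  ci = 0.89, boot_frac = 0.8, min_cpgs = 3,
                                  max_background = 500, seed = 1) {
  v_case <- group_values(dataset_case, "case")
  v_ctrl <- group_values(dataset_control, "control")
  q_lo <- (1 - ci) / 2
  q_hi <- 1 - q_lo

  rows <- list()
  samples <- list()
  with_seed(sub_seed(seed, "pathway_bayes"), {
    for (pid in names(gene_sets)) {
      genes <- gene_sets[[pid]]
      cpgs <- annotation$probe_id[annotation$gene %in% genes]
      cpgs <- intersect(cpgs, rownames(v_case))
      cpgs <- intersect(cpgs, rownames(v_ctrl))
      if (length(cpgs) < min_cpgs) {
        warning(sprintf("pathway %s maps to %d CpGs (< %d); skipped",
                        pid, length(cpgs), min_cpgs), call. = FALSE)
        next
      }
      bg <- setdiff(background_ids, cpgs)
      bg <- intersect(bg, intersect(rownames(v_case), rownames(v_ctrl)))
      if (length(bg) > max_background) bg <- sample(bg, max_background)
      n_boot <- max(2L, ceiling(boot_frac * length(cpgs)))

      ent <- lapply(list(case = v_case, control = v_ctrl), function(v) {
        vapply(seq_len(n_graphs), function(g) {
          verts <- sample(cpgs, n_boot)
          .hypergraph_entropy(v, verts, bg)
        }, numeric(1))
      })
      ec <- ent$case[!is.na(ent$case)]
      eo <- ent$control[!is.na(ent$control)]
      if (length(ec) < 2 || length(eo) < 2) next

      mc <- colMeans(matrix(sample(ec, n_resample * length(ec),
                                   replace = TRUE), length(ec)))
      mo <- colMeans(matrix(sample(eo, n_resample * length(eo),
                                   replace = TRUE), length(eo)))
      diff <- mc - mo
      qs <- stats::quantile(diff, c(q_lo, q_hi), names = FALSE)
      rows[[pid]] <- data.frame(
        pathway_id = pid, n_cpgs = length(cpgs),
        mean_case = mean(ec), mean_control = mean(eo),
        delta = mean(diff), ci_low = qs[1], ci_high = qs[2],
        significant = !(qs[1] <= 0 && qs[2] >= 0),
        stringsAsFactors = FALSE
      )
      samples[[pid]] <- ent
    }
  })
  out <- if (length(rows) == 0) {
    data.frame(pathway_id = character(0), n_cpgs = integer(0),
               mean_case = numeric(0), mean_control = numeric(0),
               delta = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), significant = logical(0))
  } else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "entropy_samples") <- samples
  out
}
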