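#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Implements the step-up closed form
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} n / j)} with the input order
#' preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) .ec_stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * n / seq(n, 1)))
  q[ro]
}

# Internal vectorized pooled-variance two-group statistics.
# values: probes x samples; case: logical index over columns.
.two_group_stats <- function(values, case) {
  x1 <- values[, case, drop = FALSE]
  x2 <- values[, !case, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  se <- sqrt((ss1 + ss2) / df * (1 / n1 + 1 / n2))
  effect <- m1 - m2
  stat <- effect / se
  # degenerate rows: zero pooled variance
  zero <- se == 0
  if (any(zero)) {
    stat[zero & effect == 0] <- 0
    stat[zero & effect != 0] <- sign(effect[zero & effect != 0]) * Inf
  }
  p <- 2 * stats::pt(-abs(stat), df)
  p[!is.finite(stat)] <- 0
  p[stat == 0 & zero] <- 1
  list(effect = effect, statistic = stat, p = p)
}

#' Identify differentially methylated probes (DMPs)
#'
#' Per-probe two-group ordinary least squares on the group indicator, which
#' is equivalent to a pooled-variance t-test. Effects are case minus control;
#' q-values come from [bh_adjust()] and the significant set is `q < alpha`.
#'
#' @param dataset M- or zscore-scale [methylation_dataset()] with at least
#'   two samples per group.
#' @param alpha FDR threshold defining the significant set (default `1e-4`).
#' @return `data.frame` (a "DMP table") with columns `probe_id`, `effect`,
#'   `statistic`, `p`, `q`, `direction` (`hyper` iff effect > 0),
#'   `significant`; the threshold is attached as attribute `"alpha"`.
#' @export
test_dmps <- function(dataset, alpha = 1e-4) {
  if (!dataset$scale %in% c("M", "zscore")) {
    .ec_stop("test_dmps requires M or zscore scale (got %s)", dataset$scale)
  }
  case <- dataset$group == "case"
  if (sum(case) < 2 || sum(!case) < 2) {
    .ec_stop("each group needs at least two samples")
  }
  st <- .two_group_stats(dataset$values, case)
  q <- bh_adjust(st$p)
  out <- data.frame(
    probe_id = rownames(dataset$values),
    effect = st$effect, statistic = st$statistic, p = st$p, q = q,
    direction = ifelse(st$effect > 0, "hyper", "hypo"),
    significant = q < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "alpha") <- alpha
  out
}

# Internal: maximal gap-constrained runs of significant probes.
# sig_ids: probe ids; returns data.frame with list-column probe_ids.
.runs_from_positions <- function(sig_ids, annotation, max_gap, min_probes) {
  if (length(sig_ids) == 0) {
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0)))
  }
  ann <- annotation[match(sig_ids, annotation$probe_id), ]
  if (anyNA(ann$position)) .ec_stop("positions missing for some DMPs")
  regions <- list()
  for (chr in unique(ann$chromosome)) {
    sub <- ann[ann$chromosome == chr, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    brk <- c(0, cumsum(diff(sub$position) > max_gap))
    for (g in split(seq_len(nrow(sub)), brk)) {
      if (length(g) >= min_probes) {
        regions[[length(regions) + 1]] <- data.frame(
          chromosome = chr,
          start = sub$position[g[1]],
          end = sub$position[g[length(g)]],
          n_probes = length(g),
          stringsAsFactors = FALSE
        )
        regions[[length(regions)]]$probe_ids <- list(sub$probe_id[g])
      }
    }
  }
  if (length(regions) == 0) {
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0)))
  }
  out <- do.call(rbind, regions)
  out[order(match(out$chromosome, unique(annotation$chromosome)),
            out$start), , drop = FALSE]
}

#' Find candidate differentially methylated regions
#'
#' Maximal same-chromosome runs of significant DMPs with inter-probe gaps of
#' at most `max_gap` base pairs; runs with fewer than `min_probes` members
#' are discarded. "More than seven DMPs" is read as at least 8, the default.
#'
#' @param dmps DMP table from [test_dmps()].
#' @param annotation Probe annotation with `chromosome` and `position`.
#' @param max_gap Maximum gap between consecutive member probes (bp).
#' @param min_probes Minimum probes per region.
#' @param alpha Optional override of the significance threshold used to
#'   select member probes (defaults to the table's own threshold).
#' @param select_by Statistic thresholded by `alpha` when selecting member
#'   probes: `"q"` (BH-adjusted, the default) or `"p"` (raw; useful for
#'   permutation calibration where a global null yields no BH discoveries).
#' @return `data.frame` of regions with a `probe_ids` list-column; empty
#'   input yields an empty table.
#' @export
find_candidate_regions <- function(dmps, annotation, max_gap = 300,
                                   min_probes = 8, alpha = NULL,
                                   select_by = c("q", "p")) {
  select_by <- match.arg(select_by)
  if (is.null(alpha)) alpha <- attr(dmps, "alpha")
  sig <- dmps$probe_id[dmps[[select_by]] < alpha]
  .runs_from_positions(sig, annotation, max_gap, min_probes)
}

#' Score candidate regions against a group-label permutation null
#'
#' The region statistic is the sum of its member effects. For each of
#' `n_perm` permutations of the group labels the full pipeline (probe tests,
#' candidate-region detection at the same thresholds, region statistics) is
#' re-run. The permutation p-value of a region is the smoothed fraction of
#' permuted regions at least as extreme,
#' \eqn{p = (1 + \#\{|stat^{perm}| \ge |stat|\}) / (1 + N_{perm.regions})},
#' and the family-wise error rate is the smoothed fraction of permutations
#' whose most extreme region beats the observed one. Extremeness is
#' two-sided via absolute values; permutations with no candidate region
#' contribute a maximum statistic of 0.
#'
#' @param dataset M- or zscore-scale dataset (the one `regions` came from).
#' @param regions Candidate regions from [find_candidate_regions()].
#' @param n_perm Number of label permutations (at least 100).
#' @param seed Integer seed for the permutation stream.
#' @param alpha,max_gap,min_probes,select_by Thresholds re-applied inside
#'   each permutation; must match those used for `regions`.
#' @return A "DMR table": `regions` plus columns `value` (region statistic),
#'   `p` and `fwer`, sorted by `p`.
#' @export
permutation_region_test <- function(dataset, regions, n_perm = 1000,
                                    seed = 1, alpha = 1e-4, max_gap = 300,
                                    min_probes = 8,
                                    select_by = c("q", "p")) {
  select_by <- match.arg(select_by)
  if (n_perm < 100) .ec_stop("n_perm must be >= 100 for a stable tail")
  if (nrow(regions) == 0) {
    out <- regions
    out$value <- numeric(0); out$p <- numeric(0); out$fwer <- numeric(0)
    return(out)
  }
  dmps <- test_dmps(dataset, alpha = alpha)
  eff <- stats::setNames(dmps$effect, dmps$probe_id)
  obs <- vapply(regions$probe_ids, function(ids) sum(eff[ids]), numeric(1))

  case <- dataset$group == "case"
  n_case <- sum(case)
  ann <- dataset$annotation

  perm_stats <- with_seed(sub_seed(seed, "region_perm"), {
    lapply(seq_len(n_perm), function(i) {
      perm_case <- seq_len(ncol(dataset$values)) %in%
        sample(ncol(dataset$values), n_case)
      st <- .two_group_stats(dataset$values, perm_case)
      crit <- if (select_by == "q") bh_adjust(st$p) else st$p
      sig <- rownames(dataset$values)[crit < alpha]
      runs <- .runs_from_positions(sig, ann, max_gap, min_probes)
      if (nrow(runs) == 0) return(numeric(0))
      e <- stats::setNames(st$effect, rownames(dataset$values))
      vapply(runs$probe_ids, function(ids) sum(e[ids]), numeric(1))
    })
  })
  pooled <- abs(unlist(perm_stats))
  max_per_perm <- vapply(perm_stats, function(s) {
    if (length(s) == 0) 0 else max(abs(s))
  }, numeric(1))

  p <- vapply(obs, function(v) {
    (1 + sum(pooled >= abs(v))) / (1 + length(pooled))
  }, numeric(1))
  fwer <- vapply(obs, function(v) {
    (1 + sum(max_per_perm >= abs(v))) / (1 + n_perm)
  }, numeric(1))

  out <- regions
  out$value <- obs
  out$p <- p
  out$fwer <- fwer
  out[order(out$p, -abs(out$value)), , drop = FALSE]
}

#' Write a DMR table as BED+ text
#'
#' Columns: chrom, start, end, name, value, p, fwer, comma-joined probe ids.
#'
#' @param dmrs DMR table from [permutation_region_test()].
#' @param path File path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = dmrs$chromosome, start = dmrs$start - 1L, end = dmrs$end,
    name = sprintf("DMR_%d", seq_len(nrow(dmrs))),
    value = dmrs$value, p = dmrs$p, fwer = dmrs$fwer,
    probes = vapply(dmrs$probe_ids, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
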