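#' Restrict datasets to their common probes
#'
#' Array harmonization: every output dataset is restricted to the
#' intersection of probe ids across all inputs, in one canonical sorted
#' order. Sample columns are untouched.
#'
#' @param datasets List of at least two [methylation_dataset()] objects.
#' @return List of datasets restricted to the common probes.
#' @export
harmonize_probes <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2) {
    .ec_stop("harmonize_probes needs at least two datasets")
  }
  ids <- lapply(datasets, function(d) rownames(d$values))
  common <- Reduce(intersect, ids)
  if (length(common) == 0) {
    # name a pair with zero overlap for the error message
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i < j && length(intersect(ids[[i]], ids[[j]])) == 0) {
          .ec_stop("no probes shared between dataset %d and dataset %d", i, j)
        }
      }
    }
    .ec_stop("no probes shared across all datasets")
  }
  common <- sort(common)
  lapply(datasets, keep_probes, probe_ids = common)
}

#' Filter probes by exclusion flags and sex chromosomes
#'
#' Removes probes carrying any of the excluded annotation flags
#' (cross-reactive, age-associated, ...) and, optionally, probes on sex
#' chromosomes. A removal report (counts per reason, plus the unique total)
#' is attached as attribute `"removal_report"`.
#'
#' @param dataset A [methylation_dataset()].
#' @param exclude_flags Character subset of
#'   `c("cross_reactive", "sex_chromosome", "age_associated")`.
#' @param exclude_sex Also drop probes whose chromosome is chrX/chrY.
#' @return Filtered dataset with a `removal_report` attribute.
#' @export
filter_probes <- function(dataset,
                          exclude_flags = c("cross_reactive",
                                            "age_associated"),
                          exclude_sex = TRUE) {
  ann <- dataset$annotation
  ann <- ann[match(rownames(dataset$values), ann$probe_id), ]
  valid <- c("cross_reactive", "sex_chromosome", "age_associated")
  if (!all(exclude_flags %in% valid)) {
    .ec_stop("unknown exclusion flag(s): %s",
             paste(setdiff(exclude_flags, valid), collapse = ", "))
  }
  drop <- rep(FALSE, nrow(ann))
  report <- list()
  for (fl in exclude_flags) {
    hit <- as.logical(ann[[fl]])
    report[[fl]] <- sum(hit)
    drop <- drop | hit
  }
  if (exclude_sex) {
    hit <- ann$chromosome %in% c("chrX", "chrY")
    report[["sex_chromosome_position"]] <- sum(hit)
    drop <- drop | hit
  }
  report[["total_removed"]] <- sum(drop)
  if (all(drop)) .ec_stop("all probes removed by filtering")
  dataset$values <- dataset$values[!drop, , drop = FALSE]
  attr(dataset, "removal_report") <- report
  dataset
}

#' Logit (base 2) transform of beta values to M-values
#'
#' \eqn{M = \log_2(\beta / (1 - \beta))} after clipping beta into
#' `[epsilon, 1 - epsilon]` so boundary values stay finite.
#'
#' @param dataset Beta-scale [methylation_dataset()].
#' @param epsilon Clipping bound in (0, 0.5); default `1e-6` leaves interior
#'   points numerically untouched.
#' @return M-scale dataset.
#' @export
beta_to_m <- function(dataset, epsilon = 1e-6) {
  if (dataset$scale != "beta") {
    .ec_stop("beta_to_m requires a beta-scale dataset (got %s)",
             dataset$scale)
  }
  if (epsilon <= 0 || epsilon >= 0.5) .ec_stop("epsilon must be in (0, 0.5)")
  b <- pmin(pmax(dataset$values, epsilon), 1 - epsilon)
  dataset$values <- log2(b / (1 - b))
  dataset$scale <- "M"
  dataset
}

#' Inverse of [beta_to_m()]
#'
#' @param dataset M-scale dataset.
#' @return Beta-scale dataset with \eqn{\beta = 2^M / (1 + 2^M)}.
#' @export
m_to_beta <- function(dataset) {
  if (dataset$scale != "M") .ec_stop("m_to_beta requires an M-scale dataset")
  dataset$values <- stats::plogis(dataset$values * log(2))
  dataset$scale <- "beta"
  dataset
}

#' Regress known covariates out of every probe
#'
#' Per probe, values are replaced by the residuals of an ordinary
#' least-squares fit on the covariates (intercept included), plus the probe's
#' original mean, so covariate-driven variation (e.g. cell-type proportions)
#' is removed while the probe's level is preserved. Covariates are centered
#' first; covariate columns that are constant after centering are dropped
#' (they are absorbed by the intercept), and rank deficiency among the
#' remaining covariates is an error.
#'
#' @param dataset A [methylation_dataset()].
#' @param covariates Samples x k numeric matrix, rows aligned with (or named
#'   by) the dataset's samples.
#' @return Dataset with adjusted values; group labels unchanged.
#' @export
adjust_covariates <- function(dataset, covariates) {
  covariates <- as.matrix(covariates)
  n <- ncol(dataset$values)
  if (!is.null(rownames(covariates))) {
    covariates <- covariates[colnames(dataset$values), , drop = FALSE]
  }
  if (nrow(covariates) != n) {
    .ec_stop("covariate rows (%d) do not align with samples (%d)",
             nrow(covariates), n)
  }
  if (ncol(covariates) >= n) .ec_stop("need fewer covariates than samples")
  cc <- scale(covariates, center = TRUE, scale = FALSE)
  keep <- apply(cc, 2, function(x) any(abs(x) > 1e-12))
  cc <- cc[, keep, drop = FALSE]
  if (ncol(cc) > 0) {
    if (qr(cc)$rank < ncol(cc)) .ec_stop("rank-deficient covariates")
    X <- cbind(1, cc)
    # hat residuals for all probes at once: values' is samples x probes
    qx <- qr(X)
    res <- t(qr.resid(qx, t(dataset$values)))
    dataset$values <- res + rowMeans(dataset$values)
  }
  dataset
}

#' Z-score normalize every probe across all samples
#'
#' Each retained probe row is centered and scaled to unit sample standard
#' deviation (n-1 denominator), pooling both groups. Constant probes cannot
#' be scaled; they are dropped and reported via attribute
#' `"dropped_constant"`.
#'
#' @param dataset A [methylation_dataset()] with at least two samples.
#' @return Z-scored dataset (scale `"zscore"`).
#' @export
zscore_normalize <- function(dataset) {
  if (ncol(dataset$values) < 2) .ec_stop("zscore needs >= 2 samples")
  sds <- apply(dataset$values, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (all(const)) .ec_stop("all probes constant; nothing to normalize")
  v <- dataset$values[!const, , drop = FALSE]
  v <- (v - rowMeans(v)) / sds[!const]
  dataset$values <- v
  dataset$scale <- "zscore"
  attr(dataset, "dropped_constant") <- names(sds)[const]
  dataset
}
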