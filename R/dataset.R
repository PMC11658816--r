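#' Construct a methylation dataset
#'
#' The universal carrier of the pipeline: a probes x samples value matrix on a
#' declared scale (`beta`, `M` or `zscore`), a case/control group assignment,
#' and a probe annotation table.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param group Named character vector mapping every sample id to `"case"` or
#'   `"control"`.
#' @param annotation Probe annotation `data.frame` as produced by
#'   [generate_probe_annotation()]; must cover every probe in `values`.
#' @param scale One of `"beta"`, `"M"`, `"zscore"`.
#' @return An object of class `MethylationDataset`: a list with elements
#'   `values`, `group`, `annotation`, `scale`.
#' @export
methylation_dataset <- function(values, group, annotation,
                                scale = c("beta", "M", "zscore")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    .ec_stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    .ec_stop("values must have unique rownames (probe ids)")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    .ec_stop("values must have unique colnames (sample ids)")
  }
  group <- as.character(group)[match(colnames(values), names(group))]
  names(group) <- colnames(values)
  if (anyNA(group) || !all(group %in% c("case", "control"))) {
    .ec_stop("group must map every sample to 'case' or 'control'")
  }
  if (!all(c("case", "control") %in% group)) {
    .ec_stop("both groups must be represented among the samples")
  }
  if (!all(rownames(values) %in% annotation$probe_id)) {
    .ec_stop("annotation does not cover all probes in values")
  }
  if (scale == "beta" &&
      (min(values) < 0 || max(values) > 1)) {
    .ec_stop("beta-scale values must lie in [0, 1]")
  }
  structure(
    list(values = values, group = group, annotation = annotation,
         scale = scale),
    class = "MethylationDataset"
  )
}

#' @export
print.MethylationDataset <- function(x, ...) {
  cat(sprintf(
    "MethylationDataset: %d probes x %d samples (%d case / %d control), scale = %s\n",
    nrow(x$values), ncol(x$values),
    sum(x$group == "case"), sum(x$group == "control"), x$scale
  ))
  invisible(x)
}

#' @export
dim.MethylationDataset <- function(x) dim(x$values)

#' Subset a dataset to a set of probes
#'
#' @param dataset A `MethylationDataset`.
#' @param probe_ids Probe ids to keep (order is preserved as given).
#' @return A `MethylationDataset` restricted to `probe_ids`.
#' @export
keep_probes <- function(dataset, probe_ids) {
  missing <- setdiff(probe_ids, rownames(dataset$values))
  if (length(missing) > 0) {
    .ec_stop("probes not in dataset: %s", paste(utils::head(missing, 5),
                                                collapse = ", "))
  }
  dataset$values <- dataset$values[probe_ids, , drop = FALSE]
  dataset
}

#' Subset a dataset to one group's samples
#'
#' @param dataset A `MethylationDataset`.
#' @param group `"case"` or `"control"`.
#' @return A plain numeric matrix of the group's columns.
#' @export
group_values <- function(dataset, group = c("case", "control")) {
  group <- match.arg(group)
  dataset$values[, dataset$group == group, drop = FALSE]
}

#' Read / write a methylation value matrix as TSV
#'
#' Probe rows, sample columns, header row of sample ids, first column
#' `probe_id`. Plain text so matrices round-trip between pipeline stages.
#'
#' @param values Numeric matrix with dimnames.
#' @param path File path.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(values, path) {
  df <- data.frame(probe_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write a sample sheet (sample_id, group, covariates)
#'
#' @param group Named character vector (sample -> case/control).
#' @param covariates Optional samples x k numeric matrix.
#' @param path File path.
#' @return `read_sample_sheet` returns a list with `group` and `covariates`.
#' @export
write_sample_sheet <- function(group, path, covariates = NULL) {
  df <- data.frame(sample_id = names(group), group = unname(group),
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  group <- stats::setNames(df$group, df$sample_id)
  cov <- NULL
  extra <- setdiff(names(df), c("sample_id", "group"))
  if (length(extra) > 0) {
    cov <- as.matrix(df[, extra, drop = FALSE])
    rownames(cov) <- df$sample_id
  }
  list(group = group, covariates = cov)
}
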