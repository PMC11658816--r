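#' Write / read gene sets in GMT format
#'
#' One record per line: set name, description, then tab-separated gene
#' symbols. `read_gmt` drops the description; round-tripping a collection
#' through `write_gmt`/`read_gmt` is lossless for names and members.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @param description Description field written for every set.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) .ec_stop("malformed GMT record: %s",
                                    substr(ln, 1, 40))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(ln) {
    strsplit(ln, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}
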