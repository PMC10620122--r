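# GMT files: one gene set per line, "name <TAB> description <TAB> gene1 ...".

#' Read a gene set collection from a GMT file
#'
#' @param path GMT file.
#' @return named list of character vectors (deduplicated, empty sets
#'   dropped with a warning); attribute `source` records the path.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    assert_that(length(parts) >= 2, sprintf("malformed GMT line: '%s'", substr(ln, 1, 40)))
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    sets[[parts[1]]] <- genes
  }
  assert_that(!anyDuplicated(names(sets)), "duplicate gene set names in GMT")
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sprintf("%d empty gene sets dropped", sum(empty)))
    sets <- sets[!empty]
  }
  attr(sets, "source") <- path
  sets
}

#' Write a gene set collection to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
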