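#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member gene symbols. Member symbols are upper-cased and de-duplicated
#' within a set.
#'
#' @param path GMT file path.
#' @return A tibble with columns `set` (unique names), `description`, and
#'   `genes` (list-column of character vectors).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort(sprintf("parse error in %s: empty file.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    abort(sprintf("parse error in %s: line %d has fewer than 3 fields.",
                  path, short[1L]))
  }
  out <- tibble(
    set = vapply(fields, `[[`, character(1), 1L),
    description = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) unique(toupper(f[-(1:2)]))))
  if (anyDuplicated(out$set)) abort("gene-set names must be unique.")
  if (any(lengths(out$genes) == 0L)) abort("every gene set must be non-empty.")
  out
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  if (!all(c("set", "description", "genes") %in% names(collection))) {
    abort("`collection` needs columns set, description, genes.")
  }
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set[i], collection$description[i],
            collection$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
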