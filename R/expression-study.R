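#' Construct an expression study
#'
#' The unit of meta-analysis: one study's log2 gene-by-sample matrix with a
#' study identifier and optional platform identifier. Gene symbols are
#' case-normalized to upper case and must be unique; values must be complete.
#'
#' @param values Numeric matrix, rows = genes (rownames required, unique after
#'   upper-casing), columns = samples (colnames required).
#' @param study_id,platform_id Identifiers.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(values, study_id, platform_id = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs gene rownames and sample colnames.")
  }
  if (anyNA(values)) abort("expression values must not contain missing values.")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) {
    abort("gene symbols must be unique within a study (after upper-casing); collapse probes first.")
  }
  structure(list(study_id = as.character(study_id),
                 platform_id = as.character(platform_id),
                 values = values),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s (%s): %d genes x %d samples\n",
              x$study_id, x$platform_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Genes of an expression study
#' @param study An [expression_study()].
#' @return Character vector of gene symbols.
#' @export
study_genes <- function(study) rownames(study$values)

#' Samples of an expression study
#' @param study An [expression_study()].
#' @return Character vector of sample identifiers.
#' @export
study_samples <- function(study) colnames(study$values)

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample identifiers and a first column of gene (or
#' probe) identifiers. Duplicate row identifiers are permitted only when
#' `allow_duplicates = TRUE` (i.e. before probe collapsing). Parse failures
#' (ragged rows, non-numeric cells, empty file) raise an error naming the
#' offending row and column.
#'
#' @param path TSV file path.
#' @param study_id,platform_id Identifiers for the resulting study; `study_id`
#'   defaults to the file name without extension.
#' @param allow_duplicates Keep duplicate row identifiers (returns the raw
#'   matrix instead of an `expression_study`)?
#' @return An [expression_study()], or a plain matrix when
#'   `allow_duplicates = TRUE`.
#' @export
read_expression_matrix <- function(path, study_id = NULL, platform_id = NA_character_,
                                   allow_duplicates = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort(sprintf("parse error in %s: no data rows.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1L]])
  lens <- lengths(fields)
  if (any(lens != width)) {
    bad <- which(lens != width)[1L]
    abort(sprintf("parse error in %s: line %d has %d fields, expected %d.",
                  path, bad, lens[bad], width))
  }
  samples <- fields[[1L]][-1L]
  body <- fields[-1L]
  ids <- toupper(vapply(body, `[[`, character(1), 1L))
  vals <- matrix(NA_real_, length(body), width - 1L,
                 dimnames = list(NULL, samples))
  for (i in seq_along(body)) {
    num <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(num)) {
      j <- which(is.na(num))[1L]
      abort(sprintf("parse error in %s: non-numeric cell at line %d, column %d ('%s').",
                    path, i + 1L, j + 1L, body[[i]][j + 1L]))
    }
    vals[i, ] <- num
  }
  rownames(vals) <- ids
  if (allow_duplicates) return(vals)
  expression_study(vals,
                   study_id = study_id %||% sub("\\.[^.]*$", "", basename(path)),
                   platform_id = platform_id)
}

#' Write an expression study (or matrix) as TSV
#'
#' @param study An [expression_study()] or a gene-by-sample matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(study, path) {
  vals <- if (inherits(study, "expression_study")) study$values else study
  df <- data.frame(gene = rownames(vals), vals, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Collapse probe rows to gene symbols
#'
#' For each gene symbol, the probe with the highest mean expression across
#' samples is retained (or the per-gene row mean / per-sample maximum when
#' `rule` is changed). Probes absent from the mapping are dropped.
#'
#' @param values Probes-by-samples numeric matrix with probe rownames.
#' @param mapping Data frame with columns `probe` and `gene`.
#' @param rule Collapse rule: `"highest_mean"` (default), `"mean"`, or `"max"`.
#' @return A genes-by-samples matrix with one row per mapped gene symbol.
#' @export
collapse_probes <- function(values, mapping, rule = c("highest_mean", "mean", "max")) {
  rule <- match.arg(rule)
  if (!is.matrix(values) || is.null(rownames(values))) {
    abort("`values` must be a matrix with probe rownames.")
  }
  if (!is.data.frame(mapping) || !all(c("probe", "gene") %in% names(mapping)) ||
      nrow(mapping) == 0L) {
    abort("`mapping` must be a non-empty data frame with columns `probe` and `gene`.")
  }
  mapping <- distinct(as_tibble(mapping[c("probe", "gene")]))
  if (anyDuplicated(mapping$probe)) {
    abort("each probe must map to exactly one gene symbol.")
  }
  mapping <- mutate(mapping, gene = toupper(.data$gene))
  keep <- rownames(values) %in% mapping$probe
  vals <- values[keep, , drop = FALSE]
  if (nrow(vals) == 0L) abort("no probes map to a gene symbol.")
  gene_of <- setNames(mapping$gene, mapping$probe)[rownames(vals)]
  out <- switch(
    rule,
    highest_mean = {
      means <- rowMeans(vals)
      ord <- order(gene_of, -means, rownames(vals))
      pick <- ord[!duplicated(gene_of[ord])]
      m <- vals[pick, , drop = FALSE]
      rownames(m) <- gene_of[pick]
      m
    },
    mean = {
      m <- rowsum(vals, gene_of) / as.vector(table(gene_of)[sort(unique(gene_of))])
      m
    },
    max = {
      genes <- sort(unique(gene_of))
      m <- do.call(rbind, lapply(genes, function(g) {
        apply(vals[gene_of == g, , drop = FALSE], 2, max)
      }))
      rownames(m) <- genes
      m
    })
  out[order(rownames(out)), , drop = FALSE]
}

#' Remove low-signal genes by sequential mean and SD quantile filters
#'
#' Mirrors the quality-control convention of filtering the bottom fraction of
#' genes by mean expression, then the bottom fraction of the survivors by
#' standard deviation. Quantiles are empirical with linear interpolation;
#' removal is strictly below the cut, so ties at the cut survive and the filter
#' never exceeds its nominal fraction.
#'
#' @param study An [expression_study()].
#' @param mean_q,sd_q Fractions in `[0, 1)`; default 0.10 each.
#' @return A filtered [expression_study()].
#' @export
filter_low_signal <- function(study, mean_q = 0.10, sd_q = 0.10) {
  if (!inherits(study, "expression_study")) abort("`study` must be an expression_study.")
  if (mean_q < 0 || mean_q >= 1 || sd_q < 0 || sd_q >= 1) {
    abort("`mean_q` and `sd_q` must lie in [0, 1).")
  }
  vals <- study$values
  if (mean_q > 0) {
    m <- rowMeans(vals)
    vals <- vals[m >= quantile(m, mean_q), , drop = FALSE]
  }
  if (sd_q > 0 && nrow(vals) > 0L) {
    s <- apply(vals, 1, sd)
    vals <- vals[s >= quantile(s, sd_q), , drop = FALSE]
  }
  if (nrow(vals) == 0L) abort("low-signal filter removed all genes.")
  expression_study(vals, study_id = study$study_id, platform_id = study$platform_id)
}

#' Cross-study gene universe
#'
#' Intersection of the gene symbol sets of all studies, in lexicographic order.
#'
#' @param studies List of [expression_study()] objects.
#' @return Character vector of shared gene symbols.
#' @export
common_genes <- function(studies) {
  if (length(studies) < 1L) abort("need at least one study.")
  sets <- lapply(studies, study_genes)
  out <- sort(Reduce(intersect, sets))
  if (length(out) == 0L) abort("the studies share no gene symbols.")
  out
}
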