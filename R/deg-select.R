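new_deg_set <- function(members, comparison, provenance) {
  members <- as_tibble(members)
  stopifnot(all(c("gene", "direction") %in% names(members)))
  if (anyDuplicated(members$gene)) abort("a gene may appear at most once per DEG set.")
  if (!all(members$direction %in% c("up", "down"))) {
    abort("direction must be 'up' or 'down'.")
  }
  members <- arrange(members, .data$gene)
  structure(members, class = c("deg_set", class(members)),
            comparison = comparison, provenance = provenance)
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("<deg_set> %s [%s]: %d genes (%d up, %d down)\n",
              attr(x, "comparison"), attr(x, "provenance"), nrow(x),
              sum(x$direction == "up"), sum(x$direction == "down")))
  NextMethod()
}

#' Comparison label of a DEG set
#' @param x A `deg_set`.
#' @return Character label.
#' @export
deg_comparison <- function(x) attr(x, "comparison")

#' Select significant genes from a meta-analysis table
#'
#' Thresholds the BH-adjusted q-values of one method of a [meta_combine()]
#' table and returns the surviving genes with their direction. `method =
#' "rem"` uses the random-effects branch (`q_rem`, direction = sign of the
#' pooled effect).
#'
#' @param meta A [meta_combine()] table.
#' @param method One of `"fisher"`, `"maxp"`, `"rop"`, `"aw"`, `"rem"`.
#' @param fdr FDR threshold in (0, 1].
#' @param comparison Label recorded on the resulting set (e.g.
#'   `"GBM_vs_NG_training"`).
#' @return A `deg_set`: tibble of `gene`, `direction` with `comparison` and
#'   `provenance` attributes.
#' @export
select_significant <- function(meta, method = "fisher", fdr = 0.05,
                               comparison = "comparison") {
  if (!is.numeric(fdr) || fdr <= 0 || fdr > 1) abort("`fdr` must lie in (0, 1].")
  q_col <- paste0("q_", method)
  dir_col <- paste0("dir_", method)
  if (!all(c(q_col, dir_col) %in% names(meta))) {
    abort(sprintf("method '%s' is not present in the meta table.", method))
  }
  keep <- meta[[q_col]] < fdr
  new_deg_set(tibble(gene = meta$gene[keep], direction = meta[[dir_col]][keep]),
              comparison = comparison,
              provenance = sprintf("%s FDR<%g", method, fdr))
}

intersect_agreeing <- function(a, b) {
  merged <- inner_join(as_tibble(a)[c("gene", "direction")],
                       as_tibble(b)[c("gene", "direction")],
                       by = "gene", suffix = c("", "_b"))
  agree <- merged$direction == merged$direction_b
  list(members = merged[agree, c("gene", "direction")],
       disagreeing = merged$gene[!agree])
}

#' Overlap of p-value-combination and effect-size DEG sets
#'
#' Genes called in both branches with agreeing direction; genes with
#' conflicting direction are excluded and reported via a warning. This is the
#' "combining both p-values and effect sizes" Venn step.
#'
#' @param p_set,es_set `deg_set`s from the same comparison.
#' @return A `deg_set`.
#' @export
dual_method_overlap <- function(p_set, es_set) {
  if (!identical(deg_comparison(p_set), deg_comparison(es_set))) {
    abort("both sets must come from the same comparison.")
  }
  res <- intersect_agreeing(p_set, es_set)
  if (length(res$disagreeing) > 0L) {
    warn(sprintf("%d gene(s) excluded for direction disagreement: %s",
                 length(res$disagreeing),
                 paste(head(res$disagreeing, 5), collapse = ", ")))
  }
  new_deg_set(res$members, comparison = deg_comparison(p_set),
              provenance = sprintf("overlap(%s; %s)",
                                   attr(p_set, "provenance"),
                                   attr(es_set, "provenance")))
}

#' Training/validation confirmation of a DEG set
#'
#' Intersection (with direction agreement) of the training and validation
#' sets for the same comparison class; the up/down split of the confirmed set
#' is attached as attribute `"counts"`.
#'
#' @param training,validation `deg_set`s.
#' @return A `deg_set`.
#' @export
train_validate <- function(training, validation) {
  res <- intersect_agreeing(training, validation)
  out <- new_deg_set(res$members, comparison = deg_comparison(training),
                     provenance = sprintf("train+validate(%s)",
                                          attr(training, "provenance")))
  attr(out, "counts") <- c(up = sum(out$direction == "up"),
                           down = sum(out$direction == "down"))
  out
}

#' GBM-specificity filter across the three comparisons
#'
#' Genes present, with agreeing direction, in the GBM-vs-NG, GBM-vs-A and
#' GBM-vs-OD sets — i.e. genes that distinguish GBM both from non-glioma
#' tissue and from the other glioma subtypes.
#'
#' @param gbm_vs_ng,gbm_vs_a,gbm_vs_od `deg_set`s of the three comparisons.
#' @return A `deg_set` labelled `"GBM_specific"`.
#' @export
specificity_filter <- function(gbm_vs_ng, gbm_vs_a, gbm_vs_od) {
  step1 <- intersect_agreeing(gbm_vs_ng, gbm_vs_a)$members
  step2 <- intersect_agreeing(step1, gbm_vs_od)$members
  new_deg_set(step2, comparison = "GBM_specific",
              provenance = "intersect(GBM_vs_NG, GBM_vs_A, GBM_vs_OD)")
}

#' Venn region counts for a list of DEG sets
#'
#' Counts genes (ignoring direction) in every non-empty region of the Venn
#' diagram over up to a handful of sets.
#'
#' @param sets Named list of `deg_set`s (or tibbles with a `gene` column).
#' @return Tibble with `region` (set names joined by `&`) and `n`.
#' @export
venn_counts <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a fully named list.")
  }
  genes <- unique(unlist(lapply(sets, function(s) s$gene)))
  membership <- vapply(sets, function(s) genes %in% s$gene,
                       logical(length(genes)))
  if (length(genes) == 1L) membership <- matrix(membership, nrow = 1L)
  region <- apply(membership, 1, function(m) paste(names(sets)[m], collapse = "&"))
  out <- dplyr::count(tibble(region = region), .data$region, name = "n")
  arrange(out, dplyr::desc(.data$n))
}

#' Write a DEG set as TSV
#'
#' @param deg_set A `deg_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_set <- function(deg_set, path) {
  out <- mutate(as_tibble(deg_set),
                comparison = deg_comparison(deg_set),
                provenance = attr(deg_set, "provenance"))
  readr::write_tsv(out, path)
  invisible(path)
}
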