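# shared two-group summaries: means, pooled SD, raw difference
contrast_stats <- function(vals, case_ids, control_ids) {
  n1 <- length(case_ids); n0 <- length(control_ids)
  if (n1 < 2L || n0 < 2L) abort("each contrast side needs at least 2 samples.")
  if (length(intersect(case_ids, control_ids)) > 0L) {
    abort("case and control samples must be disjoint.")
  }
  missing <- setdiff(c(case_ids, control_ids), colnames(vals))
  if (length(missing) > 0L) {
    abort(sprintf("samples not in the study: %s", paste(head(missing, 3), collapse = ", ")))
  }
  x1 <- vals[, case_ids, drop = FALSE]
  x0 <- vals[, control_ids, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  ss <- rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)
  sp <- sqrt(ss / (n1 + n0 - 2L))
  list(n1 = n1, n0 = n0, dbar = m1 - m0, sp = sp,
       se_scale = sqrt(1 / n1 + 1 / n0))
}

resolve_contrast <- function(annotation, case, control, samples) {
  if (!all(c("sample_id", "class") %in% names(annotation))) {
    abort("`annotation` needs columns sample_id and class.")
  }
  ann <- filter(annotation, .data$sample_id %in% samples)
  list(case_ids = ann$sample_id[ann$class == case],
       control_ids = ann$sample_id[ann$class == control])
}

#' Moderated two-sample t statistics for one study contrast
#'
#' A variance-stabilized ("fudge constant") t statistic:
#' `t_mod = (mean_case - mean_control) / (sp * sqrt(1/n1 + 1/n0) + s0)`, with
#' `sp` the pooled within-group standard deviation. With `s0 = "auto"` the
#' stabilizer is the median across genes of the classical standard-error term,
#' which keeps genes with near-zero pooled variance from dominating the
#' ranking; `s0 = 0` recovers the classical pooled-variance t exactly.
#'
#' @param study An [expression_study()].
#' @param annotation Tibble with `sample_id` and `class` covering the study's
#'   samples.
#' @param case,control Class labels of the contrast (case minus control).
#' @param s0 `"auto"` or a non-negative number.
#' @return Tibble with `gene`, `dbar` (raw log2 mean difference), `t_mod`;
#'   the `s0` actually used is attached as attribute `"s0"`.
#' @export
moderated_t <- function(study, annotation, case = "GBM", control = "NG",
                        s0 = "auto") {
  ids <- resolve_contrast(annotation, case, control, study_samples(study))
  st <- contrast_stats(study$values, ids$case_ids, ids$control_ids)
  s0_val <- if (identical(s0, "auto")) median(st$sp * st$se_scale) else {
    if (!is.numeric(s0) || s0 < 0) abort("`s0` must be \"auto\" or a number >= 0.")
    s0
  }
  out <- tibble(gene = study_genes(study), dbar = unname(st$dbar),
                t_mod = unname(st$dbar / (st$sp * st$se_scale + s0_val)))
  attr(out, "s0") <- s0_val
  out
}

#' Hedges' g effect sizes for one study contrast
#'
#' Bias-corrected standardized mean difference
#' `g = J * (mean_case - mean_control) / sp` with
#' `J = 1 - 3 / (4 * (n1 + n0 - 2) - 1)` and sampling variance
#' `v_g = (n1 + n0) / (n1 * n0) + g^2 / (2 * (n1 + n0))`. Genes with zero
#' pooled SD get `NA` (reported via a warning) and are excluded downstream.
#'
#' @inheritParams moderated_t
#' @return Tibble with `gene`, `g`, `v_g`, `dbar`, `n_case`, `n_control`.
#' @export
hedges_g <- function(study, annotation, case = "GBM", control = "NG") {
  ids <- resolve_contrast(annotation, case, control, study_samples(study))
  st <- contrast_stats(study$values, ids$case_ids, ids$control_ids)
  J <- 1 - 3 / (4 * (st$n1 + st$n0 - 2L) - 1)
  g <- J * st$dbar / st$sp
  degenerate <- st$sp == 0
  if (any(degenerate)) {
    warn(sprintf("%d gene(s) with zero pooled SD excluded from effect sizes.",
                 sum(degenerate)))
    g[degenerate] <- NA_real_
  }
  v_g <- (st$n1 + st$n0) / (st$n1 * st$n0) + g^2 / (2 * (st$n1 + st$n0))
  tibble(gene = study_genes(study), g = unname(g), v_g = unname(v_g),
         dbar = unname(st$dbar), n_case = st$n1, n_control = st$n0)
}

#' One-sided permutation p-values for the moderated t
#'
#' Class labels are permuted `B` times; the null moderated-t statistics are
#' pooled across genes within and across permutations (pooled null of size
#' `B * G`), which gives p-value resolution `1 / (1 + B * G)` even at small
#' `B`. With the add-one correction,
#' `p_right = (1 + #\{null >= t_obs\}) / (1 + B * G)` and `p_left`
#' analogously with `<=`, so p-values are always strictly positive.
#' The stabilizer `s0` is fixed at its observed-data value across permutations.
#'
#' @inheritParams moderated_t
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed for the permutation draw.
#' @return Tibble with `gene`, `t_mod`, `p_right`, `p_left`.
#' @export
permutation_pvalues <- function(study, annotation, case = "GBM", control = "NG",
                                B = 200, s0 = "auto", seed = 1L) {
  B <- stopifnot_scalar_count(B, "B")
  if (B < 1L) abort("`B` must be >= 1.")
  obs <- moderated_t(study, annotation, case, control, s0 = s0)
  s0_val <- attr(obs, "s0")
  ids <- resolve_contrast(annotation, case, control, study_samples(study))
  pooled <- c(ids$case_ids, ids$control_ids)
  vals <- study$values[, pooled, drop = FALSE]
  n1 <- length(ids$case_ids); n <- length(pooled)
  G <- nrow(vals)

  # 0/1 case-membership indicator for each permutation, n x B
  A <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      z <- numeric(n); z[sample.int(n, n1)] <- 1; z
    }, numeric(n))
  })
  n0 <- n - n1
  S1 <- vals %*% A                      # per-perm case sums, G x B
  Q1 <- (vals^2) %*% A
  tot <- rowSums(vals); tot2 <- rowSums(vals^2)
  M1 <- S1 / n1
  M0 <- (tot - S1) / n0
  ss <- (Q1 - n1 * M1^2) + ((tot2 - Q1) - n0 * M0^2)
  sp <- sqrt(pmax(ss, 0) / (n - 2L))
  null_t <- (M1 - M0) / (sp * sqrt(1 / n1 + 1 / n0) + s0_val)

  null_sorted <- sort(as.vector(null_t))
  N <- length(null_sorted)
  n_le <- findInterval(obs$t_mod, null_sorted)              # #{null <= t}
  n_lt <- findInterval(obs$t_mod, null_sorted, left.open = TRUE)  # #{null < t}
  p_right <- (1 + (N - n_lt)) / (1 + N)
  p_left <- (1 + n_le) / (1 + N)
  min_p <- 1 / (1 + N)
  if (min_p > 0.5) {
    warn(sprintf("permutation resolution is coarse: minimum attainable p = %.3f.", min_p))
  }
  tibble(gene = obs$gene, t_mod = obs$t_mod, p_right = p_right, p_left = p_left)
}

#' Full per-study differential-expression statistics for one contrast
#'
#' Convenience wrapper combining [moderated_t()], [permutation_pvalues()] and
#' [hedges_g()] into the per-study result table consumed by [meta_combine()].
#'
#' @inheritParams permutation_pvalues
#' @return Tibble with `study_id`, `gene`, `n_case`, `n_control`, `dbar`,
#'   `t_mod`, `p_right`, `p_left`, `g`, `v_g`.
#' @export
study_de <- function(study, annotation, case = "GBM", control = "NG",
                     B = 200, s0 = "auto", seed = 1L) {
  pv <- permutation_pvalues(study, annotation, case, control, B = B, s0 = s0,
                            seed = seed)
  es <- hedges_g(study, annotation, case, control)
  out <- inner_join(pv, es, by = "gene")
  mutate(out, study_id = study$study_id, .before = 1)
}
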