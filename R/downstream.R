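#' Split patients at the median expression level
#'
#' Values at or below the median go to `"low"`, values above to `"high"` (the
#' tie convention: a patient exactly at the median is low).
#'
#' @param expression Numeric per-patient values (length >= 2).
#' @return Character vector of `"low"`/`"high"` labels.
#' @export
dichotomize_by_median <- function(expression) {
  if (length(expression) < 2L) abort("need at least 2 patients.")
  if (anyNA(expression)) abort("`expression` must not contain missing values.")
  med <- median(expression)
  if (all(expression == expression[1L])) {
    abort("all values identical: one dichotomization group would be empty.")
  }
  ifelse(expression <= med, "low", "high")
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Wraps [survival::survfit()] for a single group. Censored records (event =
#' 0) reduce the risk set without contributing events; the estimate is a
#' right-continuous, non-increasing step function starting at 1.
#'
#' @param time Positive follow-up times (months).
#' @param event 0/1 event indicators.
#' @return A tibble with `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   one row per distinct observed time.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) abort("empty survival input.")
  if (any(time <= 0)) abort("times must be > 0.")
  if (!all(event %in% c(0, 1))) abort("`event` must be 0/1.")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Wraps [survival::survdiff()]: at each distinct event time, observed events
#' per group are compared with their expectation under hypergeometric margins;
#' the statistic `(sum(O - E))^2 / sum(V)` is referred to chi-square(1).
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group Two-level group labels (e.g. `"low"`/`"high"`).
#' @return An object of class `logrank_test` with `chi2`, `df`, `p`, `n`,
#'   `obs`, `exp`; see [tidy.logrank_test()].
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) abort("`group` must have exactly two non-empty levels.")
  if (sum(event) == 0) abort("no events: the log-rank test is undefined.")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(list(chi2 = unname(sd$chisq), df = 1L,
                 p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE),
                 n = as.vector(sd$n), obs = as.vector(sd$obs),
                 exp = as.vector(sd$exp), levels = levels(droplevels(group))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test (%s vs %s): chi2 = %.3f on %d df, p = %.3g\n",
              x$levels[1], x$levels[2], x$chi2, x$df, x$p))
  invisible(x)
}

#' @rdname logrank_test
#' @param x,... A `logrank_test` object; unused.
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(group = x$levels, n = x$n, observed = x$obs, expected = x$exp)
}

#' @rdname logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p)
}

#' ROC curve and AUC for a diagnostic score
#'
#' Wraps [pROC::roc()] with an explicit positive class and direction (higher
#' scores indicate the positive class). The AUC equals the Mann-Whitney
#' probability that a random positive outscores a random negative, ties
#' counted half.
#'
#' @param scores Numeric diagnostic scores.
#' @param labels Class labels.
#' @param positive The positive-class label (default: the label with the
#'   higher mean score).
#' @return An object of class `roc_result` with elements `auc`,
#'   `positive_label` and `curve` (tibble of `fpr`, `tpr` from (0,0) to
#'   (1,1)); see [tidy.roc_result()].
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) abort("`labels` must contain exactly two classes.")
  positive <- positive %||% lv[which.max(vapply(lv, function(l) mean(scores[labels == l]), numeric(1)))]
  if (!positive %in% lv) abort("`positive` is not one of the labels.")
  negative <- setdiff(lv, positive)
  r <- pROC::roc(response = factor(labels, levels = c(negative, positive)),
                 predictor = scores, levels = c(negative, positive),
                 direction = "<", quiet = TRUE)
  curve <- tibble(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- arrange(curve, .data$fpr, .data$tpr)
  structure(list(auc = as.numeric(r$auc), positive_label = positive,
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (positive class: %s)\n", x$auc, x$positive_label))
  invisible(x)
}

#' @rdname roc_auc
#' @param x,... A `roc_result`; unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname roc_auc
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, positive_label = x$positive_label)
}

#' Kruskal-Wallis rank test across groups
#'
#' Wraps [stats::kruskal.test()] (rank-based H with tie correction, referred
#' to chi-square with k - 1 df).
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return Tibble with `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) abort("need at least 2 non-empty groups.")
  if (all(values == values[1L])) {
    abort("all values identical: the tie-corrected statistic is undefined.")
  }
  kt <- kruskal.test(values, groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value)
}

#' Hypergeometric over-representation analysis
#'
#' For each set in the collection, tests whether the query gene list overlaps
#' the set more than expected by chance given the background universe:
#' `p = P(X >= overlap)` for `X` hypergeometric with the observed margins.
#' Benjamini-Hochberg adjustment across sets; sets with `q < fdr` are flagged.
#'
#' @param query Character vector of gene symbols (must lie in `background`).
#' @param collection Gene-set tibble as from [read_gmt()].
#' @param background Character vector: the gene universe (e.g. the
#'   meta-analysis intersection universe).
#' @param fdr Flagging threshold (default 0.05).
#' @return Tibble with `set`, `description`, `overlap`, `set_size`
#'   (restricted to the background), `query_size`, `p`, `q`, `significant`.
#' @export
hypergeometric_ora <- function(query, collection, background, fdr = 0.05) {
  background <- unique(toupper(background))
  if (length(background) == 0L) abort("`background` must be non-empty.")
  query <- unique(toupper(query))
  if (!all(query %in% background)) {
    abort("every query gene must belong to the background universe.")
  }
  N <- length(background)
  k <- length(query)
  rows <- purrr::map_dfr(seq_len(nrow(collection)), function(i) {
    set_bg <- intersect(collection$genes[[i]], background)
    m <- length(set_bg)
    ov <- length(intersect(query, set_bg))
    p <- if (m == 0L) 1 else phyper(ov - 1L, m, N - m, k, lower.tail = FALSE)
    tibble(set = collection$set[i], description = collection$description[i],
           overlap = ov, set_size = m, query_size = k, p = p)
  })
  rows$q <- bh_fdr(rows$p)
  rows$significant <- rows$q < fdr
  rows
}

#' Median-dichotomized survival analysis for one gene
#'
#' The standard prognostic workflow for a candidate biomarker: split patients
#' at the median expression, estimate Kaplan-Meier curves per group, and test
#' the separation with the log-rank test. When `exclude_flagged = TRUE`,
#' patients with `exclude_flag = TRUE` (e.g. G-CIMP-positive) are dropped
#' first — run once with and once without the exclusion for the sensitivity
#' analysis.
#'
#' @param survival_table Tibble with columns `time`, `event`, `expression`
#'   and optionally `exclude_flag`.
#' @param exclude_flagged Drop flagged patients first?
#' @return List with `groups` (the input plus a `group` column), `km` (tibble
#'   of per-group KM estimates), and `logrank` (a [logrank_test()] object).
#' @export
survival_by_median <- function(survival_table, exclude_flagged = FALSE) {
  need <- c("time", "event", "expression")
  if (!all(need %in% names(survival_table))) {
    abort("`survival_table` needs columns time, event, expression.")
  }
  tab <- as_tibble(survival_table)
  if (exclude_flagged && "exclude_flag" %in% names(tab)) {
    tab <- filter(tab, !.data$exclude_flag)
  }
  tab$group <- dichotomize_by_median(tab$expression)
  km <- tab |>
    group_by(.data$group) |>
    dplyr::group_modify(~ km_estimate(.x$time, .x$event)) |>
    ungroup()
  list(groups = tab,
       km = km,
       logrank = logrank_test(tab$time, tab$event, tab$group))
}
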