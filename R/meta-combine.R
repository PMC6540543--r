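check_p_matrix <- function(p_right, p_left) {
  if (!is.matrix(p_right) || !is.matrix(p_left) ||
      !identical(dim(p_right), dim(p_left))) {
    abort("`p_right` and `p_left` must be matrices of identical dimension (genes x studies).")
  }
  if (ncol(p_right) < 1L) abort("need at least one study column.")
  for (m in list(p_right, p_left)) {
    if (anyNA(m) || any(m <= 0) || any(m > 1)) {
      abort("one-sided p-values must lie in (0, 1]; zeros are not admissible (use an add-one permutation estimator).")
    }
  }
}

# two-sided wrap-up of one-sided combined p-values: 2 * min(side p), capped at 1
# two-sided wrap of side-combined p-values; p_up/p_down are retained because
# the one-sided p is exactly uniform under the null while the 2*min wrap is
# conservative away from the tails
wrap_two_sided <- function(stat_r, p_r, stat_l, p_l, up = p_r <= p_l) {
  tibble(statistic = unname(ifelse(up, stat_r, stat_l)),
         p = unname(pmin(1, 2 * pmin(p_r, p_l))),
         p_up = unname(p_r), p_down = unname(p_l),
         direction = ifelse(unname(up), "up", "down"))
}

genes_of <- function(p_right) rownames(p_right) %||% as.character(seq_len(nrow(p_right)))

#' Combine one-sided p-values by Fisher's sum of logs
#'
#' Per side (right = up-regulation, left = down-regulation) the statistic is
#' `S = -2 * sum(log(p_k))` over the `K` studies. The side p-value comes from
#' the chi-square distribution with `2K` degrees of freedom (the analytic null
#' for uniform inputs), or from a simulated null of uniform p-value matrices
#' when `reference = "permutation"`. The gene-level two-sided p is
#' `min(1, 2 * min(side p))`, with direction the winning side.
#'
#' @param p_right,p_left Genes-by-studies matrices of one-sided p-values in
#'   (0, 1], with gene rownames.
#' @param reference `"chisq"` (analytic) or `"permutation"`.
#' @param b_null Number of simulated null matrices for the permutation
#'   reference.
#' @param seed Seed for the permutation reference.
#' @return Tibble with `gene`, `statistic` (winning side's `S`), `p`, the
#'   side-combined one-sided p-values `p_up`/`p_down`, and `direction`. (All
#'   combination methods share this layout.)
#' @export
combine_fisher <- function(p_right, p_left, reference = c("chisq", "permutation"),
                           b_null = 2000, seed = 1L) {
  reference <- match.arg(reference)
  check_p_matrix(p_right, p_left)
  K <- ncol(p_right)
  s_r <- -2 * rowSums(log(p_right))
  s_l <- -2 * rowSums(log(p_left))
  if (reference == "chisq") {
    p_r <- pchisq(s_r, df = 2 * K, lower.tail = FALSE)
    p_l <- pchisq(s_l, df = 2 * K, lower.tail = FALSE)
  } else {
    null_s <- withr::with_seed(as.integer(seed), {
      -2 * rowSums(log(matrix(runif(b_null * K), b_null, K)))
    })
    null_sorted <- sort(null_s)
    tail_p <- function(s) {
      (1 + (b_null - findInterval(s, null_sorted, left.open = TRUE))) / (1 + b_null)
    }
    p_r <- tail_p(s_r)
    p_l <- tail_p(s_l)
  }
  out <- wrap_two_sided(s_r, p_r, s_l, p_l)
  mutate(out, gene = genes_of(p_right), .before = 1)
}

#' Combine one-sided p-values by the maximum-p statistic
#'
#' Per side the statistic is `max_k p_k`; under the null of `K` independent
#' uniforms its distribution function is `m^K`, which serves directly as the
#' side p-value. Two-sided wrap-up as in [combine_fisher()].
#'
#' @inheritParams combine_fisher
#' @return Tibble with `gene`, `statistic`, `p`, `direction`.
#' @export
combine_maxp <- function(p_right, p_left) {
  check_p_matrix(p_right, p_left)
  K <- ncol(p_right)
  s_r <- apply(p_right, 1, max)
  s_l <- apply(p_left, 1, max)
  out <- wrap_two_sided(s_r, s_r^K, s_l, s_l^K)
  mutate(out, gene = genes_of(p_right), .before = 1)
}

#' Combine one-sided p-values by the r-th ordered p statistic
#'
#' Per side the statistic is the `r`-th smallest of the `K` p-values; under
#' the null it follows a Beta(`r`, `K - r + 1`) distribution, whose
#' distribution function gives the side p-value. `r = K` is exactly the maxP
#' method; `r = 1` is the minimum p.
#'
#' @inheritParams combine_fisher
#' @param r Order index, `1 <= r <= K`. Default `ceiling(K / 2)`.
#' @return Tibble with `gene`, `statistic`, `p`, `direction`.
#' @export
combine_rop <- function(p_right, p_left, r = NULL) {
  check_p_matrix(p_right, p_left)
  K <- ncol(p_right)
  r <- r %||% ceiling(K / 2)
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r > K || r != floor(r)) {
    abort(sprintf("`r` must be an integer in 1..%d.", K))
  }
  kth <- function(m) apply(m, 1, function(x) sort(x, partial = r)[r])
  s_r <- kth(p_right)
  s_l <- kth(p_left)
  out <- wrap_two_sided(s_r, pbeta(s_r, r, K - r + 1),
                        s_l, pbeta(s_l, r, K - r + 1))
  mutate(out, gene = genes_of(p_right), .before = 1)
}

# minimum over sorted-prefix Fisher tails; the adaptively weighted statistic.
# returns list(stat, jstar) for a genes x K matrix of one-sided p-values
aw_min_tail <- function(p) {
  K <- ncol(p)
  sorted <- t(apply(p, 1, sort))
  if (K == 1L) sorted <- matrix(sorted, ncol = 1L)
  S <- -2 * t(apply(log(sorted), 1, cumsum))
  if (K == 1L) S <- matrix(S, ncol = 1L)
  dfs <- matrix(2 * seq_len(K), nrow(p), K, byrow = TRUE)
  tails <- pchisq(S, df = dfs, lower.tail = FALSE)
  jstar <- max.col(-tails, ties.method = "first")
  list(stat = tails[cbind(seq_len(nrow(p)), jstar)], jstar = jstar,
       cut = sorted[cbind(seq_len(nrow(p)), jstar)])
}

#' Combine one-sided p-values by the adaptively weighted statistic
#'
#' For each side and each prefix size `j = 1..K`, the Fisher statistic over
#' the `j` smallest p-values is referred to its chi-square(2j) tail; the AW
#' statistic is the minimum of these tail values over `j`. For 0/1 study
#' weights only sorted-prefix subsets can attain the minimum, so the search is
#' over `K` prefixes rather than `2^K - 1` subsets. Because the minimum of
#' dependent tail values is not uniform, the statistic's own p-value is
#' calibrated against `b_aw` simulated null matrices of uniforms. The
#' minimizing subset is reported as a 0/1 weight vector over studies.
#'
#' @inheritParams combine_fisher
#' @param b_aw Number of null matrices used for calibration (>= 1).
#' @return Tibble with `gene`, `statistic` (the minimized tail value), `p`,
#'   `direction`, and `weights` (list-column of 0/1 integer vectors over the
#'   study columns, for the winning side).
#' @export
combine_aw <- function(p_right, p_left, b_aw = 1000, seed = 1L) {
  check_p_matrix(p_right, p_left)
  b_aw <- stopifnot_scalar_count(b_aw, "b_aw")
  if (b_aw < 1L) abort("`b_aw` must be >= 1.")
  K <- ncol(p_right)
  aw_r <- aw_min_tail(p_right)
  aw_l <- aw_min_tail(p_left)
  null_stat <- withr::with_seed(as.integer(seed), {
    aw_min_tail(matrix(runif(b_aw * K), b_aw, K))$stat
  })
  null_sorted <- sort(null_stat)
  cal <- function(s) (1 + findInterval(s, null_sorted)) / (1 + b_aw)
  p_r <- cal(aw_r$stat)
  p_l <- cal(aw_l$stat)
  # the calibrated p-values are discrete; break side ties by the continuous
  # minimized tail value (calibration is monotone in it, so this refines,
  # never contradicts, the p comparison)
  out <- wrap_two_sided(aw_r$stat, p_r, aw_l$stat, p_l,
                        up = aw_r$stat <= aw_l$stat)
  win <- ifelse(out$direction == "up", "r", "l")
  weights <- lapply(seq_len(nrow(p_right)), function(i) {
    if (win[i] == "r") as.integer(p_right[i, ] <= aw_r$cut[i])
    else as.integer(p_left[i, ] <= aw_l$cut[i])
  })
  out <- mutate(out, gene = genes_of(p_right), .before = 1)
  out$weights <- weights
  out
}

#' Pool effect sizes with the DerSimonian-Laird random-effects model
#'
#' Fixed-effect weights `w = 1/v` give the heterogeneity statistic
#' `Q = sum(w * (g - g_FE)^2)`; the moment estimator of the between-study
#' variance is `tau2 = max(0, (Q - (K - 1)) / (sum(w) - sum(w^2)/sum(w)))`.
#' Random-effects weights `w* = 1/(v + tau2)` yield the pooled effect
#' `mu = sum(w* g)/sum(w*)`, its standard error `se = 1/sqrt(sum(w*))`, the
#' z-statistic `mu/se` and a two-sided normal p-value.
#'
#' @param g,v Genes-by-studies matrices of effect sizes and their sampling
#'   variances (gene rownames; `v > 0`; at least 2 study columns).
#' @return Tibble with `gene`, `mu`, `se`, `z`, `p`, `tau2`, `q_het`,
#'   `direction` (`up` iff `mu > 0`).
#' @export
pool_random_effects <- function(g, v) {
  if (!is.matrix(g) || !is.matrix(v) || !identical(dim(g), dim(v))) {
    abort("`g` and `v` must be matrices of identical dimension (genes x studies).")
  }
  if (ncol(g) < 2L) abort("random-effects pooling needs at least 2 studies.")
  if (anyNA(g) || anyNA(v)) abort("`g` and `v` must be complete; drop degenerate genes first.")
  if (any(v <= 0)) abort("all sampling variances must be > 0.")
  K <- ncol(g)
  w <- 1 / v
  sw <- rowSums(w)
  g_fe <- rowSums(w * g) / sw
  q_het <- rowSums(w * (g - g_fe)^2)
  denom <- sw - rowSums(w^2) / sw
  tau2 <- pmax(0, (q_het - (K - 1)) / denom)
  ws <- 1 / (v + tau2)
  sws <- rowSums(ws)
  if (any(sws == 0)) abort("degenerate random-effects weights (sum zero).")
  mu <- unname(rowSums(ws * g) / sws)
  se <- unname(1 / sqrt(sws))
  z <- mu / se
  tibble(gene = genes_of(g), mu = mu, se = se, z = z,
         p = 2 * pnorm(-abs(z)), tau2 = unname(tau2), q_het = unname(q_het),
         direction = ifelse(mu > 0, "up", "down"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} (G * p_(j) / j)`, capped at 1
#' (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) abort("`p` must be non-empty.")
  if (anyNA(p) || any(p <= 0) || any(p > 1)) abort("p-values must lie in (0, 1].")
  p.adjust(p, method = "BH")
}

#' Build side p-value and effect-size matrices from per-study results
#'
#' Restricts to the gene universe present, with finite effect sizes, in every
#' study (the cross-study intersection), and returns aligned matrices.
#'
#' @param study_results Tibble binding [study_de()] outputs: columns
#'   `study_id`, `gene`, `p_right`, `p_left`, `g`, `v_g`.
#' @return List with matrices `p_right`, `p_left`, `g`, `v_g` (genes x
#'   studies, lexicographic gene order) and `studies` (column order).
#' @export
build_p_matrix <- function(study_results) {
  need <- c("study_id", "gene", "p_right", "p_left", "g", "v_g")
  if (!all(need %in% names(study_results))) {
    abort(sprintf("`study_results` needs columns: %s.", paste(need, collapse = ", ")))
  }
  studies <- unique(study_results$study_id)
  ok <- filter(study_results, !is.na(.data$g), !is.na(.data$v_g))
  counts <- dplyr::count(ok, .data$gene)
  universe <- sort(counts$gene[counts$n == length(studies)])
  if (length(universe) == 0L) abort("no gene is present in every study.")
  ok <- filter(ok, .data$gene %in% universe)
  to_mat <- function(col) {
    wide <- tidyr::pivot_wider(ok[c("gene", "study_id", col)],
                               names_from = "study_id", values_from = all_of(col))
    wide <- arrange(wide, .data$gene)
    m <- as.matrix(wide[studies])
    rownames(m) <- wide$gene
    m
  }
  list(p_right = to_mat("p_right"), p_left = to_mat("p_left"),
       g = to_mat("g"), v_g = to_mat("v_g"), studies = studies)
}

#' Combine per-study evidence into a meta-analysis table
#'
#' Runs the selected p-value combination methods and (optionally)
#' DerSimonian-Laird random-effects pooling over the cross-study gene
#' universe, applying Benjamini-Hochberg FDR within each method.
#'
#' @param study_results Tibble binding [study_de()] outputs across the studies
#'   of one comparison.
#' @param methods Any of `"fisher"`, `"maxp"`, `"rop"`, `"aw"`.
#' @param rop_r Order index for roP; default `ceiling(K / 2)`.
#' @param b_aw Null matrices for AW calibration.
#' @param fisher_reference `"chisq"` or `"permutation"` (see
#'   [combine_fisher()]).
#' @param b_null Null matrices for the permutation Fisher reference.
#' @param effects Also run random-effects pooling?
#' @param seed Seed for the simulated calibration nulls.
#' @return A tibble (one row per gene) with, per method `m`, columns
#'   `stat_m`, `p_m`, `q_m`, `dir_m`; for the random-effects branch `mu`,
#'   `se`, `z`, `tau2`, `q_het`, `p_rem`, `q_rem`, `dir_rem`; and `aw_weights`
#'   when AW is run. The study count is attached as attribute `"n_studies"`.
#' @export
meta_combine <- function(study_results,
                         methods = c("fisher", "maxp", "rop", "aw"),
                         rop_r = NULL, b_aw = 1000,
                         fisher_reference = c("chisq", "permutation"),
                         b_null = 2000, effects = TRUE, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  fisher_reference <- match.arg(fisher_reference)
  mats <- build_p_matrix(study_results)
  seeds <- derive_seeds(seed, 2L)
  out <- tibble(gene = rownames(mats$p_right))
  add <- function(out, res, name) {
    res$p_up <- res$p_down <- NULL
    idx <- match(c("statistic", "p", "direction"), names(res))
    names(res)[idx] <- paste0(c("stat_", "p_", "dir_"), name)
    res[[paste0("q_", name)]] <- bh_fdr(res[[paste0("p_", name)]])
    inner_join(out, res, by = "gene")
  }
  for (m in methods) {
    res <- switch(m,
      fisher = combine_fisher(mats$p_right, mats$p_left,
                              reference = fisher_reference,
                              b_null = b_null, seed = seeds[1L]),
      maxp = combine_maxp(mats$p_right, mats$p_left),
      rop = combine_rop(mats$p_right, mats$p_left, r = rop_r),
      aw = {
        r <- combine_aw(mats$p_right, mats$p_left, b_aw = b_aw, seed = seeds[2L])
        r <- rename(r, aw_weights = "weights")
        r
      })
    out <- add(out, res, m)
  }
  if (isTRUE(effects)) {
    rem <- pool_random_effects(mats$g, mats$v_g)
    rem <- rename(rem, p_rem = "p", dir_rem = "direction")
    rem$q_rem <- bh_fdr(rem$p_rem)
    out <- inner_join(out, rem, by = "gene")
  }
  attr(out, "n_studies") <- length(mats$studies)
  out
}

#' Detection-competency counts across an FDR threshold grid
#'
#' For each combination method present in a [meta_combine()] table and each
#' threshold, counts the genes with `q <` threshold. Used to compare how many
#' DEGs each method detects as stringency varies.
#'
#' @param meta A [meta_combine()] table.
#' @param thresholds Numeric vector of FDR thresholds.
#' @return Tibble with `method`, `threshold`, `n_deg`, sorted by method then
#'   threshold (counts are non-decreasing in threshold within a method).
#' @export
detection_competency <- function(meta, thresholds = 10^seq(-20, -1)) {
  q_cols <- grep("^q_(fisher|maxp|rop|aw)$", names(meta), value = TRUE)
  if (length(q_cols) == 0L) abort("`meta` contains no combination-method q columns.")
  grid <- tidyr::expand_grid(method = sub("^q_", "", q_cols),
                             threshold = sort(thresholds))
  grid$n_deg <- purrr::map2_int(grid$method, grid$threshold,
                                function(m, t) sum(meta[[paste0("q_", m)]] < t))
  grid
}

#' Write a meta-analysis table as TSV
#'
#' Flattens the AW weight list-column (if present) to a comma-separated 0/1
#' string.
#'
#' @param meta A [meta_combine()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta_table <- function(meta, path) {
  if ("aw_weights" %in% names(meta)) {
    meta$aw_weights <- vapply(meta$aw_weights, paste, character(1), collapse = ",")
  }
  readr::write_tsv(meta, path)
  invisible(path)
}
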