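#' Configure a synthetic multi-study glioma cohort
#'
#' Builds the parameter set for [simulate_multistudy()]. The generator emulates
#' the structure of a multi-platform microarray compendium: several independent
#' studies, each a log2 gene-by-sample expression matrix over the four
#' histology classes (GBM, A, OD, NG), with gene-wise study baseline shifts
#' (platform effects), planted differential effects with between-study
#' heterogeneity, and Gaussian residual noise.
#'
#' Planted genes come in two kinds. *Pan-glioma* genes are shifted equally in
#' GBM, A and OD relative to NG (they mark glioma in general, not GBM).
#' *GBM-specific* genes are shifted only in GBM samples, upward or downward,
#' and are the recoverable targets of the specificity cascade.
#'
#' @param n_studies Number of independent studies to simulate.
#' @param n_genes Number of genes per study (before any per-study dropout).
#' @param samples_per_class Named integer vector giving the per-study sample
#'   count for each of the classes `GBM`, `A`, `OD`, `NG`.
#' @param n_pan_glioma Number of planted pan-glioma genes.
#' @param n_gbm_specific Number of planted GBM-specific genes.
#' @param gbm_down_fraction Fraction of GBM-specific genes planted as
#'   down-regulated (the rest are up-regulated).
#' @param delta Mean true effect size on the log2 scale (per planted gene,
#'   per study, before heterogeneity).
#' @param tau Between-study standard deviation of the true effect (log2 units);
#'   `tau = 0` gives identical effects in every study.
#' @param sigma Residual (within-class) standard deviation, log2 units.
#' @param study_baseline_sd Standard deviation of gene-wise per-study baseline
#'   shifts (log2 units), emulating platform effects.
#' @param dropout_fraction Fraction of genes dropped independently per study,
#'   emulating platform gene-coverage differences.
#' @param heavy_tails If `TRUE`, residual noise is scaled Student-t (5 df)
#'   instead of Gaussian; default off.
#' @param seed Integer master seed; all per-study substreams derive from it.
#'
#' @return A list of class `simulation_config`.
#' @seealso [simulate_multistudy()]
#' @export
#' @examples
#' cfg <- simulation_config(n_studies = 2, n_genes = 50,
#'                          samples_per_class = c(GBM = 5, A = 5, OD = 5, NG = 5))
simulation_config <- function(n_studies = 10,
                              n_genes = 2000,
                              samples_per_class = c(GBM = 15, A = 15, OD = 15, NG = 15),
                              n_pan_glioma = 60,
                              n_gbm_specific = 40,
                              gbm_down_fraction = 0.25,
                              delta = 1.5,
                              tau = 0.3,
                              sigma = 1,
                              study_baseline_sd = 0.5,
                              dropout_fraction = 0,
                              heavy_tails = FALSE,
                              seed = 1L) {
  n_studies <- stopifnot_scalar_count(n_studies, "n_studies")
  n_genes <- stopifnot_scalar_count(n_genes, "n_genes")
  n_pan_glioma <- stopifnot_scalar_count(n_pan_glioma, "n_pan_glioma")
  n_gbm_specific <- stopifnot_scalar_count(n_gbm_specific, "n_gbm_specific")
  classes <- c("GBM", "A", "OD", "NG")
  if (!all(classes %in% names(samples_per_class))) {
    abort("`samples_per_class` must name all of GBM, A, OD and NG.")
  }
  samples_per_class <- vapply(samples_per_class[classes], stopifnot_scalar_count,
                              integer(1), name = "samples_per_class")
  if (any(samples_per_class == 0L)) {
    abort("every class needs at least one sample per study; got a zero count.")
  }
  if (n_pan_glioma + n_gbm_specific > n_genes) {
    abort("n_pan_glioma + n_gbm_specific must not exceed n_genes.")
  }
  if (!is.numeric(sigma) || sigma <= 0) abort("`sigma` must be > 0.")
  if (!is.numeric(tau) || tau < 0) abort("`tau` must be >= 0.")
  if (gbm_down_fraction < 0 || gbm_down_fraction > 1) {
    abort("`gbm_down_fraction` must lie in [0, 1].")
  }
  if (dropout_fraction < 0 || dropout_fraction >= 1) {
    abort("`dropout_fraction` must lie in [0, 1).")
  }
  structure(
    list(n_studies = n_studies, n_genes = n_genes,
         samples_per_class = samples_per_class,
         n_pan_glioma = n_pan_glioma, n_gbm_specific = n_gbm_specific,
         gbm_down_fraction = gbm_down_fraction,
         delta = delta, tau = tau, sigma = sigma,
         study_baseline_sd = study_baseline_sd,
         dropout_fraction = dropout_fraction,
         heavy_tails = isTRUE(heavy_tails),
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Simulate a multi-study expression cohort with a truth ledger
#'
#' Generates `n_studies` independent log2 expression studies under one
#' [simulation_config()]. Each value is
#' `baseline + study shift + class effect + noise`: baselines are gene-wise
#' constants shared across studies, study shifts are gene-wise per-study
#' constants, and the class effect applies the planted per-study realized
#' effect to GBM samples (GBM-specific genes) or to GBM, A and OD samples
#' equally (pan-glioma genes). Realized effects are drawn per study with mean
#' `delta` (signed) and standard deviation `tau`. The same seed reproduces the
#' output exactly.
#'
#' @param config A [simulation_config()].
#' @return A list with elements
#'   * `studies`: named list of [expression_study()] objects;
#'   * `annotation`: tibble with `sample_id`, `study_id`, `class`;
#'   * `truth`: the truth ledger, a list with `genes` (tibble `gene`, `class`
#'     in `null`/`pan_glioma`/`gbm_up`/`gbm_down`) and `effects` (long tibble
#'     `gene`, `study_id`, `effect` of realized true effects; null genes have
#'     effect 0 everywhere).
#' @export
simulate_multistudy <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be created by simulation_config().")
  }
  cfg <- config
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  gene_class <- rep("null", cfg$n_genes)
  idx_pan <- seq_len(cfg$n_pan_glioma)
  n_down <- round(cfg$gbm_down_fraction * cfg$n_gbm_specific)
  idx_gbm <- cfg$n_pan_glioma + seq_len(cfg$n_gbm_specific)
  gene_class[idx_pan] <- "pan_glioma"
  if (cfg$n_gbm_specific > 0) {
    gene_class[idx_gbm] <- c(rep("gbm_up", cfg$n_gbm_specific - n_down),
                             rep("gbm_down", n_down))
  }
  sign_vec <- c(null = 0, pan_glioma = 1, gbm_up = 1, gbm_down = -1)[gene_class]
  planted <- sign_vec != 0

  seeds <- derive_seeds(cfg$seed, cfg$n_studies + 1L)
  baseline <- withr::with_seed(seeds[1L], runif(cfg$n_genes, 4, 12))

  classes <- rep(names(cfg$samples_per_class), cfg$samples_per_class)
  n_samp <- length(classes)
  affected <- list(pan_glioma = c("GBM", "A", "OD"),
                   gbm_up = "GBM", gbm_down = "GBM")

  studies <- vector("list", cfg$n_studies)
  effects <- vector("list", cfg$n_studies)
  annotations <- vector("list", cfg$n_studies)
  study_ids <- sprintf("S%02d", seq_len(cfg$n_studies))

  for (k in seq_len(cfg$n_studies)) {
    sid <- study_ids[k]
    out <- withr::with_seed(seeds[k + 1L], {
      shift <- rnorm(cfg$n_genes, 0, cfg$study_baseline_sd)
      eff <- numeric(cfg$n_genes)
      eff[planted] <- rnorm(sum(planted), cfg$delta * sign_vec[planted], cfg$tau)
      noise <- if (cfg$heavy_tails) {
        matrix(stats::rt(cfg$n_genes * n_samp, df = 5) * cfg$sigma * sqrt(3 / 5),
               cfg$n_genes, n_samp)
      } else {
        matrix(rnorm(cfg$n_genes * n_samp, 0, cfg$sigma), cfg$n_genes, n_samp)
      }
      vals <- baseline + shift + noise
      for (cl in unique(gene_class[planted])) {
        rows <- which(gene_class == cl)
        cols <- which(classes %in% affected[[cl]])
        vals[rows, cols] <- vals[rows, cols] + eff[rows]
      }
      keep <- if (cfg$dropout_fraction > 0) {
        runif(cfg$n_genes) >= cfg$dropout_fraction
      } else rep(TRUE, cfg$n_genes)
      list(vals = vals, eff = eff, keep = keep)
    })
    sample_ids <- sprintf("%s_%s_%02d", sid, classes,
                          unlist(lapply(cfg$samples_per_class, seq_len)))
    dimnames(out$vals) <- list(genes, sample_ids)
    studies[[k]] <- expression_study(out$vals[out$keep, , drop = FALSE],
                                     study_id = sid,
                                     platform_id = sprintf("P%02d", k))
    annotations[[k]] <- tibble(sample_id = sample_ids, study_id = sid,
                               class = classes)
    effects[[k]] <- tibble(gene = genes, study_id = sid, effect = out$eff)
  }
  names(studies) <- study_ids
  list(studies = studies,
       annotation = bind_rows(annotations),
       truth = list(genes = tibble(gene = genes, class = gene_class),
                    effects = bind_rows(effects)))
}

#' Simulate a survival cohort linked to an expression score
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hazard_ratio * expression)`; censoring times are
#' independent exponentials with rate `censor_rate` (no censoring when 0). The
#' observed time is the minimum of the two, with the event flag set when the
#' event preceded censoring.
#'
#' @param expression Numeric per-patient score (e.g. log2 expression of one gene).
#' @param baseline_hazard Baseline event rate per month; must be > 0.
#' @param log_hazard_ratio Log hazard ratio per unit of `expression`.
#' @param censor_rate Censoring rate per month; >= 0.
#' @param seed Integer seed.
#' @return A tibble with `patient_id`, `expression`, `time` (months), `event`
#'   (0/1) and `exclude_flag` (all `FALSE`; a plumbing column for sensitivity
#'   analyses that drop flagged patients).
#' @export
simulate_survival_cohort <- function(expression, baseline_hazard = 0.02,
                                     log_hazard_ratio = 0, censor_rate = 0.01,
                                     seed = 1L) {
  if (length(expression) == 0L) abort("`expression` must be non-empty.")
  if (!is.numeric(expression) || anyNA(expression)) {
    abort("`expression` must be numeric without missing values.")
  }
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be > 0.")
  if (censor_rate < 0) abort("`censor_rate` must be >= 0.")
  n <- length(expression)
  withr::with_seed(as.integer(seed), {
    t_event <- rexp(n, rate = baseline_hazard * exp(log_hazard_ratio * expression))
    t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
    tibble(patient_id = sprintf("PT%04d", seq_len(n)),
           expression = as.numeric(expression),
           time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens),
           exclude_flag = FALSE)
  })
}
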