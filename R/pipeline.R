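#' Configure the integrated meta-analysis pipeline
#'
#' Bundles the simulation parameters, the assignment of studies to the four
#' comparison branches (training and validation GBM-vs-NG, GBM-vs-A,
#' GBM-vs-OD), the per-study and combination method settings, and the
#' selection thresholds.
#'
#' The default `fdr_stringent = 0.01` is the desk-scale analogue of a very
#' stringent dual-method threshold, sized for cohorts of ~15 samples per
#' class; for compendium-scale cohorts with hundreds of samples per study a
#' threshold as extreme as `1e-19` is attainable and appropriate.
#'
#' @param n_studies,n_genes,samples_per_class,n_pan_glioma,n_gbm_specific,gbm_down_fraction,delta,tau,sigma,study_baseline_sd
#'   Passed to [simulation_config()].
#' @param training,validation Indices of the studies forming the GBM-vs-NG
#'   training and validation branches.
#' @param gbm_vs_a,gbm_vs_od Indices of the studies used for the two subtype
#'   comparisons.
#' @param B Permutations per study contrast.
#' @param b_aw,rop_r,s0,fisher_reference,b_null Method settings (see
#'   [meta_combine()]).
#' @param fdr_stringent Dual-method FDR threshold for GBM-vs-NG.
#' @param fdr_subtype Fisher FDR threshold for GBM-vs-A / GBM-vs-OD.
#' @param fdr_ora Enrichment flagging threshold.
#' @param survival_log_hr,baseline_hazard,censor_rate Parameters of the
#'   linked survival cohort simulated for the top selected gene.
#' @param seed Master seed; every random stage derives its stream from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_studies = 10, n_genes = 2000,
                            samples_per_class = c(GBM = 15, A = 15, OD = 15, NG = 15),
                            n_pan_glioma = 60, n_gbm_specific = 40,
                            gbm_down_fraction = 0.25,
                            delta = 1.5, tau = 0.3, sigma = 1,
                            study_baseline_sd = 0.5,
                            training = 1:6, validation = 7:10,
                            gbm_vs_a = 1:10, gbm_vs_od = 1:10,
                            B = 200, b_aw = 1000, rop_r = NULL, s0 = "auto",
                            fisher_reference = "chisq", b_null = 2000,
                            fdr_stringent = 0.01, fdr_subtype = 0.05,
                            fdr_ora = 0.05,
                            survival_log_hr = 0.5, baseline_hazard = 0.03,
                            censor_rate = 0.01,
                            seed = 1L) {
  for (thr in c(fdr_stringent, fdr_subtype, fdr_ora)) {
    if (thr <= 0 || thr > 1) abort("FDR thresholds must lie in (0, 1].")
  }
  idx <- c(training, validation, gbm_vs_a, gbm_vs_od)
  if (any(idx < 1) || any(idx > n_studies)) {
    abort("every referenced study index must lie in 1..n_studies.")
  }
  if (length(intersect(training, validation)) > 0L) {
    abort("training and validation studies must be disjoint.")
  }
  structure(
    list(sim = simulation_config(n_studies = n_studies, n_genes = n_genes,
                                 samples_per_class = samples_per_class,
                                 n_pan_glioma = n_pan_glioma,
                                 n_gbm_specific = n_gbm_specific,
                                 gbm_down_fraction = gbm_down_fraction,
                                 delta = delta, tau = tau, sigma = sigma,
                                 study_baseline_sd = study_baseline_sd,
                                 seed = derive_seeds(seed, 1L)),
         training = training, validation = validation,
         gbm_vs_a = gbm_vs_a, gbm_vs_od = gbm_vs_od,
         B = B, b_aw = b_aw, rop_r = rop_r, s0 = s0,
         fisher_reference = fisher_reference, b_null = b_null,
         fdr_stringent = fdr_stringent, fdr_subtype = fdr_subtype,
         fdr_ora = fdr_ora,
         survival_log_hr = survival_log_hr,
         baseline_hazard = baseline_hazard, censor_rate = censor_rate,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

run_branch <- function(sim, cfg, study_idx, case, control, seeds) {
  results <- purrr::map2(study_idx, seeds, function(k, s) {
    study_de(sim$studies[[k]], sim$annotation, case = case, control = control,
             B = cfg$B, s0 = cfg$s0, seed = s)
  })
  bind_rows(results)
}

#' Run the full integrated meta-analysis pipeline
#'
#' Executes simulate -> per-study DE -> meta-combination -> DEG selection
#' cascade -> downstream statistics under one [pipeline_config()]:
#' * GBM-vs-NG training and validation branches are each selected by the
#'   stringent dual-method rule (Fisher q and random-effects q below
#'   `fdr_stringent`, agreeing direction), then confirmed across
#'   training/validation;
#' * GBM-vs-A and GBM-vs-OD branches are selected by Fisher at
#'   `fdr_subtype`;
#' * the specificity filter intersects the three, yielding the GBM-specific
#'   set;
#' * for the top GBM-specific gene, a linked survival cohort is simulated and
#'   analysed by median dichotomization + log-rank (with and without the
#'   exclusion mask), and a GBM-vs-NG ROC is computed;
#' * when `gene_sets` is supplied, the training dual-method set is tested for
#'   over-representation against it.
#'
#' The run is a pure function of config + seed: identical inputs reproduce
#' identical outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param gene_sets Optional gene-set tibble (see [read_gmt()]) for the
#'   enrichment stage.
#' @param out_dir Optional directory; when given, all stage tables, the Venn
#'   summaries and a machine-readable report are written there.
#' @return A list of class `pipeline_result`; see Details.
#' @export
run_pipeline <- function(config, gene_sets = NULL, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created by pipeline_config().")
  }
  cfg <- config
  n_branch_studies <- length(cfg$training) + length(cfg$validation) +
    length(cfg$gbm_vs_a) + length(cfg$gbm_vs_od)
  seeds <- derive_seeds(cfg$seed, n_branch_studies + 6L)
  seed_split <- split(seeds[seq_len(n_branch_studies)],
                      rep(1:4, c(length(cfg$training), length(cfg$validation),
                                 length(cfg$gbm_vs_a), length(cfg$gbm_vs_od))))
  extra_seeds <- seeds[n_branch_studies + 1:6]

  sim <- simulate_multistudy(cfg$sim)

  de <- list(
    training = run_branch(sim, cfg, cfg$training, "GBM", "NG", seed_split[[1]]),
    validation = run_branch(sim, cfg, cfg$validation, "GBM", "NG", seed_split[[2]]),
    gbm_vs_a = run_branch(sim, cfg, cfg$gbm_vs_a, "GBM", "A", seed_split[[3]]),
    gbm_vs_od = run_branch(sim, cfg, cfg$gbm_vs_od, "GBM", "OD", seed_split[[4]]))

  meta <- purrr::imap(de, function(res, name) {
    meta_combine(res, methods = c("fisher", "maxp", "rop", "aw"),
                 rop_r = cfg$rop_r, b_aw = cfg$b_aw,
                 fisher_reference = cfg$fisher_reference, b_null = cfg$b_null,
                 effects = TRUE, seed = extra_seeds[1L])
  })

  dual <- function(m, label) {
    p_set <- select_significant(m, "fisher", cfg$fdr_stringent, label)
    es_set <- select_significant(m, "rem", cfg$fdr_stringent, label)
    list(p = p_set, es = es_set,
         overlap = suppressWarnings(dual_method_overlap(p_set, es_set)))
  }
  train <- dual(meta$training, "GBM_vs_NG_training")
  valid <- dual(meta$validation, "GBM_vs_NG_validation")
  tv <- train_validate(train$overlap, valid$overlap)
  set_a <- select_significant(meta$gbm_vs_a, "fisher", cfg$fdr_subtype, "GBM_vs_A")
  set_od <- select_significant(meta$gbm_vs_od, "fisher", cfg$fdr_subtype, "GBM_vs_OD")
  final <- specificity_filter(tv, set_a, set_od)

  competency <- detection_competency(meta$training)
  venns <- list(
    training_dual = venn_counts(list(fisher = train$p, rem = train$es)),
    train_validate = venn_counts(list(training = train$overlap,
                                      validation = valid$overlap)),
    specificity = venn_counts(list(GBM_vs_NG = tv, GBM_vs_A = set_a,
                                   GBM_vs_OD = set_od)))

  survival_res <- roc_res <- NULL
  top_gene <- if (nrow(final) > 0L) final$gene[1L] else NA_character_
  if (!is.na(top_gene)) {
    glioma_ids <- sim$annotation$sample_id[sim$annotation$class %in% c("GBM", "A", "OD")]
    expr_all <- unlist(lapply(sim$studies, function(s) {
      ids <- intersect(glioma_ids, study_samples(s))
      if (top_gene %in% study_genes(s)) s$values[top_gene, ids] else NULL
    }))
    cohort <- simulate_survival_cohort(expr_all - mean(expr_all),
                                       baseline_hazard = cfg$baseline_hazard,
                                       log_hazard_ratio = cfg$survival_log_hr,
                                       censor_rate = cfg$censor_rate,
                                       seed = extra_seeds[2L])
    survival_res <- list(all = survival_by_median(cohort),
                         flag_excluded = survival_by_median(cohort, exclude_flagged = TRUE))
    ng_gbm <- filter(sim$annotation, .data$class %in% c("GBM", "NG"))
    score_tab <- purrr::map_dfr(sim$studies, function(s) {
      ids <- intersect(ng_gbm$sample_id, study_samples(s))
      if (!top_gene %in% study_genes(s)) return(NULL)
      tibble(sample_id = ids, score = unname(s$values[top_gene, ids]))
    })
    score_tab <- inner_join(score_tab, ng_gbm, by = "sample_id")
    roc_res <- roc_auc(score_tab$score, score_tab$class, positive = "GBM")
  }

  enrichment <- NULL
  if (!is.null(gene_sets) && nrow(train$overlap) > 0L) {
    enrichment <- hypergeometric_ora(train$overlap$gene, gene_sets,
                                     background = meta$training$gene,
                                     fdr = cfg$fdr_ora)
  }

  counts <- tibble(
    stage = c("fisher_training", "rem_training", "dual_training",
              "fisher_validation", "rem_validation", "dual_validation",
              "train_validate", "gbm_vs_a", "gbm_vs_od", "gbm_specific"),
    n = c(nrow(train$p), nrow(train$es), nrow(train$overlap),
          nrow(valid$p), nrow(valid$es), nrow(valid$overlap),
          nrow(tv), nrow(set_a), nrow(set_od), nrow(final)))

  result <- structure(
    list(config = cfg, truth = sim$truth, meta = meta,
         deg_sets = list(training_fisher = train$p, training_rem = train$es,
                         training_dual = train$overlap,
                         validation_fisher = valid$p, validation_rem = valid$es,
                         validation_dual = valid$overlap,
                         train_validate = tv,
                         gbm_vs_a = set_a, gbm_vs_od = set_od,
                         gbm_specific = final),
         counts = counts, competency = competency, venns = venns,
         survival = survival_res, roc = roc_res, enrichment = enrichment,
         top_gene = top_gene),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> DEG counts by stage:\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  if (!is.na(x$top_gene)) {
    cat(sprintf("top GBM-specific gene: %s", x$top_gene))
    if (!is.null(x$roc)) cat(sprintf(" (GBM vs NG AUC = %.3f)", x$roc$auc))
    if (!is.null(x$survival)) {
      cat(sprintf("; median-split log-rank p = %.3g", x$survival$all$logrank$p))
    }
    cat("\n")
  }
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Emits the per-branch meta tables, every DEG set, the detection-competency
#' table, Venn summaries (JSON), survival/ROC/enrichment tables when present,
#' and a machine-readable `report.json` with the per-stage DEG counts and the
#' seed.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  purrr::iwalk(result$meta, function(m, name) {
    write_meta_table(m, p(sprintf("meta_%s.tsv", name)))
  })
  purrr::iwalk(result$deg_sets, function(s, name) {
    write_deg_set(s, p(sprintf("deg_%s.tsv", name)))
  })
  readr::write_tsv(result$competency, p("detection_competency.tsv"))
  jsonlite::write_json(result$venns, p("venn_summaries.json"), digits = NA)
  if (!is.null(result$survival)) {
    readr::write_tsv(result$survival$all$km, p("km_curves.tsv"))
    jsonlite::write_json(
      list(all = glance(result$survival$all$logrank),
           flag_excluded = glance(result$survival$flag_excluded$logrank)),
      p("logrank.json"), dataframe = "rows", digits = NA)
  }
  if (!is.null(result$roc)) {
    readr::write_tsv(result$roc$curve, p("roc_curve.tsv"))
  }
  if (!is.null(result$enrichment)) {
    readr::write_tsv(result$enrichment, p("enrichment.tsv"))
  }
  report <- list(seed = result$config$seed,
                 top_gene = result$top_gene,
                 auc = if (!is.null(result$roc)) result$roc$auc else NULL,
                 logrank_p = if (!is.null(result$survival)) result$survival$all$logrank$p else NULL,
                 counts = result$counts)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(out_dir)
}

#' Write a simulated cohort to disk
#'
#' One TSV matrix per study (genes x samples), a combined annotation TSV
#' (`sample_id`, `study_id`, `class`) and the truth ledger (gene classes and
#' realized per-study effects).
#'
#' @param sim A [simulate_multistudy()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_multistudy <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  purrr::iwalk(sim$studies, function(s, name) {
    write_expression_matrix(s, file.path(out_dir, paste0(name, ".tsv")))
  })
  readr::write_tsv(sim$annotation, file.path(out_dir, "annotation.tsv"))
  readr::write_tsv(sim$truth$genes, file.path(out_dir, "truth_genes.tsv"))
  readr::write_tsv(sim$truth$effects, file.path(out_dir, "truth_effects.tsv"))
  invisible(out_dir)
}
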