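# small expression study built from a plain matrix with default names
make_study <- function(values, study_id = "S01") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("%s_SMP_%02d", study_id, seq_len(ncol(values)))
  }
  expression_study(values, study_id = study_id)
}

# two-class study + annotation with iid N(0, sd) noise and an optional shift
# added to the case samples of the first `n_shift` genes
make_two_class <- function(n_genes = 50, n_case = 8, n_control = 8,
                           shift = 0, n_shift = 0, sd = 1, seed = 1,
                           study_id = "S01") {
  vals <- withr::with_seed(seed, {
    matrix(rnorm(n_genes * (n_case + n_control), sd = sd),
           n_genes, n_case + n_control)
  })
  if (n_shift > 0) {
    vals[seq_len(n_shift), seq_len(n_case)] <-
      vals[seq_len(n_shift), seq_len(n_case)] + shift
  }
  colnames(vals) <- sprintf("%s_SMP_%02d", study_id, seq_len(ncol(vals)))
  rownames(vals) <- sprintf("G%03d", seq_len(n_genes))
  study <- expression_study(vals, study_id = study_id)
  ann <- tibble::tibble(
    sample_id = colnames(vals), study_id = study_id,
    class = rep(c("GBM", "NG"), c(n_case, n_control)))
  list(study = study, annotation = ann)
}

# uniform one-sided p-value matrices for a global-null combination input
null_p_matrices <- function(G, K, seed = 1) {
  u <- withr::with_seed(seed, matrix(runif(G * K), G, K))
  rownames(u) <- sprintf("G%05d", seq_len(G))
  list(p_right = u, p_left = 1 - u + 1e-12)
}

# independent step-up BH oracle (direct definition, no p.adjust)
bh_oracle <- function(p) {
  G <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, G * p[ord] / seq_len(G))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(G)
  q[ord] <- q_sorted
  q
}

# closed-form upper tail of chi-square with even df 2K (independent of pchisq)
chisq_even_tail <- function(s, K) {
  exp(-s / 2) * sum((s / 2)^(0:(K - 1)) / factorial(0:(K - 1)))
}
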