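test_that("Fisher combination matches the closed-form chi-square tail", {
  # K = 2, right side (0.05, 0.05), left side at 0.95
  pr <- matrix(c(0.05, 0.05), 1, 2, dimnames = list("g1", NULL))
  pl <- matrix(c(0.95, 0.95), 1, 2, dimnames = list("g1", NULL))
  out <- combine_fisher(pr, pl)
  s <- -2 * (log(0.05) + log(0.05))
  expect_equal(out$statistic, s, tolerance = 1e-12)
  expect_equal(s, 11.98293, tolerance = 1e-5)
  expect_equal(out$p, 2 * chisq_even_tail(s, K = 2), tolerance = 1e-10)
  expect_equal(out$direction, "up")

  # all p = 1 on both sides: statistic 0, combined p 1
  ones <- matrix(1, 2, 3, dimnames = list(c("a", "b"), NULL))
  out1 <- combine_fisher(ones, ones)
  expect_equal(out1$statistic, c(0, 0))
  expect_equal(out1$p, c(1, 1))

  expect_error(combine_fisher(ones * 0, ones), "\\(0, 1\\]")
})

test_that("the permutation Fisher reference agrees with the analytic one under the null", {
  m <- null_p_matrices(500, 4, seed = 3)
  a <- combine_fisher(m$p_right, m$p_left, reference = "chisq")
  b <- combine_fisher(m$p_right, m$p_left, reference = "permutation",
                      b_null = 20000, seed = 9)
  expect_lt(max(abs(a$p - b$p)), 0.03)
  expect_identical(a$direction, b$direction)
})

test_that("maxP combination follows the m^K law", {
  pr <- matrix(c(0.5, 0.3, 0.2), 1, 3, dimnames = list("g1", NULL))
  pl <- matrix(0.99, 1, 3, dimnames = list("g1", NULL))
  out <- combine_maxp(pr, pl)
  expect_equal(out$statistic, 0.5)
  expect_equal(out$p, 2 * 0.125)

  ones <- matrix(1, 1, 3, dimnames = list("g1", NULL))
  expect_equal(combine_maxp(ones, ones)$p, 1)

  # K = 1 reduces to the (two-sided wrap of the) input p
  p1 <- matrix(0.07, 1, 1, dimnames = list("g1", NULL))
  q1 <- matrix(0.93, 1, 1, dimnames = list("g1", NULL))
  expect_equal(combine_maxp(p1, q1)$p, 2 * 0.07)
})

test_that("roP equals the Beta order-statistic law and maxP at r = K", {
  m <- null_p_matrices(300, 5, seed = 14)
  expect_equal(combine_rop(m$p_right, m$p_left, r = 5),
               combine_maxp(m$p_right, m$p_left))

  # Beta(2, 2) symmetry at 0.5
  pr <- matrix(c(0.1, 0.5, 0.9), 1, 3, dimnames = list("g1", NULL))
  pl <- matrix(0.999, 1, 3, dimnames = list("g1", NULL))
  out <- combine_rop(pr, pl, r = 2)
  expect_equal(out$statistic, 0.5)
  expect_equal(out$p, 2 * 0.5)

  # Monte-Carlo order-statistic oracle for the side p
  r <- 2; K <- 4
  pr2 <- matrix(c(0.21, 0.08, 0.55, 0.4), 1, 4, dimnames = list("g1", NULL))
  pl2 <- matrix(0.999, 1, 4, dimnames = list("g1", NULL))
  side_p <- combine_rop(pr2, pl2, r = r)$p / 2
  sims <- withr::with_seed(44, {
    mean(replicate(200000, sort(runif(K))[r]) <= combine_rop(pr2, pl2, r = r)$statistic)
  })
  expect_lt(abs(side_p - sims), 3 * sqrt(side_p * (1 - side_p) / 200000) + 1e-4)

  expect_error(combine_rop(pr2, pl2, r = 9), "1\\.\\.4")
})

test_that("AW picks the minimizing prefix, matching brute force over all subsets", {
  # one extreme study: the weight vector selects it alone
  pr <- matrix(c(1e-8, 0.9, 0.95, 0.8), 1, 4, dimnames = list("g1", NULL))
  pl <- matrix(0.999, 1, 4, dimnames = list("g1", NULL))
  out <- combine_aw(pr, pl, b_aw = 200, seed = 1)
  expect_equal(out$weights[[1]], c(1L, 0L, 0L, 0L))

  # sorted-prefix reduction equals exhaustive search over 2^K - 1 subsets
  brute_min <- function(p) {
    subsets <- expand.grid(rep(list(0:1), length(p)))[-1, ]
    min(apply(subsets, 1, function(w) {
      sel <- p[w == 1]
      stats::pchisq(-2 * sum(log(sel)), df = 2 * length(sel), lower.tail = FALSE)
    }))
  }
  rows <- withr::with_seed(23, matrix(runif(40), 10, 4))
  rownames(rows) <- sprintf("g%d", 1:10)
  ones <- matrix(0.999, 10, 4, dimnames = dimnames(rows))
  out2 <- combine_aw(rows, ones, b_aw = 100, seed = 2)
  expect_equal(out2$statistic, unname(apply(rows, 1, brute_min)), tolerance = 1e-12)

  # equal p-values across studies: the full-weight vector is attainable
  eq <- matrix(0.01, 1, 4, dimnames = list("g1", NULL))
  out3 <- combine_aw(eq, matrix(0.999, 1, 4, dimnames = list("g1", NULL)),
                     b_aw = 100, seed = 3)
  expect_equal(out3$weights[[1]], rep(1L, 4))
  expect_error(combine_aw(eq, eq, b_aw = 0), "b_aw")
})

test_that("DerSimonian-Laird pooling matches hand formulas and metafor", {
  # homogeneous case
  g <- matrix(0.7, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  v <- matrix(0.2, 3, 4, dimnames = dimnames(g))
  out <- pool_random_effects(g, v)
  expect_equal(out$q_het, rep(0, 3))
  expect_equal(out$tau2, rep(0, 3))
  expect_equal(out$mu, rep(0.7, 3))
  expect_equal(out$se, rep(sqrt(0.2 / 4), 3))

  # hand-evaluated K = 2 example
  g2 <- matrix(c(0.5, 1.5), 1, 2, dimnames = list("g1", NULL))
  v2 <- matrix(0.1, 1, 2, dimnames = list("g1", NULL))
  out2 <- pool_random_effects(g2, v2)
  expect_equal(out2$q_het, 5)
  expect_equal(out2$tau2, 0.4)
  expect_equal(out2$mu, 1)
  expect_equal(out2$se, 0.5)
  expect_equal(out2$z, 2)
  expect_equal(out2$direction, "up")

  # independent implementation cross-check
  skip_if_not_installed("metafor")
  gs <- withr::with_seed(77, matrix(rnorm(5 * 6, 0.4, 0.5), 5, 6))
  vs <- withr::with_seed(78, matrix(runif(5 * 6, 0.05, 0.3), 5, 6))
  rownames(gs) <- rownames(vs) <- sprintf("g%d", 1:5)
  out3 <- pool_random_effects(gs, vs)
  for (i in 1:5) {
    fit <- metafor::rma(yi = gs[i, ], vi = vs[i, ], method = "DL")
    expect_equal(out3$mu[i], unname(fit$beta[1]), tolerance = 1e-8)
    expect_equal(out3$se[i], fit$se, tolerance = 1e-8)
    expect_equal(out3$tau2[i], fit$tau2, tolerance = 1e-8)
  }
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (seed in 1:5) {
    p <- withr::with_seed(seed, runif(200)^2)
    p <- pmax(p, 1e-12)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(numeric(0)), "non-empty")
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("side-branch symmetry flips directions but not p-values", {
  m <- null_p_matrices(200, 4, seed = 51)
  flip <- function(f, ...) {
    a <- f(m$p_right, m$p_left, ...)
    b <- f(m$p_left, m$p_right, ...)
    expect_equal(b$p, a$p, tolerance = 1e-12)
    expect_true(all(b$direction != a$direction))
  }
  flip(combine_fisher)
  flip(combine_maxp)
  flip(combine_rop, r = 2)
  flip(combine_aw, b_aw = 300, seed = 4)
})

test_that("meta_combine assembles methods over the intersection universe", {
  cfg <- simulation_config(n_studies = 3, n_genes = 150,
                           samples_per_class = c(GBM = 8, A = 2, OD = 2, NG = 8),
                           n_pan_glioma = 0, n_gbm_specific = 10,
                           dropout_fraction = 0.05, seed = 61)
  sim <- simulate_multistudy(cfg)
  de <- dplyr::bind_rows(lapply(sim$studies, study_de,
                                annotation = sim$annotation, B = 50, seed = 2))
  meta <- meta_combine(de, b_aw = 100, seed = 5)
  universe <- sort(Reduce(intersect, lapply(sim$studies, study_genes)))
  expect_identical(meta$gene, universe)
  expect_equal(attr(meta, "n_studies"), 3L)
  expect_true(all(c("q_fisher", "q_maxp", "q_rop", "q_aw", "q_rem", "mu", "tau2") %in%
                    names(meta)))
  # q >= p within every method
  for (mth in c("fisher", "maxp", "rop", "aw", "rem")) {
    expect_true(all(meta[[paste0("q_", mth)]] >= meta[[paste0("p_", mth)]] - 1e-12))
  }
})

test_that("detection competency counts equal direct filtering and grow with threshold", {
  m <- null_p_matrices(400, 3, seed = 71)
  de_like <- tibble::tibble(
    study_id = rep(sprintf("S%02d", 1:3), each = 400),
    gene = rep(rownames(m$p_right), 3),
    p_right = as.vector(m$p_right), p_left = as.vector(m$p_left),
    g = rnorm(1200), v_g = runif(1200, 0.1, 0.2))
  meta <- meta_combine(de_like, b_aw = 100, seed = 2)
  grid <- c(0, 0.001, 0.05, 0.5, 1)
  comp <- detection_competency(meta, thresholds = grid)
  expect_true(all(comp$n_deg[comp$threshold == 0] == 0L))
  for (mth in unique(comp$method)) {
    sub <- comp[comp$method == mth, ]
    expect_true(all(diff(sub$n_deg) >= 0L))
    expect_equal(sub$n_deg[sub$threshold == 0.05],
                 sum(meta[[paste0("q_", mth)]] < 0.05))
  }
})
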