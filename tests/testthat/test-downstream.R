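test_that("median dichotomization follows the <=median tie convention", {
  expect_equal(dichotomize_by_median(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(dichotomize_by_median(c(5, 1, 9)), c("low", "low", "high"))
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(31))
    expect_equal(dichotomize_by_median(x),
                 ifelse(x <= median(x), "low", "high"))
  }
  expect_error(dichotomize_by_median(rep(2, 5)), "identical")
  expect_error(dichotomize_by_median(1), "at least 2")
})

# independent product-limit oracle
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    surv <- surv * (1 - d / at_risk)
    out[i] <- surv
  }
  tibble::tibble(time = ts, surv = out)
}

test_that("Kaplan-Meier estimates match the product-limit oracle", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  cens <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(cens$surv == 1))

  for (seed in 1:5) {
    time <- withr::with_seed(seed, round(rexp(40, 0.1), 1) + 0.1)
    event <- withr::with_seed(seed + 50, rbinom(40, 1, 0.7))
    km <- km_estimate(time, event)
    oracle <- km_oracle(time, event)
    got <- km[km$n_event > 0, c("time", "surv")]
    expect_equal(as.data.frame(got), as.data.frame(oracle), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # non-increasing, starts below or at 1
    expect_true(all(diff(km$surv) <= 1e-12))
  }

  # without censoring the KM curve is the empirical survival function
  t2 <- c(2, 5, 5, 9, 1)
  km2 <- km_estimate(t2, rep(1, 5))
  ecdf_surv <- vapply(km2$time, function(s) mean(t2 > s), numeric(1))
  expect_equal(km2$surv, ecdf_surv)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

# independent O/E/V tabulation oracle for the two-group log-rank statistic
logrank_oracle <- function(time, event, group) {
  group <- as.integer(as.factor(group)) - 1L
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (s in ts) {
    at_risk <- time >= s
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(time == s & event == 1)
    d1 <- sum(time == s & event == 1 & group == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

test_that("log-rank matches the O/E/V oracle and is label-invariant", {
  for (seed in 1:5) {
    n <- 60
    time <- withr::with_seed(seed, round(rexp(n, 0.08), 1) + 0.1)
    event <- withr::with_seed(seed + 9, rbinom(n, 1, 0.8))
    group <- rep(c("low", "high"), each = n / 2)
    lr <- logrank_test(time, event, group)
    expect_equal(lr$chi2, logrank_oracle(time, event, group), tolerance = 1e-8)
    relab <- logrank_test(time, event, rev(group))
    expect_equal(relab$chi2, lr$chi2, tolerance = 1e-12)
    expect_equal(lr$p, pchisq(lr$chi2, 1, lower.tail = FALSE))
  }

  # identical groups: no separation at all
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1)
  lr0 <- logrank_test(c(time, time), c(event, event), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  expect_error(logrank_test(time, c(0, 0, 0, 0), c("a", "a", "b", "b")), "no events")

  expect_equal(glance(lr0)$statistic, lr0$chi2)
  expect_equal(nrow(tidy(lr0)), 2L)
})

test_that("AUC equals the all-pairs Mann-Whitney probability", {
  # perfect separation
  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12), rep(c("NG", "GBM"), each = 3),
                     positive = "GBM")
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$curve$fpr[1], 0)
  expect_equal(perfect$curve$tpr[nrow(perfect$curve)], 1)

  auc_oracle <- function(scores, labels, positive) {
    pos <- scores[labels == positive]; neg <- scores[labels != positive]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(pairs)
  }
  for (seed in 1:5) {
    scores <- withr::with_seed(seed, round(rnorm(60), 1))  # rounding forces ties
    labels <- rep(c("GBM", "NG"), each = 30)
    scores[labels == "GBM"] <- scores[labels == "GBM"] + 1
    r <- roc_auc(scores, labels, positive = "GBM")
    expect_equal(r$auc, auc_oracle(scores, labels, "GBM"), tolerance = 1e-10)
    rneg <- roc_auc(-scores, labels, positive = "GBM")
    expect_equal(rneg$auc, 1 - r$auc, tolerance = 1e-10)
    # curve endpoints and monotonicity
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  }
  expect_error(roc_auc(1:4, rep("GBM", 4)), "two classes")
})

test_that("Kruskal-Wallis matches the hand rank formula", {
  vals <- c(1, 2, 3, 4, 5, 6)
  groups <- rep(c("a", "b"), each = 3)
  out <- kruskal_wallis(vals, groups)
  # no ties: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
  rbar <- tapply(rank(vals), groups, mean)
  H <- 12 / (6 * 7) * sum(3 * (rbar - 3.5)^2)
  expect_equal(out$statistic, unname(H))
  expect_equal(out$df, 1)
  expect_error(kruskal_wallis(rep(1, 6), groups), "identical")

  # near-nominal type-I calibration under the null
  reps <- 300
  pvals <- vapply(seq_len(reps), function(i) {
    x <- withr::with_seed(3000 + i, rnorm(30))
    kruskal_wallis(x, rep(c("a", "b", "c"), each = 10))$p.value
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
})

test_that("over-representation p-values match exact hypergeometric enumeration", {
  bg <- sprintf("G%02d", 1:20)
  coll <- tibble::tibble(set = "s1", description = "d",
                         genes = list(bg[1:5]))
  query <- c(bg[1:4], bg[10:11])      # overlap 4, query 6
  out <- hypergeometric_ora(query, coll, bg)
  oracle <- sum(vapply(4:5, function(k) {
    choose(5, k) * choose(15, 6 - k) / choose(20, 6)
  }, numeric(1)))
  expect_equal(out$p, oracle, tolerance = 1e-12)
  expect_equal(out$overlap, 4L)

  # degenerate full-overlap case and the no-overlap case
  full <- hypergeometric_ora(bg, tibble::tibble(set = "all", description = "d",
                                                genes = list(bg)), bg)
  expect_equal(full$p, 1)
  none <- hypergeometric_ora(bg[19:20],
                             tibble::tibble(set = "s", description = "d",
                                            genes = list(bg[1:5])), bg)
  expect_gt(none$p, 0.4)

  # monotone decreasing in overlap at fixed margins
  ps <- vapply(0:5, function(ov) {
    q <- c(bg[seq_len(ov)], bg[20 - seq_len(6 - ov)])
    hypergeometric_ora(q, coll, bg)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(hypergeometric_ora(c("NOPE"), coll, bg), "background")
})

test_that("median-split survival analysis wires the pieces together", {
  expr <- withr::with_seed(5, rnorm(120))
  cohort <- simulate_survival_cohort(expr, baseline_hazard = 0.05,
                                     log_hazard_ratio = 1.2, censor_rate = 0.01,
                                     seed = 6)
  res <- survival_by_median(cohort)
  expect_setequal(unique(res$groups$group), c("low", "high"))
  expect_lt(res$logrank$p, 0.05)
  # the exclusion mask drops flagged patients
  cohort$exclude_flag[1:20] <- TRUE
  res2 <- survival_by_median(cohort, exclude_flagged = TRUE)
  expect_equal(nrow(res2$groups), 100L)
})
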