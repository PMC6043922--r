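sep_data <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(c(FALSE, TRUE), each = n / 2)
  x <- cbind(rnorm(n, ifelse(y, 2.5, 0)), rnorm(n, ifelse(y, -2.5, 0)))
  list(x = x, y = y)
}

test_that("random forest separates a separable fixture and is seed-deterministic", {
  d <- sep_data()
  fit <- fit_random_forest(d$x, d$y, seed = 7)
  p <- predict(fit, d$x)
  expect_gte(mean((p >= 0.5) == d$y), 0.95)
  fit2 <- fit_random_forest(d$x, d$y, seed = 7)
  expect_identical(predict(fit2, d$x), p)
  expect_error(fit_random_forest(d$x, rep(TRUE, 60)), "single class")
})

test_that("with permuted labels out-of-bag accuracy sits at the majority rate", {
  set.seed(3)
  d <- sep_data(n = 200, seed = 3)
  y_perm <- sample(d$y)
  fit <- fit_random_forest(d$x, y_perm, seed = 11)
  oob <- 1 - fit$forest$err.rate[fit$n_trees, "OOB"]
  expect_lt(abs(oob - max(mean(y_perm), 1 - mean(y_perm))), 0.10)
})

test_that("leave-one-out folds cover every image exactly once", {
  d <- sep_data(n = 24, seed = 5)
  ids <- sprintf("img%02d", seq_len(24))
  p <- loocv_predict(d$x, d$y, groups = ids, n_trees = 100, seed = 1)
  expect_equal(length(p), 24)
  expect_false(anyNA(p))
  expect_gte(roc_auc(p, d$y)$auc, 0.9)  # separable survives LOOCV
})

test_that("patient-level grouping never leaks a patient across folds", {
  d <- sep_data(n = 24, seed = 6)
  pats <- rep(sprintf("P%d", 1:8), each = 3)
  # fold assignment equals patient id: same prediction for a patient's
  # images must come from a model that saw none of them; verify by
  # recomputing one fold manually
  p <- loocv_predict(d$x, d$y, groups = pats, n_trees = 100, seed = 2)
  test <- which(pats == "P1"); train <- which(pats != "P1")
  set.seed(2)
  fs <- sample.int(.Machine$integer.max - 1L, 8)
  refit <- fit_random_forest(d$x[train, ], d$y[train], n_trees = 100,
                             seed = fs[1])
  expect_equal(p[test], predict(refit, d$x[test, ]))
})

test_that("a one-class training fold predicts its prevalence with a warning", {
  x <- matrix(rnorm(20), 10)
  y <- c(TRUE, rep(FALSE, 9))
  expect_warning(
    p <- loocv_predict(x, y, groups = as.character(1:10), n_trees = 50),
    "single class")
  expect_equal(p[1], 0)  # fold holding out the only positive
})

test_that("ensemble combination is the aligned elementwise mean", {
  expect_equal(ensemble_combine(list(0.2, 0.6)), 0.4)
  expect_equal(ensemble_combine(list(c(a = 0.3, b = 0.9))), c(a = 0.3, b = 0.9))
  expect_equal(ensemble_combine(list(c(1, 0), c(1, 0), c(0, 1))),
               c(2 / 3, 1 / 3))
  m <- list(c(0.1, 0.9), c(0.5, 0.5), c(0.3, 0.1))
  em <- ensemble_combine(m)
  expect_true(all(em >= pmin(m[[1]], m[[2]], m[[3]]) &
                  em <= pmax(m[[1]], m[[2]], m[[3]])))
  expect_error(ensemble_combine(list(1:3 / 10, 1:2 / 10)), "lengths")
  expect_error(ensemble_combine(list(c(a = 0.1, b = 0.2), c(b = 0.1, a = 0.2))),
               "aligned")
})

test_that("AUC equals the brute-force pairwise Mann-Whitney count", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    expect_equal(roc_auc(s, y)$auc, brute(s, y), tolerance = 1e-12)
  }
})

test_that("the ROC curve steps from (0,0) to (1,1) and matches pROC's AUC", {
  set.seed(2)
  y <- rbinom(80, 1, 0.5); s <- runif(80) + 0.5 * y
  ra <- roc_auc(s, y)
  expect_equal(ra$roc$fpr[1], 0); expect_equal(ra$roc$tpr[1], 0)
  expect_equal(ra$roc$fpr[nrow(ra$roc)], 1)
  expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
  expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
  pr <- pROC::roc(y, s, levels = c(0, 1), direction = "<", quiet = TRUE)
  expect_equal(ra$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("confidence intervals contain the AUC and shrink with n", {
  set.seed(4)
  gen <- function(n) {
    y <- rep(c(0, 1), each = n / 2)
    list(y = y, s = rnorm(n, mean = 0.8 * y))
  }
  d <- gen(200)
  ci_d <- auc_ci(d$s, d$y, method = "delong")
  auc <- attr(ci_d, "auc")
  expect_true(ci_d[1] <= auc && auc <= ci_d[2])
  ci_b <- auc_ci(d$s, d$y, method = "bootstrap", n_boot = 600, seed = 9)
  expect_lt(max(abs(ci_d - ci_b)), 0.05)

  widths <- vapply(1:20, function(sd) {
    set.seed(sd)
    small <- gen(50); big <- gen(500)
    w1 <- diff(as.numeric(auc_ci(small$s, small$y)))
    w2 <- diff(as.numeric(auc_ci(big$s, big$y)))
    w1 - w2
  }, numeric(1))
  expect_gt(mean(widths > 0), 0.9)
})

test_that("the chance test is centred under the null and powered when separable", {
  y <- rep(c(0, 1), each = 10)
  s <- rep(0.3, 20); s[c(1:5, 11:15)] <- 0.7  # AUC exactly 0.5
  expect_equal(roc_auc(s, y)$auc, 0.5)
  expect_equal(significance_vs_chance(s, y)$p_value, 0.5, tolerance = 0.01)

  set.seed(5)
  y2 <- rep(c(0, 1), each = 50)
  s2 <- y2 + rnorm(100, 0, 0.3)
  res <- significance_vs_chance(s2, y2)
  expect_lt(res$p_value, 1e-3)
  # permutation-test oracle
  set.seed(6)
  perm <- replicate(2000, roc_auc(s2, sample(y2))$auc)
  expect_lt(mean(perm >= res$auc), 1e-3)
})

test_that("null p-values are approximately uniform across label permutations", {
  set.seed(7)
  pvals <- replicate(200, {
    y <- rep(c(0, 1), each = 30)
    s <- rnorm(60)
    significance_vs_chance(s, sample(y))$p_value
  })
  # AUC p-values are mildly discrete; ties warning is expected
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})
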