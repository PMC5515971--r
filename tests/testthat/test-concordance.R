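test_that("confusion counts agree with a brute-force tally", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    label <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.6, 0.4))
    call <- sample(c("+", "-"), n, replace = TRUE)
    cm <- confusion_from_pairs(call, label)
    expect_equal(cm$tp, sum(call == "+" & label == "+"))
    expect_equal(cm$fn + cm$tp, sum(label == "+"))
    expect_equal(cm$fp + cm$tn, sum(label == "-"))
    expect_equal(cm$n, n)
  }
})

test_that("confusion requires a label for every called compound", {
  sc <- generate_confusion_scenario(2, 1, 3, 1)
  extra <- sc$calls
  extra$compound[1] <- "not-in-panel"
  expect_error(confusion(extra, sc$compounds), "no DILI label")
})

test_that("perfect and degenerate matrices behave as expected", {
  perfect <- metrics(tibble::tibble(tp = 69, tn = 41, fp = 0, fn = 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$kappa, 1)
  expect_true(is.infinite(perfect$plr))
  expect_equal(perfect$nlr, 0)

  allneg <- confusion_from_pairs(rep("-", 110),
                                 c(rep("+", 69), rep("-", 41)))
  expect_equal(unlist(allneg[c("tp", "tn", "fp", "fn")]),
               c(tp = 0, tn = 41, fp = 0, fn = 69))

  expect_error(metrics(tibble::tibble(tp = 0, tn = 0, fp = 0, fn = 1)),
               "each DILI class")
})

test_that("likelihood ratios follow the sensitivity/specificity formulas", {
  # 50/69 and 30/41 print as 72.5% and 73.2% on a 69+/41- panel
  lr <- likelihood_ratios(50 / 69, 30 / 41)
  expect_equal(round(lr$plr, 2), 2.70)
  expect_equal(round(lr$nlr, 2), 0.38)
  flat <- likelihood_ratios(0.5, 0.5)
  expect_equal(flat$plr, 1)
  expect_equal(flat$nlr, 1)
  perfect <- likelihood_ratios(1, 1)
  expect_true(perfect$plr_infinite)
  expect_equal(perfect$nlr, 0)
})

test_that("kappa agrees with an independent p_o/p_e recomputation", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    label <- sample(c("+", "-"), n, replace = TRUE)
    call <- sample(c("+", "-"), n, replace = TRUE)
    if (length(unique(label)) < 2 || length(unique(call)) < 2) next
    cm <- confusion_from_pairs(call, label)
    k <- cohens_kappa(cm)
    expect_equal(k$kappa, kappa_oracle(call, label), tolerance = 1e-12)
    expect_equal(k$p_o, mean(call == label), tolerance = 1e-12)
  }
})

test_that("kappa null test reproduces published p-values", {
  p1 <- kappa_null_test(tibble::tibble(tp = 13, tn = 38, fp = 3, fn = 56))
  expect_equal(round(p1$p_value, 3), 0.097)
  expect_equal(round(p1$kappa, 3), 0.091)
  p2 <- kappa_null_test(tibble::tibble(tp = 3, tn = 40, fp = 1, fn = 66))
  expect_lt(abs(p2$p_value - 0.61), 0.01)
  expect_equal(round(p2$kappa, 3), 0.014)
})

test_that("kappa of exactly zero gives z = 0 and p = 1", {
  # calls independent of labels by construction: margins 1/2, agreement 1/2
  cm <- tibble::tibble(tp = 25, tn = 25, fp = 25, fn = 25)
  kt <- kappa_null_test(cm)
  expect_equal(kt$kappa, 0)
  expect_equal(kt$z, 0)
  expect_equal(kt$p_value, 1)
})

test_that("degenerate margins flag kappa as undefined", {
  # every compound positive and called positive: p_e = 1
  k <- cohens_kappa(tibble::tibble(tp = 10, tn = 0, fp = 0, fn = 0))
  expect_true(k$degenerate)
  expect_true(is.na(k$kappa))
})

test_that("trapezoidal AUC equals brute-force pairwise concordance", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    label <- c("+", "-", sample(c("+", "-"), n - 2, replace = TRUE))
    score <- round(rlnorm(n, 1, 1), 2)  # rounding forces ties
    for (dir in c("lower-is-positive", "higher-is-positive")) {
      r <- roc(score, label, direction = dir)
      expect_equal(r$auc, auc_bruteforce(score, label, dir),
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC is invariant under monotone transforms and flips with direction", {
  set.seed(4)
  score <- rlnorm(40, 1, 1.2)
  label <- sample(c("+", "-"), 40, replace = TRUE, prob = c(0.6, 0.4))
  a <- roc(score, label, "lower-is-positive")$auc
  expect_equal(roc(log(score), label, "lower-is-positive")$auc, a)
  expect_equal(roc(score^3, label, "lower-is-positive")$auc, a)
  expect_equal(roc(score, label, "higher-is-positive")$auc, 1 - a,
               tolerance = 1e-12)
})

test_that("ROC endpoints, separability, and class requirements hold", {
  score <- c(1, 2, 3, 10, 20, 30)
  label <- c("+", "+", "+", "-", "-", "-")
  r <- roc(score, label, "lower-is-positive")
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_equal(r$auc, 1)
  opt <- optimize_threshold(r)
  expect_equal(opt$distance, 0)
  expect_true(opt$threshold >= 3 && opt$threshold < 10)
  expect_error(roc(score, rep("+", 6)), "each class")
})

test_that("censored scores are removed or treated as never-positive", {
  score <- c(1, NA, 3, 10, NA, 30)
  label <- c("+", "+", "+", "-", "-", "-")
  r_rm <- roc(score, label, "lower-is-positive", censored = "remove")
  expect_equal(r_rm$n_removed, 2L)
  expect_equal(r_rm$n_pos + r_rm$n_neg, 4)
  r_np <- roc(score, label, "lower-is-positive", censored = "never-positive")
  expect_equal(r_np$n_removed, 0L)
  expect_equal(r_np$n_pos + r_np$n_neg, 6)
})

test_that("optimized threshold matches exhaustive search on toy instances", {
  set.seed(123)
  for (i in 1:8) {
    n <- 10
    score <- round(rlnorm(n, 1, 1), 1)
    label <- c("+", "-", sample(c("+", "-"), n - 2, replace = TRUE))
    r <- roc(score, label, "lower-is-positive")
    opt <- optimize_threshold(r)
    bf <- optimal_threshold_bruteforce(score, label, "lower-is-positive")
    expect_equal(opt$distance, unname(bf$distance), tolerance = 1e-12)
    # same calls: the returned threshold sits in the same inter-score gap
    expect_identical(score <= opt$threshold, score <= bf$threshold)
  }
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  score <- rlnorm(60, 0.5, 1)
  label <- sample(c("+", "-"), 60, replace = TRUE)
  ours <- roc(score, label, "higher-is-positive")$auc
  theirs <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(response = label, predictor = score,
              levels = c("-", "+"), direction = "<")
  )))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("cross-validation is deterministic and perfect when separable", {
  score <- c(seq(0.1, 3, length.out = 30), seq(10, 100, length.out = 20))
  label <- c(rep("+", 30), rep("-", 20))
  cv1 <- cross_validated_performance(score, label, "lower-is-positive",
                                     seed = 42)
  cv2 <- cross_validated_performance(score, label, "lower-is-positive",
                                     seed = 42)
  expect_identical(cv1, cv2)
  expect_equal(cv1$cv_sensitivity, 1)
  expect_equal(cv1$cv_specificity, 1)
  expect_error(cross_validated_performance(score, label, "lower-is-positive"),
               "seed")
})

test_that("cross-validated estimates track plug-in estimates on synthetic scores", {
  # generator-known truth: two log-normal score populations
  set.seed(314)
  n_pos <- 120; n_neg <- 80
  score <- c(rlnorm(n_pos, 0.5, 1), rlnorm(n_neg, 2.5, 1))
  label <- c(rep("+", n_pos), rep("-", n_neg))
  r <- roc(score, label, "lower-is-positive")
  opt <- optimize_threshold(r)
  plug_sens <- mean(score[label == "+"] <= opt$threshold)
  plug_spec <- mean(score[label == "-"] > opt$threshold)
  cv <- cross_validated_performance(score, label, "lower-is-positive",
                                    seed = 271)
  mc <- 3 * sqrt(0.25 / min(n_pos, n_neg))  # binomial Monte-Carlo error
  expect_lt(abs(cv$cv_sensitivity - plug_sens), mc)
  expect_lt(abs(cv$cv_specificity - plug_spec), mc)
})

test_that("report formatting matches the published rounding profile", {
  m <- metrics(tibble::tibble(tp = 42, tn = 35, fp = 6, fn = 27))
  f <- format_metrics(m)
  expect_equal(f$sensitivity_pct, "60.9")
  expect_equal(f$specificity_pct, "85.4")
  expect_equal(f$plr, "4.16")
  expect_equal(f$nlr, "0.46")
  expect_equal(f$kappa, "0.419")
  expect_equal(f$p_value, "<0.0001")
})
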