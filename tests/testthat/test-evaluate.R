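test_that("confusion counts partition the sample and validate input", {
  cm <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(2, 1, 0, 0))
  cm2 <- confusion(c(1, 0), c(0, 1))
  expect_equal(c(cm2$tp, cm2$tn), c(0, 0))
  expect_error(confusion(c(1, 0), c(1)), "length",
               class = "adr_validation_error")
  expect_error(confusion(c(1, 2), c(1, 0)), class = "adr_validation_error")

  set.seed(8)
  y <- sample(0:1, 200, TRUE); p <- sample(0:1, 200, TRUE)
  cm3 <- confusion(y, p)
  # direct pairwise counting oracle
  expect_equal(cm3$tp, sum(mapply(function(a, b) a == 1 && b == 1, y, p)))
  expect_equal(cm3$total, 200L)
})

test_that("metrics reproduce the published confusion-table arithmetic", {
  # main-drug test set: tn=93 fp=8 fn=18 tp=54
  m <- metrics(confusion_counts(tp = 54, fp = 8, fn = 18, tn = 93))
  expect_equal(m$accuracy, 147 / 173)
  expect_equal(round(100 * m$accuracy), 85)
  expect_equal(m$recall, 54 / 72)
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 54 / 62)
  expect_equal(round(m$precision, 2), 0.87)
  expect_equal(m$f1, 108 / 134)
  expect_equal(round(m$f1, 2), 0.81)

  # extra-drug test set: tn=42 fp=5 fn=9 tp=15
  m2 <- metrics(confusion_counts(tp = 15, fp = 5, fn = 9, tn = 42))
  expect_equal(m2$accuracy, 57 / 71)
  expect_equal(round(100 * m2$accuracy), 80)
  expect_equal(m2$recall, 15 / 24)

  expect_warning(m3 <- metrics(confusion_counts(tp = 0, fp = 0, fn = 3, tn = 5)),
                 "precision undefined", class = "adr_undefined_metric")
  expect_true(is.na(m3$precision))
})

test_that("roc endpoints, monotonicity, and degenerate cases behave", {
  y <- c(1, 1, 1, 0, 0)
  perfect <- roc(y, c(0.9, 0.8, 0.7, 0.2, 0.1))
  expect_equal(perfect$auc, 1)
  flat <- roc(y, rep(0.5, 5))
  expect_equal(flat$auc, 0.5)
  expect_error(roc(c(1, 1), c(0.2, 0.4)), "single class",
               class = "adr_validation_error")

  set.seed(3)
  y2 <- sample(0:1, 80, TRUE); s2 <- round(runif(80), 2)
  r <- roc(y2, s2)
  expect_equal(unname(unlist(r$points[1, c("fpr", "tpr")])), c(0, 0))
  expect_equal(unname(unlist(r$points[nrow(r$points), c("fpr", "tpr")])), c(1, 1))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("trapezoidal AUC equals the Mann-Whitney rank statistic", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(10:120, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- round(runif(n), sample(c(1, 2, 6), 1))   # heavy ties sometimes
    expect_equal(roc(y, s)$auc, auc_rank_oracle(y, s), tolerance = 1e-9)
  }
})

test_that("the all-negative sweep endpoint accuracy is the negative prevalence", {
  y <- rep(c(0, 1), c(101, 72))
  set.seed(2)
  s <- pmin(runif(173, 0.1, 0.99), 0.99)
  r <- roc(y, s)
  acc_at_1 <- r$accuracy_by_threshold$accuracy[r$accuracy_by_threshold$threshold == 1]
  expect_equal(acc_at_1, 101 / 173)
  expect_equal(round(100 * acc_at_1), 58)
})

test_that("cohens_kappa matches the closed form and known cases", {
  both <- c(rep(1, 30), rep(0, 20))
  expect_equal(cohens_kappa(both, both), 1)

  # hand-computed 2x2 table: both1=40, a-only=10, b-only=5, both0=45
  a <- rep(c(1, 1, 0, 0), c(40, 10, 5, 45))
  b <- rep(c(1, 0, 1, 0), c(40, 10, 5, 45))
  # po=.85; pA1=.5, pB1=.45 -> pe=.5; kappa=(.85-.5)/.5=0.7
  expect_equal(cohens_kappa(a, b), 0.7)
  expect_equal(cohens_kappa(b, a), 0.7)   # rater-swap invariance

  set.seed(123)
  x <- sample(0:1, 10000, TRUE); z <- sample(0:1, 10000, TRUE)
  expect_lt(abs(cohens_kappa(x, z)), 0.1)  # independent raters -> ~0

  expect_error(cohens_kappa(c(1, 0), c(1)), class = "adr_validation_error")
})

test_that("fleiss_kappa handles unanimity and approximates Cohen for 2 raters", {
  unan <- cbind(c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 1))
  expect_equal(fleiss_kappa(unan), 1)
  expect_error(fleiss_kappa(matrix(1, 4, 1)), "2 raters",
               class = "adr_validation_error")

  set.seed(21)
  truth <- sample(0:1, 400, TRUE)
  ann <- make_annotators(truth, agreement = 0.9, seed = 5)
  ck <- cohens_kappa(ann[, 1], ann[, 2])
  fk <- fleiss_kappa(ann)
  expect_lt(abs(ck - fk), 0.05)
})

test_that("evaluate_scores ties the pieces together consistently", {
  set.seed(4)
  y <- sample(0:1, 60, TRUE)
  s <- ifelse(y == 1, runif(60, 0.4, 1), runif(60, 0, 0.6))
  ev <- evaluate_scores(y, s, threshold = 0.5)
  expect_equal(ev$confusion$total, 60L)
  expect_equal(ev$metrics$accuracy,
               mean(classify(s, 0.5) == y))
  expect_equal(ev$auc, auc_rank_oracle(y, s), tolerance = 1e-9)
})
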