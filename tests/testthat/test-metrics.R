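# Summed one-class confusion matrices as printed for the four synthetic
# benchmark classes (rows = predicted, columns = true; tn fp fn tp), with
# the printed mean F1/MCC they must reproduce within 0.02.
printed_cms <- list(
  S1 = list(cm = confusion_matrix(tn = 220, fp = 20, fn = 2, tp = 238),
            f1 = 0.96, mcc = 0.92),
  S2 = list(cm = confusion_matrix(tn = 237, fp = 3, fn = 0, tp = 240),
            f1 = 0.99, mcc = 0.99),
  S3 = list(cm = confusion_matrix(tn = 203, fp = 37, fn = 19, tp = 221),
            f1 = 0.89, mcc = 0.77),
  S4 = list(cm = confusion_matrix(tn = 192, fp = 48, fn = 38, tp = 202),
            f1 = 0.82, mcc = 0.65)
)

test_that("MCC and F1 reproduce the printed benchmark metrics", {
  expect_equal(mcc(confusion_matrix(tn = 10, fp = 0, fn = 0, tp = 10)), 1.0)
  expect_equal(f1(confusion_matrix(tn = 10, fp = 0, fn = 0, tp = 10)), 1.0)
  # two-decimal agreement for the two reference classes
  expect_equal(round(mcc(printed_cms$S2$cm), 2), 0.99)
  expect_equal(round(mcc(printed_cms$S3$cm), 2), 0.77)
  expect_equal(round(f1(printed_cms$S2$cm), 2), 0.99)
  # all four classes agree with the printed means within 0.02
  for (cls in names(printed_cms)) {
    expect_lt(abs(mcc(printed_cms[[cls]]$cm) - printed_cms[[cls]]$mcc), 0.02)
    expect_lt(abs(f1(printed_cms[[cls]]$cm) - printed_cms[[cls]]$f1), 0.02)
  }
})

test_that("F1 agrees with the precision/recall harmonic mean on random CMs", {
  set.seed(91)
  for (i in 1:100) {
    cm <- confusion_matrix(tn = sample(0:50, 1), fp = sample(0:50, 1),
                           fn = sample(0:50, 1), tp = sample(1:50, 1))
    prec <- cm$tp / (cm$tp + cm$fp)
    rec <- cm$tp / (cm$tp + cm$fn)
    expect_equal(f1(cm), 2 * prec * rec / (prec + rec), tolerance = 1e-12)
  }
})

test_that("MCC handles zero marginals and is class-swap symmetric; F1 is not", {
  expect_equal(mcc(confusion_matrix(tn = 0, fp = 0, fn = 5, tp = 5)), 0)
  expect_equal(f1(confusion_matrix(tn = 0, fp = 0, fn = 0, tp = 0)), 0)
  cm <- confusion_matrix(tn = 30, fp = 10, fn = 5, tp = 20)
  swapped <- confusion_matrix(tn = cm$tp, fp = cm$fn, fn = cm$fp, tp = cm$tn)
  expect_equal(mcc(cm), mcc(swapped), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1(cm), f1(swapped))))
})

test_that("Brier Skill Score reference points and brute-force identity", {
  y <- c(0, 0, 0, 1, 1)
  expect_equal(brier_skill_score(y, y), 1.0)              # perfect forecast
  expect_equal(brier_skill_score(rep(mean(y), 5), y), 0)  # base-rate forecast
  # anti-calibrated forecasts are worse than naive
  expect_lt(brier_skill_score(1 - y, y), 0)
  # order invariance and brute-force loop equality
  set.seed(93)
  p <- runif(30); yy <- rbinom(30, 1, 0.3)
  if (sum(yy) %in% c(0, 30)) yy[1:2] <- c(0, 1)
  bs <- 0; for (i in 1:30) bs <- bs + (p[i] - yy[i])^2
  bs <- bs / 30
  base <- mean(yy); bs_naive <- base * (1 - base)
  expect_equal(brier_skill_score(p, yy), 1 - bs / bs_naive, tolerance = 1e-12)
  perm <- sample(30)
  expect_equal(brier_skill_score(p[perm], yy[perm]), brier_skill_score(p, yy))
  expect_error(brier_skill_score(rep(0.5, 4), rep(1, 4)), "single-class")
})

test_that("subject aggregation thresholds and confidence flags", {
  pred <- data.frame(
    subject_id = rep(c("a", "b", "c"), each = 10),
    group = rep("S2", 30),
    outlier_probability = c(rep(1, 10),                  # certain outlier
                            rep(0.37, 10),               # predicted healthy
                            rep(0.55, 10))               # low-confidence outlier
  )
  agg <- aggregate_subject_predictions(pred)
  a <- agg[agg$subject_id == "a", ]
  expect_equal(a$mean_outlier_probability, 1.0)
  expect_identical(a$predicted_class, "outlier")
  expect_false(a$low_confidence)
  b <- agg[agg$subject_id == "b", ]
  expect_identical(b$predicted_class, "healthy")
  c_ <- agg[agg$subject_id == "c", ]
  expect_identical(c_$predicted_class, "outlier")
  expect_true(c_$low_confidence)
  expect_equal(c_$probability_difference, 0.1, tolerance = 1e-12)
})

test_that("report assembly sums CMs and averages metrics across folds", {
  mk_fold <- function(f1v, mccv, bssv) {
    list(cm = confusion_matrix(tn = 8, fp = 2, fn = 1, tp = 9),
         f1 = f1v, mcc = mccv, bss = bssv,
         predictions = data.frame(subject_id = c("x", "y"), group = c("healthy", "S1"),
                                  outlier_probability = c(0.1, 0.9), fold = 1))
  }
  rep3 <- build_report(list(mk_fold(0.8, 0.6, 0.4), mk_fold(0.9, 0.7, 0.5),
                            mk_fold(1.0, 0.8, 0.6)))
  expect_equal(unname(rep3$mean["f1"]), 0.9)
  expect_equal(unname(rep3$mean["mcc"]), 0.7)
  expect_equal(unname(rep3$sd["mcc"]), sd(c(0.6, 0.7, 0.8)))
  expect_equal(rep3$confusion$tn, 24)
  total <- with(rep3$confusion, tn + fp + fn + tp)
  expect_equal(total, 3 * 20)
  # identical folds -> SD zero
  rep_same <- build_report(list(mk_fold(0.8, 0.6, 0.4), mk_fold(0.8, 0.6, 0.4)))
  expect_equal(unname(rep_same$sd), c(0, 0, 0))
})
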