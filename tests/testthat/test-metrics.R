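test_that("confusion counts tally correctly and swap under positive-class exchange", {
  truth <- rep(c("pos", "neg"), each = 5)
  cc <- confusion_counts(truth, truth, "pos")
  expect_equal(c(cc$FP, cc$FN), c(0, 0))
  all_pos <- confusion_counts(rep("pos", 10), truth, "pos")
  expect_equal(unlist(all_pos[c("TP", "FP", "TN", "FN")]),
               c(TP = 5, FP = 5, TN = 0, FN = 0))
  set.seed(4)
  pred <- sample(c("pos", "neg"), 10, replace = TRUE)
  a <- confusion_counts(pred, truth, "pos")
  b <- confusion_counts(pred, truth, "neg")
  expect_equal(c(a$TP, a$FP, a$TN, a$FN), c(b$TN, b$FN, b$TP, b$FP))
  expect_error(confusion_counts(pred[1:3], truth, "pos"), "length")
})

test_that("classification metrics match hand-derived values and conventions", {
  m <- classification_metrics(list(TP = 3, FP = 1, TN = 4, FN = 2), quiet = TRUE)
  expect_equal(unname(m), c(0.7, 0.75, 0.6, 2 * 0.75 * 0.6 / 1.35))
  perfect <- classification_metrics(list(TP = 7, FP = 0, TN = 3, FN = 0), quiet = TRUE)
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  expect_message(z <- classification_metrics(list(TP = 0, FP = 0, TN = 5, FN = 5)),
                 "convention")
  expect_equal(unname(z[c("precision", "f1")]), c(0, 0))
})

test_that("binary AUC equals pair enumeration, including ties and edge cases", {
  expect_equal(auc_binary(c(0.9, 0.4, 0.5, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc_binary(rep(0.3, 8), rep(c(TRUE, FALSE), 4)), 0.5)
  expect_equal(auc_binary(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_error(auc_binary(1:3, c(TRUE, TRUE, TRUE)), "positive and")
  set.seed(10)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(runif(n), 1)   # coarse grid forces ties
    expect_equal(auc_binary(scores, truth), auc_pair_oracle(scores, truth))
  }
})

test_that("AUC is complement-symmetric and invariant to monotone score transforms", {
  set.seed(2)
  truth <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(.4, .6))
  truth[1:2] <- c(TRUE, FALSE)
  scores <- rnorm(40)               # almost surely tie-free
  expect_equal(auc_binary(scores, truth) + auc_binary(-scores, truth), 1)
  expect_equal(auc_binary(exp(scores), truth), auc_binary(scores, truth))
  expect_equal(auc_binary(qlogis(plogis(scores)), truth), auc_binary(scores, truth))
})

test_that("macro one-vs-rest AUC reduces to binary and matches per-class enumeration", {
  set.seed(6)
  truth2 <- sample(c("a", "b"), 30, replace = TRUE)
  truth2[1:2] <- c("a", "b")
  s <- cbind(a = runif(30), b = runif(30))
  expect_equal(auc_macro_ovr(s, truth2),
               mean(c(auc_binary(s[, "a"], truth2 == "a"),
                      auc_binary(s[, "b"], truth2 == "b"))))
  # uninformative identical columns -> 0.5
  same <- cbind(a = rep(1, 30), b = rep(1, 30))
  expect_equal(auc_macro_ovr(same, truth2), 0.5)
  # 3-class seeded case against the brute-force pair oracle
  truth3 <- sample(c("x", "y", "z"), 45, replace = TRUE)
  truth3[1:3] <- c("x", "y", "z")
  s3 <- matrix(round(runif(45 * 3), 1), 45, dimnames = list(NULL, c("x", "y", "z")))
  oracle <- mean(vapply(c("x", "y", "z"),
                        function(cl) auc_pair_oracle(s3[, cl], truth3 == cl), numeric(1)))
  expect_equal(auc_macro_ovr(s3, truth3), oracle)
  # absent class excluded with a warning
  s4 <- cbind(s3, w = runif(45))
  expect_warning(v <- auc_macro_ovr(s4, truth3), "absent")
  expect_equal(v, oracle)  # mean over the three present classes only
})

test_that("metrics_report assembles per-class counts and headline metrics coherently", {
  set.seed(12)
  truth <- sample(c("benign", "malignant"), 50, replace = TRUE)
  scores <- cbind(benign = runif(50), malignant = runif(50))
  rep <- metrics_report(scores, truth)
  expect_identical(rep$averaging, "binary")
  pred <- colnames(scores)[max.col(scores, ties.method = "first")]
  expect_equal(rep$accuracy, mean(pred == truth))
  expect_equal(rep$auc, auc_binary(scores[, "malignant"], truth, "malignant"))
  expect_true(all(unlist(rep[c("accuracy", "precision", "recall", "f1", "auc")]) >= 0))
  # macro path
  truth3 <- sample(c("x", "y", "z"), 60, replace = TRUE)
  s3 <- matrix(runif(180), 60, dimnames = list(NULL, c("x", "y", "z")))
  rep3 <- metrics_report(s3, truth3)
  expect_identical(rep3$averaging, "macro")
  expect_equal(rep3$precision, mean(rep3$per_class$precision))
  expect_equal(nrow(rep3$per_class), 3)
})
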