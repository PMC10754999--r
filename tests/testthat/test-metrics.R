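test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unname(cm$counts), rbind(c(1L, 1L), c(0L, 1L)))
  # perfect predictions: diagonal
  y <- rep(c("AS", "RA", "OA", "HC"), each = 2)
  cmp <- confusion_matrix(y, y, c("AS", "RA", "OA", "HC"))
  expect_equal(sum(diag(cmp$counts)), 8L)
  expect_equal(sum(cmp$counts) - sum(diag(cmp$counts)), 0L)
  # degenerate predictor: one nonzero column
  cm1 <- confusion_matrix(y, rep("AS", 8), c("AS", "RA", "OA", "HC"))
  expect_equal(sum(cm1$counts[, 1]), 8L)
  expect_equal(sum(cm1$counts[, -1]), 0L)
  expect_error(confusion_matrix("A", "Z", class_order = c("A", "B")),
               class = "spectranet_label_error")
})

test_that("per-class accuracy is recall at table precision", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unname(per_class_accuracy(cm)), c(0.5, 1.0))
  # 19 of 27 correct prints as 0.7037 at 4 dp
  expect_equal(round(19 / 27, 4), 0.7037)
  counts <- rbind(c(19L, 8L), c(0L, 10L))
  dimnames(counts) <- list(true = c("AS", "x"), predicted = c("AS", "x"))
  cm2 <- structure(list(counts = counts, class_names = c("AS", "x")),
                   class = "confusion_matrix")
  expect_equal(round(per_class_accuracy(cm2)[["AS"]], 4), 0.7037)
})

test_that("macro averaging is the plain mean", {
  expect_equal(macro_average(c(0.5)), 0.5)
  expect_equal(macro_average(c(0, 1)), 0.5)
  expect_error(macro_average(numeric(0)), class = "spectranet_data_error")
})

test_that("macro report scalars derive consistently from one matrix", {
  set.seed(14)
  for (rep in 1:20) {
    cm <- random_balanced_cm()
    r <- macro_report(cm)
    # sensitivity is exactly the mean of per-class recalls
    expect_identical(r$sensitivity, mean(r$per_class_accuracy))
    # accuracy from recalls weighted by row sums equals trace/total
    rs <- rowSums(cm$counts)
    expect_equal(sum(r$per_class_accuracy * rs) / sum(rs), r$accuracy,
                 tolerance = 1e-12)
    # balanced 4-class identity: macro specificity = 1 - (1-acc)/3
    expect_equal(r$specificity, 1 - (1 - r$accuracy) / 3, tolerance = 1e-12)
    expect_true(all(c(r$accuracy, r$sensitivity, r$precision, r$specificity) >= 0))
    expect_true(all(c(r$accuracy, r$sensitivity, r$precision, r$specificity) <= 1))
  }
  # diagonal matrix: every scalar is 1
  y <- rep(letters[1:4], 3)
  rd <- macro_report(confusion_matrix(y, y, letters[1:4]))
  expect_equal(unname(c(rd$accuracy, rd$sensitivity, rd$precision, rd$specificity)),
               rep(1, 4))
})

test_that("a never-predicted class contributes zero precision with a warning", {
  cm <- confusion_matrix(c("A", "B", "B"), c("A", "A", "A"), c("A", "B"))
  expect_warning(r <- macro_report(cm), "never-predicted")
  expect_equal(r$precision, mean(c(1 / 3, 0)))
})

test_that("tidy/glance views of reports agree with the list fields", {
  cm <- confusion_matrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                         c("A", "B"))
  r <- macro_report(cm)
  td <- tidy(r)
  expect_equal(td$accuracy, unname(r$per_class_accuracy))
  expect_equal(glance(r)$sensitivity, r$sensitivity)
  ct <- tidy(cm)
  expect_equal(sum(ct$n), 4L)
})

test_that("trapezoidal AUC equals brute-force concordance with ties", {
  set.seed(15)
  for (rep in 1:30) {
    n <- sample(6:50, 1)
    k <- sample(2:4, 1)
    digits <- sample(c(1, 2, 6), 1) # low precision forces ties
    scores <- matrix(round(runif(n * k), digits), n, k)
    labels <- sample(LETTERS[1:k], n, replace = TRUE)
    if (length(unique(labels)) < k) next
    r <- roc_auc_ovr(scores, labels, LETTERS[1:k])
    for (j in seq_len(k)) {
      expect_equal(r$auc$auc[j], brute_force_auc(scores[, j], labels == LETTERS[j]),
                   tolerance = 1e-12)
    }
    expect_equal(r$macro_auc, mean(r$auc$auc), tolerance = 1e-12)
  }
})

test_that("AUC reaches the degenerate endpoints", {
  scores <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.1, 0.9))
  labels <- c("A", "A", "B", "B")
  r <- roc_auc_ovr(scores, labels, c("A", "B"))
  expect_equal(r$macro_auc, 1.0)
  const <- matrix(0.5, 4, 2)
  r2 <- roc_auc_ovr(const, labels, c("A", "B"))
  expect_equal(r2$auc$auc, c(0.5, 0.5))
  # class with no positives is excluded with a warning
  expect_warning(r3 <- roc_auc_ovr(scores, c("A", "A", "A", "A"), c("A", "B")),
                 "undefined")
  expect_true(is.na(r3$auc$auc[2]))
})

test_that("AUC matches pROC with a fixed comparison direction", {
  skip_if_not_installed("pROC")
  set.seed(16)
  scores <- matrix(runif(60), 20, 3)
  labels <- sample(c("x", "y", "z"), 20, replace = TRUE)
  ours <- roc_auc_ovr(scores, labels, c("x", "y", "z"))
  for (j in 1:3) {
    ref <- as.numeric(pROC::auc(pROC::roc(
      labels == c("x", "y", "z")[j], scores[, j],
      quiet = TRUE, direction = "<", levels = c(FALSE, TRUE)
    )))
    expect_equal(ours$auc$auc[j], ref, tolerance = 1e-12)
  }
})

test_that("chi-square has the documented invariances", {
  # homogeneous table: zero statistic
  r0 <- chi_square_contingency(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # perfectly separated 2x2 with margins 10: expected all 5, X^2 = 20
  r1 <- chi_square_contingency(rbind(c(10, 0), c(0, 10)))
  expect_equal(r1$statistic, 20)
  expect_equal(r1$dof, 1L)
  # row permutation invariance
  set.seed(17)
  tab <- matrix(rpois(8, 30) + 1, 4, 2)
  expect_equal(chi_square_contingency(tab)$statistic,
               chi_square_contingency(tab[c(3, 1, 4, 2), ])$statistic)
  # uniform count scaling multiplies the statistic
  expect_equal(chi_square_contingency(tab * 3)$statistic,
               3 * chi_square_contingency(tab)$statistic, tolerance = 1e-9)
  expect_error(chi_square_contingency(rbind(c(0, 0), c(1, 2))),
               class = "spectranet_data_error")
})

test_that("summary-statistic ANOVA reproduces the raw-data F", {
  set.seed(18)
  g <- rep(1:3, times = c(12, 15, 9))
  x <- rnorm(length(g), mean = c(0, 0.5, 1)[g])
  means <- tapply(x, g, mean); sds <- tapply(x, g, sd); ns <- tapply(x, g, length)
  ours <- anova_from_summary(means, sds, ns)
  ref <- anova(lm(x ~ factor(g)))
  expect_equal(ours$f_statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  # equal means: F = 0
  expect_equal(anova_from_summary(c(1, 1), c(2, 3), c(10, 10))$f_statistic, 0)
  # two groups: F equals the square of the pooled-variance t statistic
  t2 <- t.test(x[g == 1], x[g == 2], var.equal = TRUE)$statistic^2
  ours2 <- anova_from_summary(means[1:2], sds[1:2], ns[1:2])
  expect_equal(ours2$f_statistic, unname(t2), tolerance = 1e-10)
})

test_that("cohort summaries tabulate age and sex per group with tests", {
  set.seed(19)
  demo <- tibble::tibble(
    group = rep(c("AS", "RA", "OA", "HC"), each = 40),
    age = round(rnorm(160, 40, 6)),
    sex = sample(c("female", "male"), 160, replace = TRUE)
  )
  cs <- cohort_summary(demo, group_order = c("AS", "RA", "OA", "HC"))
  expect_equal(cs$table$n, rep(40L, 4))
  expect_equal(cs$table$female + cs$table$male, cs$table$n)
  expect_equal(cs$table$group, factor(c("AS", "RA", "OA", "HC"),
                                      levels = c("AS", "RA", "OA", "HC")))
  direct <- chi_square_contingency(as.matrix(cs$table[, c("female", "male")]))
  expect_equal(cs$gender_test$statistic, direct$statistic)
  expect_true(cs$age_test$f_statistic >= 0)
})
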