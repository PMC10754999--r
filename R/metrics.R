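#' Confusion matrix
#'
#' Class-by-class count table with rows = true class and columns = predicted
#' class, in a fixed class order (serum reports conventionally use
#' AS, RA, OA, HC).
#'
#' @param true,predicted Equal-length label vectors; every label must be in
#'   `class_order`.
#' @param class_order Character vector fixing row/column order; defaults to
#'   the union of factor levels.
#' @return A `confusion_matrix`: list with the integer `counts` matrix and
#'   `class_names`.
#' @export
confusion_matrix <- function(true, predicted, class_order = NULL) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (length(true) != length(predicted)) {
    rlang::abort("true and predicted must have equal length",
                 class = "spectranet_data_error")
  }
  if (is.null(class_order)) class_order <- sort(unique(c(true, predicted)))
  unknown <- setdiff(unique(c(true, predicted)), class_order)
  if (length(unknown) > 0) {
    rlang::abort(paste0("label(s) outside class order: ",
                        paste(unknown, collapse = ", ")),
                 class = "spectranet_label_error")
  }
  counts <- table(factor(true, levels = class_order),
                  factor(predicted, levels = class_order))
  counts <- matrix(as.integer(counts), nrow = length(class_order),
                   dimnames = list(true = class_order, predicted = class_order))
  structure(list(counts = counts, class_names = class_order),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = true, columns = predicted\n")
  print(x$counts)
  invisible(x)
}

#' Per-class accuracy (recall)
#'
#' The per-class accuracies reported in model comparison tables are
#' recalls: the diagonal count divided by the row sum (true members of the
#' class in the test set).
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector, one recall per class.
#' @export
per_class_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rs <- rowSums(cm$counts)
  if (any(rs == 0)) {
    rlang::abort(paste0("class(es) with no true samples: ",
                        paste(cm$class_names[rs == 0], collapse = ", ")),
                 class = "spectranet_data_error")
  }
  stats::setNames(diag(cm$counts) / rs, cm$class_names)
}

#' Macro average
#'
#' Unweighted arithmetic mean of a per-class metric — the "Average
#' accuracy" column of the model comparison table.
#'
#' @param values Non-empty numeric vector.
#' @return The mean.
#' @export
macro_average <- function(values) {
  if (length(values) == 0) {
    rlang::abort("cannot average an empty vector", class = "spectranet_data_error")
  }
  mean(values)
}

#' Scalar evaluation metrics from a confusion matrix
#'
#' All four headline scalars derive from one confusion matrix:
#'
#' * accuracy — micro: trace / total;
#' * sensitivity — macro recall, the unweighted mean of per-class
#'   accuracies (this reading is pinned by the reported overall sensitivity
#'   equalling the mean of the per-class accuracies of the best model);
#' * precision — macro: mean over classes of diagonal / column sum, where a
#'   never-predicted class contributes 0 (with a warning);
#' * specificity — macro one-vs-rest: mean over classes of TN / (TN + FP).
#'   For k equal-sized classes this equals `1 - (1 - accuracy)/(k - 1)`
#'   exactly, which is how the reported specificity follows from the
#'   reported accuracy under near-balanced test classes.
#'
#' @param cm A [confusion_matrix()].
#' @return A `metrics_report`: list with `accuracy`, `sensitivity`,
#'   `precision`, `specificity`, the `per_class_accuracy` vector and the
#'   confusion matrix.
#' @export
macro_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  total <- sum(counts)
  if (total == 0) {
    rlang::abort("empty confusion matrix", class = "spectranet_data_error")
  }
  pca <- per_class_accuracy(cm)
  cs <- colSums(counts)
  prec <- ifelse(cs > 0, diag(counts) / ifelse(cs > 0, cs, 1), 0)
  if (any(cs == 0)) {
    rlang::warn(paste0("never-predicted class(es) contribute precision 0: ",
                       paste(cm$class_names[cs == 0], collapse = ", ")))
  }
  spec <- vapply(seq_along(cm$class_names), function(k) {
    tp <- counts[k, k]
    fp <- cs[k] - tp
    fn <- sum(counts[k, ]) - tp
    tn <- total - tp - fp - fn
    tn / (tn + fp)
  }, numeric(1))
  structure(
    list(accuracy = sum(diag(counts)) / total,
         sensitivity = macro_average(pca),
         precision = macro_average(prec),
         specificity = macro_average(spec),
         per_class_accuracy = pca,
         confusion = cm),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f, sensitivity %.4f, precision %.4f, specificity %.4f\n",
              x$accuracy, x$sensitivity, x$precision, x$specificity))
  cat("per-class accuracy:",
      paste(sprintf("%s %.4f", names(x$per_class_accuracy), x$per_class_accuracy),
            collapse = ", "), "\n")
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' Per class, the ROC of that class's score column against the one-vs-rest
#' labels; AUC by trapezoidal integration over the empirical curve (which
#' equals the tie-corrected pairwise concordance probability). The macro
#' AUC is the unweighted mean over classes; the micro AUC pools all
#' one-vs-rest decisions and is reported alongside, clearly labelled. A
#' class with no positives or no negatives has undefined AUC and is
#' excluded from the macro mean with a warning.
#'
#' @param scores Numeric matrix, samples x classes (probabilities or
#'   arbitrary scores).
#' @param true Vector of true labels matching `class_order`.
#' @param class_order Optional class order; defaults to column names of
#'   `scores` or the sorted unique labels.
#' @return A `roc_result`: list with `auc` (tibble: class, auc), `macro_auc`,
#'   `micro_auc`, and `curves` (tibble: class, threshold, fpr, tpr).
#' @export
roc_auc_ovr <- function(scores, true, class_order = NULL) {
  scores <- as.matrix(scores)
  true <- as.character(true)
  if (is.null(class_order)) {
    class_order <- colnames(scores) %||% sort(unique(true))
  }
  if (ncol(scores) != length(class_order)) {
    rlang::abort("scores must have one column per class",
                 class = "spectranet_data_error")
  }
  per_class <- purrr::map(seq_along(class_order), function(k) {
    pos <- true == class_order[k]
    if (!any(pos) || all(pos)) {
      return(list(auc = NA_real_,
                  curve = tibble::tibble(class = class_order[k],
                                         threshold = numeric(0),
                                         fpr = numeric(0), tpr = numeric(0))))
    }
    roc_curve_binary(scores[, k], pos, class_order[k])
  })
  aucs <- vapply(per_class, function(p) p$auc, numeric(1))
  if (anyNA(aucs)) {
    rlang::warn(paste0("AUC undefined (no positives or no negatives) for: ",
                       paste(class_order[is.na(aucs)], collapse = ", ")))
  }
  micro <- roc_curve_binary(
    as.vector(scores),
    as.vector(vapply(class_order, function(cl) true == cl,
                     logical(length(true)))),
    ".micro"
  )
  structure(
    list(auc = tibble::tibble(class = class_order, auc = aucs),
         macro_auc = mean(aucs, na.rm = TRUE),
         micro_auc = micro$auc,
         curves = dplyr::bind_rows(purrr::map(per_class, "curve"))),
    class = "roc_result"
  )
}

# Empirical ROC for one binary problem. Thresholds sweep the distinct score
# values from +Inf down; ties are grouped, so the trapezoid over the curve
# equals concordance with ties counted 1/2.
roc_curve_binary <- function(score, positive, class_name) {
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  p <- positive[o]
  grp_last <- c(s[-1] != s[-length(s)], TRUE)
  tps <- cumsum(p)[grp_last]
  fps <- cumsum(!p)[grp_last]
  P <- sum(p)
  N <- sum(!p)
  tpr <- c(0, tps / P)
  fpr <- c(0, fps / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc,
       curve = tibble::tibble(class = class_name,
                              threshold = c(Inf, s[grp_last]),
                              fpr = fpr, tpr = tpr))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> macro AUC %.4f (micro %.4f)\n",
              x$macro_auc, x$micro_auc))
  print(x$auc)
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Homogeneity test for cohort composition (e.g. the gender-by-group
#' table): Pearson X^2 with `(r-1)(c-1)` degrees of freedom and no
#' continuity correction, via [stats::chisq.test()]. All expected counts
#' must be positive.
#'
#' @param counts Integer matrix (r x c).
#' @return A tibble with `statistic`, `dof`, `p_value`.
#' @export
chi_square_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    rlang::abort("zero row/column margin: expected counts undefined",
                 class = "spectranet_data_error")
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  tibble::tibble(statistic = unname(ct$statistic),
                 dof = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the F statistic from per-group means, SDs and sizes:
#' between-group mean square from the group means about the grand mean,
#' within-group mean square from the pooled variances. For two groups F is
#' the square of the pooled-variance t statistic.
#'
#' @param means,sds,ns Equal-length numeric vectors (>= 2 groups, all
#'   `ns >= 2`).
#' @return A tibble with `f_statistic`, `df_between`, `df_within`, `p_value`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k || any(ns < 2)) {
    rlang::abort("need >= 2 groups with n >= 2 and matching summary vectors",
                 class = "spectranet_data_error")
  }
  n_tot <- sum(ns)
  grand <- sum(ns * means) / n_tot
  ms_between <- sum(ns * (means - grand)^2) / (k - 1)
  ms_within <- sum((ns - 1) * sds^2) / (n_tot - k)
  if (ms_within == 0) {
    rlang::abort("zero within-group variance in all groups: F is infinite",
                 class = "spectranet_numeric_error")
  }
  f <- ms_between / ms_within
  tibble::tibble(f_statistic = f, df_between = k - 1, df_within = n_tot - k,
                 p_value = stats::pf(f, k - 1, n_tot - k, lower.tail = FALSE))
}

#' Cohort summary table
#'
#' Demographic summary in the style of a clinical Table 1: per-group age
#' mean +/- SD and female/male counts, with a one-way ANOVA on age
#' (reconstructed from the group summaries) and a Pearson chi-square test
#' on the gender-by-group table.
#'
#' @param demographics A data frame with columns `group`, `age` and `sex`
#'   (`"female"`/`"male"`).
#' @param group_order Optional explicit group order.
#' @return A list with `table` (tibble: group, n, age_mean, age_sd, female,
#'   male), `age_test` and `gender_test` tibbles.
#' @export
cohort_summary <- function(demographics, group_order = NULL) {
  need <- c("group", "age", "sex")
  if (!all(need %in% names(demographics))) {
    rlang::abort("demographics needs columns group, age, sex",
                 class = "spectranet_data_error")
  }
  if (is.null(group_order)) group_order <- unique(as.character(demographics$group))
  d <- demographics |>
    dplyr::mutate(group = factor(.data$group, levels = group_order))
  tab <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     age_mean = mean(.data$age),
                     age_sd = stats::sd(.data$age),
                     female = sum(.data$sex == "female"),
                     male = sum(.data$sex == "male"),
                     .groups = "drop")
  gender <- as.matrix(tab[, c("female", "male")])
  rownames(gender) <- as.character(tab$group)
  list(table = tab,
       age_test = anova_from_summary(tab$age_mean, tab$age_sd, tab$n),
       gender_test = chi_square_contingency(gender))
}

#' Model comparison table
#'
#' One row per model with per-class accuracy, the macro average, the four
#' headline scalars and macro AUC, with the best value per numeric column
#' flagged.
#'
#' @param experiment A `spectranet_experiment` from [run_experiment()].
#' @return A tibble, one row per model; the `best` column lists the metrics
#'   on which that model is best.
#' @export
benchmark_table <- function(experiment) {
  stopifnot(inherits(experiment, "spectranet_experiment"))
  lev <- experiment$class_levels
  rows <- purrr::map_dfr(experiment$models, function(res) {
    rep <- macro_report(res$confusion)
    roc <- roc_auc_ovr(as.matrix(res$test[, lev]), res$test$true, lev)
    out <- tibble::tibble(model = res$model)
    for (cl in lev) out[[cl]] <- unname(rep$per_class_accuracy[cl])
    out$average_accuracy <- macro_average(rep$per_class_accuracy)
    out$accuracy <- rep$accuracy
    out$sensitivity <- rep$sensitivity
    out$precision <- rep$precision
    out$specificity <- rep$specificity
    out$macro_auc <- roc$macro_auc
    out
  })
  num_cols <- setdiff(names(rows), "model")
  rows$best <- vapply(seq_len(nrow(rows)), function(i) {
    paste(num_cols[vapply(num_cols, function(cl) {
      rows[[cl]][i] == max(rows[[cl]]) }, logical(1))], collapse = ",")
  }, character(1))
  rows
}
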