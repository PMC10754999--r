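#' Training configuration
#'
#' The experimental protocol settings: 7:3 train/test split, five-fold
#' cross-validation within the training set, Adam with learning rate 1e-4,
#' batch size 8. Epochs default to 200; no early stopping, learning-rate
#' schedule or weight decay is applied, and the final-epoch weights are the
#' reported model. The split is simple random by default; stratified
#' splitting is available.
#'
#' @param batch_size Mini-batch size (default 8).
#' @param epochs Training epochs (default 200).
#' @param optimizer Only `"adam"` is implemented.
#' @param learning_rate Adam step size (default 1e-4).
#' @param split_ratio Fraction of samples in the training set (default 0.7).
#' @param n_folds Cross-validation folds (default 5).
#' @param stratified_split Preserve per-class proportions to within one
#'   sample (default `FALSE`).
#' @param seed Integer seed driving the split, fold assignment, weight
#'   initialisation, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 8L, epochs = 200L,
                         optimizer = "adam", learning_rate = 1e-4,
                         split_ratio = 0.7, n_folds = 5L,
                         stratified_split = FALSE, seed = 1L) {
  optimizer <- rlang::arg_match(optimizer, "adam")
  if (split_ratio <= 0 || split_ratio >= 1) {
    rlang::abort("split_ratio must be in (0, 1)", class = "spectranet_config_error")
  }
  if (n_folds < 2) {
    rlang::abort("n_folds must be at least 2", class = "spectranet_config_error")
  }
  if (learning_rate <= 0) {
    rlang::abort("learning_rate must be positive", class = "spectranet_config_error")
  }
  structure(
    list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         optimizer = optimizer, learning_rate = learning_rate,
         split_ratio = split_ratio, n_folds = as.integer(n_folds),
         stratified_split = isTRUE(stratified_split), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Split samples into training and test sets
#'
#' Draws `round(split_ratio * N)` training samples, deterministically given
#' the config seed. With `stratified_split = TRUE` per-class proportions are
#' preserved to within one sample; otherwise the split is simple random. A
#' class entirely absent from the training set is an error.
#'
#' @param ds A [spectra_tbl()] with one row per sample (average replicates
#'   first).
#' @param cfg A [train_config()].
#' @return A list with `train_ids` and `test_ids` (disjoint character
#'   vectors covering all samples).
#' @export
split_train_test <- function(ds, cfg) {
  stopifnot(inherits(ds, "spectra_tbl"), inherits(cfg, "train_config"))
  ids <- ds$sample_id
  labs <- as.character(ds$class_label)
  n <- length(ids)
  if (n < length(class_names(ds))) {
    rlang::abort("need at least one sample per class", class = "spectranet_data_error")
  }
  n_train <- round(cfg$split_ratio * n)
  train_ids <- with_local_seed(cfg$seed, {
    if (cfg$stratified_split) {
      by_class <- split(ids, factor(labs, levels = class_names(ds)))
      sizes <- vapply(by_class, length, integer(1))
      base <- floor(cfg$split_ratio * sizes)
      rem <- cfg$split_ratio * sizes - base
      deficit <- n_train - sum(base)
      if (deficit > 0) {
        bump <- order(rem, decreasing = TRUE)[seq_len(deficit)]
        base[bump] <- base[bump] + 1L
      }
      unlist(lapply(seq_along(by_class), function(i) {
        sample(by_class[[i]], base[i])
      }), use.names = FALSE)
    } else {
      sample(ids, n_train)
    }
  })
  test_ids <- setdiff(ids, train_ids)
  missing_cl <- setdiff(class_names(ds), labs[ids %in% train_ids])
  if (length(missing_cl) > 0) {
    rlang::abort(paste0("class(es) absent from the training set: ",
                        paste(missing_cl, collapse = ", ")),
                 class = "spectranet_split_error")
  }
  list(train_ids = train_ids, test_ids = test_ids)
}

#' Cross-validation folds
#'
#' Partitions the training ids into `n_folds` validation sets whose sizes
#' differ by at most one, deterministically given the seed. Each element
#' pairs the complementary fit ids with its validation ids.
#'
#' @param train_ids Character vector of training sample ids.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return List of `n_folds` lists with `fit_ids` and `val_ids`.
#' @export
make_folds <- function(train_ids, n_folds, seed) {
  n <- length(train_ids)
  if (n_folds > n) {
    rlang::abort("more folds than training samples",
                 class = "spectranet_config_error")
  }
  shuffled <- with_local_seed(seed, sample(train_ids))
  base <- n %/% n_folds
  extra <- n %% n_folds
  sizes <- rep(base, n_folds) + (seq_len(n_folds) <= extra)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(n_folds), function(f) {
    val <- shuffled[starts[f]:ends[f]]
    list(fold = f, fit_ids = setdiff(shuffled, val), val_ids = val)
  })
}

spectra_to_xy <- function(ds) {
  list(x = absorbance_matrix(ds),
       y = factor(as.character(ds$class_label), levels = class_names(ds)))
}

onehot <- function(y, k) {
  m <- matrix(0, length(y), k)
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

#' Train a network
#'
#' Minimises categorical cross-entropy with Adam at the configured learning
#' rate and batch size for the configured number of epochs (final-epoch
#' weights are returned; there is no early stopping). All randomness —
#' weight initialisation, shuffling, dropout — derives from `cfg$seed`, so
#' the same seed reproduces the same fit.
#'
#' @param graph A `layer_graph` whose `input_length` matches `ncol(x_fit)`.
#' @param x_fit Numeric matrix, samples x points.
#' @param y_fit Factor (or vector coercible to factor) of class labels.
#' @param x_val,y_val Optional validation data scored once per epoch.
#' @param cfg A [train_config()].
#' @return A `spectranet_fit`: the graph, fitted parameters, the per-epoch
#'   trace and the class levels.
#' @export
train_model <- function(graph, x_fit, y_fit, x_val = NULL, y_val = NULL, cfg) {
  stopifnot(inherits(graph, "layer_graph"), inherits(cfg, "train_config"))
  x_fit <- as.matrix(x_fit)
  if (ncol(x_fit) != graph$input_length) {
    rlang::abort(sprintf("graph expects input length %d but data has %d points",
                         graph$input_length, ncol(x_fit)),
                 class = "spectranet_shape_error")
  }
  y_fit <- if (is.factor(y_fit)) y_fit else factor(y_fit)
  lev <- levels(y_fit)
  if (length(lev) != graph$n_classes) {
    rlang::abort("number of classes does not match the graph output",
                 class = "spectranet_shape_error")
  }
  Y <- onehot(y_fit, graph$n_classes)
  n <- nrow(x_fit)
  params <- nn_init_params(graph, seed = cfg$seed)
  state <- adam_init(params)
  trace <- vector("list", cfg$epochs)
  t_step <- 0L
  params <- with_local_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      ep_correct <- 0L
      for (s in starts) {
        rows <- perm[s:min(s + cfg$batch_size - 1L, n)]
        fwd <- nn_forward(graph, params, x_fit[rows, , drop = FALSE],
                          training = TRUE)
        probs <- fwd$acts[[length(graph$nodes)]]
        loss <- xent_loss(probs, Y[rows, , drop = FALSE])
        if (!is.finite(loss)) {
          rlang::abort(sprintf("non-finite loss at epoch %d", ep),
                       class = "spectranet_numeric_error")
        }
        ep_loss <- ep_loss + loss * length(rows)
        ep_correct <- ep_correct +
          sum(max.col(probs, ties.method = "first") == as.integer(y_fit[rows]))
        grads <- nn_backward(graph, params, fwd, Y[rows, , drop = FALSE])
        params <- apply_running_updates(params, fwd$running_updates)
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, state, cfg$learning_rate, t_step)
        params <- upd$params
        state <- upd$state
      }
      val_acc <- NA_real_
      if (!is.null(x_val)) {
        vp <- nn_predict_probs(graph, params, as.matrix(x_val))
        val_acc <- mean(max.col(vp, ties.method = "first") ==
                          as.integer(factor(as.character(y_val), levels = lev)))
      }
      trace[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / n,
                                    train_accuracy = ep_correct / n,
                                    val_accuracy = val_acc)
    }
    # final batch-norm calibration: exact pooled statistics over the fit
    # data replace the exponential running average before inference
    calibrate_bn(graph, params, x_fit, cfg$batch_size)
  })
  structure(
    list(graph = graph, params = params, class_levels = lev,
         trace = dplyr::bind_rows(trace), config = cfg),
    class = "spectranet_fit"
  )
}

nn_predict_probs <- function(graph, params, x, batch = 64L) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, graph$n_classes)
  for (s in seq(1L, n, by = batch)) {
    rows <- s:min(s + batch - 1L, n)
    fwd <- nn_forward(graph, params, x[rows, , drop = FALSE], training = FALSE)
    out[rows, ] <- fwd$acts[[length(graph$nodes)]]
  }
  out
}

#' @export
print.spectranet_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("<spectranet_fit> %s, %d epochs; final loss %.4f, train accuracy %.3f\n",
              x$graph$name, nrow(x$trace), last$loss, last$train_accuracy))
  invisible(x)
}

#' Predict from a fitted network
#'
#' @param object A `spectranet_fit`.
#' @param newdata A [spectra_tbl()] or a numeric matrix (samples x points).
#' @param type `"prob"` for the samples x classes probability matrix as a
#'   tibble, `"class"` for a factor of predicted labels.
#' @param ... Unused.
#' @return A tibble of class probabilities or a factor.
#' @export
predict.spectranet_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- rlang::arg_match(type)
  x <- if (inherits(newdata, "spectra_tbl")) absorbance_matrix(newdata)
       else as.matrix(newdata)
  probs <- nn_predict_probs(object$graph, object$params, x)
  colnames(probs) <- object$class_levels
  if (type == "class") {
    factor(object$class_levels[max.col(probs, ties.method = "first")],
           levels = object$class_levels)
  } else {
    tibble::as_tibble(probs)
  }
}

#' Run the full comparison experiment
#'
#' Averages replicates if present, draws the train/test split, and for each
#' requested architecture runs k-fold cross-validation inside the training
#' set (validation confusion matrix per fold), retrains on the full
#' training set, and scores the untouched test set once. Fit, validation
#' and test id sets are asserted mutually disjoint in every fold.
#'
#' @param ds A [spectra_tbl()].
#' @param models Character vector of architecture names
#'   (see [build_model()]).
#' @param cfg A [train_config()].
#' @param run_cv Set `FALSE` to skip cross-validation and only train/test.
#' @return A `spectranet_experiment`: per-model results (fold metrics, test
#'   confusion matrix, test probability table) plus the split.
#' @export
run_experiment <- function(ds, models = c("alexnet1d", "resnet1d", "mscnn", "msresnet"),
                           cfg = train_config(), run_cv = TRUE) {
  stopifnot(inherits(ds, "spectra_tbl"))
  if (any(duplicated(ds$sample_id))) ds <- average_replicates(ds)
  split <- split_train_test(ds, cfg)
  xy <- spectra_to_xy(ds)
  idx <- stats::setNames(seq_len(nrow(ds)), ds$sample_id)
  lev <- class_names(ds)
  train_idx <- idx[split$train_ids]
  test_idx <- idx[split$test_ids]
  stopifnot(length(intersect(split$train_ids, split$test_ids)) == 0)
  folds <- if (run_cv) make_folds(split$train_ids, cfg$n_folds, cfg$seed) else list()

  results <- purrr::map(models, function(mname) {
    graph <- build_model(mname, input_length = ncol(xy$x), n_classes = length(lev))
    fold_results <- purrr::map(folds, function(fd) {
      stopifnot(length(intersect(fd$fit_ids, fd$val_ids)) == 0,
                length(intersect(fd$val_ids, split$test_ids)) == 0,
                length(intersect(fd$fit_ids, split$test_ids)) == 0)
      fit <- train_model(graph, xy$x[idx[fd$fit_ids], , drop = FALSE],
                         xy$y[idx[fd$fit_ids]], cfg = cfg)
      pred <- predict(fit, xy$x[idx[fd$val_ids], , drop = FALSE], type = "class")
      cm <- confusion_matrix(xy$y[idx[fd$val_ids]], pred, class_order = lev)
      list(fold = fd$fold, confusion = cm,
           val_accuracy = sum(diag(cm$counts)) / sum(cm$counts),
           trace = fit$trace)
    })
    final <- train_model(graph, xy$x[train_idx, , drop = FALSE],
                         xy$y[train_idx], cfg = cfg)
    probs <- predict(final, xy$x[test_idx, , drop = FALSE], type = "prob")
    pred <- factor(lev[max.col(as.matrix(probs), ties.method = "first")],
                   levels = lev)
    cm <- confusion_matrix(xy$y[test_idx], pred, class_order = lev)
    test_tbl <- dplyr::bind_cols(
      tibble::tibble(sample_id = split$test_ids,
                     true = xy$y[test_idx], predicted = pred),
      probs
    )
    list(model = mname, folds = fold_results, fit = final,
         confusion = cm, test = test_tbl)
  })
  names(results) <- models
  structure(
    list(models = results, split = split, config = cfg, class_levels = lev),
    class = "spectranet_experiment"
  )
}

#' @export
print.spectranet_experiment <- function(x, ...) {
  cat(sprintf("<spectranet_experiment> %d model(s), %d train / %d test samples\n",
              length(x$models), length(x$split$train_ids), length(x$split$test_ids)))
  print(benchmark_table(x))
  invisible(x)
}
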