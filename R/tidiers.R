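#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for spectranet objects
#'
#' `tidy()` returns the long, per-unit view of an object (confusion counts,
#' per-class metrics, ROC points, the per-epoch trace); `glance()` a
#' one-row summary.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name spectranet_tidiers
NULL

#' @rdname spectranet_tidiers
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)) |>
    stats::setNames(c("true", "predicted", "n")) |>
    dplyr::mutate(n = as.integer(.data$n))
}

#' @rdname spectranet_tidiers
#' @export
tidy.metrics_report <- function(x, ...) {
  counts <- x$confusion$counts
  cs <- colSums(counts)
  total <- sum(counts)
  purrr::map_dfr(seq_along(x$confusion$class_names), function(k) {
    tp <- counts[k, k]
    fp <- cs[k] - tp
    fn <- sum(counts[k, ]) - tp
    tn <- total - tp - fp - fn
    tibble::tibble(class = x$confusion$class_names[k],
                   accuracy = unname(x$per_class_accuracy[k]),
                   precision = if (cs[k] > 0) tp / cs[k] else 0,
                   specificity = tn / (tn + fp))
  })
}

#' @rdname spectranet_tidiers
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 precision = x$precision, specificity = x$specificity)
}

#' @rdname spectranet_tidiers
#' @export
tidy.roc_result <- function(x, ...) x$curves

#' @rdname spectranet_tidiers
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(macro_auc = x$macro_auc, micro_auc = x$micro_auc)
}

#' @rdname spectranet_tidiers
#' @export
tidy.spectranet_fit <- function(x, ...) x$trace

#' @rdname spectranet_tidiers
#' @export
glance.spectranet_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(model = x$graph$name,
                 n_parameters = count_parameters(x$graph),
                 epochs = nrow(x$trace),
                 final_loss = last$loss,
                 final_train_accuracy = last$train_accuracy,
                 final_val_accuracy = last$val_accuracy)
}

#' @rdname spectranet_tidiers
#' @export
tidy.spectranet_experiment <- function(x, ...) benchmark_table(x)

#' @rdname spectranet_tidiers
#' @export
tidy.layer_graph <- function(x, ...) graph_nodes_tbl(x)
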