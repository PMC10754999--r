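#' Network architectures for 1D spectra
#'
#' Declarative layer graphs for the four classifiers. All convolutions use
#' "same" padding (lengths change only at pooling stages), batch
#' normalisation is followed by ReLU, and every network ends in a dense
#' layer of `n_classes` units under softmax trained with categorical
#' cross-entropy.
#'
#' * `build_alexnet1d()` — three conv blocks with 32/64/128 filters and
#'   kernel size 3, each conv followed by batch norm and max-pool(2); then
#'   flatten, dropout 0.4, a hidden dense layer and the softmax head.
#' * `build_resnet1d()` — a stem conv (kernel 9, 24 filters) with batch
#'   norm, ReLU and max-pool(3); three residual blocks (kernel 3, filters
#'   32/64/128) whose main path is conv -> batch norm -> ReLU -> conv and
#'   whose shortcut is a single kernel-1 projection conv, merged by
#'   addition and activated; then global average pooling and the softmax
#'   head.
#' * `build_mscnn()` — three parallel branches with kernel sizes 3/7/9
#'   (32 filters each, conv -> batch norm -> ReLU -> max-pool(2)),
#'   concatenated along channels; then flatten, dropout 0.4, hidden dense
#'   and the softmax head.
#' * `build_msresnet()` — the multi-scale front end borrowed from
#'   `build_mscnn()` (kernels 3/7/9 with 16/32/64 filters, each branch
#'   conv -> batch norm -> ReLU -> max-pool(2)) feeding the residual stack
#'   of `build_resnet1d()`, global average pooling and the softmax head.
#'
#' @param input_length Number of spectral points (826 on the default grid).
#' @param n_classes Number of diagnostic classes.
#' @param hidden_units Width of the hidden dense layer where one exists
#'   (default 128).
#' @param dropout_rate Dropout rate after flatten (default 0.4).
#' @return A `layer_graph`.
#' @name architectures
NULL

add_conv_block <- function(gb, from, kernel, filters, pool = NULL) {
  id <- gb$add("conv", from, kernel_size = as.integer(kernel),
               n_filters = as.integer(filters))
  id <- gb$add("batch_norm", id)
  id <- gb$add("relu", id)
  if (!is.null(pool)) id <- gb$add("max_pool", id, pool_size = as.integer(pool))
  id
}

add_res_block <- function(gb, from, filters, kernel = 3L) {
  main <- gb$add("conv", from, kernel_size = as.integer(kernel),
                 n_filters = as.integer(filters))
  main <- gb$add("batch_norm", main)
  main <- gb$add("relu", main)
  main <- gb$add("conv", main, kernel_size = as.integer(kernel),
                 n_filters = as.integer(filters))
  short <- gb$add("conv", from, kernel_size = 1L, n_filters = as.integer(filters))
  merged <- gb$add("add", c(main, short))
  gb$add("relu", merged)
}

add_softmax_head <- function(gb, from, n_classes) {
  id <- gb$add("dense", from, units = as.integer(n_classes))
  gb$add("softmax", id)
}

#' @rdname architectures
#' @export
build_alexnet1d <- function(input_length, n_classes,
                            hidden_units = 128L, dropout_rate = 0.4) {
  gb <- graph_builder()
  id <- gb$add("input")
  for (f in c(32L, 64L, 128L)) id <- add_conv_block(gb, id, 3L, f, pool = 2L)
  id <- gb$add("flatten", id)
  id <- gb$add("dropout", id, rate = dropout_rate)
  id <- gb$add("dense", id, units = as.integer(hidden_units))
  id <- gb$add("relu", id)
  id <- add_softmax_head(gb, id, n_classes)
  new_layer_graph("alexnet1d", gb$nodes(), input_length, n_classes)
}

#' @rdname architectures
#' @export
build_resnet1d <- function(input_length, n_classes) {
  gb <- graph_builder()
  id <- gb$add("input")
  id <- add_conv_block(gb, id, 9L, 24L, pool = 3L)
  for (f in c(32L, 64L, 128L)) id <- add_res_block(gb, id, f)
  id <- gb$add("global_avg_pool", id)
  id <- gb$add("flatten", id)
  id <- add_softmax_head(gb, id, n_classes)
  new_layer_graph("resnet1d", gb$nodes(), input_length, n_classes)
}

#' @rdname architectures
#' @export
build_mscnn <- function(input_length, n_classes,
                        branch_kernels = c(3L, 7L, 9L),
                        branch_filters = 32L,
                        hidden_units = 128L, dropout_rate = 0.4) {
  gb <- graph_builder()
  inp <- gb$add("input")
  branches <- vapply(branch_kernels, function(k) {
    add_conv_block(gb, inp, k, branch_filters, pool = 2L)
  }, integer(1))
  id <- gb$add("concat", branches)
  id <- gb$add("flatten", id)
  id <- gb$add("dropout", id, rate = dropout_rate)
  id <- gb$add("dense", id, units = as.integer(hidden_units))
  id <- gb$add("relu", id)
  id <- add_softmax_head(gb, id, n_classes)
  new_layer_graph("mscnn", gb$nodes(), input_length, n_classes)
}

#' @rdname architectures
#' @export
build_msresnet <- function(input_length, n_classes,
                           branch_kernels = c(3L, 7L, 9L),
                           branch_filters = c(16L, 32L, 64L)) {
  stopifnot(length(branch_kernels) == length(branch_filters))
  gb <- graph_builder()
  inp <- gb$add("input")
  branches <- vapply(seq_along(branch_kernels), function(i) {
    add_conv_block(gb, inp, branch_kernels[i], branch_filters[i], pool = 2L)
  }, integer(1))
  id <- gb$add("concat", branches)
  for (f in c(32L, 64L, 128L)) id <- add_res_block(gb, id, f)
  id <- gb$add("global_avg_pool", id)
  id <- gb$add("flatten", id)
  id <- add_softmax_head(gb, id, n_classes)
  new_layer_graph("msresnet", gb$nodes(), input_length, n_classes)
}

#' Build an architecture by name
#'
#' @param name One of `"alexnet1d"`, `"resnet1d"`, `"mscnn"`, `"msresnet"`.
#' @param input_length,n_classes Passed to the builder.
#' @return A `layer_graph`.
#' @export
build_model <- function(name = c("alexnet1d", "resnet1d", "mscnn", "msresnet"),
                        input_length, n_classes) {
  name <- rlang::arg_match(name)
  switch(name,
    alexnet1d = build_alexnet1d(input_length, n_classes),
    resnet1d = build_resnet1d(input_length, n_classes),
    mscnn = build_mscnn(input_length, n_classes),
    msresnet = build_msresnet(input_length, n_classes)
  )
}

#' Serialise an architecture to JSON
#'
#' Writes the node list (kind, hyperparameters, edges) plus input length and
#' class count, so any backend can materialise the graph.
#'
#' @param graph A `layer_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layer_graph <- function(graph, path) {
  obj <- list(
    name = graph$name,
    input_length = graph$input_length,
    n_classes = graph$n_classes,
    nodes = lapply(graph$nodes, function(nd) {
      nd$inputs <- as.list(nd$inputs)
      nd
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

# tidy summary of graph structure used by tests and reports
graph_nodes_tbl <- function(graph) {
  purrr::map_dfr(graph$nodes, function(nd) {
    tibble::tibble(
      id = nd$id, kind = nd$kind,
      kernel_size = nd$kernel_size %||% NA_integer_,
      n_filters = nd$n_filters %||% NA_integer_,
      pool_size = nd$pool_size %||% NA_integer_,
      units = nd$units %||% NA_integer_,
      rate = nd$rate %||% NA_real_,
      n_inputs = length(nd$inputs)
    )
  })
}
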