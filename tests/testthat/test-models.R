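graph_kinds <- function(g) vapply(g$nodes, function(nd) nd$kind, character(1))

conv_nodes <- function(g) {
  tb <- tidy(g)
  tb[tb$kind == "conv", ]
}

test_that("alexnet1d has the stated conv stack, pooling and dropout", {
  g <- build_alexnet1d(826, 4)
  cv <- conv_nodes(g)
  expect_equal(cv$n_filters, c(32L, 64L, 128L))
  expect_equal(unique(cv$kernel_size), 3L)
  tb <- tidy(g)
  expect_equal(tb$pool_size[tb$kind == "max_pool"], rep(2L, 3))
  drops <- tb[tb$kind == "dropout", ]
  expect_equal(nrow(drops), 1L)
  expect_equal(drops$rate, 0.4)
  # two dense layers, the last sized to the classes, under softmax
  expect_equal(tb$units[tb$kind == "dense"], c(128L, 4L))
  expect_equal(tb$kind[nrow(tb)], "softmax")
})

test_that("alexnet1d feature length before flatten follows pool arithmetic", {
  g <- build_alexnet1d(16, 2)
  shapes <- spectranet:::graph_shapes(g)
  flat_at <- which(graph_kinds(g) == "flatten")
  pre <- shapes[[g$nodes[[flat_at]]$inputs[1]]]
  expect_equal(pre$L, 2L) # 16 -> 8 -> 4 -> 2
  expect_equal(shapes[[flat_at]]$U, 2L * 128L)
})

test_that("resnet1d has the stated stem and residual stack", {
  g <- build_resnet1d(826, 4)
  tb <- tidy(g)
  stem <- tb[tb$kind == "conv", ][1, ]
  expect_equal(stem$kernel_size, 9L)
  expect_equal(stem$n_filters, 24L)
  expect_equal(tb$pool_size[tb$kind == "max_pool"], 3L)
  # three residual merges; main-path filters 32/64/128 at kernel 3
  adds <- which(tb$kind == "add")
  expect_length(adds, 3L)
  main_convs <- tb[tb$kind == "conv" & tb$kernel_size == 3L, ]
  expect_equal(sort(unique(main_convs$n_filters)), c(32L, 64L, 128L))
  expect_equal(tb$kind[tb$kind == "global_avg_pool"], "global_avg_pool")
})

test_that("every residual shortcut is a single kernel-1 conv", {
  for (g in list(build_resnet1d(826, 4), build_msresnet(826, 4))) {
    tb <- tidy(g)
    for (i in which(tb$kind == "add")) {
      ins <- g$nodes[[i]]$inputs
      shortcut <- g$nodes[[ins[2]]]
      expect_equal(shortcut$kind, "conv")
      expect_equal(shortcut$kernel_size, 1L)
      # and it hangs directly off the block input, not off the main path
      expect_equal(shortcut$inputs, g$nodes[[ins[1] - 3L]]$inputs)
    }
  }
})

test_that("mscnn has three parallel branches with kernels 3, 7, 9", {
  g <- build_mscnn(826, 4)
  tb <- tidy(g)
  branch <- tb[tb$kind == "conv", ]
  expect_setequal(branch$kernel_size, c(3L, 7L, 9L))
  concats <- tb[tb$kind == "concat", ]
  expect_equal(nrow(concats), 1L)
  expect_equal(concats$n_inputs, 3L)
  expect_equal(nrow(tb[tb$kind == "dropout", ]), 1L)
})

test_that("msresnet fuses three distinct-kernel branches into the residual stack", {
  g <- build_msresnet(826, 4)
  tb <- tidy(g)
  concat_at <- which(tb$kind == "concat")
  expect_length(concat_at, 1L)
  branch_pools <- g$nodes[[concat_at]]$inputs
  kernels <- vapply(branch_pools, function(i) {
    # walk back from each branch pool to its conv
    j <- i
    while (g$nodes[[j]]$kind != "conv") j <- g$nodes[[j]]$inputs[1]
    g$nodes[[j]]$kernel_size
  }, integer(1))
  expect_length(unique(kernels), 3L)
  expect_setequal(kernels, c(3L, 7L, 9L)) # same multiset as mscnn by default
  # three residual merges downstream of the fusion
  adds <- which(tb$kind == "add")
  expect_length(adds, 3L)
  expect_true(all(adds > concat_at))
})

test_that("inputs too short for the pooling stages are a shape error", {
  expect_error(build_alexnet1d(4, 2), class = "spectranet_shape_error")
  expect_error(build_msresnet(1, 2), class = "spectranet_shape_error")
})

test_that("parameter counts match independent layer-by-layer arithmetic", {
  # dense 4 -> 4 with bias
  gb <- spectranet:::graph_builder()
  id <- gb$add("input")
  id <- gb$add("flatten", id)
  id <- gb$add("dense", id, units = 4L)
  id <- gb$add("softmax", id)
  g <- spectranet:::new_layer_graph("toy", gb$nodes(), 4L, 4L)
  expect_equal(count_parameters(g), 4L * 4L + 4L)

  # alexnet1d(826, 4), every layer accumulated by hand:
  conv1 <- 3 * 1 * 32 + 32;   bn1 <- 2 * 32    # L 826 -> pool -> 413
  conv2 <- 3 * 32 * 64 + 64;  bn2 <- 2 * 64    # 413 -> 206
  conv3 <- 3 * 64 * 128 + 128; bn3 <- 2 * 128  # 206 -> 103
  dense1 <- (103 * 128) * 128 + 128
  dense2 <- 128 * 4 + 4
  expected <- conv1 + bn1 + conv2 + bn2 + conv3 + bn3 + dense1 + dense2
  expect_equal(count_parameters(build_alexnet1d(826, 4)), expected)
})

test_that("softmax outputs are probability vectors for random weights", {
  set.seed(31)
  for (nm in c("alexnet1d", "resnet1d", "mscnn", "msresnet")) {
    g <- build_model(nm, 64L, 3L)
    params <- spectranet:::nn_init_params(g, 13L)
    X <- matrix(rnorm(6 * 64), 6, 64)
    probs <- spectranet:::nn_predict_probs(g, params, X)
    expect_equal(rowSums(probs), rep(1, 6), tolerance = 1e-6)
    expect_true(all(probs >= 0))
  }
})

test_that("a zeroed main path reduces a residual block to its activated shortcut", {
  f <- 5L
  gb <- spectranet:::graph_builder()
  inp <- gb$add("input")
  lift <- gb$add("conv", inp, kernel_size = 1L, n_filters = f)
  out <- spectranet:::add_res_block(gb, lift, f)
  sm_in <- gb$add("global_avg_pool", out)
  fl <- gb$add("flatten", sm_in)
  dn <- gb$add("dense", fl, units = 2L)
  gb$add("softmax", dn)
  g <- spectranet:::new_layer_graph("rb", gb$nodes(), 12L, 2L)
  params <- spectranet:::nn_init_params(g, 5L)
  # zero the main branch convs; identity shortcut (kernel-1, f x f)
  kinds <- vapply(g$nodes, function(nd) nd$kind, character(1))
  convs <- which(kinds == "conv")
  main1 <- convs[2]; main2 <- convs[3]; shortcut <- convs[4]
  params[[main1]]$W[] <- 0; params[[main1]]$b[] <- 0
  params[[main2]]$W[] <- 0; params[[main2]]$b[] <- 0
  params[[shortcut]]$W <- diag(f); params[[shortcut]]$b[] <- 0
  X <- matrix(rnorm(3 * 12), 3, 12)
  fwd <- spectranet:::nn_forward(g, params, X, training = TRUE)
  lifted <- fwd$acts[[lift]]
  block_out <- fwd$acts[[out]]
  expect_equal(block_out, pmax(lifted, 0), tolerance = 1e-12)
})

test_that("a single-branch multi-scale graph is a plain CNN", {
  g1 <- build_mscnn(128, 3, branch_kernels = 7L)
  kinds <- vapply(g1$nodes, function(nd) nd$kind, character(1))
  # one branch: concat is a no-op merge with a single input; otherwise the
  # node sequence is exactly conv -> bn -> relu -> pool -> (merge) -> head
  expect_equal(sum(kinds == "conv"), 1L)
  expect_equal(sum(kinds == "concat"), 1L)
  expect_equal(length(g1$nodes[[which(kinds == "concat")]]$inputs), 1L)
  shapes <- spectranet:::graph_shapes(g1)
  cc <- which(kinds == "concat")
  expect_identical(shapes[[cc]]$C, shapes[[g1$nodes[[cc]]$inputs[1]]]$C)
})

test_that("symmetric branches with tied weights produce identical outputs", {
  g <- build_mscnn(32, 2, branch_kernels = c(5L, 5L, 5L))
  params <- spectranet:::nn_init_params(g, 9L)
  kinds <- vapply(g$nodes, function(nd) nd$kind, character(1))
  convs <- which(kinds == "conv")
  for (i in convs[-1]) params[[i]] <- params[[convs[1]]]
  X <- matrix(rnorm(4 * 32), 4, 32)
  fwd <- spectranet:::nn_forward(g, params, X, training = FALSE)
  cc <- which(kinds == "concat")
  branch_outs <- lapply(g$nodes[[cc]]$inputs, function(i) fwd$acts[[i]])
  expect_equal(branch_outs[[1]], branch_outs[[2]])
  expect_equal(branch_outs[[1]], branch_outs[[3]])
  expect_equal(ncol(fwd$acts[[cc]]), 3L * ncol(branch_outs[[1]]))
})

test_that("layer graphs serialise to JSON with kinds, params and edges", {
  g <- build_resnet1d(64, 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_layer_graph(g, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$name, "resnet1d")
  expect_equal(back$input_length, 64L)
  expect_equal(length(back$nodes), length(g$nodes))
  expect_equal(back$nodes[[2]]$kernel_size, 9L)
})
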