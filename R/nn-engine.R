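# Self-contained 1D neural-network engine.
#
# Activations for convolutional feature maps are stored as an (L*B) x C
# matrix with row index (b-1)*L + l (position fastest), so convolutions
# reduce to one im2col gather plus one BLAS matrix product per layer.
# Dense-stage activations are B x U matrices. All layers implement an exact
# analytic backward pass (verified against finite differences in the test
# suite), and optimisation is Adam.

# Batch-norm: running statistics (EMA, momentum 0.9) only feed the
# per-epoch validation trace; the fitted model's inference statistics are
# recomputed exactly by calibrate_bn() after the final epoch, so trace
# readability and final stability are decoupled.
nn_eps <- 1e-3
bn_momentum <- 0.9

# rowwise broadcast helpers: add/multiply a length-ncol vector to every row.
# Avoids sweep(), whose internal aperm dominates profile time at these sizes.
add_rowvec <- function(M, v) M + rep(v, each = nrow(M))
mul_rowvec <- function(M, v) M * rep(v, each = nrow(M))

# ---- graph construction -----------------------------------------------------

graph_builder <- function() {
  nodes <- list()
  add <- function(kind, inputs = integer(0), ...) {
    nodes[[length(nodes) + 1L]] <<- c(list(id = length(nodes) + 1L,
                                           kind = kind,
                                           inputs = as.integer(inputs)),
                                      list(...))
    length(nodes)
  }
  list(add = add, nodes = function() nodes)
}

new_layer_graph <- function(name, nodes, input_length, n_classes) {
  g <- structure(
    list(name = name, nodes = nodes,
         input_length = as.integer(input_length),
         n_classes = as.integer(n_classes)),
    class = "layer_graph"
  )
  graph_shapes(g) # validates
  g
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(sprintf("<layer_graph> %s: input length %d -> %d classes, %d nodes, %s parameters\n",
              x$name, x$input_length, x$n_classes, length(x$nodes),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- shape propagation ------------------------------------------------------

# Returns one shape per node: list(type = "map", L, C) or list(type = "vec", U).
graph_shapes <- function(graph) {
  shapes <- vector("list", length(graph$nodes))
  for (nd in graph$nodes) {
    ins <- shapes[nd$inputs]
    shapes[[nd$id]] <- switch(nd$kind,
      input = list(type = "map", L = graph$input_length, C = 1L),
      conv = {
        s <- ins[[1]]
        stopifnot(s$type == "map")
        list(type = "map", L = s$L, C = nd$n_filters)
      },
      batch_norm = ins[[1]],
      relu = ins[[1]],
      max_pool = {
        s <- ins[[1]]
        L2 <- s$L %/% nd$pool_size
        if (L2 < 1) {
          rlang::abort(sprintf("input too short: length %d cannot be pooled by %d",
                               s$L, nd$pool_size),
                       class = "spectranet_shape_error")
        }
        list(type = "map", L = L2, C = s$C)
      },
      global_avg_pool = {
        s <- ins[[1]]
        list(type = "vec", U = s$C)
      },
      flatten = {
        s <- ins[[1]]
        if (s$type == "vec") s else list(type = "vec", U = s$L * s$C)
      },
      dense = list(type = "vec", U = nd$units),
      dropout = ins[[1]],
      softmax = ins[[1]],
      add = {
        a <- ins[[1]]; b <- ins[[2]]
        if (!identical(a, b)) {
          rlang::abort("residual add requires identical input shapes",
                       class = "spectranet_shape_error")
        }
        a
      },
      concat = {
        Ls <- vapply(ins, function(s) s$L, integer(1))
        if (length(unique(Ls)) != 1) {
          rlang::abort("concatenate requires equal input lengths",
                       class = "spectranet_shape_error")
        }
        list(type = "map", L = Ls[1], C = sum(vapply(ins, function(s) s$C, integer(1))))
      },
      rlang::abort(paste0("unknown node kind: ", nd$kind))
    )
  }
  shapes
}

#' Count trainable parameters of an architecture
#'
#' Convolution kernels and biases, batch-norm scale/shift pairs and dense
#' weights and biases; running batch-norm statistics are buffers, not
#' parameters.
#'
#' @param graph A `layer_graph`.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(graph) {
  shapes <- graph_shapes(graph)
  total <- 0
  for (nd in graph$nodes) {
    s_in <- if (length(nd$inputs) > 0) shapes[[nd$inputs[1]]] else NULL
    total <- total + switch(nd$kind,
      conv = nd$kernel_size * s_in$C * nd$n_filters + nd$n_filters,
      batch_norm = 2L * s_in$C,
      dense = s_in$U * nd$units + nd$units,
      0L
    )
  }
  as.integer(total)
}

# ---- parameter initialisation ----------------------------------------------

nn_init_params <- function(graph, seed) {
  shapes <- graph_shapes(graph)
  with_local_seed(seed, {
    lapply(graph$nodes, function(nd) {
      s_in <- if (length(nd$inputs) > 0) shapes[[nd$inputs[1]]] else NULL
      switch(nd$kind,
        conv = {
          # Glorot-uniform, the Keras layer default
          fan_in <- nd$kernel_size * s_in$C
          lim <- sqrt(6 / (fan_in + nd$n_filters))
          list(W = matrix(stats::runif(fan_in * nd$n_filters, -lim, lim),
                          fan_in, nd$n_filters),
               b = numeric(nd$n_filters))
        },
        dense = {
          lim <- sqrt(6 / (s_in$U + nd$units))
          list(W = matrix(stats::runif(s_in$U * nd$units, -lim, lim),
                          s_in$U, nd$units),
               b = numeric(nd$units))
        },
        batch_norm = list(gamma = rep(1, s_in$C), beta = numeric(s_in$C),
                          running_mean = numeric(s_in$C),
                          running_var = rep(1, s_in$C)),
        NULL
      )
    })
  })
}

# ---- layer forward/backward -------------------------------------------------

conv_indices <- function(L, B, k) {
  p <- (k - 1L) %/% 2L
  Lp <- L + 2L * p
  base <- rep((0:(B - 1L)) * Lp, each = L) + rep(seq_len(L), B)
  list(p = p, Lp = Lp, base = base,
       in_rows = base + p)
}

conv_fwd <- function(X, W, b, k, L, B) {
  C_in <- ncol(X)
  ix <- conv_indices(L, B, k)
  if (ix$p == 0) {
    Xcol <- X
  } else {
    Xp <- matrix(0, ix$Lp * B, C_in)
    Xp[ix$in_rows, ] <- X
    Xcol <- matrix(0, L * B, k * C_in)
    for (j in seq_len(k)) {
      Xcol[, ((j - 1L) * C_in + 1L):(j * C_in)] <- Xp[ix$base + (j - 1L), , drop = FALSE]
    }
  }
  Y <- add_rowvec(Xcol %*% W, b)
  list(Y = Y, cache = list(Xcol = Xcol, k = k, L = L, B = B, C_in = C_in))
}

conv_bwd <- function(dY, W, cache) {
  k <- cache$k; L <- cache$L; B <- cache$B; C_in <- cache$C_in
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(W)
  if (k == 1L) {
    dX <- dXcol
  } else {
    ix <- conv_indices(L, B, k)
    dXp <- matrix(0, ix$Lp * B, C_in)
    for (j in seq_len(k)) {
      rows <- ix$base + (j - 1L)
      dXp[rows, ] <- dXp[rows, , drop = FALSE] +
        dXcol[, ((j - 1L) * C_in + 1L):(j * C_in), drop = FALSE]
    }
    dX <- dXp[ix$in_rows, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

bn_fwd <- function(X, prm, training) {
  if (training) {
    mu <- colMeans(X)
    Xc <- add_rowvec(X, -mu)
    v <- colMeans(Xc^2)
    ivar <- 1 / sqrt(v + nn_eps)
    xhat <- mul_rowvec(Xc, ivar)
    Y <- add_rowvec(mul_rowvec(xhat, prm$gamma), prm$beta)
    new_rm <- bn_momentum * prm$running_mean + (1 - bn_momentum) * mu
    new_rv <- bn_momentum * prm$running_var + (1 - bn_momentum) * v
    list(Y = Y, cache = list(xhat = xhat, ivar = ivar, Xc = Xc),
         running = list(running_mean = new_rm, running_var = new_rv))
  } else {
    xhat <- mul_rowvec(add_rowvec(X, -prm$running_mean),
                       1 / sqrt(prm$running_var + nn_eps))
    list(Y = add_rowvec(mul_rowvec(xhat, prm$gamma), prm$beta),
         cache = NULL, running = NULL)
  }
}

bn_bwd <- function(dY, prm, cache) {
  N <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- mul_rowvec(dY, prm$gamma)
  dvar <- colSums(dxhat * cache$Xc) * (-0.5) * cache$ivar^3
  dxi <- mul_rowvec(dxhat, cache$ivar)
  dmu <- -colSums(dxi)
  dX <- dxi + mul_rowvec(cache$Xc, 2 * dvar / N) + rep(dmu / N, each = N)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool_indices <- function(L, B, p) {
  L2 <- L %/% p
  lapply(seq_len(p), function(j) {
    rep((0:(B - 1L)) * L, each = L2) + rep(seq(1L, by = p, length.out = L2), B) + (j - 1L)
  })
}

maxpool_fwd <- function(X, p, L, B) {
  idx <- pool_indices(L, B, p)
  Y <- X[idx[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(Y), ncol(Y))
  for (j in seq_len(p)[-1]) {
    cand <- X[idx[[j]], , drop = FALSE]
    upd <- cand > Y
    Y[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(Y = Y, cache = list(arg = arg, p = p, L = L, B = B))
}

maxpool_bwd <- function(dY, cache) {
  idx <- pool_indices(cache$L, cache$B, cache$p)
  dX <- matrix(0, cache$L * cache$B, ncol(dY))
  for (j in seq_len(cache$p)) {
    sel <- (cache$arg == j) * dY
    dX[idx[[j]], ] <- dX[idx[[j]], , drop = FALSE] + sel
  }
  dX
}

flatten_fwd <- function(X, L, B) {
  C <- ncol(X)
  Y <- matrix(aperm(array(X, c(L, B, C)), c(2, 1, 3)), B, L * C)
  list(Y = Y, cache = list(L = L, B = B, C = C))
}

flatten_bwd <- function(dY, cache) {
  matrix(aperm(array(dY, c(cache$B, cache$L, cache$C)), c(2, 1, 3)),
         cache$L * cache$B, cache$C)
}

softmax_rows <- function(Z) {
  Zs <- Z - apply(Z, 1, max)
  E <- exp(Zs)
  E / rowSums(E)
}

# ---- graph forward/backward -------------------------------------------------

# X_in: B x input_length matrix of spectra (one row per sample).
nn_forward <- function(graph, params, X_in, training = FALSE,
                       dropout_masks = NULL) {
  B <- nrow(X_in)
  L0 <- graph$input_length
  shapes <- graph_shapes(graph)
  acts <- vector("list", length(graph$nodes))
  caches <- vector("list", length(graph$nodes))
  running_updates <- list()
  for (nd in graph$nodes) {
    ins <- acts[nd$inputs]
    s_in <- if (length(nd$inputs) > 0) shapes[[nd$inputs[1]]] else NULL
    out <- switch(nd$kind,
      input = list(Y = matrix(as.vector(t(X_in)), ncol = 1), cache = NULL),
      conv = conv_fwd(ins[[1]], params[[nd$id]]$W, params[[nd$id]]$b,
                      nd$kernel_size, s_in$L, B),
      batch_norm = {
        r <- bn_fwd(ins[[1]], params[[nd$id]], training)
        if (!is.null(r$running)) running_updates[[as.character(nd$id)]] <- r$running
        r
      },
      relu = {
        mask <- ins[[1]] > 0
        list(Y = ins[[1]] * mask, cache = list(mask = mask))
      },
      max_pool = maxpool_fwd(ins[[1]], nd$pool_size, s_in$L, B),
      global_avg_pool = {
        grp <- rep(seq_len(B), each = s_in$L)
        list(Y = rowsum(ins[[1]], grp, reorder = TRUE) / s_in$L,
             cache = list(L = s_in$L, B = B))
      },
      flatten = {
        if (s_in$type == "vec") list(Y = ins[[1]], cache = list(identity = TRUE))
        else flatten_fwd(ins[[1]], s_in$L, B)
      },
      dense = list(Y = add_rowvec(ins[[1]] %*% params[[nd$id]]$W,
                                  params[[nd$id]]$b),
                   cache = list(X = ins[[1]])),
      dropout = {
        if (training) {
          mask <- if (!is.null(dropout_masks)) dropout_masks[[as.character(nd$id)]]
                  else (matrix(stats::runif(length(ins[[1]])), nrow(ins[[1]])) >=
                          nd$rate) / (1 - nd$rate)
          list(Y = ins[[1]] * mask, cache = list(mask = mask))
        } else {
          list(Y = ins[[1]], cache = list(mask = 1))
        }
      },
      softmax = list(Y = softmax_rows(ins[[1]]), cache = NULL),
      add = list(Y = ins[[1]] + ins[[2]], cache = NULL),
      concat = {
        widths <- vapply(ins, ncol, integer(1))
        list(Y = do.call(cbind, ins), cache = list(widths = widths))
      }
    )
    acts[[nd$id]] <- out$Y
    caches[[nd$id]] <- out$cache
  }
  list(acts = acts, caches = caches, running_updates = running_updates)
}

# Backward from the softmax cross-entropy head. `probs` is the softmax
# output, `onehot` the B x K label matrix. Returns gradients per node.
nn_backward <- function(graph, params, fwd, onehot) {
  n <- length(graph$nodes)
  last <- graph$nodes[[n]]
  stopifnot(last$kind == "softmax")
  grads <- vector("list", n)
  dacts <- vector("list", n)
  B <- nrow(onehot)
  # combined softmax + cross-entropy gradient at the softmax input
  dacts[[last$inputs[1]]] <- (fwd$acts[[n]] - onehot) / B
  for (i in rev(seq_len(n - 1L))) {
    nd <- graph$nodes[[i]]
    dY <- dacts[[i]]
    if (is.null(dY)) next
    cache <- fwd$caches[[i]]
    ins <- nd$inputs
    push <- function(j, g) {
      dacts[[j]] <<- if (is.null(dacts[[j]])) g else dacts[[j]] + g
    }
    switch(nd$kind,
      input = NULL,
      conv = {
        r <- conv_bwd(dY, params[[i]]$W, cache)
        grads[[i]] <- list(W = r$dW, b = r$db)
        push(ins[1], r$dX)
      },
      batch_norm = {
        r <- bn_bwd(dY, params[[i]], cache)
        grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
        push(ins[1], r$dX)
      },
      relu = push(ins[1], dY * cache$mask),
      max_pool = push(ins[1], maxpool_bwd(dY, cache)),
      global_avg_pool = {
        push(ins[1], dY[rep(seq_len(cache$B), each = cache$L), , drop = FALSE] / cache$L)
      },
      flatten = {
        if (isTRUE(cache$identity)) push(ins[1], dY)
        else push(ins[1], flatten_bwd(dY, cache))
      },
      dense = {
        grads[[i]] <- list(W = crossprod(cache$X, dY), b = colSums(dY))
        push(ins[1], dY %*% t(params[[i]]$W))
      },
      dropout = push(ins[1], dY * cache$mask),
      add = { push(ins[1], dY); push(ins[2], dY) },
      concat = {
        off <- 0L
        for (j in seq_along(ins)) {
          w <- cache$widths[j]
          push(ins[j], dY[, (off + 1L):(off + w), drop = FALSE])
          off <- off + w
        }
      }
    )
  }
  grads
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    trainable <- setdiff(names(p), c("running_mean", "running_var"))
    st <- lapply(p[trainable], function(w) list(m = w * 0, v = w * 0))
    st
  })
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

apply_running_updates <- function(params, updates) {
  for (id in names(updates)) {
    i <- as.integer(id)
    params[[i]]$running_mean <- updates[[id]]$running_mean
    params[[i]]$running_var <- updates[[id]]$running_var
  }
  params
}

# Mean categorical cross-entropy of softmax probabilities.
xent_loss <- function(probs, onehot) {
  -mean(log(pmax(rowSums(probs * onehot), 1e-12)))
}


# Recompute exact batch-norm running statistics with one pass over `x`
# (training-mode normalisation upstream, dropout disabled): the pooled
# mean/variance over all batches replaces the lagging EMA, so inference
# matches what the final weights were trained against. Deterministic.
calibrate_bn <- function(graph, params, x, batch_size) {
  bn_ids <- which(vapply(graph$nodes, function(nd) nd$kind == "batch_norm",
                         logical(1)))
  if (length(bn_ids) == 0) return(params)
  no_dropout <- list()
  for (nd in graph$nodes) {
    if (nd$kind == "dropout") no_dropout[[as.character(nd$id)]] <- 1
  }
  acc <- lapply(bn_ids, function(i) list(n = 0, s = 0, ss = 0))
  names(acc) <- as.character(bn_ids)
  n <- nrow(x)
  for (s0 in seq(1L, n, by = batch_size)) {
    rows <- s0:min(s0 + batch_size - 1L, n)
    fwd <- nn_forward(graph, params, x[rows, , drop = FALSE],
                      training = TRUE, dropout_masks = no_dropout)
    for (i in bn_ids) {
      X <- fwd$acts[[graph$nodes[[i]]$inputs[1]]]
      key <- as.character(i)
      acc[[key]]$n <- acc[[key]]$n + nrow(X)
      acc[[key]]$s <- acc[[key]]$s + colSums(X)
      acc[[key]]$ss <- acc[[key]]$ss + colSums(X^2)
    }
  }
  for (i in bn_ids) {
    a <- acc[[as.character(i)]]
    mu <- a$s / a$n
    params[[i]]$running_mean <- mu
    params[[i]]$running_var <- pmax(a$ss / a$n - mu^2, 0)
  }
  params
}
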