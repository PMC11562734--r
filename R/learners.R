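# Internal learners behind the per-representation models.
#
# Vector representations (B-MF / C-MF / MD) use gradient-boosted trees
# (xgboost, histogram method, single thread, seeded: bit-reproducible).
# The image representation uses a convolutional random-feature ridge
# regressor: fixed seeded convolution filters + ReLU + spatial mean pooling,
# with a closed-form ridge readout. The graph representation uses a
# message-passing random-feature ridge regressor: seeded random
# message-passing weights over the bond graph, component-wise pooling, ridge
# readout. Measurement conditions enter the image/graph models as scalars
# concatenated to the pooled (penultimate) feature vector.

as_design <- function(X) {
  # sparse storage pays off for the mostly-zero fingerprint designs
  if (requireNamespace("Matrix", quietly = TRUE) && mean(X != 0) < 0.5) {
    methods::as(X, "CsparseMatrix")
  } else {
    X
  }
}

fit_xgb <- function(X, y, params, seed) {
  d <- xgboost::xgb.DMatrix(as_design(X), label = y, nthread = 1)
  with_seed(seed, xgboost::xgb.train(
    params = list(
      objective = "reg:squarederror",
      max_depth = params$max_depth %||% 6L,
      learning_rate = params$learning_rate %||% 0.1,
      subsample = params$subsample %||% 1,
      colsample_bytree = params$colsample_bytree %||% 1,
      tree_method = "hist",
      nthread = 1,
      seed = as.integer(seed)
    ),
    data = d, nrounds = params$nrounds %||% 150L, verbose = 0
  ))
}

predict_xgb <- function(booster, X) {
  as.numeric(stats::predict(booster, xgboost::xgb.DMatrix(as_design(X), nthread = 1)))
}

# Closed-form ridge regression with centred/scaled design. Constant columns
# are kept with zero weight.
fit_ridge <- function(X, y, lambda) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sd, "/")
  p <- ncol(Z)
  A <- crossprod(Z) / nrow(Z) + diag(lambda, p)
  b <- crossprod(Z, y - mean(y)) / nrow(Z)
  beta <- solve(A, b)
  list(mu = mu, sd = sd, beta = as.numeric(beta), intercept = mean(y),
       lambda = lambda)
}

predict_ridge <- function(fit, X) {
  Z <- sweep(sweep(X, 2L, fit$mu), 2L, fit$sd, "/")
  as.numeric(Z %*% fit$beta) + fit$intercept
}

# --- convolutional random features ------------------------------------------

# Fixed seeded filter bank; valid convolution via im2col, ReLU, then mean
# pooling over a 2x2 grid of spatial regions -> 4 * n_filters features,
# plus global ink statistics.
make_conv_filters <- function(n_filters, patch, seed) {
  with_seed(seed, matrix(stats::rnorm(patch * patch * n_filters, sd = 1 / patch),
                         patch * patch, n_filters))
}

conv_feature_row <- function(img, W, patch, stride, grid = 3L) {
  px <- nrow(img)
  pos <- seq(1L, px - patch + 1L, by = stride)
  g <- length(pos)
  cols <- matrix(0, patch * patch, g * g)
  k <- 1L
  for (i in pos) for (j in pos) {
    cols[, k] <- as.numeric(img[i:(i + patch - 1L), j:(j + patch - 1L)])
    k <- k + 1L
  }
  act <- pmax(crossprod(cols, W), 0)   # (g*g) x n_filters
  reg_i <- ceiling(rep(seq_len(g), each = g) / g * grid)
  reg_j <- ceiling(rep(seq_len(g), g) / g * grid)
  region <- (reg_i - 1L) * grid + reg_j
  pooled <- rowsum(act, region) / as.numeric(table(region))
  # coarse row/column ink profiles retain layout information the pooled
  # activations blur out
  bin <- max(px %/% 16L, 1L)
  prof_r <- colSums(matrix(rowSums(img), nrow = bin)) / px
  prof_c <- colSums(matrix(colSums(img), nrow = bin)) / px
  c(as.numeric(t(pooled)), mean(img), stats::sd(as.numeric(img)),
    prof_r, prof_c)
}

conv_features <- function(imgs, n_filters, patch, stride, seed) {
  W <- make_conv_filters(n_filters, patch, seed)
  n <- dim(imgs)[1L]
  rows <- lapply(seq_len(n), function(i) conv_feature_row(imgs[i, , ], W, patch, stride))
  do.call(rbind, rows)
}

# Mean-pool the raw canvas to a g x g grid (a skip connection past the
# convolution stage).
pool_raw <- function(imgs, factor = 8L) {
  n <- dim(imgs)[1L]
  px <- dim(imgs)[2L]
  g <- px %/% factor
  idx <- rep(seq_len(g), each = factor)[seq_len(px)]
  do.call(rbind, lapply(seq_len(n), function(i) {
    as.numeric(rowsum(t(rowsum(imgs[i, , ], idx)), idx)) / factor^2
  }))
}

# The image design: two convolution scales (coarse 12 px and fine 6 px
# patches, independent filter banks) plus the pooled raw canvas.
mi_design <- function(imgs, n_filters, seed) {
  cbind(
    conv_features(imgs, n_filters, 12L, 6L, seed),
    conv_features(imgs, max(8L, n_filters %/% 2L), 6L, 3L, (seed + 1) %% 2147483647),
    pool_raw(imgs, 8L)
  )
}

# --- message-passing random features ----------------------------------------

mg_input_dim <- function() length(.mg_elements) + 1L + 3L  # one-hot + degree/charge/ring

make_mp_weights <- function(hidden, layers, seed) {
  d0 <- mg_input_dim()
  with_seed(seed, {
    list(
      W_in = matrix(stats::rnorm(d0 * hidden, sd = 1 / sqrt(d0)), d0, hidden),
      W_msg = lapply(seq_len(layers), function(l)
        matrix(stats::rnorm(hidden * hidden, sd = 1 / sqrt(hidden)), hidden, hidden)),
      W_self = lapply(seq_len(layers), function(l)
        matrix(stats::rnorm(hidden * hidden, sd = 1 / sqrt(hidden)), hidden, hidden))
    )
  })
}

# One graph -> pooled feature vector: tanh message passing over bonds,
# then per-component (cation/anion) sum and mean pooling, concatenated.
mp_feature_row <- function(graph, weights, layers) {
  X <- graph$node_features
  H <- tanh(X %*% weights$W_in)
  n <- nrow(H)
  e <- graph$edges
  for (l in seq_len(layers)) {
    M <- matrix(0, n, ncol(H))
    if (nrow(e)) {
      for (k in seq_len(nrow(e))) {
        M[e$a1[k], ] <- M[e$a1[k], ] + H[e$a2[k], ]
        M[e$a2[k], ] <- M[e$a2[k], ] + H[e$a1[k], ]
      }
    }
    H <- tanh(H %*% weights$W_self[[l]] + M %*% weights$W_msg[[l]])
  }
  comp <- graph$nodes$component
  pool <- function(rows) {
    if (!length(rows)) return(c(numeric(ncol(H)), numeric(ncol(H))))
    c(colSums(H[rows, , drop = FALSE]), colMeans(H[rows, , drop = FALSE]))
  }
  c(pool(which(comp == "cation")), pool(which(comp == "anion")))
}

mp_features <- function(graphs, hidden, layers, seed) {
  weights <- make_mp_weights(hidden, layers, seed)
  do.call(rbind, lapply(graphs, mp_feature_row, weights = weights, layers = layers))
}
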