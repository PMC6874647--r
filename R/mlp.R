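# Minimal feedforward network: ReLU hidden layers, sigmoid output, binary
# cross-entropy loss, RMSprop updates. Sized for the small balanced training
# sets this package produces, so plain R matrix code is fast enough.

mlp_init <- function(n_in, hidden) {
  dims <- c(n_in, hidden, 1L)
  weights <- list()
  for (i in seq_len(length(dims) - 1L)) {
    fan_in <- dims[i]
    weights[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * dims[i + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, dims[i + 1L]),
      b = rep(0, dims[i + 1L])
    )
  }
  weights
}

mlp_forward <- function(weights, x) {
  acts <- list(x)
  n_layer <- length(weights)
  for (i in seq_len(n_layer)) {
    z <- acts[[i]] %*% weights[[i]]$W +
      matrix(weights[[i]]$b, nrow(acts[[i]]), length(weights[[i]]$b),
             byrow = TRUE)
    acts[[i + 1L]] <- if (i < n_layer) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  acts
}

# y in {0,1}; returns fitted model (weights + input standardisation).
mlp_fit <- function(x, y, hidden = c(128L, 64L), epochs = 100L,
                    batch_size = 8L, learning_rate = 1e-3, seed = 1L) {
  stopifnot(nrow(x) == length(y))
  with_local_seed(seed, {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ < 1e-8] <- 1
    xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

    weights <- mlp_init(ncol(x), hidden)
    cache <- lapply(weights, function(w) {
      list(W = w$W * 0, b = w$b * 0)
    })
    rho <- 0.9
    eps <- 1e-8
    n <- nrow(xs)
    n_layer <- length(weights)

    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      for (st in starts) {
        idx <- ord[st:min(st + batch_size - 1L, n)]
        xb <- xs[idx, , drop = FALSE]
        yb <- y[idx]
        acts <- mlp_forward(weights, xb)
        m <- length(idx)
        # d(BCE)/dz at sigmoid output
        delta <- (acts[[n_layer + 1L]] - yb) / m
        for (i in rev(seq_len(n_layer))) {
          gW <- crossprod(acts[[i]], delta)
          gb <- colSums(delta)
          if (i > 1L) {
            delta <- (delta %*% t(weights[[i]]$W)) * (acts[[i]] > 0)
          }
          cache[[i]]$W <- rho * cache[[i]]$W + (1 - rho) * gW^2
          cache[[i]]$b <- rho * cache[[i]]$b + (1 - rho) * gb^2
          weights[[i]]$W <- weights[[i]]$W -
            learning_rate * gW / (sqrt(cache[[i]]$W) + eps)
          weights[[i]]$b <- weights[[i]]$b -
            learning_rate * gb / (sqrt(cache[[i]]$b) + eps)
        }
      }
    }
    structure(
      list(weights = weights, center = center, scale = scale_,
           hidden = hidden),
      class = "mlp_model"
    )
  })
}

mlp_predict <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  acts <- mlp_forward(model$weights, xs)
  as.numeric(acts[[length(acts)]])
}

# Run `code` under a temporary RNG state so callers' streams are untouched.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
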