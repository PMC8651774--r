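# Minimal fully-connected network used as the fusion head: ReLU hidden
# layers, softmax cross-entropy output, inverted dropout on the hidden
# activations during training, full-batch Adam. Written in plain matrix
# algebra; sizes here are tiny (40 -> 64 -> 20 -> K), so this is fast.

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    L <- length(sizes) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], 0,
                             sqrt(2 / sizes[l])), sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    list(W = W, b = b, sizes = sizes)
  })
}

mlp_forward <- function(model, X, dropout = 0, train = FALSE) {
  L <- length(model$W)
  A <- list(X)
  masks <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    Z <- sweep(H %*% model$W[[l]], 2, model$b[[l]], `+`)
    if (l < L) {
      H <- pmax(Z, 0)
      if (train && dropout > 0) {
        m <- matrix(stats::rbinom(length(H), 1, 1 - dropout) / (1 - dropout),
                    nrow(H), ncol(H))
        H <- H * m
        masks[[l]] <- m
      }
    } else {
      H <- Z
    }
    A[[l + 1L]] <- H
  }
  list(A = A, masks = masks, logits = H)
}

mlp_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# y: integer class labels 1..K. Returns the trained model.
mlp_train <- function(X, y, sizes, epochs = 300L, lr = 1e-3, dropout = 0.5,
                      seed = 1L) {
  K <- sizes[length(sizes)]
  n <- nrow(X)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  model <- mlp_init(sizes, seed)
  L <- length(model$W)
  mW <- lapply(model$W, function(w) w * 0); vW <- mW
  mb <- lapply(model$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      fw <- mlp_forward(model, X, dropout = dropout, train = TRUE)
      P <- mlp_softmax(fw$logits)
      delta <- (P - Y) / n
      for (l in rev(seq_len(L))) {
        gW <- t(fw$A[[l]]) %*% delta
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(model$W[[l]])
          if (!is.null(fw$masks[[l - 1L]])) delta <- delta * fw$masks[[l - 1L]]
          delta <- delta * (fw$A[[l]] > 0)
        }
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
        corr1 <- 1 - b1^ep; corr2 <- 1 - b2^ep
        model$W[[l]] <- model$W[[l]] -
          lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        model$b[[l]] <- model$b[[l]] -
          lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
  })
  model
}

mlp_predict_proba <- function(model, X) {
  mlp_softmax(mlp_forward(model, X)$logits)
}
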