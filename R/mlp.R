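## Minimal fully connected feed-forward regressor: ReLU hidden layers with
## inverted dropout, a single linear output, mean-squared-error loss, and
## Adam updates over shuffled mini-batches. Written in plain matrix algebra;
## deterministic under a fixed seed and single-threaded BLAS.

mlp_init <- function(n_in, hidden, seed) {
  with_seed(seed, {
    dims <- c(n_in, hidden, 1L)
    w <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(w)) {
      # He initialization, suited to ReLU units
      w[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                    sd = sqrt(2 / dims[l])),
                       dims[l], dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
    structure(list(w = w, b = b, hidden = hidden, n_in = n_in,
                   losses = numeric()), class = "mlp")
  })
}

mlp_forward <- function(model, x, dropout = 0, training = FALSE) {
  nl <- length(model$w)
  a <- vector("list", nl)   # a[[l]] is the input to layer l
  a[[1L]] <- x
  h <- x
  for (l in seq_len(nl - 1L)) {
    z <- sweep(h %*% model$w[[l]], 2L, model$b[[l]], "+")
    h <- pmax(z, 0)
    if (training && dropout > 0) {
      m <- matrix(stats::runif(length(h)) >= dropout, nrow(h), ncol(h))
      h <- h * m / (1 - dropout)
    }
    if (l + 1L <= nl) a[[l + 1L]] <- h
  }
  out <- sweep(h %*% model$w[[nl]], 2L, model$b[[nl]], "+")
  list(pred = out[, 1L], a = a)
}

#' Train a fully connected regressor
#'
#' @param x Numeric feature matrix (rows = examples); standardize
#'   mixed-scale columns beforehand (see [train_gate_model()]).
#' @param y Numeric label vector (finite).
#' @param hidden Integer vector of hidden-layer widths.
#' @param epochs Number of full passes over the data (0 returns the
#'   initialized, untrained network).
#' @param batch_size Mini-batch size (capped at `nrow(x)`).
#' @param learning_rate Adam step size.
#' @param dropout Dropout probability on hidden activations, in `[0, 0.5]`.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout masks.
#' @return Object of class `mlp`; `$losses` records the per-epoch mean
#'   squared training loss.
#' @export
mlp_train <- function(x, y, hidden = c(64L, 32L), epochs = 30L,
                      batch_size = 32L, learning_rate = 1e-3, dropout = 0,
                      seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), nrow(x) >= 1L, all(is.finite(y)),
            dropout >= 0, dropout <= 0.5, epochs >= 0L)
  model <- mlp_init(ncol(x), hidden, derive_seed(seed, "mlp_init"))
  if (epochs == 0L) return(model)
  nl <- length(model$w)
  zero_like <- function(p) lapply(p, function(q) q * 0)
  mw <- zero_like(model$w); vw <- zero_like(model$w)
  mb <- zero_like(model$b); vb <- zero_like(model$b)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  n <- nrow(x)
  bs <- min(batch_size, n)
  losses <- numeric(epochs)
  with_seed(derive_seed(seed, "mlp_train"), {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1L, n)]
        fw <- mlp_forward(model, x[idx, , drop = FALSE],
                          dropout = dropout, training = TRUE)
        resid <- fw$pred - y[idx]
        ep_loss <- ep_loss + sum(resid^2)
        dz <- matrix(2 * resid / length(idx), ncol = 1L)
        step <- step + 1L
        for (l in rev(seq_len(nl))) {
          dw <- crossprod(fw$a[[l]], dz)
          db <- colSums(dz)
          if (l > 1L) {
            da <- dz %*% t(model$w[[l]])
            # post-dropout ReLU activations are positive iff the unit fired
            # and survived dropout; the inverted-dropout scale must be
            # reapplied on the way back
            dz <- da * (fw$a[[l]] > 0)
            if (dropout > 0) dz <- dz / (1 - dropout)
          }
          mw[[l]] <- b1 * mw[[l]] + (1 - b1) * dw
          vw[[l]] <- b2 * vw[[l]] + (1 - b2) * dw^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * db
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * db^2
          c1 <- 1 - b1^step; c2 <- 1 - b2^step
          model$w[[l]] <- model$w[[l]] -
            learning_rate * (mw[[l]] / c1) / (sqrt(vw[[l]] / c2) + eps)
          model$b[[l]] <- model$b[[l]] -
            learning_rate * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
        }
      }
      losses[ep] <- ep_loss / n
      if (!is.finite(losses[ep])) {
        stop("non-finite training loss at epoch ", ep)
      }
    }
  })
  model$losses <- losses
  model
}

#' Predict with a trained regressor
#'
#' @param object An `mlp` model.
#' @param x Feature matrix with `object$n_in` columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mlp <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$n_in) {
    stop("feature width ", ncol(x), " does not match model input ",
         object$n_in)
  }
  mlp_forward(object, x)$pred
}
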