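## Per-gate ensembles of feed-forward regressors predicting log2 enrichment
## ratios from one-hot + embedding features.

## Published per-gate optima of the random hyperparameter search.
GATE_DEFAULTS <- list(
  HI      = list(hidden_layers = c(64L, 32L, 32L, 32L), batch_size = 256L,
                 epochs = 50L, learning_rate = 1e-3, dropout = 0.1),
  WT_GATE = list(hidden_layers = c(64L, 32L, 32L), batch_size = 32L,
                 epochs = 30L, learning_rate = 1e-3, dropout = 0.3),
  SL      = list(hidden_layers = c(64L, 64L, 32L, 32L), batch_size = 32L,
                 epochs = 20L, learning_rate = 1e-3, dropout = 0.1),
  LO      = list(hidden_layers = c(64L, 64L, 32L, 32L, 32L), batch_size = 32L,
                 epochs = 30L, learning_rate = 1e-3, dropout = 0.2))

#' Model configuration for one gate
#'
#' Defaults are the selected architecture and hyperparameters per gate:
#' HI `[64,32,32,32]`, batch 256, 50 epochs, dropout 0.1; WT-like
#' `[64,32,32]`, batch 32, 30 epochs, dropout 0.3; SL `[64,64,32,32]`,
#' batch 32, 20 epochs, dropout 0.1; LO `[64,64,32,32,32]`, batch 32,
#' 30 epochs, dropout 0.2; learning rate 1e-3 throughout.
#'
#' @param gate One of `r paste(GATES, collapse = ", ")`.
#' @param hidden_layers Integer vector of hidden widths (overrides the
#'   gate default).
#' @param dropout,batch_size,epochs,learning_rate Training
#'   hyperparameters (override the gate defaults).
#' @param n_seeds Ensemble size (independent initializations; default 10).
#' @return Object of class `model_config`.
#' @export
model_config <- function(gate, hidden_layers = NULL, dropout = NULL,
                         batch_size = NULL, epochs = NULL,
                         learning_rate = NULL, n_seeds = 10L) {
  stopifnot(gate %in% GATES)
  d <- GATE_DEFAULTS[[gate]]
  cfg <- list(gate = gate,
              hidden_layers = if (is.null(hidden_layers)) d$hidden_layers
                              else as.integer(hidden_layers),
              dropout = if (is.null(dropout)) d$dropout else dropout,
              batch_size = if (is.null(batch_size)) d$batch_size
                           else as.integer(batch_size),
              epochs = if (is.null(epochs)) d$epochs else as.integer(epochs),
              learning_rate = if (is.null(learning_rate)) d$learning_rate
                              else learning_rate,
              n_seeds = as.integer(n_seeds))
  stopifnot(length(cfg$hidden_layers) >= 1L, cfg$dropout >= 0,
            cfg$dropout <= 0.5, cfg$n_seeds >= 1L, cfg$epochs >= 0L)
  structure(cfg, class = "model_config")
}

## trainable parameter count of an architecture
mlp_param_count <- function(n_in, hidden) {
  dims <- c(n_in, hidden, 1L)
  sum(dims[-length(dims)] * dims[-1L]) + sum(dims[-1L])
}

#' Train one ensemble member for a gate
#'
#' Embedding feature columns are z-scored using training-set statistics
#' (stored with the member and reapplied at prediction time); one-hot
#' columns stay binary. The network is trained for exactly `cfg$epochs`
#' epochs minimizing mean squared error.
#'
#' @param features Feature matrix from [build_feature_matrix()] (its
#'   `embed_cols` attribute marks the embedding block).
#' @param labels Numeric log2 enrichment ratios (finite).
#' @param cfg A [model_config()].
#' @param seed Integer seed for this member.
#' @return Object of class `gate_member`.
#' @export
train_gate_model <- function(features, labels, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  ec <- attr(features, "embed_cols")
  if (is.null(ec)) ec <- integer()
  x <- as.matrix(features)
  center <- numeric(ncol(x)); scale <- rep(1, ncol(x))
  if (length(ec)) {
    center[ec] <- colMeans(x[, ec, drop = FALSE])
    s <- apply(x[, ec, drop = FALSE], 2L, stats::sd)
    scale[ec] <- ifelse(s > 0, s, 1)
    x[, ec] <- sweep(sweep(x[, ec, drop = FALSE], 2L, center[ec]), 2L,
                     scale[ec], "/")
  }
  net <- mlp_train(x, labels, hidden = cfg$hidden_layers,
                   epochs = cfg$epochs, batch_size = cfg$batch_size,
                   learning_rate = cfg$learning_rate, dropout = cfg$dropout,
                   seed = seed)
  structure(list(net = net, center = center, scale = scale,
                 embed_cols = ec, cfg = cfg, seed = seed),
            class = "gate_member")
}

#' @export
predict.gate_member <- function(object, features, ...) {
  x <- as.matrix(features)
  ec <- object$embed_cols
  if (length(ec)) {
    x[, ec] <- sweep(sweep(x[, ec, drop = FALSE], 2L, object$center[ec]), 2L,
                     object$scale[ec], "/")
  }
  predict(object$net, x)
}

#' Train the seed ensemble for one gate
#'
#' `cfg$n_seeds` members with independent initializations; member seeds are
#' derived deterministically from `seed`.
#'
#' @inheritParams train_gate_model
#' @param seed Master seed of the ensemble.
#' @return Object of class `gate_ensemble`.
#' @export
train_gate_ensemble <- function(features, labels, cfg, seed = 1L) {
  members <- lapply(seq_len(cfg$n_seeds), function(s) {
    train_gate_model(features, labels, cfg,
                     seed = derive_seed(seed, paste0(cfg$gate, ":member", s)))
  })
  structure(list(gate = cfg$gate, cfg = cfg, members = members,
                 n_train = nrow(features), seed = seed),
            class = "gate_ensemble")
}

#' Ensemble predictions with uncertainty
#'
#' @param ensemble A [train_gate_ensemble()] result.
#' @param features Feature matrix (same width as at training).
#' @return List with `mean` and `sd` (numeric vectors; `sd` is 0 for a
#'   single-member ensemble) and `members` (matrix, one column per member).
#' @export
predict_ensemble <- function(ensemble, features) {
  stopifnot(inherits(ensemble, "gate_ensemble"))
  preds <- vapply(ensemble$members, predict, numeric(nrow(features)),
                  features = features)
  preds <- matrix(preds, nrow = nrow(features),
                  dimnames = list(rownames(features), NULL))
  list(mean = rowMeans(preds),
       sd = if (ncol(preds) == 1L) rep(0, nrow(preds))
            else apply(preds, 1L, stats::sd),
       members = preds)
}

#' Default random-search space for the gate regressors
#' @return List of candidate values per hyperparameter.
#' @export
default_search_space <- function() {
  list(batch_size = c(32L, 64L, 128L, 256L, 512L),
       epochs = c(10L, 20L, 30L, 40L, 50L),
       learning_rate = c(1e-5, 1e-4, 5e-4, 1e-3),
       n_layers = c(3L, 4L, 5L),
       layer_width = c(32L, 64L, 128L, 256L),
       dropout = c(0, 0.1, 0.2, 0.3, 0.4, 0.5))
}

#' Random hyperparameter search for one gate
#'
#' Samples `n_trials` configurations from the search space, trains a
#' single-member model per trial on the training split, and selects the
#' configuration with the highest Pearson correlation on the validation
#' split. Ties are broken by lower parameter count, then sampling order.
#'
#' @param x_train,y_train,x_val,y_val Disjoint train/validation splits.
#' @param gate Gate label (stored in the returned configuration).
#' @param n_trials Number of sampled configurations (>= 1).
#' @param seed Integer seed; the same seed reproduces the trial list.
#' @param search_space As [default_search_space()].
#' @param n_seeds Ensemble size recorded in the winning configuration.
#' @return List with `best` (a [model_config()]) and `trials` (data.frame
#'   with per-trial hyperparameters, validation Pearson r and parameter
#'   count).
#' @export
hyperparameter_search <- function(x_train, y_train, x_val, y_val,
                                  gate = "HI", n_trials = 20L, seed = 1L,
                                  search_space = default_search_space(),
                                  n_seeds = 10L) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  # safe uniform draw (sample() would misread a length-1 candidate set)
  draw <- function(v, n = 1L) v[sample.int(length(v), n, replace = TRUE)]
  trials <- with_seed(derive_seed(seed, "hyperparameter_search"), {
    lapply(seq_len(n_trials), function(i) {
      nl <- draw(search_space$n_layers)
      list(hidden_layers = draw(search_space$layer_width, nl),
           batch_size = draw(search_space$batch_size),
           epochs = draw(search_space$epochs),
           learning_rate = draw(search_space$learning_rate),
           dropout = draw(search_space$dropout))
    })
  })
  r_val <- numeric(n_trials); n_par <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    tr <- trials[[i]]
    cfg <- model_config(gate, hidden_layers = tr$hidden_layers,
                        dropout = tr$dropout, batch_size = tr$batch_size,
                        epochs = tr$epochs, learning_rate = tr$learning_rate,
                        n_seeds = 1L)
    member <- train_gate_model(x_train, y_train, cfg,
                               seed = derive_seed(seed, paste0("trial", i)))
    p <- predict(member, x_val)
    r_val[i] <- if (stats::sd(p) > 0) stats::cor(p, y_val) else -Inf
    n_par[i] <- mlp_param_count(ncol(x_train), tr$hidden_layers)
  }
  ord <- order(-r_val, n_par, seq_len(n_trials))
  best_i <- ord[1L]
  tr <- trials[[best_i]]
  best <- model_config(gate, hidden_layers = tr$hidden_layers,
                       dropout = tr$dropout, batch_size = tr$batch_size,
                       epochs = tr$epochs, learning_rate = tr$learning_rate,
                       n_seeds = n_seeds)
  trials_df <- data.frame(
    trial = seq_len(n_trials),
    hidden = vapply(trials, function(t) paste(t$hidden_layers,
                                              collapse = "-"), character(1)),
    batch_size = vapply(trials, `[[`, integer(1), "batch_size"),
    epochs = vapply(trials, `[[`, integer(1), "epochs"),
    learning_rate = vapply(trials, `[[`, numeric(1), "learning_rate"),
    dropout = vapply(trials, `[[`, numeric(1), "dropout"),
    val_pearson = r_val, n_params = n_par,
    selected = seq_len(n_trials) == best_i)
  list(best = best, trials = trials_df)
}
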