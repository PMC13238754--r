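# shared small training problem: linear function of one-hot features
make_linear_problem <- function(n_singles = 80L, n_doubles = 250L,
                                seed = 1L) {
  uni <- enumerate_variant_space(default_cfg)
  set.seed(seed)
  ids <- c("WT", sample(uni$variant_id[uni$n_sub == 1L], n_singles),
           sample(uni$variant_id[uni$n_sub == 2L], n_doubles))
  x <- build_feature_matrix(ids, hash_embedding_provider(16L), default_cfg)
  w <- rnorm(240L, 0, 0.5)
  list(ids = ids, x = x, y = as.numeric(x[, 1:240] %*% w))
}

test_that("the regressor fits constant and planted-linear labels", {
  prob <- make_linear_problem(seed = 3L)
  cfg <- model_config("SL", epochs = 40L, dropout = 0, n_seeds = 1L)
  member <- train_gate_model(prob$x, prob$y, cfg, seed = 11L)
  expect_gt(cor(predict(member, prob$x), prob$y), 0.95)

  const <- train_gate_model(prob$x[1:60, ], rep(2.5, 60L),
                            model_config("HI", epochs = 80L, batch_size = 16L,
                                         dropout = 0, n_seeds = 1L),
                            seed = 2L)
  expect_lt(max(abs(predict(const, prob$x[1:60, ]) - 2.5)), 0.5)
})

test_that("training is deterministic under a fixed seed", {
  prob <- make_linear_problem(n_singles = 40L, n_doubles = 60L, seed = 5L)
  cfg <- model_config("WT_GATE", epochs = 5L, n_seeds = 1L)
  m1 <- train_gate_model(prob$x, prob$y, cfg, seed = 7L)
  m2 <- train_gate_model(prob$x, prob$y, cfg, seed = 7L)
  expect_identical(predict(m1, prob$x), predict(m2, prob$x))
  m3 <- train_gate_model(prob$x, prob$y, cfg, seed = 8L)
  expect_false(identical(predict(m1, prob$x), predict(m3, prob$x)))
})

test_that("zero epochs yield a finite untrained network", {
  prob <- make_linear_problem(n_singles = 20L, n_doubles = 20L, seed = 2L)
  m <- train_gate_model(prob$x, prob$y,
                        model_config("HI", epochs = 0L, n_seeds = 1L),
                        seed = 1L)
  expect_true(all(is.finite(predict(m, prob$x))))
})

test_that("a divergent optimizer run reports the failing epoch", {
  prob <- make_linear_problem(n_singles = 20L, n_doubles = 20L, seed = 2L)
  expect_error(
    mlp_train(prob$x * 1e200, prob$y * 1e200, hidden = c(32L, 16L, 16L),
              epochs = 3L, learning_rate = 1e-3, seed = 1L),
    "epoch")
})

test_that("ensemble predictions are the member mean with seed spread", {
  prob <- make_linear_problem(n_singles = 30L, n_doubles = 50L, seed = 4L)
  cfg <- model_config("SL", epochs = 8L, n_seeds = 4L)
  ens <- train_gate_ensemble(prob$x, prob$y, cfg, seed = 6L)
  pr <- predict_ensemble(ens, prob$x)
  # brute-force averaging oracle over the individual members
  manual <- sapply(ens$members, predict, features = prob$x)
  expect_equal(pr$mean, rowMeans(manual))
  expect_equal(pr$sd, apply(manual, 1L, sd))
  expect_true(all(pr$sd >= 0))

  one <- train_gate_ensemble(prob$x, prob$y,
                             model_config("SL", epochs = 2L, n_seeds = 1L),
                             seed = 6L)
  expect_equal(predict_ensemble(one, prob$x)$sd, rep(0, nrow(prob$x)))
})

test_that("feature width mismatches are refused", {
  prob <- make_linear_problem(n_singles = 20L, n_doubles = 20L, seed = 2L)
  m <- train_gate_model(prob$x, prob$y,
                        model_config("HI", epochs = 1L, n_seeds = 1L))
  expect_error(predict(m$net, prob$x[, 1:100]), "feature width")
})

test_that("ensemble averaging is more stable than single members", {
  prob <- make_linear_problem(n_singles = 60L, n_doubles = 120L, seed = 9L)
  cfg <- model_config("WT_GATE", epochs = 6L, n_seeds = 5L)
  # repeated full retrains under different master seeds
  runs <- lapply(1:4, function(s) {
    pr <- predict_ensemble(
      train_gate_ensemble(prob$x, prob$y, cfg, seed = 100L + s), prob$x)
    list(mean = pr$mean, single = pr$members[, 1L])
  })
  across <- function(get) {
    m <- sapply(runs, get)
    mean(apply(m, 1L, var))
  }
  expect_lt(across(function(r) r$mean), across(function(r) r$single))
})

test_that("random hyperparameter search selects by validation correlation", {
  prob <- make_linear_problem(n_singles = 60L, n_doubles = 140L, seed = 10L)
  itr <- 1:150; ival <- 151:200
  expect_error(hyperparameter_search(prob$x[itr, ], prob$y[itr],
                                     prob$x[ival, ], prob$y[ival],
                                     n_trials = 0L), "n_trials")
  # a one-point search space returns its only configuration
  space1 <- list(batch_size = 32L, epochs = 10L, learning_rate = 1e-3,
                 n_layers = 3L, layer_width = 32L, dropout = 0)
  hs <- hyperparameter_search(prob$x[itr, ], prob$y[itr], prob$x[ival, ],
                              prob$y[ival], n_trials = 2L, seed = 3L,
                              search_space = space1)
  expect_equal(hs$best$hidden_layers, rep(32L, 3L))
  expect_equal(hs$best$epochs, 10L)

  # same seed reproduces the sampled trial list exactly
  h1 <- hyperparameter_search(prob$x[itr, ], prob$y[itr], prob$x[ival, ],
                              prob$y[ival], n_trials = 3L, seed = 5L)
  h2 <- hyperparameter_search(prob$x[itr, ], prob$y[itr], prob$x[ival, ],
                              prob$y[ival], n_trials = 3L, seed = 5L)
  expect_identical(h1$trials, h2$trials)
  expect_equal(sum(h1$trials$selected), 1L)
  # the winner is the trial with the best validation correlation
  expect_equal(which(h1$trials$selected),
               order(-h1$trials$val_pearson, h1$trials$n_params)[1L])
})

test_that("an adequately trained config beats an untrained one on validation", {
  prob <- make_linear_problem(n_singles = 60L, n_doubles = 140L, seed = 12L)
  itr <- 1:150; ival <- 151:200
  space <- list(batch_size = 32L, epochs = c(1L, 30L), learning_rate = 1e-3,
                n_layers = 3L, layer_width = c(32L, 64L), dropout = 0)
  hs <- hyperparameter_search(prob$x[itr, ], prob$y[itr], prob$x[ival, ],
                              prob$y[ival], n_trials = 8L, seed = 2L,
                              search_space = space)
  expect_equal(hs$best$epochs, 30L)
})
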