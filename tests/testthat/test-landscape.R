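# a tiny trained four-gate setup shared by the landscape tests
make_tiny_ensembles <- function(n_seeds = 2L, epochs = 4L, seed = 1L,
                                n_train = 120L) {
  uni <- enumerate_variant_space(default_cfg)
  set.seed(seed)
  ids <- c("WT", sample(uni$variant_id[uni$n_sub == 1L], 50L),
           sample(uni$variant_id[uni$n_sub == 2L], n_train))
  prov <- hash_embedding_provider(8L)
  x <- build_feature_matrix(ids, prov, default_cfg)
  w <- rnorm(240L, 0, 0.3)
  ensembles <- setNames(lapply(GATES, function(g) {
    y <- as.numeric(x[, 1:240] %*% w) + rnorm(length(ids), 0, 0.05)
    train_gate_ensemble(x, y,
                        model_config(g, epochs = epochs, n_seeds = n_seeds),
                        seed = derive_seed(seed, g))
  }), GATES)
  list(ensembles = ensembles, provider = prov, ids = ids)
}

test_that("double-mutant cycle epistasis follows its defining identity", {
  expect_equal(epistasis(-2.382, -1.042, -1.681), -1.743)
  expect_equal(epistasis(1.3, -0.4, 1.3 + -0.4), 0)
  expect_equal(epistasis(0, 0, 2.5), -2.5)
  # invariant to the labelling of the two substitutions
  expect_equal(epistasis(-2.382, -1.042, -1.681),
               epistasis(-1.042, -2.382, -1.681))
})

test_that("the landscape is assembled seed-wise and matches a manual oracle", {
  tiny <- make_tiny_ensembles()
  co <- calibration_preset()
  vars <- c("WT", "K15Y", "R39A", "K15Y_R39A")
  land <- build_landscape(tiny$ensembles, co, variants = vars,
                          provider = tiny$provider, cfg = default_cfg)
  expect_equal(land$variant_id[1:4], vars)
  wt <- land[land$variant_id == "WT", ]
  expect_equal(wt$ddg_mean, 0)
  expect_equal(wt$ddg_sd, 0)
  expect_true(is.na(wt$epsilon_mean))

  # manual recomputation straight from the member networks
  feats <- build_feature_matrix(vars, tiny$provider, default_cfg)
  n_seeds <- 2L
  ddg <- sapply(seq_len(n_seeds), function(s) {
    l2 <- sapply(c("HI", "SL", "WT_GATE", "LO"), function(g) {
      predict(tiny$ensembles[[g]]$members[[s]], feats)
    })
    raw <- apply_calibration(co, l2)
    raw - raw[1L]  # anchor to WT
  })
  eps <- ddg[2L, ] + ddg[3L, ] - ddg[4L, ]
  i <- match("K15Y_R39A", land$variant_id)
  expect_equal(land$ddg_mean[i], mean(ddg[4L, ]))
  expect_equal(land$ddg_sd[i], sd(ddg[4L, ]))
  expect_equal(land$epsilon_mean[i], mean(eps))
  expect_equal(land$epsilon_sd[i], sd(eps))
})

test_that("missing component singles are added and seed counts must agree", {
  tiny <- make_tiny_ensembles()
  land <- build_landscape(tiny$ensembles, calibration_preset(),
                          variants = "K15Y_R39A",
                          provider = tiny$provider, cfg = default_cfg)
  expect_setequal(land$variant_id, c("K15Y_R39A", "WT", "K15Y", "R39A"))
  expect_false(anyNA(land$epsilon_mean[land$n_sub == 2L]))

  bad <- tiny$ensembles
  bad$LO$cfg$n_seeds <- 5L
  expect_error(build_landscape(bad, calibration_preset(),
                               variants = "K15Y", provider = tiny$provider,
                               cfg = default_cfg), "same number of seeds")
})

test_that("a single-seed landscape has zero spread", {
  tiny <- make_tiny_ensembles(n_seeds = 1L, epochs = 2L)
  land <- build_landscape(tiny$ensembles, calibration_preset(),
                          variants = c("WT", "K15Y", "K15Y_R39A"),
                          provider = tiny$provider, cfg = default_cfg)
  expect_true(all(land$ddg_sd == 0))
  expect_true(all(land$epsilon_sd[land$n_sub == 2L] == 0))
})

test_that("epistasis is invariant to a constant shift of the calibration", {
  tiny <- make_tiny_ensembles()
  co <- calibration_preset()
  shifted <- co
  shifted["bias"] <- co["bias"] + 5
  vars <- c("WT", "K15Y", "R39A", "K15Y_R39A", "T11A", "T11A_V34P", "V34P")
  l1 <- build_landscape(tiny$ensembles, co, variants = vars,
                        provider = tiny$provider, cfg = default_cfg)
  l2 <- build_landscape(tiny$ensembles, shifted, variants = vars,
                        provider = tiny$provider, cfg = default_cfg)
  # WT anchoring cancels any global additive offset entirely
  expect_equal(l1$ddg_mean, l2$ddg_mean)
  expect_equal(l1$epsilon_mean, l2$epsilon_mean)
})

test_that("pair averages are symmetric and complete", {
  uni <- enumerate_variant_space(default_cfg)
  entries <- uni
  entries$ddg_mean <- 1
  entries$epsilon_mean <- NA_real_
  d <- entries$n_sub == 2L
  entries$epsilon_mean[d] <- ifelse(entries$pos1[d] == 11L &
                                      entries$pos2[d] == 13L, 2, 0)
  pa <- pair_averages(entries)
  expect_equal(nrow(pa), 66L)
  expect_equal(pa$n, rep(361L, 66L))
  expect_equal(pa$mean_epsilon[pa$pos_i == 11L & pa$pos_j == 13L], 2)
  expect_equal(sum(pa$mean_epsilon != 0), 1L)
  m <- pair_matrix(pa, "mean_epsilon")
  expect_equal(m, t(m))
  expect_equal(m["11", "13"], m["13", "11"])
})

test_that("gate-position frequencies expose planted hotspots", {
  # plant a landscape, find the position whose substitutions are most
  # deleterious on average, and check it is over-represented in LO vs HI
  land <- plant_landscape(default_cfg, seed = 17L)
  uni <- land$universe
  s <- uni[uni$n_sub == 1L, ]
  pos_mean <- tapply(s$ddg_true, s$pos1, mean)
  hotspot <- as.integer(names(which.max(pos_mean)))
  sc <- simulation_config(n_variants = 229L, presort_reads = 30000L,
                          reads_per_gate = 15000L,
                          corrupted_read_fraction = 0, seed = 17L)
  sim <- simulate_sort(land, gate_binning_model(), sc)
  tbl <- count_variants(sim$reads, default_cfg)
  gpf <- gate_position_frequency(tbl)
  expect_true(all(gpf$frequency >= 0 & gpf$frequency <= 1))
  f_lo <- gpf$frequency[gpf$gate == "LO" & gpf$position == hotspot]
  f_hi <- gpf$frequency[gpf$gate == "HI" & gpf$position == hotspot]
  expect_gt(f_lo, f_hi)
})
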