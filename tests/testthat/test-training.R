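test_that("an epoch visits every bin exactly once with observed-track pairing", {
  bins <- data.frame(chrom = "chrT", bin = 0:3)
  tracks <- data.frame(cell = c("c1", "c2"), assay = c("a1", "a1"))
  ep <- sample_epoch(bins, tracks, seed = 3L)
  expect_equal(nrow(ep), 4L)
  expect_setequal(ep$bin, 0:3)
  expect_true(all(paste(ep$cell, ep$assay) %in% paste(tracks$cell, tracks$assay)))
  # determinism
  expect_identical(ep, sample_epoch(bins, tracks, seed = 3L))
  expect_false(identical(ep, sample_epoch(bins, tracks, seed = 4L)))
  expect_error(sample_epoch(bins, tracks[0, ], seed = 1L), "no observed tracks")
})

test_that("track sampling is uniform over observed tracks", {
  bins <- data.frame(chrom = "chrT", bin = 0L)
  tracks <- data.frame(cell = c("c1", "c2"), assay = c("a1", "a1"))
  picks <- vapply(seq_len(10000L), function(i) {
    sample_epoch(bins, tracks, seed = i)$cell
  }, character(1))
  freq <- mean(picks == "c1")
  expect_gt(freq, 0.48)
  expect_lt(freq, 0.52)
})

test_that("track folds partition tracks with near-equal sizes, seeded", {
  tracks <- data.frame(cell = rep(sprintf("c%d", 1:5), each = 2),
                       assay = rep(c("a1", "a2"), 5))
  f <- make_track_folds(tracks, k = 5L, seed = 2L)
  expect_identical(sort(unique(f$fold)), 1:5)
  expect_true(all(table(f$fold) == 2L))
  expect_identical(f, make_track_folds(tracks, k = 5L, seed = 2L))
  f2 <- make_track_folds(tracks[1:7, ], k = 3L, seed = 2L)
  expect_lte(diff(range(table(f2$fold))), 1L)
  expect_error(make_track_folds(tracks[1:3, ], k = 5L), "exceeds")
})

test_that("initialization honors the uniform and Glorot ranges, seeded", {
  cfg <- model_config(16L, 16L, 8L, 8L, 8L, n_hidden_layers = 2L,
                      n_hidden_units = 64L)
  g <- tiny_grid(50000)
  m <- initialize_model(new_epi_model(cfg, g, sprintf("c%d", 1:40),
                                      sprintf("a%d", 1:40)), seed = 4L)
  emb <- c(m$factors$cell, m$factors$assay, m$factors$genome$chrT$g25,
           m$factors$genome$chrT$g250, m$factors$genome$chrT$g5k)
  expect_gte(min(emb), -0.5)
  expect_lte(max(emb), 0.5)
  expect_lt(abs(mean(emb)), 0.005)
  lim1 <- sqrt(6 / (input_width(cfg) + 64))
  W1 <- m$dnn$layers[[1L]]$W
  expect_lte(max(abs(W1)), lim1)
  expect_identical(m$dnn$layers[[1L]]$b, numeric(64L))
  m2 <- initialize_model(new_epi_model(cfg, g, sprintf("c%d", 1:40),
                                       sprintf("a%d", 1:40)), seed = 4L)
  expect_identical(m, m2)
})

test_that("a zero learning rate leaves every parameter unchanged", {
  m <- toy_model()
  batch <- data.frame(chrom = "chrT", bin = 0:9, cell = "c1", assay = "a1",
                      value = stats::runif(10))
  step <- train_step(m, batch, config = training_config(learning_rate = 0))
  expect_identical(step$model$factors, m$factors)
  expect_identical(step$model$dnn, m$dnn)
  expect_true(is.finite(step$loss))
})

test_that("the first ADAM step moves a single parameter by about lr", {
  # one-parameter quadratic: model reduced to the output bias, loss
  # (b - y)^2; ADAM's first bias-corrected step is lr * sign(gradient)
  cfg <- model_config(1L, 1L, 1L, 1L, 1L, n_hidden_layers = 1L,
                      n_hidden_units = 1L)
  m <- new_epi_model(cfg, tiny_grid(100), "c", "a")   # all-zero weights
  mask <- trainable_mask(m, cell = FALSE, assay = FALSE, genome = FALSE,
                         dnn = TRUE)
  batch <- data.frame(chrom = "chrT", bin = 0L, cell = "c", assay = "a",
                      value = 5)
  cfg_t <- training_config(learning_rate = 0.01)
  step <- train_step(m, batch, mask = mask, config = cfg_t)
  # gradient on b is 2(b - y) = -10; first step = lr * m_hat/(sqrt(v_hat)+eps)
  expect_equal(step$model$dnn$out$b, 0.01, tolerance = 1e-6)
})

test_that("a full mask makes train_step a no-op on parameters", {
  m <- toy_model()
  mask <- trainable_mask(m, cell = FALSE, assay = FALSE, genome = FALSE,
                         dnn = FALSE)
  batch <- data.frame(chrom = "chrT", bin = 0:9, cell = "c2", assay = "a2",
                      value = stats::runif(10))
  step <- train_step(m, batch, mask = mask)
  expect_identical(step$model$factors, m$factors)
  expect_identical(step$model$dnn, m$dnn)
})

test_that("stage-1 descends and is reproducible; stage-2 freezes bit-exactly", {
  comp <- tiny_compendium()
  cfg <- model_config(4L, 4L, 4L, 3L, 2L, n_hidden_layers = 2L,
                      n_hidden_units = 16L)
  tc <- fast_tconfig()
  m0 <- initialize_model(new_epi_model(cfg, comp$grid, comp$observed$cells,
                                       comp$observed$assays), seed = 5L)
  regions <- data.frame(chrom = "chrT", start_bin = 0L, end_bin = 200L)
  m1 <- fit_stage1(comp$observed, regions, m0, tc)
  ll <- attr(m1, "loss_log")
  expect_lt(ll[length(ll)], ll[1L])
  # all parameter groups moved
  expect_false(identical(m1$factors$cell, m0$factors$cell))
  expect_false(identical(m1$factors$assay, m0$factors$assay))
  expect_false(identical(m1$dnn, m0$dnn))
  # reproducibility
  m1b <- fit_stage1(comp$observed, regions, m0, tc)
  expect_identical(attr(m1b, "loss_log"), attr(m1, "loss_log"))
  expect_identical(m1b$factors, m1$factors)

  m2 <- fit_stage2(comp$observed, "chrT", m1, tc)
  expect_identical(m2$factors$cell, m1$factors$cell)
  expect_identical(m2$factors$assay, m1$factors$assay)
  expect_identical(m2$dnn, m1$dnn)
  expect_false(identical(m2$factors$genome$chrT, m1$factors$genome$chrT))
  expect_error(fit_stage2(comp$observed, "chrZ", m1, tc), "unknown chromosome")
  expect_error(fit_stage1(comp$observed, regions[0, ], m0, tc), "empty")
})

test_that("stage-2 reduces reconstruction error of observed tracks", {
  comp <- tiny_compendium()
  cfg <- model_config(4L, 4L, 8L, 4L, 2L, n_hidden_layers = 2L,
                      n_hidden_units = 32L)
  tc <- fast_tconfig(e1 = 60L, e2 = 60L, seed = 7L, batch_size = 500L)
  m0 <- initialize_model(new_epi_model(cfg, comp$grid, comp$observed$cells,
                                       comp$observed$assays), seed = 7L)
  regions <- data.frame(chrom = "chrT", start_bin = 0L, end_bin = 150L)
  m1 <- fit_stage1(comp$observed, regions, m0, tc)
  obs <- observed_tracks(comp$observed)
  recon_mse <- function(model) {
    mean(vapply(seq_len(nrow(obs)), function(i) {
      truth <- get_track(comp$observed, obs$cell[i], obs$assay[i])$chrT
      mse_global(truth, predict_signal(model, obs$cell[i], obs$assay[i],
                                       "chrT", 0:(length(truth) - 1L)))
    }, numeric(1)))
  }
  m2 <- fit_stage2(comp$observed, "chrT", m1, tc)
  expect_lt(recon_mse(m2), recon_mse(m1))
})

test_that("extending with a twin cell recovers its predictions; old ones frozen", {
  comp <- tiny_compendium()
  cfg <- model_config(4L, 4L, 6L, 3L, 2L, n_hidden_layers = 2L,
                      n_hidden_units = 32L)
  tc <- fast_tconfig(e1 = 80L, e2 = 80L, seed = 8L, batch_size = 500L)
  m0 <- initialize_model(new_epi_model(cfg, comp$grid, comp$observed$cells,
                                       comp$observed$assays), seed = 8L)
  regions <- data.frame(chrom = "chrT", start_bin = 0L, end_bin = 150L)
  m <- fit_model(comp$observed, regions, m0, tc)

  # new "cell" whose single track copies an existing observed track
  obs <- observed_tracks(comp$observed)
  src_cell <- obs$cell[1L]; src_assay <- obs$assay[1L]
  ts_new <- track_set(comp$grid, c(m$cells, "Cnew"), m$assays)
  ts_new <- add_track(ts_new, "Cnew", src_assay,
                      get_track(comp$observed, src_cell, src_assay))
  m_ext <- fit_new_entity(m, ts_new, "Cnew", kind = "cell", config = tc)

  # existing parameters byte-exact, existing predictions unchanged
  expect_identical(m_ext$factors$cell[seq_along(m$cells), , drop = FALSE],
                   m$factors$cell)
  expect_identical(m_ext$factors$assay, m$factors$assay)
  expect_identical(m_ext$dnn, m$dnn)
  expect_identical(m_ext$factors$genome, m$factors$genome)
  bins <- 0:99
  expect_identical(predict_signal(m_ext, src_cell, src_assay, "chrT", bins),
                   predict_signal(m, src_cell, src_assay, "chrT", bins))

  # twin predictions close to the source cell's on the trained assay
  y_src <- predict_signal(m, src_cell, src_assay, "chrT", 0:399)
  y_new <- predict_signal(m_ext, "Cnew", src_assay, "chrT", 0:399)
  expect_lt(mean((y_src - y_new)^2), 0.05)
  expect_error(fit_new_entity(m_ext, ts_new, "Cnew", kind = "cell", config = tc),
               "already registered")
})

test_that("chromosome training order does not change stage-2 results", {
  spec <- synthetic_spec(chrom_lengths = c(cA = 5000, cB = 5000), seed = 6L)
  comp <- make_compendium(spec)
  cfg <- model_config(3L, 3L, 4L, 2L, 2L, n_hidden_layers = 1L,
                      n_hidden_units = 8L)
  tc <- fast_tconfig(e1 = 5L, e2 = 5L, seed = 6L)
  m0 <- initialize_model(new_epi_model(cfg, comp$grid, comp$observed$cells,
                                       comp$observed$assays), seed = 6L)
  regions <- data.frame(chrom = c("cA", "cB"), start_bin = 0L, end_bin = 50L)
  m1 <- fit_stage1(comp$observed, regions, m0, tc)
  ab <- fit_stage2(comp$observed, "cB", fit_stage2(comp$observed, "cA", m1, tc), tc)
  ba <- fit_stage2(comp$observed, "cA", fit_stage2(comp$observed, "cB", m1, tc), tc)
  expect_identical(ab$factors$genome, ba$factors$genome)
})
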