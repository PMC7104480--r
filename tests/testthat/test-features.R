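test_that("feature widths follow the published arithmetic exactly", {
  cfg <- model_config()
  expect_identical(genome_feature_width(cfg), 110L)
  expect_identical(8L * (cfg$n_g25 + cfg$n_g250) + cfg$n_g5k, 565L)
  expect_identical(raw_track_feature_count(), 8112L)
  expect_identical(raw_track_feature_count(1014L, 8L), 8L * 1014L)
})

test_that("windowed factor means average the covered bins", {
  g <- tiny_grid(100000)
  m <- toy_model(g, config = model_config(2L, 2L, 25L, 40L, 45L,
                                          n_hidden_layers = 1L,
                                          n_hidden_units = 4L))
  v <- window_factor_mean(m, "chrT", 50000, half_width = 250)
  expect_length(v, 110L)
  # +/- 250 bp covers exactly 20 bins; check against a direct mean
  bins <- (50000 - 250) %/% 25 + 0:19
  gch <- m$factors$genome$chrT
  direct <- c(colMeans(gch$g25[bins + 1L, ]),
              colMeans(gch$g250[bins %/% 10 + 1L, ]),
              colMeans(gch$g5k[bins %/% 200 + 1L, ]))
  expect_equal(unname(v), unname(direct))
  # constant factors give the constant back
  m2 <- m
  m2$factors$genome$chrT <- lapply(gch, function(x) {x[] <- 0.7; x})
  expect_true(all(window_factor_mean(m2, "chrT", 50000) == 0.7))
  expect_warning(window_factor_mean(m, "chrT", 100, half_width = 250),
                 "clipped")
})

test_that("promoter multi-window features have the 565-column layout", {
  g <- tiny_grid(100000)
  m <- toy_model(g, config = model_config(2L, 2L, 25L, 40L, 45L,
                                          n_hidden_layers = 1L,
                                          n_hidden_units = 4L))
  v <- promoter_multiwindow_features(m, "chrT", 50000, "+")
  expect_length(v, 565L)
  expect_length(grep("^w[1-8]_g25_", names(v)), 200L)
  expect_length(grep("^w[1-8]_g250_", names(v)), 320L)
  expect_length(grep("^g5k_", names(v)), 45L)
  # strand mirrors the window order
  vm <- promoter_multiwindow_features(m, "chrT", 50000, "-")
  expect_equal(unname(vm[paste0("w1_g250_", 1:40)]),
               unname(m$factors$genome$chrT$g250[50000 %/% 250 + 8L, ]))
  # constant factors give a constant vector
  m2 <- m
  m2$factors$genome$chrT <- lapply(m$factors$genome$chrT, function(x) {x[] <- 1.5; x})
  expect_true(all(promoter_multiwindow_features(m2, "chrT", 50000, "+") == 1.5))
  expect_error(promoter_multiwindow_features(m, "chrT", 500, "+"),
               "leaves chromosome")
})

test_that("40-kbp aggregation averages 1600 bins per locus", {
  g <- tiny_grid(100000)   # 4000 bins -> 2.5 loci at 40 kbp
  m <- toy_model(g, config = model_config(2L, 2L, 4L, 3L, 2L,
                                          n_hidden_layers = 1L,
                                          n_hidden_units = 4L))
  A <- aggregate_factors(m, "chrT", resolution = 40000)
  expect_identical(dim(A), c(3L, 9L))
  gch <- m$factors$genome$chrT
  direct <- c(colMeans(gch$g25[1:1600, ]),
              colMeans(gch$g250[rep(1:160, each = 10), ]),
              colMeans(gch$g5k[rep(1:8, each = 200), ]))
  expect_equal(unname(A[1L, ]), unname(direct))
  # terminal partial locus averages its actual 800 bins
  direct_last <- colMeans(gch$g25[3201:4000, ])
  expect_equal(unname(A[3L, 1:4]), unname(direct_last))
  m2 <- m
  m2$factors$genome$chrT <- lapply(gch, function(x) {x[] <- -0.2; x})
  expect_true(all(abs(aggregate_factors(m2, "chrT") + 0.2) < 1e-12))
  expect_error(aggregate_factors(m, "chrT", resolution = 12345), "multiple")
})

test_that("expression labels use a strict threshold on gene-body means", {
  g <- genomic_grid(c(chrT = 500))
  rna <- c(1, 1, 0, 0, 0.5, 0.5, rep(0, 14))
  genes <- data.frame(chrom = "chrT", start = c(0, 100, 200),
                      end = c(50, 150, 250))
  labs <- expression_labels(rna, genes, g)
  expect_identical(labs, c(TRUE, FALSE, FALSE))  # mean exactly 0.5 is inactive
  expect_identical(expression_labels(rep(0, 10), genes, g), rep(FALSE, 3))
  expect_error(expression_labels(rna, data.frame(chrom = "chrT", start = 1,
                                                 end = 1), g), "zero-length")
})

test_that("cv_classify separates separable data and is seeded", {
  set.seed(10)
  n <- 200
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(f1 = as.numeric(y) * 2 + stats::rnorm(n, 0, 0.05),
             f2 = stats::rnorm(n))
  res <- cv_classify(X, y, learner = glm_learner(), k = 10L, seed = 3L)
  expect_gt(res$map, 0.98)
  res2 <- cv_classify(X, y, learner = glm_learner(), k = 10L, seed = 3L)
  expect_identical(res$fold, res2$fold)
  expect_equal(res$ap, res2$ap)
  # shuffled labels fall to roughly the positive rate
  y_shuf <- sample(y)
  res_null <- cv_classify(X, y_shuf, learner = glm_learner(), k = 10L, seed = 3L)
  expect_lt(res_null$map, 0.75)
  expect_gt(res_null$map, 0.25)
})

test_that("cv_classify with a constant scorer gives prevalence-level AP", {
  const_learner <- list(fit = function(X, y, Xv, yv) NULL,
                        score = function(fit, X) rep(0.5, nrow(X)))
  set.seed(11)
  y <- stats::runif(300) < 0.3
  X <- matrix(stats::rnorm(600), ncol = 2)
  res <- cv_classify(X, y, learner = const_learner, k = 10L, seed = 1L)
  # tied scores collapse to one threshold: AP = fold prevalence
  expect_equal(res$map, mean(vapply(seq_len(10L), function(f) {
    mean(y[res$fold == f])
  }, numeric(1))), tolerance = 1e-12)
})

test_that("cv_classify skips folds without positives, with a warning", {
  y <- c(rep(FALSE, 30), TRUE, TRUE, TRUE)
  X <- matrix(stats::rnorm(66), ncol = 2)
  w <- capture_warnings(
    res <- cv_classify(X, y, learner = glm_learner(), k = 8L, seed = 2L))
  expect_true(any(grepl("no positive", w)))
  expect_true(length(res$skipped) >= 1L)
  expect_true(all(is.na(res$ap[res$skipped])))
})

test_that("the PEI harness searches the documented strength grid", {
  grid <- 10^seq(-4, 4, length.out = 10)
  expect_equal(min(grid), 1e-4)
  expect_equal(max(grid), 1e4)
  expect_length(grid, 10L)
  set.seed(12)
  n <- 80
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(as.numeric(y) + stats::rnorm(n, 0, 0.05), stats::rnorm(n))
  res <- cv_pei(X, y, seed = 4L, n_repeats = 2L)
  expect_gt(res$mean_ap, 0.95)
  expect_length(res$strengths, 10L)
  res2 <- cv_pei(X, y, seed = 4L, n_repeats = 2L)
  expect_identical(res$ap, res2$ap)
})

test_that("the gradient-boosted default learner plugs into the harness", {
  set.seed(13)
  n <- 120
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(as.numeric(y) * 3 + stats::rnorm(n, 0, 0.1),
             stats::rnorm(n))
  res <- cv_classify(X, y, learner = xgboost_learner(nrounds = 50L),
                     k = 5L, seed = 5L)
  expect_gt(res$map, 0.95)
})
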