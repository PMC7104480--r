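test_that("global MSE is the mean squared difference", {
  expect_equal(mse_global(c(0, 2), c(1, 1)), 1)
  x <- stats::runif(50)
  expect_equal(mse_global(x, x), 0)
  p <- sample.int(50)
  expect_equal(mse_global(x[p], (x + 0.3)[p]), mse_global(x, x + 0.3))
  expect_error(mse_global(1:3, 1:4), "length")
})

test_that("top-1% MSE selects floor(N/100) positions with index tie-break", {
  set.seed(1)
  obs <- stats::runif(200)
  imp <- stats::runif(200)
  expect_equal(mse_top1(obs, imp, "observed"),
               top1_bruteforce(obs, imp, obs))
  # with unique values exactly 2 of 200 positions enter
  top2 <- order(-obs)[1:2]
  expect_equal(mse_top1(obs, imp, "observed"),
               mean((obs[top2] - imp[top2])^2))
  # symmetric when imputed == observed
  expect_equal(mse_top1(obs, obs, "observed"), mse_top1(obs, obs, "imputed"))
  # monotone transform of observed preserves the observed-ranked selection
  expect_equal(mse_top1(obs, exp(obs), "observed"),
               mse_top1(obs, exp(obs), "imputed"))
  expect_error(mse_top1(stats::runif(99), stats::runif(99)), "at least 100")
})

test_that("region MSE deduplicates bins shared by overlapping regions", {
  g <- genomic_grid(c(chrT = 250))
  obs <- c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9)
  imp <- obs + c(1, rep(0, 8), 2)
  all_regions <- data.frame(chrom = "chrT", start = 0, end = 250)
  expect_equal(mse_regions(obs, imp, all_regions, g), mse_global(obs, imp))
  one_bin <- data.frame(chrom = "chrT", start = 0, end = 25)
  expect_equal(mse_regions(obs, imp, one_bin, g), 1)
  overlapping <- data.frame(chrom = "chrT", start = c(0, 0), end = c(25, 25))
  expect_equal(mse_regions(obs, imp, overlapping, g), 1)
  expect_error(mse_regions(obs, imp, all_regions[0, ], g), "empty")
})

test_that("the six-metric report assembles all MSE variants", {
  g <- tiny_grid(25000)
  set.seed(2)
  obs <- list(chrT = stats::runif(1000, 0, 3))
  imp <- list(chrT = obs$chrT + stats::rnorm(1000, 0, 0.2))
  prom <- data.frame(chrom = "chrT", start = 0, end = 2000)
  gene <- data.frame(chrom = "chrT", start = 2000, end = 12000)
  enh <- data.frame(chrom = "chrT", start = c(15000, 20000),
                    end = c(15500, 20500))
  rep_ <- evaluate_imputation(obs, imp, g, prom, gene, enh)
  expect_named(rep_, c("MSEglobal", "MSE1obs", "MSE1imp", "MSEProm",
                       "MSEGene", "MSEEnh"))
  expect_true(all(unlist(rep_) >= 0))
  expect_equal(rep_$MSEglobal, mse_global(obs$chrT, imp$chrT))
})

test_that("peak-count stratification counts cell types and flags zeros", {
  calls <- list(c1 = c(TRUE, TRUE, FALSE, FALSE),
                c2 = c(TRUE, FALSE, FALSE, FALSE),
                c3 = c(TRUE, TRUE, FALSE, FALSE),
                c4 = c(TRUE, FALSE, FALSE, TRUE))
  s <- stratify_by_peak_count(calls)
  expect_identical(s$count, c(4L, 2L, 0L, 1L))
  expect_identical(s$excluded, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(stratify_by_peak_count(list()), "at least one")
  expect_error(stratify_by_peak_count(list(a = TRUE, b = c(TRUE, FALSE))),
               "inconsistent")
  # no peaks anywhere: everything excluded
  s0 <- stratify_by_peak_count(list(a = rep(FALSE, 5)))
  expect_true(all(s0$excluded))
})

test_that("stratified precision/recall match a brute-force confusion matrix", {
  thr <- asinh(2)
  # hand-built 2-cell, 6-bin fixture
  obs <- list(c1 = c(2.0, 0.1, 1.6, 0.0, 3.0, 0.2),
              c2 = c(1.9, 1.5, 0.1, 0.0, 2.8, 1.5))
  imp <- list(c1 = c(1.8, 0.2, 1.2, 0.1, 2.9, 1.6),
              c2 = c(2.0, 1.6, 0.2, 0.2, 0.3, 0.1))
  calls <- list(c1 = obs$c1 >= thr, c2 = obs$c2 >= thr)
  got <- stratified_prf(obs, imp, calls)
  want <- prf_bruteforce(obs, imp, calls, thr)
  expect_equal(got, want)
  # self-evaluation of consistent signal is perfect in every stratum
  self <- stratified_prf(obs, obs, calls)
  expect_true(all(self$precision == 1))
  expect_true(all(self$recall == 1))
  # all predictions below threshold: recall 0, precision omitted as NA
  low <- lapply(obs, function(x) x * 0)
  degen <- stratified_prf(obs, low, calls)
  expect_true(all(degen$recall == 0))
  expect_true(all(is.na(degen$precision)))
})

test_that("pairwise relationships recover constructed correlations", {
  g <- tiny_grid(25000)
  set.seed(3)
  a <- list(chrT = stats::runif(1000))
  regions <- data.frame(chrom = "chrT",
                        start = seq(0, 24000, by = 1000),
                        end = seq(500, 24500, by = 1000))
  expect_equal(pairwise_relationship(a, a, regions, g), 1)
  b <- list(chrT = -a$chrT + 2)
  expect_equal(pairwise_relationship(a, b, regions, g), -1)
  # independent tracks over many regions decorrelate
  g2 <- genomic_grid(c(chrT = 25 * 4000))
  set.seed(4)
  a2 <- list(chrT = stats::rnorm(4000))
  b2 <- list(chrT = stats::rnorm(4000))
  r1000 <- data.frame(chrom = "chrT", start = (0:999) * 100,
                      end = (0:999) * 100 + 100)
  expect_lt(abs(pairwise_relationship(a2, b2, r1000, g2)), 0.1)
  expect_error(pairwise_relationship(a, a, regions[1:2, ], g), "at least 3")
  # spearman option is invariant to monotone transforms of per-region means
  # (single-bin regions make the means the values themselves)
  bins1 <- data.frame(chrom = "chrT", start = (0:99) * 25, end = (0:99) * 25 + 25)
  c2 <- list(chrT = exp(a$chrT))
  expect_equal(pairwise_relationship(a, c2, bins1, g, method = "spearman"), 1)
  expect_lt(pairwise_relationship(a, c2, bins1, g, method = "pearson"), 1)
})

test_that("average precision follows the step formula with tied thresholds", {
  expect_equal(average_precision(c(TRUE, FALSE), c(0.9, 0.1)), 1)
  expect_equal(average_precision(c(FALSE, TRUE), c(0.9, 0.1)), 0.5)
  # perfect ranking
  expect_equal(average_precision(c(TRUE, TRUE, FALSE, FALSE),
                                 c(4, 3, 2, 1)), 1)
  # tied scores collapse into a single threshold
  expect_equal(average_precision(c(TRUE, FALSE), c(0.5, 0.5)), 0.5)
  expect_equal(average_precision(c(TRUE, FALSE, TRUE, FALSE),
                                 rep(1, 4)), 0.5)
  # invariant under strictly monotone score transforms
  set.seed(5)
  y <- stats::runif(40) < 0.3
  y[1] <- TRUE
  s <- stats::rnorm(40)
  expect_equal(average_precision(y, s), average_precision(y, exp(s)))
  expect_error(average_precision(logical(3), 1:3), "positive")
})
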