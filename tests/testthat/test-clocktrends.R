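test_that("variance explained matches the closed-form R-squared", {
  x <- c(1, 3, 4, 7, 9)
  y <- c(2.1, 2.8, 4.2, 6.9, 8.4)
  expect_equal(variance_explained(y, x), 100 * cor(x, y)^2,
               tolerance = 1e-10)
  # exact linear data
  expect_equal(variance_explained(2 * x - 1, x), 100)
  # constant response: 0 by convention, with a note
  expect_message(r0 <- variance_explained(rep(3, 6), 1:6), "convention")
  expect_equal(r0, 0)
  expect_error(variance_explained(y, rep(5, 5)), "constant")
  expect_error(variance_explained(y[1:4], x[1:4]), "at least 5")
})

test_that("variance explained is invariant to affine rescaling of y", {
  set.seed(31)
  x <- runif(30, 0, 25)
  y <- 1 - 0.4 * x + rnorm(30, sd = 0.8)
  expect_equal(variance_explained(y, x),
               variance_explained(-2.5 * y + 7, x), tolerance = 1e-10)
})

test_that("flat genes explain almost no variance at the cohort size", {
  hits <- vapply(1:50, function(seed) {
    set.seed(seed)
    devA <- c(rep(92, 23), rep(101, 55)) - rnorm(78, 83.3, 3.7)
    y <- rnorm(78, sd = 1)
    variance_explained(y, devA) < 10
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("local linear smoothing reproduces lines and flags empty regions", {
  set.seed(32)
  x <- runif(40, 0, 20)
  # exact reproduction of linear data at every grid point
  y <- 1 + 0.5 * x
  tr <- local_linear_trend(x, y, bandwidth = 2)
  expect_equal(tr$fit, 1 + 0.5 * tr$grid, tolerance = 1e-9)
  # constant data -> constant smooth
  trc <- local_linear_trend(x, rep(4, 40), bandwidth = 2)
  expect_equal(trc$fit, rep(4, nrow(trc)), tolerance = 1e-9)
  # far-away grid points are masked, not extrapolated
  trm <- local_linear_trend(x, y, bandwidth = 0.5,
                            grid = c(5, 10, 1000))
  expect_true(is.na(trm$fit[3]) && !anyNA(trm$fit[1:2]))
})

test_that("each smoothed value equals an independently solved WLS fit", {
  set.seed(33)
  x <- sort(runif(60, 0, 10))
  y <- 0.3 * x^2 - x + rnorm(60, sd = 0.1)
  bw <- 0.8
  grid <- c(2, 5, 8)
  tr <- local_linear_trend(x, y, bandwidth = bw, grid = grid)
  for (i in seq_along(grid)) {
    w <- exp(-(x - grid[i])^2 / (2 * bw^2))
    ref <- lm(y ~ x, weights = w)
    expect_equal(tr$fit[i], unname(predict(ref, data.frame(x = grid[i]))),
                 tolerance = 1e-8)
  }
})

test_that("panels sort stably by developmental age", {
  specs <- list(gene_spec("Rock2", housekeeping = TRUE),
                gene_spec("Ywhaz", housekeeping = TRUE),
                gene_spec("g", slope_devA = -0.2))
  devA <- c(5, 12, 3, 12, NA, 8)
  gp <- gen_expression_panel(ifelse(is.na(devA), 0, devA), specs, seed = 34)
  gp$panel$metadata$devA_h <- devA
  sorted <- sort_by_devA(gp$panel)
  expect_identical(sorted$metadata$devA_h, c(3, 5, 8, 12, 12, NA))
  # stable: the two tied EBs keep their original relative order
  tied <- sorted$metadata$eb_id[sorted$metadata$devA_h %in% 12]
  expect_identical(tied, c("eb002", "eb004"))
  # un-clocked EBs are appended and flagged
  expect_true(sorted$metadata$unclocked[6])
  expect_identical(colnames(sorted$ct), sorted$metadata$eb_id)
  # already sorted input is the identity
  again <- sort_by_devA(sorted)
  expect_identical(colnames(again$ct), colnames(sorted$ct))
  # matches a reference sort of the finite ages
  expect_identical(sorted$metadata$devA_h[1:5], sort(devA[is.finite(devA)]))
})

test_that("threshold choice barely moves a steep curve's onset", {
  # decline far away: crossing times follow the single-logistic closed form
  p <- impulse_params(3000, 0.5, 0.3, 80, 200)
  s <- gen_impulse_series(p, seq(40, 140, by = 1.5), "none")
  res <- threshold_robustness(list(s), thresholds = c(300, 600))
  analytic <- (log(600 / (3000 - 600)) - log(300 / (3000 - 300))) / 0.5
  expect_equal(res$max_mean_spread, analytic, tolerance = 1e-3)
})

test_that("cohort timing is robust to thresholds between 300 and 600", {
  coh <- gen_cohort(cohort_config(n_ebs = 30, seed = 35))
  res <- threshold_robustness(coh$series, thresholds = c(300, 450, 600))
  expect_lt(res$max_mean_spread, 1.5)
  expect_true(all(res$table$n_onset == 30))
  # an absurd threshold yields an empty row, not an error
  res2 <- threshold_robustness(coh$series[1:3], thresholds = c(300, 1e6))
  expect_identical(res2$table$n_onset[2], 0L)
  expect_true(is.na(res2$table$onset_mean[2]))
})

test_that("DevA explains trend genes better than harvest time", {
  set.seed(36)
  onset <- rnorm(78, 83.3, 3.7)
  harvest <- c(rep(92, 23), rep(101, 55))
  devA <- harvest - onset
  specs <- list(gene_spec("Rock2", housekeeping = TRUE),
                gene_spec("Ywhaz", housekeeping = TRUE),
                gene_spec("tight", intercept = 3, slope_devA = -0.3,
                          noise_sd = 0.3),
                gene_spec("flat", intercept = 0, slope_devA = 0,
                          noise_sd = 1))
  gp <- gen_expression_panel(devA, specs, harvest_h = harvest, seed = 36)
  norm <- normalize_neg_ddct(gp$panel, c("Rock2", "Ywhaz"))
  tight <- norm$neg_ddct["tight", ]
  expect_gt(variance_explained(tight, devA),
            variance_explained(tight, harvest))
  # designed trend genes rank above designed flat genes
  expect_gt(variance_explained(tight, devA),
            variance_explained(norm$neg_ddct["flat", ], devA))
})
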