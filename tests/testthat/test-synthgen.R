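test_that("zero-noise series equal the model curve exactly", {
  p <- impulse_params(2500, 0.6, 0.25, 82, 98)
  times <- seq(60, 120, by = 2)
  s <- gen_impulse_series(p, times, "none")
  expect_equal(s$counts, impulse_value(p, times))
  expect_error(gen_impulse_series(p, c(1, 1, 2), "none"), "increasing")
})

test_that("gaussian noise has the configured scale", {
  p <- impulse_params(3000, 0.5, 0.3, 85, 100)
  times <- seq(60, 119, length.out = 40)
  mu <- impulse_value(p, times)
  sds <- vapply(1:20, function(seed) {
    s <- gen_impulse_series(p, times, "gaussian", noise_scale = 30,
                            seed = seed)
    sd(s$counts - mu)
  }, numeric(1))
  # rounding and clipping at zero leave the residual scale near 30
  expect_lt(abs(mean(sds) - 30) / 30, 0.25)
})

test_that("default cohort onsets fall in the expected window", {
  coh <- gen_cohort(cohort_config(n_ebs = 50, seed = 4))
  expect_true(all(coh$truth$onset_true > 70 & coh$truth$onset_true < 96))
  # and the realized curves cross 300 points at the designed onsets
  ons <- vapply(seq_len(50), function(i)
    detect_onset(impulse_params(coh$truth$A[i], coh$truth$beta1[i],
                                coh$truth$beta2[i], coh$truth$t1[i],
                                coh$truth$t2[i]), 300), numeric(1))
  expect_equal(ons, coh$truth$onset_true, tolerance = 1e-4)
})

test_that("cohort generation is deterministic given the seed", {
  a <- gen_cohort(cohort_config(n_ebs = 6, seed = 77))
  b <- gen_cohort(cohort_config(n_ebs = 6, seed = 77))
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$series, `[[`, "counts"),
                   lapply(b$series, `[[`, "counts"))
})

test_that("generated onset means match the configured distribution", {
  onsets <- unlist(lapply(1:50, function(seed)
    gen_cohort(cohort_config(n_ebs = 10, seed = seed))$truth$onset_true))
  sem <- 3.7 / sqrt(length(onsets))
  expect_lt(abs(mean(onsets) - 83.3), 3 * sem)
})

test_that("radii respect the truncation bounds and couple to amplitude", {
  coh <- gen_cohort(cohort_config(n_ebs = 60, seed = 12))
  r <- coh$truth$radius_um
  expect_true(all(r >= 81 & r <= 176))
  # amplitude never exceeds its size cap
  expect_true(all(coh$truth$A <= 3e-3 * r^3 + 1e-9))
})

test_that("GFP cap geometry follows the impulse curve", {
  p <- impulse_params(1000, 5, 5, 70, 110)
  locus <- c(1, 0, 0)

  # N = 0 everywhere: clutter only
  p0 <- impulse_params(0, 5, 5, 70, 110)
  fr0 <- gen_point_cloud_series(100, locus, p0, times = c(50, 90),
                                clutter_rate = 10, seed = 1)
  for (f in fr0) {
    d <- sqrt(rowSums(as.matrix(f$points[, 1:3])^2))
    expect_true(all(d > 100 * 1.05))  # nothing on the EB shell
  }

  # full occupancy: cap covers the whole shell (angular extent pi)
  fr1 <- gen_point_cloud_series(100, locus, p, times = 90,
                                clutter_rate = 0, seed = 2)
  u <- as.matrix(fr1[[1]]$points[, 1:3])
  u <- u / sqrt(rowSums(u^2))
  ang <- acos(pmin(pmax(u %*% locus, -1), 1))
  expect_gt(max(ang), 3.0)   # points reach the antipode

  # cap contiguity: all GFP points within the angular radius of the cap
  p_half <- impulse_params(1000, 5, 5, 70, 110)
  fr2 <- gen_point_cloud_series(100, locus, p_half, times = 90,
                                clutter_rate = 0, counts = 250, seed = 3)
  u2 <- as.matrix(fr2[[1]]$points[, 1:3])
  u2 <- u2 / sqrt(rowSums(u2^2))
  ang2 <- acos(pmin(pmax(u2 %*% locus, -1), 1))
  theta <- acos(1 - 2 * 250 / 1000)
  expect_true(all(ang2 <= theta + 1e-6))
})

test_that("rise and decline caps with equal counts share the locus center", {
  # slow rise and decline: pick frames on both flanks with equal N
  p <- impulse_params(1000, 0.5, 0.5, 80, 100)
  t_rise <- detect_onset(p, 400)
  t_fall <- 180 - t_rise          # symmetric curve about t = 90
  expect_equal(impulse_value(p, t_rise), impulse_value(p, t_fall),
               tolerance = 1e-6)
  locus <- c(0, 1, 0)
  frames <- gen_point_cloud_series(100, locus, p,
                                   times = c(t_rise, t_fall),
                                   clutter_rate = 0, seed = 4)
  for (f in frames) {
    u <- as.matrix(f$points[, 1:3])
    centroid <- colMeans(u / sqrt(rowSums(u^2)))
    centroid <- centroid / sqrt(sum(centroid^2))
    expect_lt(acos(sum(centroid * locus)), 0.2)
  }
})

test_that("expression panels invert to the designed -ddCt signal", {
  specs <- list(gene_spec("Rock2", housekeeping = TRUE, noise_sd = 0),
                gene_spec("Ywhaz", housekeeping = TRUE, noise_sd = 0),
                gene_spec("lin", intercept = 2, slope_devA = -0.3,
                          noise_sd = 0))
  devA <- seq(0, 20, length.out = 11)
  gp <- gen_expression_panel(devA, specs, hk_noise_sd = 0, seed = 3)
  norm <- normalize_neg_ddct(gp$panel, c("Rock2", "Ywhaz"))
  expect_equal(norm$neg_ddct, gp$truth$neg_ddct, tolerance = 1e-10)
  # the recovered signal is the designed line, centered on the control
  # median
  line <- 2 - 0.3 * devA
  expect_equal(unname(norm$neg_ddct["lin", ]), line - median(line),
               tolerance = 1e-10)
})

test_that("CHIR presets down-shift Wnt3 expression", {
  groups <- rep(c("control", "chir_long"), each = 12)
  gp <- gen_expression_panel(runif(24, 5, 20), default_gene_panel(),
                             groups = groups, seed = 6)
  norm <- normalize_neg_ddct(gp$panel, c("Rock2", "Ywhaz"))
  w <- norm$neg_ddct["Wnt3", ]
  expect_lt(median(w[groups == "chir_long"]),
            median(w[groups == "control"]))
})

test_that("a 12-cycle expression range is a 4096-fold change", {
  specs <- list(gene_spec("Rock2", housekeeping = TRUE, noise_sd = 0),
                gene_spec("Ywhaz", housekeeping = TRUE, noise_sd = 0),
                gene_spec("wide", intercept = 0, slope_devA = 1,
                          noise_sd = 0))
  gp <- gen_expression_panel(seq(0, 12, length.out = 7), specs,
                             hk_noise_sd = 0, seed = 8)
  norm <- normalize_neg_ddct(gp$panel, c("Rock2", "Ywhaz"))
  expect_equal(fold_range(norm$neg_ddct["wide", ]), 4096)
})

test_that("panel-level errors are caught", {
  specs <- list(gene_spec("Rock2", housekeeping = TRUE),
                gene_spec("Ywhaz", housekeeping = TRUE),
                gene_spec("dup"), gene_spec("dup"))
  expect_error(gen_expression_panel(1:5, specs), "duplicate")
  expect_error(gen_expression_panel(numeric(0), specs[1:3]), "empty")
})

test_that("a two-harvest design yields a 78-EB panel", {
  set.seed(10)
  groups <- rep("control", 78)
  harvest <- c(rep(92, 23), rep(101, 55))
  onset <- rnorm(78, 83.3, 3.7)
  gp <- gen_expression_panel(harvest - onset, default_gene_panel(),
                             groups = groups, harvest_h = harvest,
                             seed = 10)
  expect_identical(ncol(gp$panel$ct), 78L)
})
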